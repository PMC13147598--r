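# Shared helpers: name canonicalisation, timestamp handling, small utilities.

#' Flow stream labels, in hierarchy-independent display order
#' @keywords internal
FS_LEVELS <- c("FS1", "FS2", "FS3", "FS4")

#' Evaluation window labels and their offsets in hours
#' @keywords internal
WINDOW_OFFSETS <- c("24h" = 24, "72h" = 72, "discharge" = Inf)

ENCOUNTER_TYPES <- c("ED", "IP", "OPD", "ITF")
ADMISSION_TYPES <- c("Medical", "Surgical", "Other")
EVENT_TYPES <- c("order", "location_transfer", "icu_entry", "icu_exit",
                 "theatre_emergency", "mtp_activation")
ORDER_SUBTYPES <- c("blood_test", "ct", "mr", "ir", "consult", "group_hold",
                    "medication", "allied_health_consult", "pharmacy_consult",
                    "one_to_one_nursing", "risk_assessment")

#' Canonicalise free-text service/location names
#'
#' Team, ward, consult-target and location strings are matched after trimming,
#' collapsing internal whitespace and case-folding, so that
#' `"General  Medicine "` and `"general medicine"` compare equal. Consult-order
#' naming inconsistency against admitting-team identifiers is a known EMR
#' data-quality problem; canonical matching is the automated stand-in for
#' manual recoding.
#'
#' @param x character vector
#' @return canonicalised character vector
#' @export
#' @examples
#' canon_name(c(" ICU ", "General  Medicine"))
canon_name <- function(x) {
  x <- as.character(x)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Parse timestamps to POSIXct (UTC)
#'
#' Accepts POSIXct input unchanged (coerced to UTC) or character in ISO 8601
#' ("2024-01-02T03:04:00" / "2024-01-02 03:04:00", optional seconds and
#' trailing "Z"). Unparseable values become NA and are handled (excluded and
#' logged) by the cleaning stage.
#'
#' @param x character or POSIXct vector
#' @return POSIXct vector in UTC
#' @export
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out) & !is.na(x))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(x[idx], tz = "UTC", format = fmt)
  }
  out
}

#' Format timestamps as ISO 8601 (UTC, minute resolution kept as seconds)
#' @param x POSIXct vector
#' @return character vector like "2024-01-02T03:04:00Z"
#' @export
format_ts <- function(x) {
  ifelse(is.na(x), NA_character_,
         format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

# numeric seconds -> POSIXct UTC
num_to_ts <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")

# round numeric seconds down to whole minutes (EMR timestamps are minute-level)
floor_minute <- function(x) floor(x / 60) * 60

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

assert_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# truncated log-normal sampler: resample up to 25 times, then clamp
rlnorm_trunc <- function(n, median, sdlog, lower = 0, upper = Inf) {
  meanlog <- log(median)
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) && tries < 25L) {
    x[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lower), upper)
  x
}
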