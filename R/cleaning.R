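# Cleaning: duplicate removal, implausible-row exclusion, format
# standardisation. No imputation — what was not recorded in a structured
# field stays absent ("assumed not collected").

ENC_MANDATORY <- c("mrn", "encounter_type", "start_ts", "end_ts",
                   "admitting_team", "ward")
EV_MANDATORY <- c("mrn", "event_type", "ts")

empty_cleaning_log <- function() {
  data.table::data.table(table = character(), ref = character(),
                         reason = character())
}

clean_entry <- function(table, ref, reason) {
  if (!length(ref)) return(empty_cleaning_log())
  data.table::data.table(table = table, ref = ref, reason = reason)
}

# squish whitespace only; case-folding is silent representation, whitespace
# damage is a logged standardisation
squish <- function(x) gsub("\\s+", " ", trimws(as.character(x)))

standardise_names <- function(dt, cols, table, id_col) {
  logs <- empty_cleaning_log()
  changed <- rep(FALSE, nrow(dt))
  for (col in intersect(cols, names(dt))) {
    old <- as.character(dt[[col]])
    new <- squish(old)
    changed <- changed | (!is.na(old) & new != old)
    data.table::set(dt, j = col, value = tolower(new))
  }
  if (any(changed))
    logs <- clean_entry(table, dt[[id_col]][changed], "format_standardised")
  logs
}

#' Clean raw encounter and event tables
#'
#' Applies the cleaning rules in a fixed order and logs every removed row
#' exactly once:
#'
#' 1. Timestamps are parsed to UTC POSIXct; rows with unparseable timestamps
#'    are excluded (`implausible_excluded`).
#' 2. Service/location strings are standardised (whitespace squished, case
#'    folded); rows whose values needed whitespace repair are logged
#'    (`format_standardised`) but retained.
#' 3. Exact duplicate rows are collapsed to one (`duplicate_removed`).
#' 4. Encounters with negative duration (end before start) are excluded
#'    (`implausible_excluded`).
#'
#' Absent structured values are left absent; nothing is imputed.
#'
#' @param encounters raw encounter table (data.frame/data.table); timestamps
#'   may be POSIXct or ISO 8601 strings
#' @param events raw event table
#' @return list with cleaned `encounters`, `events` and `log`
#'   (table, ref, reason)
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5, seed = 1))
#' cleaned <- clean_events(cohort$encounters, cohort$events)
#' cleaned$log
clean_events <- function(encounters, events) {
  enc <- data.table::as.data.table(encounters)
  ev <- data.table::as.data.table(events)
  assert_columns(enc, ENC_MANDATORY, "encounter table")
  assert_columns(ev, EV_MANDATORY, "event table")
  if (!"encounter_id" %in% names(enc))
    enc[, encounter_id := sprintf("ENCROW%07d", .I)]
  if (!"event_id" %in% names(ev))
    ev[, event_id := sprintf("EVTROW%08d", .I)]
  logs <- list(empty_cleaning_log())

  enc[, `:=`(start_ts = parse_ts(start_ts), end_ts = parse_ts(end_ts))]
  ev[, ts := parse_ts(ts)]

  bad_enc <- which(is.na(enc$start_ts) | is.na(enc$end_ts))
  if (length(bad_enc)) {
    logs <- c(logs, list(clean_entry("encounters",
                                     enc$encounter_id[bad_enc],
                                     "implausible_excluded")))
    enc <- enc[-bad_enc]
  }
  bad_ev <- which(is.na(ev$ts))
  if (length(bad_ev)) {
    logs <- c(logs, list(clean_entry("events", ev$event_id[bad_ev],
                                     "implausible_excluded")))
    ev <- ev[-bad_ev]
  }

  logs <- c(logs, list(
    standardise_names(enc, c("admitting_team", "ward"), "encounters",
                      "encounter_id"),
    standardise_names(ev, c("target_service", "location"), "events",
                      "event_id")))

  dup <- duplicated(enc)
  if (any(dup)) {
    logs <- c(logs, list(clean_entry("encounters", enc$encounter_id[dup],
                                     "duplicate_removed")))
    enc <- enc[!dup]
  }
  dup <- duplicated(ev)
  if (any(dup)) {
    logs <- c(logs, list(clean_entry("events", ev$event_id[dup],
                                     "duplicate_removed")))
    ev <- ev[!dup]
  }

  neg <- which(enc$end_ts < enc$start_ts)
  if (length(neg)) {
    logs <- c(logs, list(clean_entry("encounters", enc$encounter_id[neg],
                                     "implausible_excluded")))
    enc <- enc[-neg]
  }

  list(encounters = enc[], events = ev[],
       log = data.table::rbindlist(logs))
}
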