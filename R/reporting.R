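# Stratified cohort summaries, source-by-stream cross-tabulation and the
# data-quality report.

med_iqr <- function(x, type) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
  stats::quantile(x, c(0.5, 0.25, 0.75), type = type, names = FALSE)
}

fmt_med_iqr <- function(q, digits = 1) {
  if (any(is.na(q))) return(NA_character_)
  sprintf("%.*f (%.*f, %.*f)", digits, q[1], digits, q[2], digits, q[3])
}

#' Stratified stream summary
#'
#' One row per flow stream plus an overall row: n, age median (IQR), % female,
#' LOS days median (IQR), admission-type counts and percentages, ICU admission
#' %, polypharmacy %, allied-health and medical-consult medians (IQR).
#' Medians and IQRs use the quartile definition in `rules$quartile_type`
#' (default: linear interpolation). Mental-health admissions, when present,
#' are excluded from the admission-type block only, never from
#' classification. Empty streams yield an n = 0 row with absent statistics.
#'
#' @param episodes de-identified episode table
#' @param assignments discharge-window assignments ([classify_features()])
#' @param features discharge-window features ([derive_features()])
#' @param rules a [rule_config()]
#' @param exclude_admission_types admission types excluded from the
#'   admission-type block (default "Mental Health")
#' @return data.table, one row per stream and an "Overall" row
#' @export
#' @examples
#' run <- run_pipeline(cohort_config(n_patients = 50, seed = 1),
#'                     defects = defects_off())
#' run$stream_summary[, .(stream, n, los_days_median_iqr)]
summarize_streams <- function(episodes, assignments, features,
                              rules = rule_config(),
                              exclude_admission_types = "Mental Health") {
  ep <- data.table::as.data.table(episodes)
  asg <- data.table::as.data.table(assignments)
  ft <- data.table::as.data.table(features)
  asg <- asg[window == "discharge", .(episode_id, stream)]
  ft <- ft[window == "discharge"]
  if (!all(ep$episode_id %in% asg$episode_id))
    stop("every episode needs a discharge-window assignment", call. = FALSE)
  d <- merge(merge(ep, asg, by = "episode_id"),
             ft[, .(episode_id, los_days_observed, icu_hours_cumulative,
                    polypharmacy_flag, n_allied_health, n_consults_total)],
             by = "episode_id")
  qt <- rules$quartile_type

  one <- function(dd, label) {
    n <- nrow(dd)
    age_q <- med_iqr(dd$age, qt)
    los_q <- med_iqr(dd$los_days_observed, qt)
    ah_q <- med_iqr(dd$n_allied_health, qt)
    co_q <- med_iqr(dd$n_consults_total, qt)
    at <- dd[!admission_type %in% exclude_admission_types]
    at_n <- vapply(ADMISSION_TYPES,
                   function(a) sum(at$admission_type == a), integer(1))
    data.table::data.table(
      stream = label, n = n,
      age_median_iqr = fmt_med_iqr(age_q, 0),
      pct_female = if (n) round(100 * mean(dd$gender == "female"), 1)
        else NA_real_,
      los_days_median_iqr = fmt_med_iqr(los_q),
      los_days_median = los_q[1],
      n_medical = at_n[["Medical"]], n_surgical = at_n[["Surgical"]],
      n_other = at_n[["Other"]],
      pct_medical = if (nrow(at)) round(100 * at_n[["Medical"]] / nrow(at), 1)
        else NA_real_,
      pct_surgical = if (nrow(at)) round(100 * at_n[["Surgical"]] / nrow(at), 1)
        else NA_real_,
      pct_other = if (nrow(at)) round(100 * at_n[["Other"]] / nrow(at), 1)
        else NA_real_,
      pct_icu = if (n) round(100 * mean(dd$icu_hours_cumulative > 0), 1)
        else NA_real_,
      pct_polypharmacy = if (n) round(100 * mean(dd$polypharmacy_flag), 1)
        else NA_real_,
      allied_health_median_iqr = fmt_med_iqr(ah_q),
      consults_median_iqr = fmt_med_iqr(co_q)
    )
  }
  rows <- lapply(FS_LEVELS, function(s) one(d[stream == s], s))
  res <- data.table::rbindlist(c(list(one(d, "Overall")), rows))
  res[]
}

#' Source-by-stream cross-tabulation
#'
#' Counts of admission episodes by admission source (ED/OPD/IP/ITF) and
#' discharge-window flow stream.
#'
#' @param episodes de-identified episode table carrying `admission_source`
#' @param assignments discharge-window assignments
#' @return 4 x 4 integer matrix (source x stream); margins sum to the cohort
#' @export
source_by_stream <- function(episodes, assignments) {
  ep <- data.table::as.data.table(episodes)
  asg <- data.table::as.data.table(assignments)
  asg <- asg[window == "discharge", .(episode_id, stream)]
  d <- merge(ep[, .(episode_id, admission_source)], asg, by = "episode_id")
  bad <- setdiff(unique(d$admission_source), ENCOUNTER_TYPES)
  if (length(bad))
    stop(sprintf("unknown admission source code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  tab <- table(factor(d$admission_source, levels = ENCOUNTER_TYPES),
               factor(d$stream, levels = FS_LEVELS))
  matrix(as.integer(tab), 4, 4, dimnames = list(ENCOUNTER_TYPES, FS_LEVELS))
}

#' Data-quality report
#'
#' Reproducible quality metrics for one pipeline run:
#'
#' * `problem_list_completeness`: structured problem-list population rate
#'   over cleaned encounters;
#' * `self_consult_count` / `self_consult_rate`: consult orders whose target
#'   equals the episode's admitting team, and their share of all consults;
#' * `duplicate_rows_removed`, `implausible_rows_removed`: cleaning-log
#'   counts;
#' * `mtp_recorded` and, when an external reference count is supplied,
#'   `mtp_reference` and `mtp_ratio` (recorded / reference; absent when the
#'   reference is missing or zero);
#' * `demographic_inconsistencies`: episodes whose recorded accommodation
#'   differs from the patient's latest snapshot — visible drift that
#'   client-level overwriting would have erased.
#'
#' @param cleaned output of [clean_events()] (uses `encounters` and `log`)
#' @param episodes de-identified episode table
#' @param events de-identified, episode-keyed event table
#' @param reference_counts optional named numeric vector of external
#'   reference counts, e.g. `c(mtp_activation = 355)`
#' @return named list of quality metrics
#' @export
quality_report <- function(cleaned, episodes, events,
                           reference_counts = NULL) {
  enc <- data.table::as.data.table(cleaned$encounters)
  lg <- data.table::as.data.table(cleaned$log)
  ep <- data.table::as.data.table(episodes)
  ev <- data.table::as.data.table(events)

  completeness <- if ("problem_list_populated" %in% names(enc) && nrow(enc))
    mean(enc$problem_list_populated) else NA_real_

  n_consults <- 0L
  n_self <- 0L
  if (nrow(ev)) {
    con <- merge(ev[event_type == "order" & order_subtype == "consult",
                    .(episode_id, target = canon_name(target_service))],
                 ep[, .(episode_id, team = canon_name(admitting_team))],
                 by = "episode_id")
    n_consults <- nrow(con)
    n_self <- con[!is.na(target) & target != "" & target == team, .N]
  }

  mtp_recorded <- if (nrow(ev)) ev[event_type == "mtp_activation", .N] else 0L
  mtp_reference <- if (!is.null(reference_counts) &&
                       "mtp_activation" %in% names(reference_counts))
    unname(reference_counts[["mtp_activation"]]) else NA_real_
  mtp_ratio <- if (is.na(mtp_reference) || mtp_reference <= 0) NA_real_
               else mtp_recorded / mtp_reference

  demo_inconsistent <- 0L
  if (nrow(ep) && "usual_accommodation" %in% names(ep)) {
    latest <- ep[order(study_id, -as.numeric(discharge_ts)),
                 .SD[1], by = study_id][, .(study_id,
                                            latest_acc = usual_accommodation)]
    demo_inconsistent <- merge(ep, latest, by = "study_id")[
      usual_accommodation != latest_acc, .N]
  }

  list(
    problem_list_completeness = completeness,
    self_consult_count = n_self,
    self_consult_rate = if (n_consults) n_self / n_consults else NA_real_,
    duplicate_rows_removed = lg[reason == "duplicate_removed", .N],
    implausible_rows_removed = lg[reason == "implausible_excluded", .N],
    format_standardised_rows = lg[reason == "format_standardised", .N],
    mtp_recorded = mtp_recorded,
    mtp_reference = mtp_reference,
    mtp_ratio = mtp_ratio,
    demographic_inconsistencies = demo_inconsistent
  )
}
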