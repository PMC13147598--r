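# Deterministic episode-of-care linkage and de-identification.

#' Link cleaned encounters and events into admission episodes
#'
#' For each patient (MRN), encounters are sorted by start time and merged
#' transitively: a new episode starts whenever the gap between an encounter's
#' start and the running maximum end of the previous encounters exceeds
#' `gap_threshold_hours`. Events are attached to the episode whose overall
#' time span (first encounter start to last encounter end, inclusive)
#' contains them. Events whose MRN is absent from the encounter table, or
#' whose timestamp falls outside every episode span, are excluded as orphans
#' with a warning.
#'
#' Episode fields: `admission_ts` is the earliest non-ED encounter start
#' (falling back to the earliest start for ED-only episodes), `discharge_ts`
#' the latest end, `admission_source` the type of the earliest encounter, and
#' demographics are taken from the earliest encounter snapshot, which
#' minimises exposure to retrospective client-level overwrites.
#'
#' @param encounters cleaned encounter table (see [clean_events()])
#' @param events cleaned event table
#' @param gap_threshold_hours time-based linkage threshold (default 6 h)
#' @return list with `episodes`, `events` (episode-keyed) and `orphans`
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5, seed = 1))
#' cleaned <- clean_events(cohort$encounters, cohort$events)
#' linked <- link_episodes(cleaned$encounters, cleaned$events)
#' linked$episodes[, .(mrn, episode_no, admission_ts, discharge_ts)]
link_episodes <- function(encounters, events, gap_threshold_hours = 6) {
  if (!is.numeric(gap_threshold_hours) || gap_threshold_hours <= 0)
    stop("gap_threshold_hours must be > 0", call. = FALSE)
  enc <- data.table::as.data.table(encounters)
  ev <- data.table::as.data.table(events)
  thr <- gap_threshold_hours * 3600

  if (nrow(enc) == 0L) {
    return(list(episodes = data.table::data.table(), events = ev[0],
                orphans = ev))
  }

  # canonical order makes linkage invariant to input row permutation
  data.table::setorder(enc, mrn, start_ts, end_ts, encounter_id)
  enc[, run_end := data.table::shift(cummax(as.numeric(end_ts))), by = mrn]
  enc[, new_ep := is.na(run_end) | (as.numeric(start_ts) - run_end > thr)]
  enc[, episode_no := cumsum(new_ep), by = mrn]
  enc[, c("run_end", "new_ep") := NULL]

  episodes <- enc[, {
    o <- order(start_ts, encounter_id)
    first <- o[1]
    non_ed <- which(encounter_type != "ED")
    adm_i <- if (length(non_ed)) non_ed[which.min(start_ts[non_ed])] else first
    list(
      span_start = min(start_ts),
      span_end = max(end_ts),
      admission_ts = start_ts[adm_i],
      discharge_ts = max(end_ts),
      admission_source = encounter_type[first],
      admission_type = if ("admission_type" %in% names(.SD))
        admission_type[adm_i] else NA_character_,
      admitting_team = admitting_team[adm_i],
      ward = ward[adm_i],
      age = if ("age" %in% names(.SD)) age[first] else NA_real_,
      gender = if ("gender" %in% names(.SD)) gender[first] else NA_character_,
      postcode = if ("postcode" %in% names(.SD)) postcode[first]
        else NA_character_,
      usual_accommodation = if ("usual_accommodation" %in% names(.SD))
        usual_accommodation[first] else NA_character_,
      day_procedure_flag = if ("day_procedure_flag" %in% names(.SD))
        any(day_procedure_flag) else FALSE,
      problem_list_populated = if ("problem_list_populated" %in% names(.SD))
        any(problem_list_populated) else NA,
      n_encounters = .N
    )
  }, by = .(mrn, episode_no)]

  # attach events to the episode whose span contains them
  if (nrow(ev)) {
    spans <- episodes[, .(mrn, episode_no,
                          s = as.numeric(span_start), e = as.numeric(span_end))]
    ev[, ts_num := as.numeric(ts)]
    ev <- spans[ev, on = .(mrn, s <= ts_num, e >= ts_num),
                mult = "first",
                .(event_id = i.event_id, mrn = i.mrn, episode_no = x.episode_no,
                  event_type = i.event_type, order_subtype = i.order_subtype,
                  ts = i.ts, target_service = i.target_service,
                  location = i.location, structured_flag = i.structured_flag)]
    orphans <- ev[is.na(episode_no)]
    if (nrow(orphans)) {
      warning(sprintf(
        "%d event(s) could not be attached to any episode and were excluded",
        nrow(orphans)), call. = FALSE)
      ev <- ev[!is.na(episode_no)]
    }
    data.table::setorder(ev, mrn, episode_no, ts, event_id)
  } else {
    orphans <- ev[0]
  }

  data.table::setorder(episodes, mrn, episode_no)
  list(episodes = episodes[], events = ev[], orphans = orphans)
}

#' De-identify linked episodes
#'
#' Replaces MRNs with opaque study identifiers. Assignment is by sorted MRN,
#' so it is invariant to input row order; the same MRN always maps to the
#' same study identifier. The identity map is returned separately and must be
#' stored apart from the analytical dataset.
#'
#' @param episodes episode table carrying `mrn` (from [link_episodes()])
#' @param events episode-keyed event table carrying `mrn`
#' @return list with de-identified `episodes` (keyed by `episode_id` and
#'   `study_id`, no `mrn`), `events`, and `identity_map` (mrn, study_id)
#' @export
deidentify <- function(episodes, events) {
  ep <- data.table::as.data.table(episodes)
  ev <- data.table::as.data.table(events)
  assert_columns(ep, c("mrn", "episode_no"), "episode table")
  mrns <- sort(unique(ep$mrn))
  map <- data.table::data.table(mrn = mrns,
                                study_id = sprintf("SID%06d", seq_along(mrns)))
  if (anyDuplicated(map$study_id))
    stop("study_id collision during de-identification", call. = FALSE)
  ep <- merge(ep, map, by = "mrn", sort = FALSE)
  ep[, episode_id := sprintf("%s-E%d", study_id, episode_no)]
  ep[, mrn := NULL]
  data.table::setcolorder(ep, c("episode_id", "study_id", "episode_no"))
  if (nrow(ev)) {
    ev <- merge(ev, map, by = "mrn", sort = FALSE)
    ev[, episode_id := sprintf("%s-E%d", study_id, episode_no)]
    ev[, mrn := NULL]
    data.table::setcolorder(ev, c("episode_id", "study_id"))
    data.table::setorder(ev, episode_id, ts, event_id)
  } else {
    ev <- ev[, c(list(episode_id = character(), study_id = character()),
                 .SD)][0]
    ev[, mrn := NULL]
  }
  data.table::setorder(ep, study_id, episode_no)
  list(episodes = ep[], events = ev[], identity_map = map)
}

#' Re-identify a de-identified table via the identity map
#'
#' The controlled inverse of [deidentify()]: joins `study_id` back to `mrn`.
#'
#' @param x de-identified table carrying `study_id`
#' @param identity_map the map returned by [deidentify()]
#' @return `x` with an `mrn` column restored
#' @export
reidentify <- function(x, identity_map) {
  x <- data.table::as.data.table(x)
  assert_columns(x, "study_id", "de-identified table")
  merge(x, identity_map, by = "study_id", sort = FALSE)
}
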