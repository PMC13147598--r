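# Documentation-defect injection: duplicates, negative durations,
# self-consults, bypassed structured fields, demographic overwrites and
# under-reported high-acuity events.

empty_defect_log <- function() {
  data.table::data.table(kind = character(), table = character(),
                         ref = character(), detail = character())
}

defect_entry <- function(kind, table, ref, detail = "") {
  data.table::data.table(kind = kind, table = table, ref = ref,
                         detail = detail)
}

#' Inject documentation defects into synthetic EMR tables
#'
#' Emulates the defect catalogue seen in real EMR extracts. Every injected
#' defect is logged exactly once against the row (or patient) it touched:
#'
#' * `duplicate`: verbatim copies of sampled event rows are appended.
#' * `negative_duration`: sampled encounters get an end before their start.
#' * `self_consult`: sampled episodes receive, at admission, a consult order
#'   whose target service is the episode's own admitting team.
#' * `missing_problem_list`: the structured problem-list field of sampled
#'   encounters is blanked (populated = FALSE).
#' * `demographic_overwrite`: the patient's demographics are changed on the
#'   latest encounter and copied back over all earlier encounters, emulating
#'   client-level (not admission-level) storage.
#' * `mtp_removed`: massive-transfusion-pack events are deleted, emulating
#'   high-acuity under-reporting against an external reference.
#'
#' @param tables list with `encounters` and `events` data.tables as produced
#'   by [generate_cohort()]
#' @param defects a [defect_config()]
#' @param seed base seed; the defect substream uses `seed + seed_offset`
#' @return list with modified `encounters`, `events` and `defect_log`
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 1))
#' out <- inject_defects(cohort[c("encounters", "events")],
#'                       defect_config(), seed = 1)
#' out$defect_log
inject_defects <- function(tables, defects, seed = 1L) {
  stopifnot(inherits(defects, "flow_defect_config"))
  enc <- data.table::copy(tables$encounters)
  ev <- data.table::copy(tables$events)
  assert_columns(enc, names(empty_encounters()), "encounter table")
  assert_columns(ev, names(empty_events()), "event table")
  log <- list(empty_defect_log())
  set.seed(as.integer((as.double(seed) + defects$seed_offset) %% 2147483629))

  # high-acuity under-reporting first, so removals can never interact with
  # duplicated rows and defect counts stay exactly reconcilable
  if (defects$high_acuity_underreport_fraction > 0 && nrow(ev)) {
    mtp <- which(ev$event_type == "mtp_activation")
    drop <- mtp[stats::runif(length(mtp)) <
                  defects$high_acuity_underreport_fraction]
    if (length(drop)) {
      log <- c(log, list(defect_entry("mtp_removed", "events",
                                      ev$event_id[drop])))
      ev <- ev[-drop]
    }
  }

  # duplicates: exact row copies (same event_id), so the cleaning stage can
  # collapse them and the log count is exactly recoverable
  if (defects$duplicate_rate > 0 && nrow(ev)) {
    idx <- which(stats::runif(nrow(ev)) < defects$duplicate_rate)
    if (length(idx)) {
      log <- c(log, list(defect_entry("duplicate", "events",
                                      ev$event_id[idx])))
      ev <- data.table::rbindlist(list(ev, ev[idx]))
    }
  }

  if (defects$negative_duration_rate > 0 && nrow(enc)) {
    idx <- which(stats::runif(nrow(enc)) < defects$negative_duration_rate)
    if (length(idx)) {
      enc[idx, end_ts := start_ts - round(stats::runif(.N, 1, 48)) * 3600]
      log <- c(log, list(defect_entry("negative_duration", "encounters",
                                      enc$encounter_id[idx])))
    }
  }

  # self-consults: entered by the admitting team for its own service as part
  # of the admission process (at most one per inpatient encounter)
  if (defects$self_consult_rate > 0 && nrow(enc)) {
    ip <- enc[encounter_type != "ED"]
    idx <- which(stats::runif(nrow(ip)) < defects$self_consult_rate)
    if (length(idx)) {
      rows <- ip[idx]
      new_ev <- data.table::data.table(
        event_id = sprintf("EVTSC%05d", seq_along(idx)),
        mrn = rows$mrn, event_type = "order", order_subtype = "consult",
        ts = rows$start_ts + 1800, target_service = rows$admitting_team,
        location = "", structured_flag = TRUE)
      ev <- data.table::rbindlist(list(ev, new_ev))
      log <- c(log, list(defect_entry("self_consult", "events",
                                      new_ev$event_id,
                                      detail = rows$admitting_team)))
    }
  }

  pl_rate <- defects$missing_structured_field_rate[["problem_list"]] %||% 0
  if (pl_rate > 0 && nrow(enc)) {
    idx <- which(stats::runif(nrow(enc)) < pl_rate)
    if (length(idx)) {
      enc[idx, problem_list_populated := FALSE]
      log <- c(log, list(defect_entry("missing_problem_list", "encounters",
                                      enc$encounter_id[idx])))
    }
  }

  if (defects$demographic_overwrite_rate > 0 && nrow(enc)) {
    pts <- unique(enc$mrn)
    hit <- pts[stats::runif(length(pts)) < defects$demographic_overwrite_rate]
    if (length(hit)) {
      for (m in hit) {
        rows <- which(enc$mrn == m)
        new_acc <- sample(setdiff(ACCOMMODATION_POOL,
                                  enc$usual_accommodation[rows[1]]), 1)
        enc[rows, usual_accommodation := new_acc]
      }
      log <- c(log, list(defect_entry("demographic_overwrite", "encounters",
                                      hit)))
    }
  }

  list(encounters = enc[], events = ev[],
       defect_log = data.table::rbindlist(log))
}

#' Simulate a full synthetic EMR extract
#'
#' Convenience wrapper: [generate_cohort()] followed by [inject_defects()],
#' returning the defect-injected tables together with the merged truth log.
#'
#' @param config a [cohort_config()]
#' @param defects a [defect_config()]; use [defects_off()] for a clean extract
#' @return list with `encounters`, `events` and `truth` (patients, defects,
#'   mtp_true_count)
#' @export
simulate_emr <- function(config, defects = defect_config()) {
  cohort <- generate_cohort(config)
  out <- inject_defects(cohort[c("encounters", "events")], defects,
                        seed = config$seed)
  truth <- cohort$truth
  truth$defects <- out$defect_log
  list(encounters = out$encounters, events = out$events, truth = truth)
}
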