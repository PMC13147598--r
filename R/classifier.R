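# Hierarchical flow-stream classification: FS1, then FS4, then FS2, FS3
# residual. Single-row rule functions return a criteria trace; a vectorised
# path classifies whole feature tables.

trace_row <- function(criterion, satisfied) {
  data.table::data.table(criterion = criterion, satisfied = satisfied)
}

#' FS1 rule: concluded short stay, scheduled day care
#'
#' Satisfied iff the episode is discharged within the window, the concluded
#' length of stay is under `fs1_los_hours`, and (when required) the
#' day-procedure flag is set. An episode still admitted at an interim window
#' cannot satisfy FS1 because its length of stay is not concluded.
#'
#' @param features one feature row (list or single-row data.frame) from
#'   [derive_features()]
#' @param rules a [rule_config()]
#' @return list with `met` (logical) and `trace` (criterion, satisfied)
#' @export
meets_fs1 <- function(features, rules = rule_config()) {
  f <- as.list(features)
  discharged <- isTRUE(f$discharged_within_window)
  los_ok <- discharged && f$los_days_observed * 24 < rules$fs1_los_hours
  dp_ok <- !rules$fs1_require_day_procedure || isTRUE(f$day_procedure_flag)
  trace <- rbind(trace_row("fs1_discharged", discharged),
                 trace_row("fs1_los_lt_bound", los_ok),
                 trace_row("fs1_day_procedure", dp_ok))
  list(met = discharged && los_ok && dp_ok, trace = trace)
}

#' FS2 rule: single-specialty admission
#'
#' Satisfied iff external consults and total consults are within their bounds
#' and the length-of-stay bound is not violated. The LOS bound is assessed
#' dynamically: while the admission is still open, it counts as provisionally
#' satisfied so long as the stay observed so far is under `fs2_los_days`.
#'
#' @inheritParams meets_fs1
#' @return list with `met` and `trace`
#' @export
meets_fs2 <- function(features, rules = rule_config()) {
  f <- as.list(features)
  c_ext <- f$n_consults_external <= rules$fs2_max_external_consults
  c_tot <- f$n_consults_total <= rules$fs2_max_total_consults
  los_ok <- f$los_days_observed < rules$fs2_los_days
  trace <- rbind(trace_row("fs2_external_consults", c_ext),
                 trace_row("fs2_total_consults", c_tot),
                 trace_row("fs2_los_not_violated", los_ok))
  list(met = c_ext && c_tot && los_ok, trace = trace)
}

#' FS4 rule: hypercomplex, high-acuity admission
#'
#' Six criteria, combined as a disjunction by default (`fs4_combination =
#' "any"`) or as k-of-n: (a) cumulative ICU hours at or above
#' `fs4_icu_hours`; (b) presence in a critical location; (c) emergency
#' theatre; (d) treatment intensity — at least one CT/MR and at least
#' `fs4_min_bloods` blood tests; (e) group-and-hold ordered; (f) an
#' admission-anchored first-24 h surge: at least `fs4_min_consults_24h`
#' medical consults or at least `fs4_min_transfers_24h` intra-hospital
#' transfers within 24 h of admission. Individual criteria can be disabled
#' via `fs4_criteria`.
#'
#' @inheritParams meets_fs1
#' @return list with `met` and `trace` (each evaluated criterion)
#' @export
meets_fs4 <- function(features, rules = rule_config()) {
  f <- as.list(features)
  crit <- c(
    icu = f$icu_hours_cumulative >= rules$fs4_icu_hours,
    critical_location = isTRUE(f$critical_location_flag),
    emergency_theatre = isTRUE(f$emergency_theatre_flag),
    treatment_intensity = f$n_ct_mr >= 1 && f$n_bloods >= rules$fs4_min_bloods,
    group_hold = isTRUE(f$group_hold_flag),
    surge_24h = f$n_consults_first24h >= rules$fs4_min_consults_24h ||
      f$n_transfers_first24h >= rules$fs4_min_transfers_24h
  )
  enabled <- names(which(rules$fs4_criteria))
  n_met <- sum(crit[enabled])
  met <- if (rules$fs4_combination == "any") n_met >= 1L
         else n_met >= rules$fs4_min_criteria
  trace <- trace_row(paste0("fs4_", enabled), unname(crit[enabled]))
  list(met = met, trace = trace)
}

#' Assign a flow stream to one feature row
#'
#' Evaluates the rule sets in the configured hierarchy order (default FS1,
#' FS4, FS2) and returns the first satisfied stream; FS3 is the residual. The
#' trace concatenates the criteria actually evaluated, so an FS3 assignment
#' shows FS1, FS4 and FS2 all unsatisfied.
#'
#' @inheritParams meets_fs1
#' @return list with `stream`, `trace`
#' @export
#' @examples
#' run <- run_pipeline(cohort_config(n_patients = 5, seed = 1),
#'                     defects = defects_off())
#' assign_stream(run$features[window == "discharge"][1])
assign_stream <- function(features, rules = rule_config()) {
  fns <- list(FS1 = meets_fs1, FS2 = meets_fs2, FS4 = meets_fs4)
  traces <- list()
  for (s in rules$hierarchy) {
    if (s == "FS3") break
    r <- fns[[s]](features, rules)
    traces <- c(traces, list(r$trace))
    if (r$met) {
      return(list(stream = s, trace = data.table::rbindlist(traces)))
    }
  }
  list(stream = "FS3", trace = data.table::rbindlist(traces))
}

#' Vectorised classification of a feature table
#'
#' Identical semantics to [assign_stream()], applied to every row at once.
#'
#' @param features feature table from [derive_features()]
#' @param rules a [rule_config()]
#' @return the feature table's (episode_id, study_id, window) keys with a
#'   `stream` column and a compact `trace` string
#' @export
classify_features <- function(features, rules = rule_config()) {
  f <- data.table::as.data.table(features)
  if (nrow(f) == 0L) {
    return(data.table::data.table(episode_id = character(),
                                  study_id = character(), window = character(),
                                  stream = character(), trace = character()))
  }
  fs1 <- f$discharged_within_window &
    (f$los_days_observed * 24 < rules$fs1_los_hours) &
    (!rules$fs1_require_day_procedure | f$day_procedure_flag)
  fs2 <- (f$n_consults_external <= rules$fs2_max_external_consults) &
    (f$n_consults_total <= rules$fs2_max_total_consults) &
    (f$los_days_observed < rules$fs2_los_days)
  crit <- cbind(
    icu = f$icu_hours_cumulative >= rules$fs4_icu_hours,
    critical_location = f$critical_location_flag,
    emergency_theatre = f$emergency_theatre_flag,
    treatment_intensity = (f$n_ct_mr >= 1) & (f$n_bloods >= rules$fs4_min_bloods),
    group_hold = f$group_hold_flag,
    surge_24h = (f$n_consults_first24h >= rules$fs4_min_consults_24h) |
      (f$n_transfers_first24h >= rules$fs4_min_transfers_24h)
  )
  enabled <- names(which(rules$fs4_criteria))
  n_met <- rowSums(crit[, enabled, drop = FALSE])
  fs4 <- if (rules$fs4_combination == "any") n_met >= 1L
         else n_met >= rules$fs4_min_criteria
  met <- list(FS1 = fs1, FS2 = fs2, FS4 = fs4)

  stream <- rep("FS3", nrow(f))
  undecided <- rep(TRUE, nrow(f))
  for (s in rules$hierarchy) {
    if (s == "FS3") break
    take <- undecided & met[[s]]
    stream[take] <- s
    undecided <- undecided & !met[[s]]
  }
  trace <- sprintf("fs1:%d;fs4:%d;fs2:%d", as.integer(fs1), as.integer(fs4),
                   as.integer(fs2))
  out <- f[, .(episode_id, study_id, window)]
  out[, `:=`(stream = stream, trace = trace)]
  out[]
}

#' Classify trajectories across the three evaluation windows
#'
#' Derives features at 24 h, 72 h and discharge, classifies each window, and
#' returns one record per episode with the three labels and a `changed` flag.
#' Because the rule inputs are monotone counters and the interim LOS bound is
#' provisional, labels can only move toward higher resource intensity; an FS1
#' episode that escalates is reclassified directly into the stream its
#' resource profile now satisfies (per-window re-evaluation, no FS1-internal
#' transitions).
#'
#' @param episodes de-identified episode table
#' @param events de-identified, episode-keyed event table
#' @param rules a [rule_config()]
#' @return list with `trajectories` (episode_id, study_id, stream_24h,
#'   stream_72h, stream_discharge, changed), `assignments` (long form with
#'   traces) and `features`
#' @export
classify_trajectories <- function(episodes, events, rules = rule_config()) {
  features <- derive_features(episodes, events, rules)
  assignments <- classify_features(features, rules)
  wide <- data.table::dcast(assignments, episode_id + study_id ~ window,
                            value.var = "stream")
  data.table::setnames(wide, c("24h", "72h", "discharge"),
                       c("stream_24h", "stream_72h", "stream_discharge"))
  wide[, changed := !(stream_24h == stream_72h &
                        stream_72h == stream_discharge)]
  data.table::setorder(wide, episode_id)
  list(trajectories = wide[], assignments = assignments, features = features)
}

#' Transition counts between two evaluation windows
#'
#' @param trajectories trajectory table from [classify_trajectories()]
#' @param from,to window labels ("24h", "72h", "discharge")
#' @return 4 x 4 integer matrix (rows = `from` stream, columns = `to` stream);
#'   row sums equal the `from` window stream counts and the grand total the
#'   cohort size
#' @export
transition_table <- function(trajectories, from = "24h", to = "72h") {
  cols <- c("24h" = "stream_24h", "72h" = "stream_72h",
            "discharge" = "stream_discharge")
  from <- match.arg(from, names(cols))
  to <- match.arg(to, names(cols))
  tr <- data.table::as.data.table(trajectories)
  if (nrow(tr) == 0L) {
    m <- matrix(0L, 4, 4, dimnames = list(FS_LEVELS, FS_LEVELS))
    return(m)
  }
  tab <- table(factor(tr[[cols[from]]], levels = FS_LEVELS),
               factor(tr[[cols[to]]], levels = FS_LEVELS))
  m <- matrix(as.integer(tab), 4, 4, dimnames = list(FS_LEVELS, FS_LEVELS))
  m
}

#' Percentage of episodes that changed stream during admission
#'
#' @param trajectories trajectory table from [classify_trajectories()]
#' @return `100 * #changed / #total`
#' @export
percent_reclassified <- function(trajectories) {
  tr <- data.table::as.data.table(trajectories)
  if (nrow(tr) == 0L)
    stop("percent_reclassified is undefined for an empty trajectory table",
         call. = FALSE)
  100 * sum(tr$changed) / nrow(tr)
}
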