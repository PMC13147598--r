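# Resource-utilisation features per (episode, evaluation window).

#' Evaluation windows
#'
#' Windows end at `min(admission_ts + offset, discharge_ts)` with offsets of
#' 24 h, 72 h and infinity (discharge). Only events strictly before the
#' window end are counted, so features are monotone non-decreasing across the
#' nested windows.
#'
#' @return named numeric vector of offsets in hours
#' @export
evaluation_windows <- function() WINDOW_OFFSETS

# Pair icu_entry/icu_exit events per episode into intervals (numeric secs).
# An entry with no exit is an open stay (end = NA, clipped at each window
# end); an exit with no preceding entry is a documentation defect and is
# ignored. Returns list(pairs = data.table(episode_id, s, e),
# n_unpaired_exits).
pair_icu_intervals <- function(events) {
  icu <- events[event_type %in% c("icu_entry", "icu_exit"),
                .(episode_id, event_type, ts_num = as.numeric(ts))]
  if (nrow(icu) == 0L) {
    return(list(pairs = data.table::data.table(episode_id = character(),
                                               s = numeric(), e = numeric()),
                n_unpaired_exits = 0L))
  }
  data.table::setorder(icu, episode_id, ts_num, event_type)
  bad <- 0L
  pairs <- icu[, {
    s <- numeric(); e <- numeric(); open <- NA_real_
    for (k in seq_len(.N)) {
      if (event_type[k] == "icu_entry") {
        if (!is.na(open)) { # entry while open: close previous at new entry
          s <- c(s, open); e <- c(e, ts_num[k])
        }
        open <- ts_num[k]
      } else {
        if (is.na(open)) {
          bad <<- bad + 1L # unpaired exit, ignored
        } else {
          s <- c(s, open); e <- c(e, ts_num[k]); open <- NA_real_
        }
      }
    }
    if (!is.na(open)) { s <- c(s, open); e <- c(e, NA_real_) }
    list(s = s, e = e)
  }, by = episode_id]
  list(pairs = pairs, n_unpaired_exits = bad)
}

#' Count medical consults for one episode
#'
#' A medical consult is a structured consult order. Consults whose target
#' service equals the episode's admitting team (after name canonicalisation)
#' are self-consults and are excluded from the external count when
#' `exclude_self` is TRUE. Consults with an empty target service cannot be
#' attributed and count toward the total only. Allied health and pharmacy
#' consults are never medical consults.
#'
#' @param events one episode's event table
#' @param admitting_team the episode's admitting team
#' @param end_ts window end; only consults with `ts < end_ts` are counted
#' @param exclude_self drop self-consults from the external count
#' @return list with `n_external`, `n_total`, `n_unattributed`
#' @export
count_consults <- function(events, admitting_team, end_ts,
                           exclude_self = TRUE) {
  ev <- data.table::as.data.table(events)
  con <- ev[event_type == "order" & order_subtype == "consult" &
              as.numeric(ts) < as.numeric(parse_ts(end_ts))]
  tgt <- canon_name(con$target_service)
  team <- canon_name(admitting_team)
  unattributed <- is.na(tgt) | tgt == ""
  self <- !unattributed & tgt == team
  n_total <- nrow(con)
  n_external <- sum(!unattributed & (!self | !exclude_self))
  list(n_external = n_external, n_total = n_total,
       n_unattributed = sum(unattributed))
}

#' Derive resource-utilisation features per episode and window
#'
#' For every episode and requested evaluation window this computes the
#' feature set consumed by the flow-stream classifier and the summary
#' reports. Conventions:
#'
#' * only events with `ts < end_ts` are counted (window end is
#'   `min(admission_ts + offset, discharge_ts)`);
#' * `los_days_observed` is the concluded length of stay when the episode is
#'   discharged within the window, else time observed so far;
#' * `icu_hours_cumulative` sums paired ICU entry/exit intervals clipped to
#'   the window; an open ICU stay is clipped at the window end;
#' * "within 24 h" counters (`n_consults_first24h`, `n_transfers_first24h`)
#'   are anchored to `[admission_ts, admission_ts + 24 h)` regardless of the
#'   evaluation window;
#' * `polypharmacy_flag` is `n_medications >= polypharmacy_threshold`
#'   (summary use only, never classification).
#'
#' @param episodes de-identified episode table ([deidentify()])
#' @param events de-identified, episode-keyed event table
#' @param rules a [rule_config()] (critical-location set, polypharmacy
#'   threshold)
#' @param windows subset of `c("24h", "72h", "discharge")`
#' @return data.table with one row per (episode_id, window); the number of
#'   unpaired ICU exits encountered is attached as attribute
#'   `n_unpaired_icu_exits`
#' @export
#' @examples
#' run <- run_pipeline(cohort_config(n_patients = 10, seed = 1),
#'                     defects = defects_off())
#' run$features[window == "discharge"][1:3]
derive_features <- function(episodes, events, rules = rule_config(),
                            windows = names(WINDOW_OFFSETS)) {
  stopifnot(inherits(rules, "flow_rule_config"))
  windows <- match.arg(windows, names(WINDOW_OFFSETS), several.ok = TRUE)
  ep <- data.table::as.data.table(episodes)
  ev <- data.table::as.data.table(events)
  assert_columns(ep, c("episode_id", "admission_ts", "discharge_ts",
                       "admitting_team"), "episode table")

  base <- ep[, .(episode_id,
                 study_id = if ("study_id" %in% names(ep)) study_id
                   else episode_id,
                 adm = as.numeric(admission_ts),
                 dis = as.numeric(discharge_ts),
                 day_procedure_flag =
                   if ("day_procedure_flag" %in% names(ep))
                     day_procedure_flag else FALSE,
                 team = canon_name(admitting_team))]

  if (nrow(ev)) {
    assert_columns(ev, c("episode_id", "event_type", "order_subtype", "ts",
                         "target_service", "location"), "event table")
    evx <- merge(
      ev[, .(episode_id, event_type, order_subtype,
             ts_num = as.numeric(ts),
             target = canon_name(target_service),
             loc = canon_name(location))],
      base[, .(episode_id, adm, team)], by = "episode_id")
    evx[, `:=`(
      is_consult = event_type == "order" & order_subtype == "consult",
      is_transfer = event_type == "location_transfer")]
    evx[, is_self := is_consult & !is.na(target) & target != "" &
          target == team]
    evx[, is_external := is_consult & !is.na(target) & target != "" & !is_self]
    evx[, in24 := ts_num >= adm & ts_num < adm + 86400]
    evx[, is_critical := (is_transfer & loc %in% rules$fs4_critical_locations) |
          event_type == "icu_entry"]
  } else {
    evx <- NULL
  }

  icu <- pair_icu_intervals(
    if (nrow(ev)) ev
    else data.table::data.table(episode_id = character(),
                                event_type = character(),
                                ts = num_to_ts(numeric())))

  out <- vector("list", length(windows))
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    off <- WINDOW_OFFSETS[[w]]
    f <- data.table::copy(base)
    f[, end := if (is.infinite(off)) dis else pmin(adm + off * 3600, dis)]
    f[, discharged_within_window := dis <= end]
    f[, los_days_observed := (data.table::fifelse(discharged_within_window,
                                                  dis, end) - adm) / 86400]
    zero <- list(n_bloods = 0L, n_ct_mr = 0L, n_ir = 0L,
                 n_consults_total = 0L, n_consults_external = 0L,
                 n_consults_unattributed = 0L, n_consults_first24h = 0L,
                 n_transfers_total = 0L, n_transfers_first24h = 0L,
                 n_medications = 0L, n_allied_health = 0L, n_pharmacy = 0L,
                 group_hold_flag = FALSE, critical_location_flag = FALSE,
                 emergency_theatre_flag = FALSE,
                 one_to_one_nursing_flag = FALSE)
    if (!is.null(evx)) {
      evw <- merge(evx, f[, .(episode_id, end)], by = "episode_id")
      evw <- evw[ts_num < end]
      agg <- evw[, .(
        n_bloods = sum(order_subtype == "blood_test"),
        n_ct_mr = sum(order_subtype %in% c("ct", "mr")),
        n_ir = sum(order_subtype == "ir"),
        n_consults_total = sum(is_consult),
        n_consults_external = sum(is_external),
        n_consults_unattributed = sum(is_consult & (is.na(target) |
                                                      target == "")),
        n_consults_first24h = sum(is_external & in24),
        n_transfers_total = sum(is_transfer),
        n_transfers_first24h = sum(is_transfer & in24),
        n_medications = sum(order_subtype == "medication"),
        n_allied_health = sum(order_subtype == "allied_health_consult"),
        n_pharmacy = sum(order_subtype == "pharmacy_consult"),
        group_hold_flag = any(order_subtype == "group_hold"),
        critical_location_flag = any(is_critical),
        emergency_theatre_flag = any(event_type == "theatre_emergency"),
        one_to_one_nursing_flag = any(order_subtype == "one_to_one_nursing")
      ), by = episode_id]
      f <- merge(f, agg, by = "episode_id", all.x = TRUE)
    }
    for (col in names(zero)) {
      if (!col %in% names(f)) f[, (col) := zero[[col]]]
      else data.table::set(f, which(is.na(f[[col]])), col, zero[[col]])
    }
    # cumulative ICU hours, clipped to [admission, window end]
    f[, icu_hours_cumulative := 0]
    if (nrow(icu$pairs)) {
      ip <- merge(icu$pairs, f[, .(episode_id, adm, end)], by = "episode_id")
      ih <- ip[, .(h = sum(pmax(
        0, pmin(data.table::fifelse(is.na(e), Inf, e), end) -
          pmax(s, adm)) / 3600)), by = episode_id]
      f[ih, icu_hours_cumulative := i.h, on = "episode_id"]
    }
    f[, polypharmacy_flag := n_medications >= rules$polypharmacy_threshold]
    f[, window := w]
    f[, c("adm", "dis", "end", "team") := NULL]
    out[[wi]] <- f
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("episode_id", "study_id", "window"))
  data.table::setattr(res, "n_unpaired_icu_exits", icu$n_unpaired_exits)
  res[]
}
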