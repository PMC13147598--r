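# Independent oracles and small fixture builders. The oracles re-test every
# rule threshold directly (plain base-R logic, no shared code with the
# classifier or feature derivation), so agreement is meaningful.

WINDOW_SECS <- c("24h" = 24 * 3600, "72h" = 72 * 3600, "discharge" = Inf)

canon0 <- function(x) tolower(gsub("\\s+", " ", trimws(as.character(x))))

# brute-force stream assignment from a feature row, default thresholds only
brute_force_assign <- function(f) {
  f <- as.list(f)
  fs1 <- isTRUE(f$discharged_within_window) &&
    (f$los_days_observed * 24 < 24) && isTRUE(f$day_procedure_flag)
  fs4 <- (f$icu_hours_cumulative >= 24) ||
    isTRUE(f$critical_location_flag) ||
    isTRUE(f$emergency_theatre_flag) ||
    (f$n_ct_mr >= 1 && f$n_bloods >= 5) ||
    isTRUE(f$group_hold_flag) ||
    (f$n_consults_first24h >= 3) || (f$n_transfers_first24h >= 4)
  fs2 <- (f$n_consults_external <= 1) && (f$n_consults_total <= 2) &&
    (f$los_days_observed < 5)
  if (fs1) "FS1" else if (fs4) "FS4" else if (fs2) "FS2" else "FS3"
}

# brute-force stream from raw event rows for one episode at one window;
# ep: one-row data.frame (admission_ts, discharge_ts, admitting_team,
# day_procedure_flag); ev: that episode's events
brute_force_episode_stream <- function(ep, ev, window) {
  adm <- as.numeric(ep$admission_ts)
  dis <- as.numeric(ep$discharge_ts)
  end <- min(adm + WINDOW_SECS[[window]], dis)
  tsn <- as.numeric(ev$ts)
  team <- canon0(ep$admitting_team)
  tgt <- canon0(ev$target_service)
  is_con <- ev$event_type == "order" & ev$order_subtype == "consult"
  is_ext <- is_con & !is.na(tgt) & tgt != "" & tgt != team
  inw <- tsn < end
  in24 <- tsn >= adm & tsn < adm + 86400
  is_tr <- ev$event_type == "location_transfer"
  crit_set <- canon0(c("ED Resus", "Theatre", "ICU", "Spinal"))

  n_ext <- sum(is_ext & inw)
  n_tot <- sum(is_con & inw)
  n_con24 <- sum(is_ext & in24)
  n_tr24 <- sum(is_tr & in24)
  n_blood <- sum(ev$order_subtype == "blood_test" & inw)
  n_ctmr <- sum(ev$order_subtype %in% c("ct", "mr") & inw)
  gh <- any(ev$order_subtype == "group_hold" & inw)
  theatre <- any(ev$event_type == "theatre_emergency" & inw)
  critical <- any((is_tr & canon0(ev$location) %in% crit_set & inw) |
                    (ev$event_type == "icu_entry" & inw))

  # ICU pairing: walk entries/exits in time order, clip to [adm, end]
  icu_idx <- which(ev$event_type %in% c("icu_entry", "icu_exit"))
  icu_idx <- icu_idx[order(tsn[icu_idx])]
  hours <- 0
  open <- NA_real_
  for (k in icu_idx) {
    if (ev$event_type[k] == "icu_entry") {
      if (!is.na(open)) hours <- hours +
          max(0, min(tsn[k], end) - max(open, adm)) / 3600
      open <- tsn[k]
    } else if (!is.na(open)) {
      hours <- hours + max(0, min(tsn[k], end) - max(open, adm)) / 3600
      open <- NA_real_
    }
  }
  if (!is.na(open)) hours <- hours + max(0, end - max(open, adm)) / 3600

  discharged <- dis <= end
  los_days <- (if (discharged) dis - adm else end - adm) / 86400

  fs1 <- discharged && los_days * 24 < 24 && isTRUE(ep$day_procedure_flag)
  fs4 <- hours >= 24 || critical || theatre ||
    (n_ctmr >= 1 && n_blood >= 5) || gh || n_con24 >= 3 || n_tr24 >= 4
  fs2 <- n_ext <= 1 && n_tot <= 2 && los_days < 5
  if (fs1) "FS1" else if (fs4) "FS4" else if (fs2) "FS2" else "FS3"
}

# random feature table, wide enough to hit every rule branch
random_features <- function(n, seed = 1) {
  set.seed(seed)
  data.table::data.table(
    episode_id = sprintf("R%05d", seq_len(n)),
    study_id = sprintf("R%05d", seq_len(n)),
    window = "discharge",
    los_days_observed = round(stats::runif(n, 0, 12), 2),
    discharged_within_window = stats::runif(n) < 0.7,
    day_procedure_flag = stats::runif(n) < 0.4,
    n_consults_external = sample(0:4, n, replace = TRUE),
    n_consults_total = sample(0:5, n, replace = TRUE),
    n_consults_first24h = sample(0:4, n, replace = TRUE),
    n_bloods = sample(0:9, n, replace = TRUE),
    n_ct_mr = sample(0:3, n, replace = TRUE),
    n_ir = sample(0:2, n, replace = TRUE),
    group_hold_flag = stats::runif(n) < 0.15,
    icu_hours_cumulative = round(stats::runif(n, 0, 48), 1),
    critical_location_flag = stats::runif(n) < 0.15,
    emergency_theatre_flag = stats::runif(n) < 0.1,
    n_transfers_first24h = sample(0:6, n, replace = TRUE),
    n_transfers_total = sample(0:8, n, replace = TRUE),
    n_allied_health = sample(0:4, n, replace = TRUE),
    n_medications = sample(0:8, n, replace = TRUE),
    polypharmacy_flag = FALSE,
    n_consults_unattributed = 0L,
    n_pharmacy = 0L,
    one_to_one_nursing_flag = FALSE
  )
}

# single hand-built episode + events for feature tests
make_episode <- function(episode_id = "SID000001-E1", los_days = 2,
                         admission = "2024-03-01T08:00:00Z",
                         team = "general medicine",
                         day_procedure = FALSE) {
  adm <- parse_ts(admission)
  data.table::data.table(
    episode_id = episode_id, study_id = sub("-E\\d+$", "", episode_id),
    episode_no = 1L, admission_ts = adm,
    discharge_ts = adm + los_days * 86400,
    admission_source = "ED", admission_type = "Medical",
    admitting_team = team, ward = "ward a",
    age = 60, gender = "female", postcode = "5000",
    usual_accommodation = "private residence",
    day_procedure_flag = day_procedure, problem_list_populated = TRUE,
    n_encounters = 1L)
}

make_events <- function(episode_id, types, subtypes = "", offsets_h,
                        targets = "", locations = "") {
  n <- length(offsets_h)
  adm <- parse_ts("2024-03-01T08:00:00Z")
  data.table::data.table(
    episode_id = episode_id, study_id = sub("-E\\d+$", "", episode_id),
    event_id = sprintf("T%04d", seq_len(n)), episode_no = 1L,
    event_type = rep_len(types, n), order_subtype = rep_len(subtypes, n),
    ts = adm + offsets_h * 3600,
    target_service = rep_len(targets, n),
    location = rep_len(locations, n), structured_flag = TRUE)
}

# compact default-config cohorts shared across test files (small n)
tiny_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(
        run_pipeline(cohort_config(n_patients = 150, seed = 303),
                     defects = defects_off()))
    cache
  }
})
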