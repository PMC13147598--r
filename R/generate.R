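# Synthetic EMR cohort generator: seeded encounter/event tables with
# per-stream resource archetypes, late-escalation journeys and ground truth.

# Derive a per-patient substream seed from the run seed. Patient i's draws
# depend only on (seed, i), so enlarging the cohort never perturbs earlier
# patients. Kept strictly below 2^31 - 1.
patient_seed <- function(seed, i) {
  as.integer((as.double(seed %% 65011L) * 29989 + as.double(i) * 7919) %%
               2147483629)
}

# event accumulator: grows column vectors for one patient's events
ev_new <- function() {
  list(type = character(), subtype = character(), ts = numeric(),
       target = character(), location = character(), seq = integer())
}

ev_add <- function(ev, type, ts, subtype = "", target = "", location = "") {
  n <- length(ts)
  if (n == 0L) return(ev)
  ev$type <- c(ev$type, rep_len(type, n))
  ev$subtype <- c(ev$subtype, rep_len(subtype, n))
  ev$ts <- c(ev$ts, ts)
  ev$target <- c(ev$target, rep_len(target, n))
  ev$location <- c(ev$location, rep_len(location, n))
  ev$seq <- c(ev$seq, seq_along(ts) + (if (length(ev$seq)) max(ev$seq) else 0L))
  ev
}

# uniform minute-floored order times inside (adm, adm + los_secs)
order_times <- function(n, adm, los_secs, lo = 300, hi_margin = 300) {
  if (n <= 0L) return(numeric())
  hi <- max(lo + 60, los_secs - hi_margin)
  sort(floor_minute(adm + stats::runif(n, lo, hi)))
}

sample_external_targets <- function(n, team) {
  if (n <= 0L) return(character())
  sample(setdiff(TEAM_POOL, team), n, replace = TRUE)
}

# Core single-episode sampler. Operates on numeric seconds; consumes the
# current global RNG stream. Returns discharge time, the day-procedure flag
# and the accumulated event columns.
sample_episode_core <- function(archetype, p, adm, team, ward) {
  ev <- ev_new()

  los_days <- p$los_shift_days +
    rlnorm_trunc(1, p$los_median_days - p$los_shift_days, p$los_dispersion,
                 lower = max(0, p$los_min_days - p$los_shift_days),
                 upper = p$los_max_days - p$los_shift_days)

  # ICU stay is drawn before LOS is frozen so a long ICU stay can extend it
  icu_dur_h <- 0
  if (stats::runif(1) < p$icu_probability) {
    icu_dur_h <- rlnorm_trunc(1, p$icu_median_hours, p$icu_sdlog,
                              lower = p$icu_min_hours, upper = p$icu_max_hours)
    if (icu_dur_h >= 24) {
      los_days <- max(los_days, icu_dur_h / 24 + 0.5)
    } else {
      # short ICU visit must fit inside the stay and remain under 24 h
      icu_dur_h <- min(icu_dur_h, los_days * 24 * 0.8, 20)
    }
  }

  los_secs <- max(1800, floor_minute(los_days * 86400))
  dis <- adm + los_secs

  day_proc <- stats::runif(1) < p$day_procedure_probability

  # diagnostics
  n_ct <- if (stats::runif(1) < p$imaging_probability) sample(1:2, 1) else 0L
  n_blood <- stats::rpois(1, p$blood_mean)
  if (n_ct > 0) n_blood <- min(n_blood, p$blood_cap_if_imaging)
  n_ir <- stats::rpois(1, p$ir_mean)
  if (n_blood > 0)
    ev <- ev_add(ev, "order", order_times(n_blood, adm, los_secs), "blood_test")
  if (n_ct > 0)
    ev <- ev_add(ev, "order", order_times(n_ct, adm, los_secs),
                 sample(c("ct", "mr"), 1))
  if (n_ir > 0)
    ev <- ev_add(ev, "order", order_times(n_ir, adm, los_secs), "ir")

  # external medical consults
  n_consults_24 <- 0L
  if (!is.na(p$consult_first24_exact)) {
    k <- p$consult_first24_exact
    t24 <- sort(floor_minute(adm + stats::runif(k, 3600,
                                                min(72000, los_secs - 600))))
    for (tt in t24)
      ev <- ev_add(ev, "order", tt, "consult",
                   target = sample_external_targets(1, team))
    n_consults_24 <- k
    if (los_secs > 90000) {
      k2 <- stats::rpois(1, p$consult_extra_rate)
      if (k2 > 0) {
        t2 <- sort(floor_minute(adm + stats::runif(k2, 90000, los_secs - 600)))
        for (tt in t2)
          ev <- ev_add(ev, "order", tt, "consult",
                       target = sample_external_targets(1, team))
      }
    }
  } else {
    nc <- if (p$consult_max == 1) stats::rbinom(1, 1, min(1, p$consult_rate))
          else stats::rpois(1, p$consult_rate)
    nc <- min(nc, p$consult_max)
    if (nc > 0) {
      tts <- order_times(nc, adm, los_secs)
      n_consults_24 <- sum(tts < adm + 86400)
      for (tt in tts)
        ev <- ev_add(ev, "order", tt, "consult",
                     target = sample_external_targets(1, team))
    }
  }

  # ICU stay: transfer in, paired entry/exit, transfer back to the home ward
  has_icu <- icu_dur_h > 0
  if (has_icu) {
    max_start <- max(0, los_secs - icu_dur_h * 3600 - 1200)
    icu_start <- adm + floor_minute(stats::runif(1, 0, min(max_start, 43200)))
    icu_end <- icu_start + floor_minute(icu_dur_h * 3600)
    icu_end <- min(icu_end, dis - 600)
    if (icu_end <= icu_start) icu_end <- icu_start + 600
    ev <- ev_add(ev, "location_transfer", icu_start, location = "ICU")
    ev <- ev_add(ev, "icu_entry", icu_start)
    ev <- ev_add(ev, "icu_exit", icu_end)
    ev <- ev_add(ev, "location_transfer", min(icu_end + 300, dis - 60),
                 location = ward)
  }

  # plain intra-hospital transfers between non-critical wards
  n_tr <- min(stats::rpois(1, p$transfer_mean), p$transfer_cap)
  if (n_tr > 0)
    ev <- ev_add(ev, "location_transfer", order_times(n_tr, adm, los_secs),
                 location = sample(WARD_POOL, 1))

  # medications (row count is the medication burden)
  poly <- stats::runif(1) < p$polypharmacy_fraction
  n_med <- if (poly) 5L + stats::rpois(1, p$med_extra_mean)
           else min(stats::rpois(1, p$med_mean), 4L)
  if (n_med > 0)
    ev <- ev_add(ev, "order", order_times(n_med, adm, los_secs), "medication")

  # allied health and pharmacy consults (never medical consults)
  n_ah <- stats::rpois(1, p$allied_mean)
  if (n_ah > 0)
    ev <- ev_add(ev, "order", order_times(n_ah, adm, los_secs),
                 "allied_health_consult",
                 target = sample(ALLIED_POOL, 1))
  n_ph <- stats::rpois(1, p$pharmacy_mean)
  if (n_ph > 0)
    ev <- ev_add(ev, "order", order_times(n_ph, adm, los_secs),
                 "pharmacy_consult", target = "pharmacy")

  force_gh <- FALSE
  if (archetype == "FS4" && !has_icu) {
    # guarantee a qualifying pattern for every hypercomplex journey:
    # group-and-hold plus an early consult surge when no long ICU stay drawn
    force_gh <- TRUE
    need <- max(0L, 3L - n_consults_24)
    if (need > 0) {
      tts <- sort(floor_minute(adm + stats::runif(need, 7200, 72000)))
      for (tt in tts)
        ev <- ev_add(ev, "order", tt, "consult",
                     target = sample_external_targets(1, team))
    }
  }
  if (force_gh || stats::runif(1) < p$group_hold_probability)
    ev <- ev_add(ev, "order", order_times(1, adm, los_secs), "group_hold")

  if (stats::runif(1) < p$theatre_emergency_probability) {
    tt <- adm + floor_minute(stats::runif(1, 600, min(86400, los_secs - 600)))
    ev <- ev_add(ev, "theatre_emergency", tt)
    ev <- ev_add(ev, "location_transfer", tt, location = "Theatre")
  }
  if (stats::runif(1) < p$mtp_probability)
    ev <- ev_add(ev, "mtp_activation",
                 adm + floor_minute(stats::runif(1, 600, 43200)))
  if (stats::runif(1) < p$one_to_one_probability)
    ev <- ev_add(ev, "order", order_times(1, adm, los_secs),
                 "one_to_one_nursing")
  if (stats::runif(1) < 0.7)
    ev <- ev_add(ev, "order", adm + 900, "risk_assessment")

  list(dis = dis, day_procedure = day_proc, ev = ev)
}

# Append a late acuity surge (>= 24 h after admission): transfer to ICU, an
# ICU stay of 30-96 h, then a 2-7 day ward recovery before discharge. This is
# what turns an ordinary FS2/FS3 journey into an FS4 one at 72 h or discharge.
escalate_episode <- function(core, adm, ward) {
  icu_start <- adm + floor_minute((24 + stats::runif(1, 2, 36)) * 3600)
  icu_dur <- floor_minute(stats::runif(1, 30, 96) * 3600)
  icu_end <- icu_start + icu_dur
  new_dis <- max(core$dis,
                 icu_end + floor_minute(stats::runif(1, 48, 168) * 3600))
  ev <- core$ev
  ev <- ev_add(ev, "location_transfer", icu_start, location = "ICU")
  ev <- ev_add(ev, "icu_entry", icu_start)
  ev <- ev_add(ev, "icu_exit", icu_end)
  ev <- ev_add(ev, "location_transfer", icu_end + 300, location = ward)
  core$ev <- ev
  core$dis <- new_dis
  core
}

ev_to_dt <- function(ev, mrn) {
  data.table::data.table(
    mrn = rep_len(mrn, length(ev$ts)),
    event_type = ev$type,
    order_subtype = ev$subtype,
    ts = ev$ts,
    target_service = ev$target,
    location = ev$location,
    structured_flag = TRUE,
    seq = ev$seq
  )
}

#' Sample one archetype episode's event stream
#'
#' Draws a single admission journey for the given flow-stream archetype using
#' the current RNG state and returns its time-sorted event list. This is the
#' building block of [generate_cohort()], exposed for inspection and testing.
#'
#' @param archetype one of "FS1", "FS2", "FS3", "FS4"
#' @param params an [archetype_params()] block (defaults to the archetype's
#'   default block)
#' @param admission_ts admission instant (POSIXct or ISO 8601 string)
#' @param team admitting team name
#' @param ward home ward name
#' @return list with `admission_ts`, `discharge_ts`, `day_procedure_flag` and
#'   `events` (a time-sorted data.table: event_type, order_subtype, ts,
#'   target_service, location, structured_flag)
#' @export
#' @examples
#' set.seed(1)
#' ep <- sample_archetype_episode("FS1")
#' ep$events
sample_archetype_episode <- function(archetype,
                                     params = default_archetypes()[[archetype]],
                                     admission_ts = "2024-01-01T08:00:00Z",
                                     team = "general medicine",
                                     ward = "ward a") {
  if (!is.character(archetype) || length(archetype) != 1L ||
      !archetype %in% FS_LEVELS)
    stop("unknown archetype: must be one of FS1, FS2, FS3, FS4", call. = FALSE)
  stopifnot(inherits(params, "flow_archetype_params"))
  adm <- as.numeric(parse_ts(admission_ts))
  core <- sample_episode_core(archetype, params, adm, team, ward)
  events <- ev_to_dt(core$ev, mrn = "")[, c("mrn", "seq") := NULL]
  data.table::setorder(events, ts, event_type, order_subtype)
  events[, ts := num_to_ts(ts)]
  list(admission_ts = num_to_ts(adm), discharge_ts = num_to_ts(core$dis),
       day_procedure_flag = core$day_procedure, events = events[])
}

empty_encounters <- function() {
  data.table::data.table(
    encounter_id = character(), mrn = character(), encounter_type = character(),
    start_ts = num_to_ts(numeric()), end_ts = num_to_ts(numeric()),
    admitting_team = character(), ward = character(),
    age = numeric(), gender = character(), postcode = character(),
    usual_accommodation = character(), admission_type = character(),
    day_procedure_flag = logical(), problem_list_populated = logical()
  )
}

empty_events <- function() {
  data.table::data.table(
    event_id = character(), mrn = character(), event_type = character(),
    order_subtype = character(), ts = num_to_ts(numeric()),
    target_service = character(), location = character(),
    structured_flag = logical()
  )
}

empty_truth <- function() {
  list(
    patients = data.table::data.table(
      mrn = character(), archetype = character(), escalated = logical(),
      n_intended_episodes = integer()),
    defects = empty_defect_log(),
    mtp_true_count = 0L
  )
}

#' Generate a synthetic EMR cohort
#'
#' Draws `config$n_patients` patients: an intended flow-stream archetype from
#' the mixing weights, one admission journey per patient (a small fraction
#' re-present with a second, clearly separated journey), an optional late
#' acuity surge for FS2/FS3-intended patients, and per-journey event streams
#' from the archetype parameter blocks. ED-sourced journeys carry an ED
#' encounter followed by the inpatient encounter with an administrative gap
#' well inside the linkage threshold. Output is defect-free; pass the tables
#' through [inject_defects()] to emulate documentation problems.
#'
#' @param config a [cohort_config()]
#' @return list with `encounters`, `events` (data.tables conforming to the
#'   cleaning/linkage input schema) and `truth` (patients table: mrn,
#'   archetype, escalated, n_intended_episodes; plus an empty defect log and
#'   the true count of massive-transfusion events)
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' cohort$truth$patients
generate_cohort <- function(config) {
  stopifnot(inherits(config, "flow_cohort_config"))
  n <- config$n_patients
  if (n == 0L) {
    return(list(encounters = empty_encounters(), events = empty_events(),
                truth = empty_truth()))
  }

  cal0 <- as.numeric(parse_ts(config$calendar_start))
  cal_span <- config$calendar_days * 86400
  gap_max_s <- config$multi_encounter_gap_hours_max * 3600

  enc_list <- vector("list", n)
  ev_list <- vector("list", n)
  truth_arch <- character(n)
  truth_esc <- logical(n)
  truth_nep <- integer(n)
  mrns <- sprintf("MRN%06d", seq_len(n))

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    arch <- sample(FS_LEVELS, 1, prob = config$mixing_weights)
    p <- config$archetypes[[arch]]
    escalate <- arch %in% c("FS2", "FS3") &&
      stats::runif(1) < config$escalation_fraction
    source <- sample(ENCOUNTER_TYPES, 1,
                     prob = config$admission_source_weights[ENCOUNTER_TYPES])
    team <- sample(TEAM_POOL, 1)
    ward <- sample(WARD_POOL, 1)
    age <- round(min(102, max(16, stats::rnorm(1, p$age_median, p$age_sd))))
    gender <- if (stats::runif(1) < p$female_probability) "female" else "male"
    postcode <- as.character(sample(5000:5999, 1))
    accommodation <- sample(ACCOMMODATION_POOL, 1, prob = c(0.85, 0.10, 0.05))
    adm_type <- sample(ADMISSION_TYPES, 1, prob = p$admission_type_weights)

    n_ep <- if (stats::runif(1) < config$repeat_episode_probability) 2L else 1L
    adm <- cal0 + floor_minute(stats::runif(1, 0, cal_span))

    enc_rows <- list()
    ev_acc <- NULL
    for (e in seq_len(n_ep)) {
      core <- sample_episode_core(arch, p, adm, team, ward)
      if (e == 1L && escalate) core <- escalate_episode(core, adm, ward)
      if (e == 2L &&
          stats::runif(1) < config$accommodation_change_probability) {
        accommodation <- sample(setdiff(ACCOMMODATION_POOL, accommodation), 1)
      }
      day_proc <- core$day_procedure
      mk_enc <- function(type, s, en) {
        data.table::data.table(
          mrn = mrns[i], encounter_type = type, start_ts = s, end_ts = en,
          admitting_team = team, ward = ward, age = age, gender = gender,
          postcode = postcode, usual_accommodation = accommodation,
          admission_type = adm_type, day_procedure_flag = day_proc,
          problem_list_populated = TRUE)
      }
      if (source == "ED") {
        ed_end <- adm - floor_minute(stats::runif(1, 900, gap_max_s))
        ed_start <- ed_end - floor_minute(stats::runif(1, 1, 8) * 3600)
        enc_rows <- c(enc_rows, list(mk_enc("ED", ed_start, ed_end),
                                     mk_enc("IP", adm, core$dis)))
      } else {
        enc_rows <- c(enc_rows, list(mk_enc(source, adm, core$dis)))
      }
      ev_acc <- if (is.null(ev_acc)) core$ev else {
        core$ev$seq <- core$ev$seq + max(ev_acc$seq, 0L)
        Map(c, ev_acc, core$ev)
      }
      if (e < n_ep) {
        gap <- rlnorm_trunc(1, config$repeat_gap_median_days,
                            config$repeat_gap_sdlog, lower = 1) * 86400
        adm <- core$dis + floor_minute(gap)
      }
    }

    enc_list[[i]] <- data.table::rbindlist(enc_rows)
    ev_list[[i]] <- ev_to_dt(ev_acc, mrns[i])
    truth_arch[i] <- arch
    truth_esc[i] <- escalate
    truth_nep[i] <- n_ep
  }

  encounters <- data.table::rbindlist(enc_list)
  events <- data.table::rbindlist(ev_list)
  data.table::setorder(encounters, mrn, start_ts)
  encounters[, encounter_id := sprintf("ENC%07d", .I)]
  data.table::setorder(events, mrn, ts, seq)
  events[, event_id := sprintf("EVT%08d", .I)]
  events[, seq := NULL]

  encounters[, `:=`(start_ts = num_to_ts(start_ts), end_ts = num_to_ts(end_ts))]
  events[, ts := num_to_ts(ts)]
  data.table::setcolorder(encounters, names(empty_encounters()))
  data.table::setcolorder(events, names(empty_events()))

  truth <- empty_truth()
  truth$patients <- data.table::data.table(
    mrn = mrns, archetype = truth_arch, escalated = truth_esc,
    n_intended_episodes = truth_nep)
  truth$mtp_true_count <- events[event_type == "mtp_activation", .N]

  list(encounters = encounters[], events = events[], truth = truth)
}
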