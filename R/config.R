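# Configuration objects: cohort generator, defect injector, classification rules.

TEAM_POOL <- c("general medicine", "general surgery", "cardiology",
               "orthopaedics", "respiratory", "gastroenterology",
               "vascular surgery", "neurology", "urology", "renal")
WARD_POOL <- c("ward a", "ward b", "ward c", "ward d", "ward e", "ward f")
CRITICAL_LOCATIONS <- c("ED Resus", "Theatre", "ICU", "Spinal")
ALLIED_POOL <- c("physiotherapy", "occupational therapy", "speech pathology",
                 "dietetics", "social work")
ACCOMMODATION_POOL <- c("private residence", "residential aged care", "other")

#' Per-archetype generator parameter block
#'
#' One block per flow-stream archetype. Length of stay is log-normal
#' (median `los_median_days`, dispersion `los_dispersion` on the log scale)
#' truncated to `[los_min_days, los_max_days]`; the truncation bounds are what
#' keep each archetype inside its intended rule set (e.g. the short-stay
#' archetype never reaches 24 h).
#'
#' @param los_median_days median length of stay, days
#' @param los_dispersion sdlog of the log-normal LOS
#' @param los_min_days,los_max_days truncation bounds, days
#' @param los_shift_days shift of a shifted log-normal LOS: the log-normal is
#'   sampled for `los_median_days - los_shift_days` and offset by the shift.
#'   Used by the multidisciplinary archetype so its median stays exactly on
#'   its anchor while its support stays above the single-specialty LOS bound
#'   (plain resample-truncation would inflate the median)
#' @param consult_rate expected external medical consults (Bernoulli when
#'   `consult_max = 1`, else Poisson mean)
#' @param consult_max cap on sampled consults (`Inf` for none)
#' @param consult_first24_exact if not `NA`, exactly this many external
#'   consults are placed inside the first 24 h (the multidisciplinary
#'   archetype front-loads two, which is what separates it from the
#'   single-specialty stream at the first evaluation window)
#' @param consult_extra_rate Poisson mean of additional external consults
#'   placed after 24 h (only with `consult_first24_exact`)
#' @param blood_mean Poisson mean of blood-test orders
#' @param blood_cap_if_imaging cap on blood orders when a CT/MR is present
#'   (keeps sub-FS4 archetypes below the treatment-intensity criterion)
#' @param imaging_probability probability of >= 1 CT/MR order
#' @param ir_mean Poisson mean of interventional radiology orders
#' @param icu_probability probability of an ICU stay
#' @param icu_median_hours,icu_sdlog log-normal ICU duration parameters
#' @param icu_min_hours,icu_max_hours ICU duration truncation, hours
#' @param transfer_mean,transfer_cap Poisson mean / cap of non-critical
#'   intra-hospital transfers
#' @param polypharmacy_fraction probability of a high medication burden
#'   (>= 5 medication orders)
#' @param med_mean Poisson mean of medication orders otherwise (capped at 4)
#' @param med_extra_mean Poisson mean added on top of 5 under polypharmacy
#' @param allied_mean,pharmacy_mean Poisson means of allied-health and
#'   pharmacy consults
#' @param day_procedure_probability probability of the day-procedure flag
#' @param group_hold_probability probability of a group-and-hold order
#' @param mtp_probability probability of a massive-transfusion-pack activation
#' @param theatre_emergency_probability probability of an emergency theatre
#'   booking
#' @param one_to_one_probability probability of a one-to-one nursing order
#' @param admission_type_weights weights over Medical/Surgical/Other
#' @param age_median,age_sd age distribution (normal, clipped to 16..102)
#' @param female_probability probability gender is recorded female
#' @return a list with class `flow_archetype_params`
#' @export
archetype_params <- function(los_median_days, los_dispersion,
                             los_min_days = 0, los_max_days = Inf,
                             los_shift_days = 0,
                             consult_rate = 0, consult_max = Inf,
                             consult_first24_exact = NA_integer_,
                             consult_extra_rate = 0,
                             blood_mean = 0, blood_cap_if_imaging = Inf,
                             imaging_probability = 0, ir_mean = 0,
                             icu_probability = 0, icu_median_hours = 48,
                             icu_sdlog = 0.5, icu_min_hours = 0,
                             icu_max_hours = Inf,
                             transfer_mean = 0, transfer_cap = Inf,
                             polypharmacy_fraction = 0, med_mean = 1,
                             med_extra_mean = 3,
                             allied_mean = 0, pharmacy_mean = 0,
                             day_procedure_probability = 0,
                             group_hold_probability = 0,
                             mtp_probability = 0,
                             theatre_emergency_probability = 0,
                             one_to_one_probability = 0,
                             admission_type_weights = c(Medical = 0.6,
                                                        Surgical = 0.35,
                                                        Other = 0.05),
                             age_median = 63, age_sd = 16,
                             female_probability = 0.42) {
  p <- as.list(environment())
  probs <- c("imaging_probability", "icu_probability",
             "polypharmacy_fraction", "day_procedure_probability",
             "group_hold_probability", "mtp_probability",
             "theatre_emergency_probability", "one_to_one_probability",
             "female_probability")
  for (f in probs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_config(f, "must be a probability in [0, 1]")
  }
  for (f in c("los_median_days", "los_dispersion")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop_config(f, "must be strictly positive")
  }
  if (los_shift_days < 0 || los_shift_days >= los_median_days)
    stop_config("los_shift_days", "must lie in [0, los_median_days)")
  for (f in c("consult_rate", "blood_mean", "ir_mean", "transfer_mean",
              "med_mean", "allied_mean", "pharmacy_mean",
              "consult_extra_rate")) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0) stop_config(f, "must be >= 0")
  }
  if (abs(sum(p$admission_type_weights) - 1) > 1e-9)
    stop_config("admission_type_weights", "must sum to 1")
  structure(p, class = "flow_archetype_params")
}

default_archetypes <- function() {
  list(
    FS1 = archetype_params(
      los_median_days = 0.2, los_dispersion = 0.30, los_max_days = 0.999,
      consult_rate = 0.05, consult_max = 1,
      blood_mean = 1, blood_cap_if_imaging = 4, imaging_probability = 0.05,
      icu_probability = 0.031, icu_median_hours = 3, icu_sdlog = 0.3,
      icu_max_hours = 20,
      transfer_mean = 0.2, transfer_cap = 2,
      polypharmacy_fraction = 0.006, med_mean = 0.8,
      allied_mean = 0.05,
      day_procedure_probability = 1.0,
      admission_type_weights = c(Medical = 0.724, Surgical = 0.187,
                                 Other = 0.089),
      age_median = 61, age_sd = 15, female_probability = 0.40),
    FS2 = archetype_params(
      los_median_days = 2.0, los_dispersion = 0.76, los_max_days = 4.95,
      consult_rate = 0.6, consult_max = 1,
      blood_mean = 3, blood_cap_if_imaging = 4, imaging_probability = 0.25,
      ir_mean = 0.05,
      transfer_mean = 0.8, transfer_cap = 3,
      polypharmacy_fraction = 0.15, med_mean = 2.5,
      allied_mean = 0.3, pharmacy_mean = 0.1,
      admission_type_weights = c(Medical = 0.49, Surgical = 0.50,
                                 Other = 0.01),
      age_median = 62, age_sd = 18, female_probability = 0.44),
    FS3 = archetype_params(
      los_median_days = 8.4, los_dispersion = 1.4, los_shift_days = 5.0,
      consult_first24_exact = 2L, consult_extra_rate = 1.0,
      blood_mean = 8, blood_cap_if_imaging = 4, ir_mean = 0.3,
      transfer_mean = 1.5, transfer_cap = 3,
      polypharmacy_fraction = 0.93, med_mean = 2, med_extra_mean = 4,
      allied_mean = 2, pharmacy_mean = 0.5,
      admission_type_weights = c(Medical = 0.600, Surgical = 0.397,
                                 Other = 0.003),
      age_median = 70, age_sd = 14, female_probability = 0.44),
    FS4 = archetype_params(
      los_median_days = 11.2, los_dispersion = 0.855, los_min_days = 1.5,
      consult_rate = 2.0,
      blood_mean = 12, imaging_probability = 0.9, ir_mean = 0.5,
      icu_probability = 0.96, icu_median_hours = 72, icu_sdlog = 0.5,
      icu_min_hours = 24,
      transfer_mean = 4,
      polypharmacy_fraction = 0.90, med_mean = 3, med_extra_mean = 5,
      allied_mean = 3, pharmacy_mean = 0.8,
      group_hold_probability = 0.5, mtp_probability = 0.05,
      theatre_emergency_probability = 0.15, one_to_one_probability = 0.3,
      admission_type_weights = c(Medical = 0.4378, Surgical = 0.5615,
                                 Other = 0.0007),
      age_median = 62, age_sd = 15, female_probability = 0.38)
  )
}

#' Cohort generator configuration
#'
#' The stated world of the synthetic cohort: archetype mixing weights default
#' to the discharge-window stream distribution of a large quaternary-hospital
#' cohort (45.0 / 32.7 / 18.6 / 3.7 per cent), per-archetype length-of-stay
#' medians to 0.2 / 2.0 / 8.4 / 11.2 days, the short-stay ICU rate to 3.1%
#' and polypharmacy to 0.6%, the multidisciplinary polypharmacy rate to 93%,
#' and the hypercomplex ICU rate to 96%. `escalation_fraction` of
#' FS2/FS3-intended patients receive a late (after 24 h) acuity surge — an
#' ICU stay of at least 24 h appended to an otherwise ordinary journey — so
#' that reclassification happens at 72 h or discharge.
#'
#' @param n_patients number of patients (>= 0)
#' @param mixing_weights named proportions over archetypes FS1..FS4; must sum
#'   to 1 within 1e-9
#' @param escalation_fraction proportion of FS2/FS3-intended patients given a
#'   late acuity surge
#' @param archetypes list of four [archetype_params()] blocks named FS1..FS4
#' @param admission_source_weights weights over ED/OPD/IP/ITF admission sources
#' @param repeat_episode_probability probability a patient re-presents with a
#'   second, separate admission episode (gap >= 24 h, beyond the linkage
#'   threshold)
#' @param repeat_gap_median_days,repeat_gap_sdlog log-normal inter-episode gap
#' @param accommodation_change_probability probability the re-presentation
#'   carries genuinely changed accommodation (the substrate the
#'   demographic-overwrite defect acts on)
#' @param multi_encounter_gap_hours_max max administrative gap between an ED
#'   encounter and the inpatient encounter of the same journey; kept well
#'   under the 6 h linkage threshold so intended segmentation is recoverable
#' @param calendar_start first possible admission instant (ISO 8601)
#' @param calendar_days admissions are spread uniformly over this many days
#' @param seed integer seed; identical (config, seed) pairs give byte-identical
#'   tables. Per-patient substreams are derived from it so adding patients
#'   does not perturb earlier patients' draws.
#' @return a list with class `flow_cohort_config`
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 10, seed = 1)
cohort_config <- function(n_patients,
                          mixing_weights = c(FS1 = 0.450, FS2 = 0.327,
                                             FS3 = 0.186, FS4 = 0.037),
                          escalation_fraction = 0.04,
                          archetypes = default_archetypes(),
                          admission_source_weights = c(ED = 0.60, OPD = 0.25,
                                                       IP = 0.10, ITF = 0.05),
                          repeat_episode_probability = 0.03,
                          repeat_gap_median_days = 7, repeat_gap_sdlog = 0.8,
                          accommodation_change_probability = 0.08,
                          multi_encounter_gap_hours_max = 3,
                          calendar_start = "2024-01-01T00:00:00Z",
                          calendar_days = 365,
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 0 || n_patients != floor(n_patients))
    stop_config("n_patients", "must be a non-negative integer")
  if (!setequal(names(mixing_weights), FS_LEVELS))
    stop_config("mixing_weights", "must be named FS1..FS4")
  mixing_weights <- mixing_weights[FS_LEVELS]
  if (any(mixing_weights < 0) || abs(sum(mixing_weights) - 1) > 1e-9)
    stop_config("mixing_weights", "must be non-negative and sum to 1 (1e-9)")
  if (escalation_fraction < 0 || escalation_fraction > 1)
    stop_config("escalation_fraction", "must be in [0, 1]")
  if (!setequal(names(archetypes), FS_LEVELS))
    stop_config("archetypes", "must contain blocks FS1..FS4")
  for (a in FS_LEVELS) {
    if (!inherits(archetypes[[a]], "flow_archetype_params"))
      stop_config(paste0("archetypes$", a), "must be archetype_params()")
  }
  if (!setequal(names(admission_source_weights), ENCOUNTER_TYPES))
    stop_config("admission_source_weights", "must be named ED/IP/OPD/ITF")
  admission_source_weights <-
    admission_source_weights / sum(admission_source_weights)
  for (f in c("repeat_episode_probability", "accommodation_change_probability"))
    if (get(f) < 0 || get(f) > 1) stop_config(f, "must be in [0, 1]")
  if (multi_encounter_gap_hours_max <= 0)
    stop_config("multi_encounter_gap_hours_max", "must be > 0")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_config("seed", "must be a single integer")
  structure(list(
    n_patients = as.integer(n_patients),
    mixing_weights = mixing_weights,
    escalation_fraction = escalation_fraction,
    archetypes = archetypes,
    admission_source_weights = admission_source_weights[ENCOUNTER_TYPES],
    repeat_episode_probability = repeat_episode_probability,
    repeat_gap_median_days = repeat_gap_median_days,
    repeat_gap_sdlog = repeat_gap_sdlog,
    accommodation_change_probability = accommodation_change_probability,
    multi_encounter_gap_hours_max = multi_encounter_gap_hours_max,
    calendar_start = calendar_start,
    calendar_days = calendar_days,
    seed = as.integer(seed)
  ), class = "flow_cohort_config")
}

#' Documentation-defect injection configuration
#'
#' Rates of the defect catalogue observed in real EMR extracts: exact
#' duplicate rows, negative encounter durations, consults entered by the
#' admitting team for its own service, bypassed structured fields (problem
#' list populated in under 75% of cases, hence a default missingness of
#' 0.27), client-level demographic overwrites, and under-reporting of
#' high-acuity events (massive-transfusion activations recorded 144 times
#' against 355 blood-bank activations, hence a default removal fraction of
#' 1 - 144/355).
#'
#' @param duplicate_rate fraction of event rows duplicated verbatim
#' @param negative_duration_rate fraction of encounters whose end is rewritten
#'   to precede the start
#' @param self_consult_rate fraction of episodes that receive a consult order
#'   targeting their own admitting team, entered at admission
#' @param missing_structured_field_rate per-field missingness; named vector,
#'   currently `problem_list`
#' @param demographic_overwrite_rate fraction of patients whose latest
#'   demographic snapshot is copied back over all earlier encounters
#' @param high_acuity_underreport_fraction fraction of
#'   massive-transfusion-pack events deleted from the record
#' @param seed_offset added to the cohort seed for the defect substream
#' @return list with class `flow_defect_config`
#' @export
defect_config <- function(duplicate_rate = 0.01,
                          negative_duration_rate = 0.005,
                          self_consult_rate = 0.01,
                          missing_structured_field_rate = c(problem_list = 0.27),
                          demographic_overwrite_rate = 0.02,
                          high_acuity_underreport_fraction = 1 - 144 / 355,
                          seed_offset = 1000L) {
  rates <- c(duplicate_rate, negative_duration_rate, self_consult_rate,
             missing_structured_field_rate, demographic_overwrite_rate,
             high_acuity_underreport_fraction)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop_config("rates", "must all lie in [0, 1]")
  structure(list(
    duplicate_rate = duplicate_rate,
    negative_duration_rate = negative_duration_rate,
    self_consult_rate = self_consult_rate,
    missing_structured_field_rate = missing_structured_field_rate,
    demographic_overwrite_rate = demographic_overwrite_rate,
    high_acuity_underreport_fraction = high_acuity_underreport_fraction,
    seed_offset = as.integer(seed_offset)
  ), class = "flow_defect_config")
}

#' Defect-free configuration (all rates zero)
#' @return a `flow_defect_config` with every rate set to 0
#' @export
defects_off <- function() {
  defect_config(duplicate_rate = 0, negative_duration_rate = 0,
                self_consult_rate = 0,
                missing_structured_field_rate = c(problem_list = 0),
                demographic_overwrite_rate = 0,
                high_acuity_underreport_fraction = 0)
}

#' Classification rule configuration
#'
#' Thresholds of the four flow-stream rule sets and the hierarchical
#' evaluation order. FS1: day procedure and concluded LOS under
#' `fs1_los_hours`. FS2: at most `fs2_max_external_consults` external medical
#' consults, at most `fs2_max_total_consults` consults in total (the
#' continuity-of-care refinement), and LOS under `fs2_los_days`; the LOS
#' bound is treated as provisionally satisfied while the admission is still
#' open and the bound not yet violated. FS4: a disjunction (default) over six
#' criteria — cumulative ICU hours, critical-location presence, emergency
#' theatre, treatment intensity (CT/MR plus bloods), group-and-hold, and the
#' admission-anchored first-24 h consult/transfer surges — optionally
#' combinable as k-of-n. FS3 is the residual stream.
#'
#' @param fs1_los_hours FS1 length-of-stay bound, hours
#' @param fs1_require_day_procedure require the day-procedure flag for FS1
#' @param fs2_max_external_consults,fs2_max_total_consults FS2 consult bounds
#' @param fs2_los_days FS2 length-of-stay bound, days
#' @param fs4_icu_hours cumulative ICU-hours threshold
#' @param fs4_min_bloods blood-test threshold of the treatment-intensity
#'   criterion
#' @param fs4_min_consults_24h,fs4_min_transfers_24h first-24 h thresholds
#' @param fs4_critical_locations locations whose presence qualifies for FS4
#' @param fs4_criteria named logical toggles over criteria a..f
#' @param fs4_combination "any" (default) or "k_of_n"
#' @param fs4_min_criteria k when `fs4_combination = "k_of_n"`
#' @param hierarchy evaluation order; a permutation of FS1..FS4 ending in FS3
#' @param polypharmacy_threshold medication orders that define polypharmacy
#'   (summary reporting only, never classification)
#' @param quartile_type `stats::quantile()` type for reported medians/IQRs
#'   (7 = linear interpolation, 1 = nearest rank)
#' @return list with class `flow_rule_config`
#' @export
#' @examples
#' rules <- rule_config()
rule_config <- function(fs1_los_hours = 24,
                        fs1_require_day_procedure = TRUE,
                        fs2_max_external_consults = 1,
                        fs2_max_total_consults = 2,
                        fs2_los_days = 5,
                        fs4_icu_hours = 24,
                        fs4_min_bloods = 5,
                        fs4_min_consults_24h = 3,
                        fs4_min_transfers_24h = 4,
                        fs4_critical_locations = CRITICAL_LOCATIONS,
                        fs4_criteria = c(icu = TRUE, critical_location = TRUE,
                                         emergency_theatre = TRUE,
                                         treatment_intensity = TRUE,
                                         group_hold = TRUE, surge_24h = TRUE),
                        fs4_combination = c("any", "k_of_n"),
                        fs4_min_criteria = 1L,
                        hierarchy = c("FS1", "FS4", "FS2", "FS3"),
                        polypharmacy_threshold = 5,
                        quartile_type = 7) {
  fs4_combination <- match.arg(fs4_combination)
  thr <- c(fs1_los_hours, fs2_los_days, fs4_icu_hours, fs4_min_bloods,
           fs4_min_consults_24h, fs4_min_transfers_24h,
           polypharmacy_threshold)
  if (any(thr <= 0)) stop_config("thresholds", "must be strictly positive")
  if (fs2_max_external_consults < 0 || fs2_max_total_consults < 0)
    stop_config("fs2 consult bounds", "must be >= 0")
  if (!identical(sort(hierarchy), sort(FS_LEVELS)) ||
      hierarchy[length(hierarchy)] != "FS3")
    stop_config("hierarchy",
                "must be a permutation of FS1..FS4 ending in FS3")
  need <- c("icu", "critical_location", "emergency_theatre",
            "treatment_intensity", "group_hold", "surge_24h")
  if (!all(need %in% names(fs4_criteria)))
    stop_config("fs4_criteria", "must name all six criteria")
  structure(list(
    fs1_los_hours = fs1_los_hours,
    fs1_require_day_procedure = fs1_require_day_procedure,
    fs2_max_external_consults = fs2_max_external_consults,
    fs2_max_total_consults = fs2_max_total_consults,
    fs2_los_days = fs2_los_days,
    fs4_icu_hours = fs4_icu_hours,
    fs4_min_bloods = fs4_min_bloods,
    fs4_min_consults_24h = fs4_min_consults_24h,
    fs4_min_transfers_24h = fs4_min_transfers_24h,
    fs4_critical_locations = canon_name(fs4_critical_locations),
    fs4_criteria = fs4_criteria[need],
    fs4_combination = fs4_combination,
    fs4_min_criteria = as.integer(fs4_min_criteria),
    hierarchy = hierarchy,
    polypharmacy_threshold = polypharmacy_threshold,
    quartile_type = quartile_type
  ), class = "flow_rule_config")
}
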