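test_that("stream summary medians/IQRs follow the configured quartile rule", {
  run <- tiny_run()
  s <- run$stream_summary
  expect_equal(s[stream == "Overall", n], sum(s[stream != "Overall", n]))
  # direct recomputation of one stream's LOS median
  d <- merge(run$episodes,
             run$assignments[window == "discharge", .(episode_id, stream)],
             by = "episode_id")
  d[, los := as.numeric(discharge_ts - admission_ts, units = "days")]
  for (fs in FS_LEVELS) {
    if (!nrow(d[stream == fs])) next
    expect_equal(s[stream == fs, los_days_median],
                 stats::quantile(d[stream == fs, los], 0.5, type = 7,
                                 names = FALSE))
  }
  # arithmetic spot checks of the quartile helper
  expect_equal(flowstream:::med_iqr(1:5, 7), c(3, 2, 4))
  expect_equal(flowstream:::med_iqr(7, 7), c(7, 7, 7))
  expect_equal(flowstream:::fmt_med_iqr(c(3, 2, 4), 0), "3 (2, 4)")
})

test_that("empty streams report n = 0 with absent statistics", {
  cfg <- cohort_config(n_patients = 40, seed = 9,
                       mixing_weights = c(FS1 = 1, FS2 = 0, FS3 = 0, FS4 = 0),
                       escalation_fraction = 0)
  run <- run_pipeline(cfg, defects = defects_off())
  s <- run$stream_summary
  expect_equal(s[stream == "FS4", n], 0)
  expect_true(is.na(s[stream == "FS4", los_days_median]))
  expect_true(is.na(s[stream == "FS4", age_median_iqr]))
})

test_that("source-by-stream cross-tabulation has exact margins", {
  run <- tiny_run()
  m <- source_by_stream(run$episodes, run$assignments)
  expect_equal(sum(m), nrow(run$episodes))
  # brute-force tally
  d <- merge(run$episodes,
             run$assignments[window == "discharge", .(episode_id, stream)],
             by = "episode_id")
  for (src in rownames(m)) for (fs in colnames(m)) {
    expect_equal(m[src, fs],
                 nrow(d[admission_source == src & stream == fs]))
  }
  # all-ED cohort: single nonzero row
  d2 <- data.table::copy(run$episodes)[, admission_source := "ED"]
  m2 <- source_by_stream(d2, run$assignments)
  expect_equal(sum(m2["ED", ]), nrow(d2))
  expect_equal(sum(m2) - sum(m2["ED", ]), 0)
  # unknown source code errors with the offending row named
  d3 <- data.table::copy(run$episodes)[1, admission_source := "MARS"]
  expect_error(source_by_stream(d3, run$assignments), "MARS")
  # empty cohort -> all-zero table
  expect_equal(sum(source_by_stream(run$episodes[0], run$assignments[0])), 0)
})

test_that("defect-free runs have full completeness and zero defect counts", {
  run <- tiny_run()
  q <- run$quality
  expect_equal(q$problem_list_completeness, 1.0)
  expect_equal(q$self_consult_count, 0L)
  expect_equal(q$duplicate_rows_removed, 0L)
  expect_equal(q$implausible_rows_removed, 0L)
  # with re-presentations disabled there is no demographic drift at all
  run0 <- run_pipeline(cohort_config(n_patients = 60, seed = 9,
                                     repeat_episode_probability = 0),
                       defects = defects_off())
  expect_equal(run0$quality$demographic_inconsistencies, 0L)
})

test_that("problem-list completeness recovers the injected missingness", {
  run <- suppressWarnings(run_pipeline(
    cohort_config(n_patients = 1500, seed = 77),
    defects = defect_config(duplicate_rate = 0, negative_duration_rate = 0,
                            self_consult_rate = 0,
                            missing_structured_field_rate =
                              c(problem_list = 0.27),
                            demographic_overwrite_rate = 0,
                            high_acuity_underreport_fraction = 0)))
  expect_lt(abs(run$quality$problem_list_completeness - 0.73), 0.02)
})

test_that("MTP under-reporting reproduces the recorded/reference ratio", {
  # 355 true activations, the default removal fraction leaves about 144
  enc <- data.table::data.table(
    encounter_id = sprintf("E%03d", 1:355), mrn = sprintf("M%03d", 1:355),
    encounter_type = "IP",
    start_ts = parse_ts("2024-01-01T00:00:00Z") + (1:355) * 86400,
    end_ts = parse_ts("2024-01-01T00:00:00Z") + (1:355) * 86400 + 7200,
    admitting_team = "general surgery", ward = "ward a", age = 50,
    gender = "male", postcode = "5000",
    usual_accommodation = "private residence", admission_type = "Surgical",
    day_procedure_flag = FALSE, problem_list_populated = TRUE)
  ev <- data.table::data.table(
    event_id = sprintf("V%03d", 1:355), mrn = enc$mrn,
    event_type = "mtp_activation", order_subtype = "",
    ts = enc$start_ts + 600, target_service = "", location = "",
    structured_flag = TRUE)
  out <- inject_defects(list(encounters = enc, events = ev),
                        defect_config(duplicate_rate = 0,
                                      negative_duration_rate = 0,
                                      self_consult_rate = 0,
                                      missing_structured_field_rate =
                                        c(problem_list = 0),
                                      demographic_overwrite_rate = 0),
                        seed = 4)
  cl <- clean_events(out$encounters, out$events)
  lk <- link_episodes(cl$encounters, cl$events, 6)
  de <- deidentify(lk$episodes, lk$events)
  q <- quality_report(cl, de$episodes, de$events,
                      reference_counts = c(mtp_activation = 355))
  expect_lt(abs(q$mtp_recorded - 144), 28)  # ~3 sd of Binomial(355, 144/355)
  expect_lt(abs(q$mtp_ratio - 0.406), 0.08)
  # a zero reference makes the ratio undefined, not zero
  q0 <- quality_report(cl, de$episodes, de$events,
                       reference_counts = c(mtp_activation = 0))
  expect_true(is.na(q0$mtp_ratio))
})

test_that("demographic overwrite hides drift the quality report would show", {
  cfg <- cohort_config(n_patients = 300, seed = 53,
                       repeat_episode_probability = 0.5,
                       accommodation_change_probability = 0.5)
  cohort <- generate_cohort(cfg)
  # untouched cohort: genuine accommodation changes are visible
  cl <- clean_events(cohort$encounters, cohort$events)
  lk <- suppressWarnings(link_episodes(cl$encounters, cl$events, 6))
  de <- deidentify(lk$episodes, lk$events)
  q_before <- quality_report(cl, de$episodes, de$events)
  expect_gt(q_before$demographic_inconsistencies, 0)
  # overwriting every patient's history erases the visible drift
  out <- inject_defects(cohort[c("encounters", "events")],
                        defect_config(duplicate_rate = 0,
                                      negative_duration_rate = 0,
                                      self_consult_rate = 0,
                                      missing_structured_field_rate =
                                        c(problem_list = 0),
                                      demographic_overwrite_rate = 1,
                                      high_acuity_underreport_fraction = 0),
                        seed = 53)
  cl2 <- clean_events(out$encounters, out$events)
  lk2 <- suppressWarnings(link_episodes(cl2$encounters, cl2$events, 6))
  de2 <- deidentify(lk2$episodes, lk2$events)
  q_after <- quality_report(cl2, de2$episodes, de2$events)
  expect_equal(q_after$demographic_inconsistencies, 0L)
})
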