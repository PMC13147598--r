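empty_events_fixture <- function() {
  data.table::data.table(event_id = character(), mrn = character(),
                         event_type = character(),
                         order_subtype = character(),
                         ts = parse_ts(character()),
                         target_service = character(), location = character(),
                         structured_flag = logical())
}

mk_enc <- function(mrn, start_h, end_h, type = "IP", team = "general medicine",
                   id = NULL) {
  t0 <- parse_ts("2024-02-01T00:00:00Z")
  data.table::data.table(
    encounter_id = id %||% sprintf("E%s-%g", mrn, start_h),
    mrn = mrn, encounter_type = type,
    start_ts = t0 + start_h * 3600, end_ts = t0 + end_h * 3600,
    admitting_team = team, ward = "ward a", age = 50, gender = "male",
    postcode = "5000", usual_accommodation = "private residence",
    admission_type = "Medical", day_procedure_flag = FALSE,
    problem_list_populated = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cleaning excludes negative durations and collapses duplicates", {
  enc <- rbind(mk_enc("A", 0, 10), mk_enc("A", 12, 8, id = "NEG"),
               mk_enc("B", 0, 5, id = "DUP"), mk_enc("B", 0, 5, id = "DUP"))
  ev <- data.table::data.table(event_id = "V1", mrn = "A",
                               event_type = "order",
                               order_subtype = "blood_test",
                               ts = parse_ts("2024-02-01T02:00:00Z"),
                               target_service = "", location = "",
                               structured_flag = TRUE)
  out <- clean_events(enc, ev)
  expect_equal(nrow(out$encounters), 2)
  expect_identical(out$log[reason == "implausible_excluded", ref], "NEG")
  expect_identical(out$log[reason == "duplicate_removed", ref], "DUP")
})

test_that("cleaning logs whitespace standardisation but keeps the row", {
  enc <- mk_enc("A", 0, 10, team = " General   Medicine ")
  out <- clean_events(enc, empty_events_fixture())
  expect_equal(out$encounters$admitting_team, "general medicine")
  expect_identical(out$log[reason == "format_standardised", ref],
                   enc$encounter_id)
})

test_that("unparseable timestamps are excluded and logged", {
  enc <- mk_enc("A", 0, 10)
  ev <- data.table::data.table(event_id = c("V1", "V2"), mrn = "A",
                               event_type = "order",
                               order_subtype = "blood_test",
                               ts = c("2024-02-01T02:00:00Z", "not a time"),
                               target_service = "", location = "",
                               structured_flag = TRUE)
  out <- suppressWarnings(clean_events(enc, ev))
  expect_equal(nrow(out$events), 1)
  expect_identical(out$log[reason == "implausible_excluded", ref], "V2")
})

test_that("missing mandatory columns raise a schema error naming the column", {
  enc <- mk_enc("A", 0, 10)[, !"admitting_team"]
  expect_error(clean_events(enc, empty_events_fixture()), "admitting_team")
})

test_that("linkage merges and splits on the gap threshold", {
  # 2 h gap, 6 h threshold -> one episode
  enc <- rbind(mk_enc("A", 0, 10), mk_enc("A", 12, 20))
  out <- link_episodes(clean_events(enc, empty_events_fixture())$encounters,
                       empty_events_fixture(), gap_threshold_hours = 6)
  expect_equal(nrow(out$episodes), 1)
  expect_equal(out$episodes$n_encounters, 2)

  # 48 h gap -> two episodes
  enc <- rbind(mk_enc("A", 0, 10), mk_enc("A", 58, 70))
  out <- link_episodes(enc, empty_events_fixture(), 6)
  expect_equal(nrow(out$episodes), 2)

  # transitive chain: A-B gap 3 h, B-C gap 3 h, total span > threshold
  enc <- rbind(mk_enc("A", 0, 2), mk_enc("A", 5, 6.5), mk_enc("A", 9.5, 12))
  out <- link_episodes(enc, empty_events_fixture(), 6)
  expect_equal(nrow(out$episodes), 1)
})

test_that("orphan events are warning-logged and excluded", {
  enc <- mk_enc("A", 0, 10)
  ev <- data.table::data.table(
    event_id = c("V1", "V2"), mrn = c("A", "GHOST"), event_type = "order",
    order_subtype = "blood_test",
    ts = parse_ts(c("2024-02-01T02:00:00Z", "2024-02-01T02:00:00Z")),
    target_service = "", location = "", structured_flag = TRUE)
  expect_warning(out <- link_episodes(enc, ev, 6), "excluded")
  expect_equal(nrow(out$events), 1)
  expect_equal(out$orphans$event_id, "V2")
})

test_that("linkage is invariant to input row permutation", {
  sim <- generate_cohort(cohort_config(n_patients = 80, seed = 31))
  cl <- clean_events(sim$encounters, sim$events)
  base <- link_episodes(cl$encounters, cl$events, 6)
  set.seed(1)
  shuf <- link_episodes(cl$encounters[sample(.N)], cl$events[sample(.N)], 6)
  expect_identical(as.data.frame(base$episodes), as.data.frame(shuf$episodes))
  expect_identical(as.data.frame(base$events), as.data.frame(shuf$events))
})

test_that("conservation: encounters partition into episodes, events attach once", {
  sim <- generate_cohort(cohort_config(n_patients = 120, seed = 37))
  cl <- clean_events(sim$encounters, sim$events)
  out <- link_episodes(cl$encounters, cl$events, 6)
  expect_equal(sum(out$episodes$n_encounters), nrow(cl$encounters))
  expect_equal(nrow(out$events) + nrow(out$orphans), nrow(cl$events))
})

test_that("raising the gap threshold never increases episode count", {
  sim <- generate_cohort(cohort_config(n_patients = 100, seed = 41,
                                       repeat_episode_probability = 0.3))
  cl <- clean_events(sim$encounters, sim$events)
  n_prev <- Inf
  for (thr in c(2, 6, 24, 200)) {
    n <- nrow(suppressWarnings(link_episodes(cl$encounters, cl$events,
                                             thr))$episodes)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("de-identification round-trips and hides the MRN", {
  sim <- generate_cohort(cohort_config(n_patients = 100, seed = 43,
                                       repeat_episode_probability = 0.2))
  cl <- clean_events(sim$encounters, sim$events)
  lk <- link_episodes(cl$encounters, cl$events, 6)
  de <- deidentify(lk$episodes, lk$events)
  expect_false("mrn" %in% names(de$episodes))
  expect_false("mrn" %in% names(de$events))
  expect_equal(nrow(de$identity_map), length(unique(lk$episodes$mrn)))
  # same mrn -> same study_id across episodes
  multi <- lk$episodes[, .N, by = mrn][N > 1]
  if (nrow(multi)) {
    back <- reidentify(de$episodes, de$identity_map)
    expect_true(all(back[, data.table::uniqueN(study_id), by = mrn]$V1 == 1))
  }
  # round trip recovers the original assignment exactly
  back <- reidentify(de$episodes, de$identity_map)
  orig <- lk$episodes[order(mrn, episode_no),
                      .(mrn, episode_no, admission_ts)]
  rec <- back[order(mrn, episode_no), .(mrn, episode_no, admission_ts)]
  expect_identical(as.data.frame(orig), as.data.frame(rec))
})
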