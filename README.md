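# flowstream

Resource-based **patient flow stream** classification from routinely
collected EMR data, for hospital operations analysts and health-services
researchers.

Diagnosis-Related Groups are assigned after discharge and support funding,
not real-time planning. Flow streams stratify admissions instead by the
resources they are actually consuming: every admission episode is assigned
to one of four streams by a hierarchical rule set over EMR-derived
resource-utilisation features, re-evaluated at 24 h, 72 h and at discharge,
so operational load is visible while the patient is still in the building.

| Stream | Profile | Rule set (defaults) |
|---|---|---|
| **FS1** | short-stay / ambulatory, scheduled care | day procedure **and** concluded LOS < 24 h |
| **FS2** | single specialty | ≤ 1 external medical consult, ≤ 2 total, LOS < 5 d (assessed dynamically) |
| **FS3** | intermediate, multidisciplinary | residual — meets none of FS1 / FS2 / FS4 |
| **FS4** | hypercomplex, high acuity | any of: cumulative ICU ≥ 24 h · critical location (ED Resus / Theatre / ICU / Spinal) · emergency theatre · CT/MR and ≥ 5 bloods · group-and-hold · ≥ 3 consults or ≥ 4 transfers within 24 h of admission |

Rule sets are evaluated in the order **FS1 → FS4 → FS2 → FS3** and the first
hit wins. Upper-bound criteria (LOS) count as provisionally satisfied while
an admission is open and the bound not yet violated; because every other
input is a monotone counter, labels can only move toward higher intensity
(FS2→FS3, FS2→FS4, FS3→FS4) and FS4 is absorbing.

The package covers the full pipeline on tabular EMR extracts (CSV):

* `generate_cohort()` / `inject_defects()` / `simulate_emr()` — seeded
  synthetic EMR encounter/event tables with per-stream resource archetypes
  (LOS, consults, imaging, ICU, transfers, medications anchored to a
  published quaternary-hospital cohort), late-escalation journeys, injected
  documentation defects (duplicates, negative durations, self-consults,
  blanked problem lists, demographic overwrites, under-reported MTP
  activations) and a ground-truth log;
* `clean_events()` — duplicate collapse, implausible-row exclusion, format
  standardisation, all logged; no imputation;
* `link_episodes()` — deterministic episode-of-care linkage by MRN with a
  transitive time-gap threshold (default 6 h);
* `deidentify()` / `reidentify()` — opaque study identifiers with a separate
  identity map;
* `derive_features()` / `count_consults()` — windowed resource features with
  self-consult exclusion and clipped cumulative ICU hours;
* `meets_fs1/fs2/fs4()`, `assign_stream()`, `classify_trajectories()`,
  `transition_table()`, `percent_reclassified()` — classification with
  criteria traces;
* `summarize_streams()`, `source_by_stream()`, `quality_report()` —
  stratified summaries (median/IQR), cross-tabulations, data-quality
  metrics.

## Worked example

```r
library(flowstream)
run <- run_pipeline(cohort_config(n_patients = 10000, seed = 101))

run$stream_summary[, .(stream, n, age_median_iqr, los_days_median_iqr,
                       pct_icu, pct_polypharmacy)]
#>     stream     n age_median_iqr los_days_median_iqr pct_icu pct_polypharmacy
#> 1: Overall 10297    63 (52, 74)      0.9 (0.2, 4.3)     6.8             26.1
#> 2:     FS1  4616    61 (50, 71)      0.2 (0.2, 0.2)     2.8              0.7
#> 3:     FS2  3259    62 (50, 74)      1.8 (1.1, 2.8)     0.0             15.6
#> 4:     FS3  1830    71 (61, 80)     8.5 (6.4, 13.7)     0.0             93.1
#> 5:     FS4   592    63 (52, 74)    10.5 (7.8, 16.1)    97.6             75.0
```

10,000 patients produced 10,297 admission episodes (some re-present). The
four streams separate exactly as the model intends: LOS medians order
0.2 < 1.8 < 8.5 < 10.5 days, ICU admission concentrates in FS4 (97.6%) with
the small scheduled-care ICU fraction in FS1 (2.8%), and polypharmacy peaks
in the multidisciplinary stream FS3 (93.1%).

```r
run$transitions_24h_72h
#>      FS1  FS2  FS3 FS4
#> FS1 4616    0    0   0
#> FS2    0 3259    0 120
#> FS3    0    0 1830  79
#> FS4    0    0    0 393

run$percent_reclassified
#> [1] 1.93
```

Between 24 h and 72 h the only movement is escalation into FS4 (120
episodes from FS2, 79 from FS3 — the late-deterioration journeys the
generator injects at rate 0.04); FS1 counts are identical at every window.
Overall, 1.93% of episodes ever change stream, echoing the under-5%
stability the model is designed around.

The quality report quantifies the injected documentation damage, e.g.
`run$quality$problem_list_completeness` ≈ 0.73 under the default blanking
rate of 0.27, and `quality_report(..., reference_counts =
c(mtp_activation = 355))` reports the recorded/reference MTP ratio.

## Command line

```sh
Rscript exec/flowstream simulate --config cfg.json --out-dir out --seed 1
Rscript exec/flowstream link --encounters out/encounters.csv --events out/events.csv --gap-hours 6 --out-dir out
Rscript exec/flowstream classify --episodes out/episodes.csv --events out/episode_events.csv --out-dir out
Rscript exec/flowstream run-all --config cfg.json --out-dir out
```

`cfg.json` holds `cohort_config()` fields, e.g.
`{"n_patients": 1000, "seed": 1}`. The identity map is written to a separate
`identity/` directory.

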