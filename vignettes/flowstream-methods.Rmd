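---
title: "Flow-stream classification: model, synthetic data and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-stream classification: model, synthetic data and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Diagnosis-based casemix groupings (DRGs) are assigned after discharge and say
little about how much of a hospital's capacity an admission is consuming
*right now*. Flow streams are an alternative, resource-based stratification
computable from routinely collected EMR data: every admission episode is
placed into one of four streams by a hierarchical rule set over
resource-utilisation features, re-evaluated at 24 h, 72 h and discharge.

| Stream | Intuition | Criteria (defaults) |
|---|---|---|
| FS1 | short-stay / ambulatory, scheduled care | day procedure **and** concluded LOS < 24 h |
| FS2 | single-specialty admission | ≤ 1 external medical consult, ≤ 2 consults total, LOS < 5 d |
| FS3 | intermediate complexity, multidisciplinary | residual: meets none of FS1/FS2/FS4 |
| FS4 | hypercomplex, high acuity | any of: cumulative ICU ≥ 24 h; critical location (ED Resus, Theatre, ICU, Spinal); emergency theatre; CT/MR **and** ≥ 5 bloods; group-and-hold; within 24 h of admission ≥ 3 medical consults or ≥ 4 transfers |

Episodes are evaluated **in the order FS1, FS4, FS2, FS3**: the first
satisfied rule set wins, FS3 is the residual. Ties cannot occur because the
hierarchy is a strict order. `rule_config()` exposes every threshold, the
criterion toggles, an any-of / k-of-n combination mode for FS4, and the
hierarchy itself (any permutation ending in FS3).

Two semantic choices matter and are worth stating precisely:

* **Provisional upper bounds.** At an interim window an upper-bound
  criterion such as "LOS < 5 days" counts as satisfied while it is not yet
  violated. This is the only reading under which stream counts can evolve
  the way a dynamic classification must: FS2 shrinks monotonically as
  admissions outlive the bound, and nobody oscillates. Conversely FS1
  requires a *concluded* stay: an episode still open at 24 h cannot be FS1.
* **Admission-anchored 24 h counters.** The FS4 "within 24 h" sub-criteria
  use the fixed interval `[admission, admission + 24 h)` at every window,
  because they describe the admission's opening surge, not the window.

Together with the fact that every other rule input is a monotone counter,
these choices yield a ratchet: FS1 assignments are constant across windows,
FS4 is absorbing, and the only possible moves are FS2→FS3, FS2→FS4 and
FS3→FS4. The test suite asserts this as a property, not an example.

### Consult counting

A *medical consult* is a structured consult order to a specialty team
**outside** the admitting unit. Orders targeting the admitting team itself
("self-consults", a known documentation artefact entered during admission)
are excluded from the external count and from the FS4 first-24 h surge, but
do count toward the FS2 *total* bound of two — which implements the
continuity-of-care refinement that allows a second consult from the
patient's usual team without ejecting them from FS2. Consults with an empty
target cannot be attributed and count toward the total only. Team names are
compared after whitespace-squishing and case-folding; this is the automated
stand-in for the manual recoding that inconsistent consult-order naming
otherwise forces.

## Pipeline

```{r}
library(flowstream)
run <- run_pipeline(cohort_config(n_patients = 10000, seed = 101))
run$stream_summary
run$transitions_24h_72h
run$percent_reclassified
```

`run_pipeline()` chains the stages, each of which is exported on its own:

1. **Cleaning** (`clean_events`): timestamps parsed to UTC; rows with
   unparseable timestamps or negative durations excluded; exact duplicate
   rows collapsed; names standardised. Every removed row is logged once with
   a reason code. Nothing is imputed: a value absent from a structured field
   is treated as not collected.
2. **Linkage** (`link_episodes`): per patient, encounters sorted by start
   and merged *transitively* whenever the gap to the running maximum end is
   at most the threshold (default 6 h). The threshold is a design choice —
   long enough to bridge ED-to-ward administrative gaps, short enough to
   separate re-presentations — and is exposed because the right value is a
   property of local administrative practice. Events attach to the episode
   whose span contains them; events with unknown patients or out-of-span
   timestamps are excluded as orphans with a warning rather than fabricated
   into episodes.
3. **De-identification** (`deidentify`): MRNs are replaced by study
   identifiers assigned over sorted MRNs (hence order-invariant); the map is
   returned as a separate artefact and written to a separate directory.
   `reidentify()` is the controlled inverse.
4. **Features** (`derive_features`): counters per episode and window; only
   events strictly before the window end count; ICU hours are the sum of
   paired entry/exit intervals clipped to the window (an open stay clips at
   the window end; an unpaired exit is ignored and counted as a defect).
   Cumulative ICU hours across multiple stays — rather than a single-stay
   maximum — is used because it better reflects resource consumption.
5. **Classification and reporting** as described above; summaries use
   configurable quartiles (default type 7, linear interpolation; nearest-rank
   available) and percentages are rendered to one decimal place.

## The synthetic cohort: what it emulates, what it does not

No real extract ships with the package; the generator produces the world the
downstream stages are tested against. Its defaults are anchored to the
published stratified summary of a 332,711-admission quaternary-hospital
cohort:

* archetype mixing weights 0.450 / 0.327 / 0.186 / 0.037 (the discharge
  stream distribution);
* LOS medians 0.2 / 2.0 / 8.4 / 11.2 days, log-normal, with dispersions
  chosen so the interquartile ranges bracket the published IQRs;
* FS1 ICU rate 3.1% and polypharmacy 0.6%; FS3 polypharmacy 93%; FS4 ICU
  rate 96%;
* 4% of FS2/FS3-intended patients receive a late acuity surge (an ICU stay
  ≥ 24 h beginning after the first day, followed by a 2–7 day ward
  recovery), so reclassification happens at 72 h or discharge — mirroring
  the published deterioration example.

Distributional *forms* are stand-ins: the source reports only medians,
IQRs and percentages, so log-normal LOS, Poisson counts and Bernoulli flags
are choices, made once. Three of them deserve explanation:

* **FS3 LOS is a shifted log-normal** (5 d + log-normal with median 3.4 d,
  sdlog 1.4). A plain log-normal truncated above the 5-day FS2 bound would
  inflate the median well past its 8.4 d anchor; the shift pins the median
  exactly while keeping all support above the bound.
* **FS3 front-loads exactly two external consults in the first 24 h.** The
  published window counts show FS3 already populated at 24 h with under 5%
  of patients ever reclassified; under provisional-LOS semantics that is
  only possible if multidisciplinary patients fail the FS2 consult rule
  early. Two consults breach FS2 (max 1 external) while staying below the
  FS4 surge threshold (3).
* **FS3 orders no CT/MR** (interventional radiology stands in for its
  imaging load) so that the FS4 treatment-intensity criterion remains a
  discriminator; its blood-test counts are otherwise unconstrained. This is
  a deliberate non-realism: real intermediate-complexity patients get CT
  scans. A green archetype-separability test therefore establishes that the
  classifier recovers *rule-consistent* archetypes, not that the rules would
  partition real patients this cleanly.

Day procedures are an episode-level flag the generator sets with
probability 1 for the FS1 archetype (it models scheduled day care); real
extracts must map their scheduled-care indicator onto it. Admission sources
are drawn from ED/OPD/IP/ITF (ED-sourced journeys get an ED encounter
followed by the inpatient encounter with an administrative gap well under
the linkage threshold); a small fraction of patients re-present with a
second episode at least 24 h after discharge, so intended segmentation is
unambiguous at the default threshold. Timestamps are minute-resolution over
a configurable calendar year. Diagnoses, ICD-10 codes and DRGs are
deliberately out of scope: archetypes emulate resource-use structure only.

Reproducibility: one run seed, with per-patient substreams derived from it,
so identical `(config, seed)` pairs are byte-identical and enlarging the
cohort never perturbs earlier patients' draws. Defect injection uses a
seed offset on the same base seed.

### Injected documentation defects

`defect_config()` reproduces the published defect catalogue: exact duplicate
rows; negative encounter durations; self-consults; structured problem lists
blanked at rate 0.27 (populated "in less than 75%" of cases); client-level
demographic overwrites that copy the latest snapshot over all earlier
encounters; and deletion of massive-transfusion activations at rate
1 − 144/355 (the published recorded-versus-blood-bank ratio). Every injected
defect is logged exactly once, and the cleaning log reconciles exactly
against the truth log for the defect kinds cleaning can see — an acceptance
criterion, not just a unit test. The quality report measures the rest:
completeness, self-consult rate, the recorded/reference MTP ratio (absent
when no reference is supplied), and demographic drift still visible —
note that a full overwrite *erases* visible drift, which is exactly the
published limitation.

## Numerical and degenerate-input conventions

* Window end `min(admission + offset, discharge)`; events count iff
  `ts < end`. Episode spans for event *attachment* are closed intervals.
* LOS is reported to 0.1 d in written outputs but classification uses full
  precision.
* Empty cohorts: `generate_cohort()` returns typed empty tables;
  `transition_table()` returns a zero matrix; `percent_reclassified()`
  errors (undefined, not zero); empty streams summarise as n = 0 with
  absent statistics, not zeros.
* A `study_id` collision during de-identification is a hard error.
* Unknown admission-source codes abort the cross-tabulation, naming the
  code.

## Known limitations

* The generator's archetypes are rule-consistent by construction; recovery
  rates near 100% say nothing about clinical validity of the rule set on
  real data (the published validation was manual chart review, out of
  scope here).
* Free-text extraction (past medical history, comorbidity scores) is not
  modelled or parsed.
* The polypharmacy threshold (≥ 5 medication orders) is a reporting
  convention — the source leaves polypharmacy undefined — and never enters
  classification.
* The CLI accepts JSON configuration only (no TOML parser in the supported
  dependency set).
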