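Package: flowstream
Title: Resource-Based Patient Flow Stream Classification from EMR Event Streams
Version: 0.1.0
Authors@R:
    person("Flowstream", "Maintainers", email = "maintainers@flowstream.invalid",
           role = c("aut", "cre"))
Description: Tools to stratify hospital admissions into four resource-based
    "flow streams" from routinely collected electronic medical record (EMR)
    extracts. The package generates seeded synthetic EMR encounter and event
    tables with per-stream resource archetypes and injected documentation
    defects, cleans and deterministically links encounters into admission
    episodes with a time-based gap threshold, de-identifies episodes via a
    separate identity map, derives resource-utilisation features at 24 h,
    72 h and discharge evaluation windows, classifies every episode with a
    hierarchical rule set (FS1, FS4, FS2, then FS3), and reports stream
    transitions, stratified cohort summaries and data-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
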