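# End-to-end orchestration (simulate -> clean -> link -> de-identify ->
# classify -> report), CSV writers and a small command-line front end.

#' Run the full flow-stream pipeline in memory
#'
#' Generates a synthetic cohort (unless raw tables are supplied), cleans it,
#' links encounters into episodes at the gap threshold, de-identifies them,
#' classifies every episode at the three evaluation windows and produces the
#' summary, transition and quality reports.
#'
#' @param config a [cohort_config()]; ignored when `raw` is supplied
#' @param defects a [defect_config()]
#' @param rules a [rule_config()]
#' @param gap_hours linkage gap threshold in hours
#' @param raw optional list with `encounters`/`events` (and optionally
#'   `truth`) to run the pipeline on pre-existing tables
#' @param reference_counts optional external reference counts for the quality
#'   report, e.g. `c(mtp_activation = 355)`
#' @return list with `raw`, `truth`, `cleaned`, `cleaning_log`, `episodes`,
#'   `episode_events`, `identity_map`, `features`, `assignments`,
#'   `trajectories`, `transitions_24h_72h`, `transitions_72h_discharge`,
#'   `percent_reclassified`, `stream_summary`, `source_by_stream`, `quality`
#' @export
#' @examples
#' run <- run_pipeline(cohort_config(n_patients = 30, seed = 7),
#'                     defects = defects_off())
#' run$trajectories[1:3]
#' run$percent_reclassified
run_pipeline <- function(config = cohort_config(n_patients = 1000),
                         defects = defect_config(),
                         rules = rule_config(),
                         gap_hours = 6,
                         raw = NULL,
                         reference_counts = NULL) {
  if (is.null(raw)) raw <- simulate_emr(config, defects)
  truth <- raw$truth %||% NULL

  cleaned <- clean_events(raw$encounters, raw$events)
  linked <- link_episodes(cleaned$encounters, cleaned$events, gap_hours)
  deid <- deidentify(linked$episodes, linked$events)

  cls <- classify_trajectories(deid$episodes, deid$events, rules)
  t1 <- transition_table(cls$trajectories, "24h", "72h")
  t2 <- transition_table(cls$trajectories, "72h", "discharge")

  summary <- summarize_streams(deid$episodes, cls$assignments, cls$features,
                               rules)
  srctab <- source_by_stream(deid$episodes, cls$assignments)
  quality <- quality_report(cleaned, deid$episodes, deid$events,
                            reference_counts)

  list(raw = raw[c("encounters", "events")], truth = truth,
       cleaned = cleaned[c("encounters", "events")],
       cleaning_log = cleaned$log,
       episodes = deid$episodes, episode_events = deid$events,
       identity_map = deid$identity_map,
       features = cls$features, assignments = cls$assignments,
       trajectories = cls$trajectories,
       transitions_24h_72h = t1, transitions_72h_discharge = t2,
       percent_reclassified = percent_reclassified(cls$trajectories),
       stream_summary = summary, source_by_stream = srctab,
       quality = quality)
}

# write a data.table as CSV with ISO 8601 timestamps and rounded LOS
write_flow_csv <- function(dt, path) {
  dt <- data.table::copy(data.table::as.data.table(dt))
  for (col in names(dt)) {
    if (inherits(dt[[col]], "POSIXct"))
      data.table::set(dt, j = col, value = format_ts(dt[[col]]))
  }
  if ("los_days_observed" %in% names(dt))
    dt[, los_days_observed := round(los_days_observed, 1)]
  data.table::fwrite(dt, path)
  invisible(path)
}

write_matrix_csv <- function(m, path) {
  dt <- data.table::as.data.table(m, keep.rownames = "from")
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Write pipeline outputs to a directory
#'
#' Writes `encounters.csv`/`events.csv` (raw), `cleaning_log.csv`,
#' `episodes.csv`, `episode_events.csv`, `features.csv`, `assignments.csv`,
#' `trajectories.csv`, `transitions_24h_72h.csv`,
#' `transitions_72h_discharge.csv`, `stream_summary.csv`,
#' `source_by_stream.csv`, `quality_report.csv` and `truth.csv` (when
#' present). The identity map is written separately to `map_dir`
#' (default `<out_dir>/identity`), mirroring its storage apart from the
#' analytical dataset.
#'
#' @param run output of [run_pipeline()]
#' @param out_dir output directory (created if needed)
#' @param map_dir directory for `identity_map.csv`
#' @return invisibly, the output directory
#' @export
write_pipeline_outputs <- function(run, out_dir,
                                   map_dir = file.path(out_dir, "identity")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
  write_flow_csv(run$raw$encounters, file.path(out_dir, "encounters.csv"))
  write_flow_csv(run$raw$events, file.path(out_dir, "events.csv"))
  write_flow_csv(run$cleaning_log, file.path(out_dir, "cleaning_log.csv"))
  write_flow_csv(run$episodes, file.path(out_dir, "episodes.csv"))
  write_flow_csv(run$episode_events, file.path(out_dir, "episode_events.csv"))
  write_flow_csv(run$features, file.path(out_dir, "features.csv"))
  write_flow_csv(run$assignments, file.path(out_dir, "assignments.csv"))
  write_flow_csv(run$trajectories, file.path(out_dir, "trajectories.csv"))
  write_matrix_csv(run$transitions_24h_72h,
                   file.path(out_dir, "transitions_24h_72h.csv"))
  write_matrix_csv(run$transitions_72h_discharge,
                   file.path(out_dir, "transitions_72h_discharge.csv"))
  write_flow_csv(run$stream_summary, file.path(out_dir, "stream_summary.csv"))
  write_matrix_csv(run$source_by_stream,
                   file.path(out_dir, "source_by_stream.csv"))
  q <- run$quality
  write_flow_csv(data.table::data.table(metric = names(q),
                                        value = vapply(q, function(v)
                                          as.character(v %||% NA), "")),
                 file.path(out_dir, "quality_report.csv"))
  if (!is.null(run$truth)) {
    write_flow_csv(run$truth$patients, file.path(out_dir, "truth.csv"))
    write_flow_csv(run$truth$defects, file.path(out_dir, "truth_defects.csv"))
  }
  write_flow_csv(run$identity_map, file.path(map_dir, "identity_map.csv"))
  invisible(out_dir)
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        out[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  out
}

cohort_config_from_json <- function(path, seed_override = NULL) {
  cfg <- if (is.null(path)) list() else jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
  if (!is.null(seed_override)) cfg$seed <- as.integer(seed_override)
  if (!is.null(cfg$mixing_weights)) cfg$mixing_weights <-
      unlist(cfg$mixing_weights)
  keep <- intersect(names(cfg), names(formals(cohort_config)))
  do.call(cohort_config, cfg[keep])
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config <json> --out-dir <dir> [--seed N]`,
#' `link --encounters <csv> --events <csv> [--gap-hours 6] --out-dir <dir>`,
#' `classify --episodes <csv> --events <csv> --out-dir <dir>`, and
#' `run-all --config <json> --out-dir <dir> [--seed N]`. The JSON config
#' holds [cohort_config()] fields (`n_patients`, `seed`, `mixing_weights`,
#' ...). Installed as `exec/flowstream`; run via
#' `Rscript <pkg>/exec/flowstream <subcommand> ...`.
#'
#' @param args character vector of command-line arguments
#' @return invisibly, NULL
#' @export
flowstream_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: flowstream <simulate|link|classify|run-all> [--options]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- cli_args_to_list(args[-1])
  out_dir <- opt[["out-dir"]] %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (cmd == "simulate") {
    cfg <- cohort_config_from_json(opt$config, opt$seed)
    sim <- simulate_emr(cfg)
    write_flow_csv(sim$encounters, file.path(out_dir, "encounters.csv"))
    write_flow_csv(sim$events, file.path(out_dir, "events.csv"))
    write_flow_csv(sim$truth$patients, file.path(out_dir, "truth.csv"))
  } else if (cmd == "link") {
    enc <- data.table::fread(opt$encounters)
    ev <- data.table::fread(opt$events)
    cleaned <- clean_events(enc, ev)
    linked <- link_episodes(cleaned$encounters, cleaned$events,
                            as.numeric(opt[["gap-hours"]] %||% 6))
    deid <- deidentify(linked$episodes, linked$events)
    write_flow_csv(deid$episodes, file.path(out_dir, "episodes.csv"))
    write_flow_csv(deid$events, file.path(out_dir, "episode_events.csv"))
    write_flow_csv(cleaned$log, file.path(out_dir, "cleaning_log.csv"))
    map_dir <- opt[["map-dir"]] %||% file.path(out_dir, "identity")
    dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
    write_flow_csv(deid$identity_map, file.path(map_dir, "identity_map.csv"))
  } else if (cmd == "classify") {
    ep <- data.table::fread(opt$episodes)
    ep[, `:=`(admission_ts = parse_ts(admission_ts),
              discharge_ts = parse_ts(discharge_ts))]
    ev <- data.table::fread(opt$events)
    ev[, ts := parse_ts(ts)]
    cls <- classify_trajectories(ep, ev)
    write_flow_csv(cls$assignments, file.path(out_dir, "assignments.csv"))
    write_flow_csv(cls$trajectories, file.path(out_dir, "trajectories.csv"))
    if (isTRUE(opt[["dump-features"]]) || !is.null(opt[["dump-features"]]))
      write_flow_csv(cls$features, file.path(out_dir, "features.csv"))
    write_matrix_csv(transition_table(cls$trajectories, "24h", "72h"),
                     file.path(out_dir, "transitions_24h_72h.csv"))
    write_matrix_csv(transition_table(cls$trajectories, "72h", "discharge"),
                     file.path(out_dir, "transitions_72h_discharge.csv"))
  } else if (cmd == "run-all") {
    cfg <- cohort_config_from_json(opt$config, opt$seed)
    run <- run_pipeline(cfg)
    write_pipeline_outputs(run, out_dir)
  } else {
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  }
  invisible(NULL)
}
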