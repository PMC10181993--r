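#' Default configuration for an end-to-end pipeline run
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param n_varieties,n_plants_per_variety Cohort size.
#' @param noise_cv Conductivity noise level.
#' @param pressures Centrifuge pressure grid.
#' @param n_regions Synthetic bearing-table size.
#' @param uncovered_fraction_range Per-region uncovered share range.
#' @param k Number of vulnerability clusters.
#' @param min_coverage Regional coverage threshold, percent.
#' @return Named list, validated by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_varieties = 30L,
                            n_plants_per_variety = 6L, noise_cv = 0.05,
                            pressures = default_pressures(),
                            n_regions = 12L,
                            uncovered_fraction_range = c(0, 0.3),
                            k = 4L, min_coverage = 40) {
  list(out_dir = out_dir, seed = as.integer(seed),
       n_varieties = as.integer(n_varieties),
       n_plants_per_variety = as.integer(n_plants_per_variety),
       noise_cv = noise_cv, pressures = pressures,
       n_regions = as.integer(n_regions),
       uncovered_fraction_range = uncovered_fraction_range,
       k = as.integer(k), min_coverage = min_coverage)
}

validate_config <- function(config) {
  need <- names(formals(pipeline_config))
  need <- setdiff(need, "out_dir")
  missing <- setdiff(c("out_dir", need), names(config))
  if (length(missing) > 0) {
    stop("config is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(config$n_varieties >= config$k, config$noise_cv >= 0,
            config$min_coverage >= 0)
  invisible(config)
}

# deterministic per-stage sub-seed from the master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  (seed * 1000L + stage) %% .Machine$integer.max
}

#' Run the full pipeline: simulate, fit, aggregate, cluster, risk
#'
#' Executes the stages in dependency order, writing every intermediate
#' table as CSV to `config$out_dir` plus a JSON run manifest with file
#' checksums. Given the same config (including seed) the output file
#' contents are identical across runs.
#'
#' @param config List from [pipeline_config()], or a path to a YAML/JSON
#'   config read by the caller.
#' @param sweeps Optional pre-existing long sweep table (or CSV path); when
#'   supplied the simulation stage is skipped.
#' @param bearing Optional pre-existing bearing table (or CSV path).
#' @return The run manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config, sweeps = NULL, bearing = NULL) {
  validate_config(config)
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(sweeps)) {
    if (!file.exists(sweeps)) stop("stage simulate: sweeps file not found: ",
                                   sweeps, call. = FALSE)
    sweeps <- read_sweeps(sweeps)
  }
  if (is.character(bearing)) {
    if (!file.exists(bearing)) stop("stage risk: bearing file not found: ",
                                    bearing, call. = FALSE)
    bearing <- read_bearing(bearing)
  }

  panel <- default_variety_panel(config$n_varieties)
  stages <- character(0)

  run_stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(sweeps)) {
    cohort <- run_stage("simulate", gen_cohort(
      panel, config$n_plants_per_variety, pressures = config$pressures,
      noise_cv = config$noise_cv, seed = stage_seed(config$seed, 1L)))
    sweeps <- cohort$sweeps
    utils::write.csv(cohort$truth, file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  write_sweeps(sweeps, file.path(config$out_dir, "sweeps.csv"))

  fits <- run_stage("fit", fit_sweeps(sweeps))
  utils::write.csv(fits, file.path(config$out_dir, "fits.csv"),
                   row.names = FALSE)

  summaries <- run_stage("aggregate",
                         suppressWarnings(aggregate_variety(fits)))
  utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                   row.names = FALSE)

  clust <- run_stage("cluster", cluster_varieties(summaries, k = config$k))
  utils::write.csv(clust$assignment,
                   file.path(config$out_dir, "clusters.csv"),
                   row.names = FALSE)

  if (is.null(bearing)) {
    bt <- run_stage("bearing", gen_bearing_table(
      config$n_regions, panel$variety_name,
      uncovered_fraction_range = config$uncovered_fraction_range,
      seed = stage_seed(config$seed, 2L)))
    bearing <- bt$table
  }
  utils::write.csv(bearing, file.path(config$out_dir, "bearing.csv"),
                   row.names = FALSE)

  report <- run_stage("risk", ri_report(bearing, clust$assignment,
                                        min_coverage = config$min_coverage))
  utils::write.csv(report$risks, file.path(config$out_dir, "risks.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg <- config
  cfg$pressures <- as.numeric(cfg$pressures)
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  outputs <- c("sweeps.csv", "fits.csv", "summaries.csv", "clusters.csv",
               "bearing.csv", "risks.csv", "summary.json", "config.json")
  outputs <- outputs[file.exists(file.path(config$out_dir, outputs))]
  manifest <- list(
    stages = stages,
    seed = config$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = as.list(tools::md5sum(file.path(config$out_dir, outputs)))
  )
  names(manifest$files) <- outputs
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a small demo dataset for documentation and tests
#'
#' Deterministic per seed: a 6-variety x 4-plant sweep table, one small
#' dehydration stack with its water-potential timeline, a vessels table and
#' a 3-region bearing table.
#'
#' @param out_dir Directory to write into (created if needed).
#' @param seed Master seed.
#' @return Invisible named vector of the files written.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- default_variety_panel(6L)
  cohort <- gen_cohort(panel, 4L, seed = stage_seed(seed, 11L))
  write_sweeps(cohort$sweeps, file.path(out_dir, "demo_sweeps.csv"))

  events <- data.frame(frame = c(4L, 8L, 12L, 16L, 20L),
                       area_px = c(40L, 35L, 50L, 30L, 45L),
                       row = c(5L, 20L, 35L, 12L, 42L),
                       col = c(5L, 30L, 10L, 45L, 40L))
  stack <- gen_dehydration_stack(24L, c(56L, 56L), events,
                                 background_noise_sd = 0.5,
                                 seed = stage_seed(seed, 12L))
  write_stack(stack, file.path(out_dir, "demo_stack.tif"))
  timeline <- gen_psi_timeline(-0.5, -3.5, duration_h = 2,
                               interval_min = 30)
  write_timeline(timeline, file.path(out_dir, "demo_psi.csv"))

  vs <- gen_vessels(60, xylem_area_mm2 = 1.2, seed = stage_seed(seed, 13L))
  vessels <- cbind(data.frame(section_id = "S01", variety = "VAR01"),
                   vs$vessels, xylem_area_m2 = vs$xylem_area_m2)
  utils::write.csv(vessels, file.path(out_dir, "demo_vessels.csv"),
                   row.names = FALSE)

  bt <- gen_bearing_table(3L, panel$variety_name,
                          seed = stage_seed(seed, 14L))
  utils::write.csv(bt$table, file.path(out_dir, "demo_bearing.csv"),
                   row.names = FALSE)

  files <- c(sweeps = "demo_sweeps.csv", stack = "demo_stack.tif",
             psi = "demo_psi.csv", vessels = "demo_vessels.csv",
             bearing = "demo_bearing.csv")
  invisible(stats::setNames(file.path(out_dir, files), names(files)))
}
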