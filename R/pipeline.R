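# End-to-end orchestration: simulate -> process -> detect -> join -> fit ->
# validate, with every intermediate artefact materialized as CSV in a run
# directory plus a JSON manifest sufficient to reproduce the run.

#' Assemble and validate a pipeline run configuration
#'
#' @param seed Master seed; every stage RNG derives from it.
#' @param sim Named list of [sim_config()] overrides.
#' @param kinematics List: `window_s`, `flip_pitch`.
#' @param segmentation List: `dive_threshold_m`, `min_duration_s`,
#'   `trip_gap_min`.
#' @param search List: `pitch_threshold`, `depth_threshold`, `min_event_s`.
#' @param covariates List: `source` (`"simulated"` to use the simulator's
#'   raster, or `"file"` with `grid_path` naming ASCII-grid layers
#'   `<layer>.asc` in a directory).
#' @param model List: `fit` (logical), `predictors`, `n_iter`, `burn_in`,
#'   `n_chains`, `method`, `prior`.
#' @param write_sensors Write per-trip sensor CSVs into the run directory?
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1, sim = list(), kinematics = list(),
                       segmentation = list(), search = list(),
                       covariates = list(source = "simulated"),
                       model = list(fit = TRUE), write_sensors = TRUE) {
  cfg <- list(seed = seed, sim = sim, kinematics = kinematics,
              segmentation = segmentation, search = search,
              covariates = covariates, model = model,
              write_sensors = isTRUE(write_sensors))
  cfg$covariates$source <- cfg$covariates$source %||% "simulated"
  if (cfg$covariates$source == "file" && is.null(cfg$covariates$grid_path)) {
    abort("config error: covariates requested from file but key 'covariates$grid_path' is missing.",
          class = "sealsearch_config_error")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort("config error: key 'seed' must be a single integer.",
          class = "sealsearch_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Executes simulate -> kinematics -> dive segmentation -> search detection
#' -> covariate join -> model fit -> validation, writing all artefacts and a
#' manifest into `out_dir`. Rerunning with the same configuration and seed
#' reproduces byte-identical dive tables and posterior summaries.
#'
#' @param config A [run_config()] (or plain list of its arguments).
#' @param out_dir Run directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return List: `dives`, `events`, `fit` (or `NULL`), `validation`,
#'   `manifest`, `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("seal-run-"),
                         quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  counts <- list()
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    if (!quiet) message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "sealsearch_pipeline_error", parent = e)
    })
  }

  scfg <- do.call(sim_config, config$sim)
  dep <- stage("simulate", simulate_deployment(scfg, config$seed))
  say("simulate", "%d trips over a %dx%d-cell grid",
      length(dep$trips), scfg$grid_n, scfg$grid_n)

  kin_args <- config$kinematics
  seg_args <- config$segmentation
  srch_args <- config$search
  processed <- stage("process", purrr::imap(dep$trips, function(trip, i) {
    kin <- derive_kinematics(trip$sensors,
                             window_s = kin_args$window_s %||% 2,
                             flip_pitch = isTRUE(kin_args$flip_pitch))
    res <- summarize_dives(
      kin,
      dive_threshold_m = seg_args$dive_threshold_m %||% -1.5,
      min_duration_s = seg_args$min_duration_s %||% 8,
      pitch_threshold = srch_args$pitch_threshold %||% 70,
      depth_threshold = srch_args$depth_threshold %||% -3,
      min_event_s = srch_args$min_event_s %||% 0,
      trip_gap_min = seg_args$trip_gap_min %||% 30)
    if (nrow(res$dives) > 0) {
      res$dives$trip_id <- i
      res$dives$dive_id <- sprintf("%s-t%02d-%s", res$dives$seal_id, i,
                                   sub("^.*-", "", res$dives$dive_id))
      if (nrow(res$events) > 0) {
        res$events$dive_id <- sprintf("%s-t%02d-%s",
                                      res$dives$seal_id[1], i,
                                      sub("^.*-", "", res$events$dive_id))
      }
    }
    if (config$write_sensors) {
      write_sensor_csv(trip$sensors,
                       file.path(out_dir, sprintf("sensors-trip%02d.csv", i)))
      write_gps_csv(trip$gps, file.path(out_dir, sprintf("gps-trip%02d.csv", i)))
    }
    list(trip = trip, dives = res$dives, events = res$events)
  }))
  dives <- bind_rows(purrr::map(processed, "dives"))
  events <- bind_rows(purrr::map(processed, "events"))
  say("detect", "%d dives, %d search events", nrow(dives), nrow(events))
  counts$dives <- nrow(dives); counts$events <- nrow(events)

  env <- if (config$covariates$source == "file") {
    stage("covariates", load_env_grid(config$covariates$grid_path))
  } else dep$env
  dives <- stage("covariates", {
    joined <- purrr::map2_dfr(processed, seq_along(processed), function(pr, i) {
      if (nrow(pr$dives) == 0) return(pr$dives)
      join_covariates(pr$dives, pr$trip$gps, env$grid,
                      special_polygons = env$polygons %||% list())
    })
    prepare_model_frame(joined)
  })
  write_dive_table(dives, file.path(out_dir, "dives.csv"))
  if (nrow(events) > 0) write_events_csv(events, file.path(out_dir, "events.csv"))
  truth_dives <- bind_rows(purrr::imap(dep$trips, function(trip, i) {
    mutate(trip$truth$dives, trip_index = i,
           seal_id = attr(trip$sensors, "seal_id"))
  }))
  readr::write_csv(truth_dives, file.path(out_dir, "truth-dives.csv"), progress = FALSE)

  fit <- NULL
  if (isTRUE(config$model$fit %||% TRUE) &&
      length(unique(dives$seal_id)) >= 2 && dplyr::n_distinct(dives$searching) > 1) {
    mcfg <- config$model
    fit <- stage("fit", fit_search_model(
      dives,
      predictors = mcfg$predictors %||% search_predictors(),
      n_iter = mcfg$n_iter %||% 7500, burn_in = mcfg$burn_in %||% 2000,
      n_chains = mcfg$n_chains %||% 3,
      method = mcfg$method %||% "gibbs", prior = mcfg$prior %||% "shared",
      seed = derive_seed(config$seed, 6L)))
    write_posterior_summary(fit, file.path(out_dir, "posterior-summary.csv"))
    say("fit", "max R-hat %.3f", max(fit$summary$rhat, na.rm = TRUE))
  } else {
    say("fit", "skipped (disabled, single seal, or constant response)")
  }

  validation <- stage("validate", validation_report(
    dep, pitch_threshold = srch_args$pitch_threshold %||% 70,
    depth_threshold = srch_args$depth_threshold %||% -3,
    sweep = NULL))
  readr::write_csv(validation$confusion,
                   file.path(out_dir, "validation-confusion.csv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sealsearch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    counts = counts,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done", "artefacts in %s", out_dir)
  invisible(list(dives = dives, events = events, fit = fit,
                 validation = validation, manifest = manifest,
                 out_dir = out_dir))
}

# Load an env_grid from a directory of <layer>.asc files.
load_env_grid <- function(dir) {
  paths <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (length(paths) == 0) {
    abort(sprintf("no .asc layers found under '%s'.", dir),
          class = "sealsearch_config_error")
  }
  layers <- list(); meta <- NULL
  for (p in paths) {
    g <- read_ascii_grid(p)
    layers[[sub("\\.asc$", "", basename(p))]] <- g$matrix
    meta <- g
  }
  list(grid = env_grid(layers, x0 = meta$x0, y0 = meta$y0,
                       cellsize = meta$cellsize),
       polygons = list())
}
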