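# Detector validation against ground-truth labels, and the
# parameter-recovery experiment for the hierarchical model.

#' Confusion matrix for dive classifications
#'
#' Standard 2x2 counts comparing predicted searching flags with observed
#' (ground-truth) flags, pooled and optionally per seal.
#'
#' @param data Data frame with logical columns `predicted` and `observed`,
#'   optionally `seal_id` (and `dive_id` when rows from two sources must be
#'   matched first — see [match_dive_labels()]).
#' @return Tibble with one row per seal plus a `"pooled"` row: `tp, fp, fn,
#'   tn, n, accuracy, sensitivity, specificity`.
#' @export
confusion <- function(data) {
  check_columns(data, c("predicted", "observed"), "classification table")
  cm <- function(d, id) {
    tp <- sum(d$predicted & d$observed)
    fp <- sum(d$predicted & !d$observed)
    fn <- sum(!d$predicted & d$observed)
    tn <- sum(!d$predicted & !d$observed)
    tibble(seal_id = id, tp = tp, fp = fp, fn = fn, tn = tn,
           n = tp + fp + fn + tn,
           accuracy = (tp + tn) / (tp + fp + fn + tn),
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  per_seal <- if ("seal_id" %in% names(data)) {
    bind_rows(purrr::map(split(data, data$seal_id), ~ cm(.x, .x$seal_id[1])))
  } else NULL
  bind_rows(per_seal, cm(data, "pooled"))
}

#' Match predicted and observed dive labels by dive id
#'
#' @param predicted Tibble `dive_id, searching` from the detector.
#' @param observed Tibble `dive_id, searching` from ground truth.
#' @return Tibble `dive_id, predicted, observed` ready for [confusion()].
#' @export
match_dive_labels <- function(predicted, observed) {
  check_columns(predicted, c("dive_id", "searching"), "predicted labels")
  check_columns(observed, c("dive_id", "searching"), "observed labels")
  unmatched <- c(setdiff(predicted$dive_id, observed$dive_id),
                 setdiff(observed$dive_id, predicted$dive_id))
  if (length(unmatched) > 0) {
    abort(sprintf("unmatched dive_id(s): %s",
                  paste(head(unmatched, 5), collapse = ", ")),
          class = "sealsearch_alignment_error")
  }
  obs <- as.logical(observed$searching[match(predicted$dive_id,
                                             observed$dive_id)])
  tibble(dive_id = predicted$dive_id,
         predicted = as.logical(predicted$searching),
         observed = obs)
}

#' Bundled camera ground-truthing counts for the pitch metric
#'
#' Published validation counts from a four-seal study in which dives with
#' concurrent head-down video footage were scored independently by a human
#' observer (observed) and by the pitch/depth threshold rule (predicted).
#' Two seals each had a single false positive; the other two had only false
#' negatives (attributed to tag placement). Of `n_dives_total` dives
#' recorded on the tags, `n_dives_matched` could be matched to concurrent
#' video.
#'
#' @return Tibble `seal_id, observed, predicted, n` with attributes
#'   `n_dives_total` (3138) and `n_dives_matched` (93).
#' @export
video_validation_counts <- function() {
  counts <- tibble(
    seal_id = rep(c("R306", "RM38", "RW02", "RV18"), each = 4),
    observed = rep(c(TRUE, TRUE, FALSE, FALSE), times = 4),
    predicted = rep(c(TRUE, FALSE, TRUE, FALSE), times = 4),
    n = c(2, 8, 0, 26,
          0, 9, 0, 20,
          12, 0, 1, 2,
          8, 0, 1, 0)
  )
  attr(counts, "n_dives_total") <- 3138L
  attr(counts, "n_dives_matched") <- 93L
  counts
}

#' Confusion summary from aggregated counts
#'
#' Expands a count table (`observed, predicted, n`, optionally `seal_id`)
#' to per-dive rows and delegates to [confusion()].
#'
#' @param counts Count tibble such as [video_validation_counts()].
#' @return See [confusion()].
#' @export
confusion_from_counts <- function(counts) {
  check_columns(counts, c("observed", "predicted", "n"), "count table")
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), ]
  confusion(rows)
}

# Overlap-match detected dives/events to planted truth intervals.
overlap_any <- function(start, end, t_start, t_end) {
  vapply(seq_along(start), function(i) {
    any(start[i] <= t_end & end[i] >= t_start)
  }, logical(1))
}

#' Validate the detector on one simulated trip
#'
#' Runs the full processing chain (kinematics, dive segmentation, event
#' detection) on a simulated trip and scores it against the simulator's
#' truth labels.
#'
#' @param trip A [simulate_sensor_trip()] result.
#' @param pitch_threshold,depth_threshold,min_event_s Detector settings.
#' @param window_s Gravity-filter window (s).
#' @return List: `dives` (per-dive tibble with predicted and observed
#'   flags), `event_recall`, `event_spurious_rate`, counts of planted and
#'   detected events.
#' @export
validate_trip <- function(trip, pitch_threshold = 70, depth_threshold = -3,
                          min_event_s = 0, window_s = 2) {
  kin <- derive_kinematics(trip$sensors, window_s = window_s)
  res <- summarize_dives(kin, pitch_threshold = pitch_threshold,
                         depth_threshold = depth_threshold,
                         min_event_s = min_event_s)
  truth <- trip$truth
  if (nrow(res$dives) == 0) {
    return(list(dives = tibble(), event_recall = NA_real_,
                event_spurious_rate = NA_real_,
                n_events_true = nrow(truth$events), n_events_detected = 0))
  }
  # match detected dives to truth dives by interval overlap
  d <- res$dives
  truth_idx <- vapply(seq_len(nrow(d)), function(i) {
    hit <- which(truth$dives$start_s <= d$end_s[i] &
                   truth$dives$end_s >= d$start_s[i])
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  dives <- mutate(d, truth_dive = truth_idx,
                  predicted = .data$searching,
                  observed = truth$dives$searching[truth_idx])
  ev_true <- truth$events
  ev_det <- res$events
  recall <- if (nrow(ev_true) == 0) NA_real_ else
    mean(overlap_any(ev_true$start_s, ev_true$end_s,
                     ev_det$start_s, ev_det$end_s))
  spurious <- if (nrow(ev_det) == 0) 0 else
    mean(!overlap_any(ev_det$start_s, ev_det$end_s,
                      ev_true$start_s, ev_true$end_s))
  list(dives = dives, event_recall = recall, event_spurious_rate = spurious,
       n_events_true = nrow(ev_true), n_events_detected = nrow(ev_det))
}

#' Validation report for a simulated deployment
#'
#' Aggregates [validate_trip()] over every trip of a deployment: dive-level
#' confusion matrix (pooled and per seal), event-level recall and spurious
#' rate, and a sensitivity curve over pitch thresholds.
#'
#' @param deployment A [simulate_deployment()] result.
#' @param pitch_threshold,depth_threshold,min_event_s,window_s Detector
#'   settings for the headline numbers.
#' @param sweep Pitch thresholds (deg) for the sensitivity curve; `NULL` to
#'   skip.
#' @return List of class `validation_report`: `confusion`, `event_recall`,
#'   `event_spurious_rate`, `sweep` (tibble `pitch_threshold, sensitivity,
#'   accuracy`), `dives`.
#' @export
validation_report <- function(deployment, pitch_threshold = 70,
                              depth_threshold = -3, min_event_s = 0,
                              window_s = 2, sweep = seq(50, 85, by = 5)) {
  run_all <- function(thr) {
    purrr::map(deployment$trips, validate_trip, pitch_threshold = thr,
               depth_threshold = depth_threshold,
               min_event_s = min_event_s, window_s = window_s)
  }
  base <- run_all(pitch_threshold)
  dives <- bind_rows(purrr::map(base, "dives"))
  conf <- confusion(dives)
  recalls <- purrr::map_dbl(base, "event_recall")
  n_true <- purrr::map_dbl(base, "n_events_true")
  n_det <- purrr::map_dbl(base, "n_events_detected")
  spur <- purrr::map_dbl(base, "event_spurious_rate")
  sweep_tbl <- NULL
  if (!is.null(sweep)) {
    sweep_tbl <- purrr::map_dfr(sweep, function(thr) {
      res <- if (thr == pitch_threshold) base else run_all(thr)
      dd <- bind_rows(purrr::map(res, "dives"))
      cm <- filter(confusion(dd), .data$seal_id == "pooled")
      tibble(pitch_threshold = thr, sensitivity = cm$sensitivity,
             accuracy = cm$accuracy)
    })
  }
  structure(
    list(confusion = conf,
         event_recall = stats::weighted.mean(recalls, n_true, na.rm = TRUE),
         event_spurious_rate = stats::weighted.mean(spur, pmax(n_det, 1),
                                                    na.rm = TRUE),
         sweep = sweep_tbl, dives = dives),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  pooled <- filter(x$confusion, .data$seal_id == "pooled")
  cat(sprintf("<validation_report> %d dives; accuracy %.1f%%, event recall %.1f%%, spurious %.1f%%\n",
              pooled$n, 100 * pooled$accuracy, 100 * x$event_recall,
              100 * x$event_spurious_rate))
  invisible(x)
}

#' Parameter-recovery experiment for the search model
#'
#' Simulates a dive table from the hierarchical logistic model with known
#' coefficients and refits it, reporting, per coefficient: the generating
#' truth, posterior mean and sd, the 95% HPD, and whether the truth lies
#' within the HPD and within three posterior sds of the posterior mean.
#' Deterministic given `seed`.
#'
#' @param config A [sim_config()]; its `beta0`, `beta`, `sigma_alpha` are
#'   the generating truth.
#' @param seed Master seed (simulation and sampler).
#' @param ... Passed to [fit_search_model()] (e.g. `n_iter`, `n_chains`).
#' @return List: `recovery` (tibble, one row per coefficient), `fit`,
#'   `dives`.
#' @export
recovery_experiment <- function(config = sim_config(), seed = 1, ...) {
  sim <- simulate_dive_table(config, seed)
  fit <- fit_search_model(sim$dives, predictors = names(config$beta),
                          seed = derive_seed(seed, 5L), ...)
  truth <- c("(Intercept)" = unname(sim$truth$beta0), sim$truth$beta,
             sigma_alpha = unname(sim$truth$sigma_alpha))
  rec <- fit$summary %>%
    filter(.data$term %in% names(truth)) %>%
    mutate(truth = unname(truth[.data$term]),
           within_3sd = abs(.data$estimate - .data$truth) <= 3 * .data$std.error,
           hpd_covers = .data$conf.low <= .data$truth &
             .data$truth <= .data$conf.high) %>%
    dplyr::relocate("truth", .after = "term")
  list(recovery = rec, fit = fit, dives = sim$dives)
}
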