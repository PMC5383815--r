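# ggplot2 visualisations for the pipeline's result types.

#' Caterpillar plot of posterior estimates
#'
#' Posterior means with 95% HPD intervals for the fixed effects (and
#' optionally the per-seal random intercepts) of a fitted search model.
#'
#' @param object A `search_fit`.
#' @param include_random Also show the per-seal intercepts?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.search_fit <- function(object, include_random = FALSE, ...) {
  s <- object$summary
  keep <- seq_len(object$n_beta)
  if (include_random) keep <- c(keep, grep("^alpha\\[", s$term))
  s <- s[keep, ]
  s$term <- factor(s$term, levels = rev(s$term))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "posterior mean (95% HPD)", y = NULL,
                  title = "Search-occurrence model: posterior estimates") +
    ggplot2::theme_minimal()
}

#' Trace plot of posterior draws
#' @param fit A `search_fit`.
#' @param terms Parameters to show (default: the fixed effects).
#' @return A ggplot.
#' @export
plot_traces <- function(fit, terms = fit$par_names[seq_len(fit$n_beta)]) {
  d <- filter(posterior_draws(fit), .data$term %in% terms)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(colour = "chain", y = NULL) +
    ggplot2::theme_minimal()
}

#' Depth and pitch profile of a processed record
#'
#' Two aligned panels — depth and pitch against time — with detected search
#' events shaded; the visual check used when ground-truthing the pitch
#' metric against video.
#'
#' @param kin A kinematics-augmented series from [derive_kinematics()].
#' @param events Optional event tibble from [detect_search_events()] /
#'   [summarize_dives()].
#' @param pitch_threshold,depth_threshold Detector thresholds drawn as
#'   reference lines.
#' @return A ggplot.
#' @export
plot_dive_profile <- function(kin, events = NULL, pitch_threshold = 70,
                              depth_threshold = -3) {
  d <- tidyr::pivot_longer(as_tibble(kin)[c("time", "depth", "pitch")],
                           cols = c("depth", "pitch"),
                           names_to = "channel", values_to = "value")
  refs <- tibble(channel = c("depth", "pitch"),
                 value = c(depth_threshold, pitch_threshold))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value))
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      fill = "goldenrod", alpha = 0.3)
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = refs, ggplot2::aes(yintercept = .data$value),
                        linetype = 2, colour = "red3") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Sensitivity curve over pitch thresholds
#' @param object A `validation_report` with a threshold sweep.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validation_report <- function(object, ...) {
  if (is.null(object$sweep)) {
    abort("validation report has no threshold sweep (sweep = NULL).")
  }
  d <- tidyr::pivot_longer(object$sweep, cols = c("sensitivity", "accuracy"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pitch_threshold, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "pitch threshold (deg)", y = NULL,
                  title = "Detector performance vs pitch threshold") +
    ggplot2::theme_minimal()
}

#' Map of search effort
#'
#' Dive locations sized by time spent searching — the standard spatial
#' summary of foraging effort for a tracked animal.
#'
#' @param dives Covariate-joined dive tibble (columns `x, y,
#'   search_time_s`, optionally `shore_km`).
#' @return A ggplot.
#' @export
plot_search_map <- function(dives) {
  check_columns(dives, c("x", "y", "search_time_s"), "dive table")
  aes_args <- ggplot2::aes(x = .data$x, y = .data$y,
                           size = .data$search_time_s)
  p <- ggplot2::ggplot(dives, aes_args)
  if ("shore_km" %in% names(dives)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$shore_km),
                                 alpha = 0.7) +
      ggplot2::scale_colour_gradient(low = "white", high = "darkgreen")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)",
                  size = "search time (s)") +
    ggplot2::theme_minimal()
}
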