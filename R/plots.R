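#' Diagnostic plots
#'
#' `autoplot()` methods give quick ggplot2 diagnostics for each result type:
#' a FRET histogram with its fitted mixture and thresholds, a time course
#' with its one-phase association curve, a survival curve with its
#' exponential fit, and an idealized trajectory.
#'
#' @param object A fitted smfret object.
#' @param ... Unused.
#' @return A ggplot.
#' @name smfret_plots
NULL

#' @rdname smfret_plots
#' @export
autoplot.fret_mixture_fit <- function(object, ...) {
  comp <- object$components
  grid <- tibble(x = seq(min(object$histogram$x), max(object$histogram$x),
                         length.out = 400))
  curves <- purrr::pmap(comp, function(weight, mean, sd) {
    mutate(grid, density = weight * dnorm(.data$x, mean, sd))
  }) |>
    purrr::imap(~ mutate(.x, component = paste0("component ", .y))) |>
    bind_rows()
  total <- grid |>
    mutate(density = purrr::reduce(
      purrr::pmap(comp, function(weight, mean, sd) weight * dnorm(grid$x, mean, sd)),
      `+`), component = "sum")
  ggplot2::ggplot(object$histogram, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey80") +
    ggplot2::geom_line(data = bind_rows(curves, total),
                       ggplot2::aes(y = .data$density, colour = .data$component)) +
    ggplot2::geom_vline(xintercept = object$thresholds, linetype = 2) +
    ggplot2::labs(x = "FRET efficiency", y = "density",
                  title = "Three-Gaussian mixture fit") +
    ggplot2::theme_minimal()
}

#' @rdname smfret_plots
#' @param trim_after Hide timepoints later than this from the plot (the fit
#'   always uses all points); `NULL` shows everything.
#' @export
autoplot.assoc_fit <- function(object, trim_after = NULL, ...) {
  pts <- object$data
  if (!is.null(trim_after)) pts <- filter(pts, .data$t_min <= trim_after)
  grid <- tibble(t_min = seq(0, max(pts$t_min), length.out = 200))
  grid$f_unwound <- predict(object, grid$t_min)
  ggplot2::ggplot(pts, ggplot2::aes(.data$t_min, .data$f_unwound)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "fraction unwound",
                  title = "One-phase association fit") +
    ggplot2::theme_minimal()
}

#' @rdname smfret_plots
#' @export
autoplot.fret_survival <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$duration_s, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "dwell time (s)", y = "1 - CDF") +
    ggplot2::theme_minimal()
}

#' @rdname smfret_plots
#' @export
autoplot.exp_fit <- function(object, ...) {
  curve <- object$data
  grid <- tibble(duration_s = seq(0, max(curve$duration_s), length.out = 200))
  e <- object$estimate
  grid$survival <- e[["y0"]] + e[["A1"]] * exp(-e[["k"]] * grid$duration_s)
  ggplot2::ggplot(curve, ggplot2::aes(.data$duration_s, .data$survival)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "dwell time (s)", y = "1 - CDF",
                  title = sprintf("Single-exponential fit: k = %.3g s⁻¹",
                                  e[["k"]])) +
    ggplot2::theme_minimal()
}

#' @rdname smfret_plots
#' @export
autoplot.hmm_fit <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(.data$time_s, .data$state)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "state",
                  title = "Viterbi-idealized state path") +
    ggplot2::theme_minimal()
}

#' Plot one molecule's intensity trace and FRET trajectory
#'
#' @param traces A trace tibble.
#' @param molecule Molecule id to plot.
#' @param background Per-channel background subtracted before computing FRET.
#' @return A ggplot with intensity and FRET panels.
#' @export
plot_trace <- function(traces, molecule = 1, background = 0) {
  tr <- filter(traces, .data$molecule == !!molecule,
               .data$excitation == "donor_ex")
  fr <- compute_fret(tr, background, background)
  long <- tidyr::pivot_longer(tr, c("donor", "acceptor"),
                              names_to = "channel", values_to = "intensity")
  p1 <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$intensity,
                                           colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(donor = "darkgreen",
                                            acceptor = "firebrick")) +
    ggplot2::labs(x = NULL, y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(fr, ggplot2::aes(.data$time_s, .data$fret)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(-0.1, 1.1)) +
    ggplot2::labs(x = "time (s)", y = "FRET") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p1, p2, ncol = 1)
  } else {
    p2
  }
}
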