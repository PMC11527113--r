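#' Fraction-unwound time course from a snapshot dataset
#'
#' Computes the unwound fraction at each timepoint of a snapshot experiment.
#' By default the classification window is derived per dataset: a single
#' three-Gaussian fit to all FRET values pooled across timepoints yields the
#' intersection thresholds (the populations only shift weight over time, so
#' pooling stabilizes the peak positions). A fixed [classification_rule()]
#' (e.g. [rule_pam_proximal()]) can be supplied instead for reproduction
#' runs.
#'
#' @param snapshots A `snapshot_dataset` from [simulate_snapshot_experiment()]
#'   or any tibble with columns `t_min` and `fret`.
#' @param rule A [classification_rule()], or `NULL` to derive thresholds
#'   from a pooled three-Gaussian fit.
#' @param per_timepoint_fit If `TRUE` (and `rule` is `NULL`), fit the
#'   mixture and derive thresholds separately at every timepoint instead of
#'   pooling.
#' @param bin_width Histogram bin width passed to [fit_three_gaussians()].
#' @return A tibble with one row per timepoint: `t_min`, `f_unwound`,
#'   `n_total` (classified values), plus the window bounds used.
#' @export
fraction_unwound_timecourse <- function(snapshots, rule = NULL,
                                        per_timepoint_fit = FALSE,
                                        bin_width = 0.02) {
  stopifnot(all(c("t_min", "fret") %in% names(snapshots)))
  tps <- sort(unique(snapshots$t_min))
  fit_rule <- function(values) {
    thresholds_rule(fit_three_gaussians(values, bin_width = bin_width))
  }
  if (is.null(rule) && !per_timepoint_fit) {
    rule <- fit_rule(snapshots$fret)
  }
  purrr::map(tps, function(tp) {
    values <- snapshots$fret[snapshots$t_min == tp]
    r <- rule %||% fit_rule(values)
    fu <- fraction_unwound(values, r)
    tibble(t_min = tp, f_unwound = fu$f_unwound, n_total = fu$n_total,
           lower = r$lower, upper = r$upper)
  }) |>
    bind_rows()
}

#' Fit the one-phase association model to a time course
#'
#' Estimates `(y0, plateau, k)` in `y = y0 + (plateau - y0) * (1 - exp(-k t))`
#' by nonlinear least squares. Starting values are `y0 =` first fraction,
#' `plateau =` last fraction and `k = 1 / median(t)`; parameters are kept in
#' loose sanity bounds (`[-0.2, 1.2]` for the fractions) so noisy boundary
#' data do not wedge the optimizer. Supplying `n_total` counts (or explicit
#' `weights`) turns on inverse-variance weighting from the binomial error of
#' each fraction.
#'
#' @param points A tibble with columns `t_min` and `f_unwound`, optionally
#'   `n_total` (as from [fraction_unwound_timecourse()]).
#' @param weights Optional numeric weights (overrides binomial weighting).
#' @return An object of class `assoc_fit`: estimates, standard errors,
#'   residual sum of squares, a `direction` field (`"increasing"` /
#'   `"decreasing"`) and flags `k_identifiable`, `converged`. Time is in
#'   minutes, so `k` is in min^-1 (`k_per_s` gives the s^-1 conversion).
#' @examples
#' pts <- tibble::tibble(t_min = c(1, 2, 3, 4, 7, 10, 13, 20),
#'                       f_unwound = one_phase_association(c(1, 2, 3, 4, 7, 10, 13, 20),
#'                                                         0.35, 0.79, 0.3))
#' fit_one_phase_association(pts)
#' @export
fit_one_phase_association <- function(points, weights = NULL) {
  stopifnot(all(c("t_min", "f_unwound") %in% names(points)))
  points <- as_tibble(points)
  if (nrow(points) < 4 || length(unique(points$t_min)) < 3) {
    abort("need >= 4 points with >= 3 distinct times",
          class = "smfret_invalid_parameter")
  }
  t <- points$t_min
  y <- points$f_unwound

  if (sd(y) == 0) {
    # constant series: intercept and plateau coincide, rate unidentifiable
    return(new_assoc_fit(
      estimate = c(y0 = y[1], plateau = y[1], k = NA_real_),
      se = c(y0 = NA_real_, plateau = NA_real_, k = NA_real_),
      fit_residual = 0, direction = "flat",
      k_identifiable = FALSE, converged = TRUE, data = points))
  }

  w <- weights
  if (is.null(w) && "n_total" %in% names(points)) {
    p_mid <- pmin(pmax(y, 0.05), 0.95)
    w <- points$n_total / (p_mid * (1 - p_mid))
  }
  if (is.null(w)) w <- rep(1, length(y))

  df <- tibble(t = t, y = y, w = w)
  start <- list(y0 = y[which.min(t)], plateau = y[which.max(t)],
                k = 1 / max(median(t), 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (plateau - y0) * (1 - exp(-k * t)),
      data = df, start = start, weights = df$w,
      lower = c(-0.2, -0.2, 1e-6), upper = c(1.2, 1.2, Inf),
      control = nls.control(maxiter = 500, tol = 1e-10)
    ),
    error = function(e) {
      abort("one-phase association fit did not converge",
            class = "smfret_fit_failure", parent = e)
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(est)))
  new_assoc_fit(
    estimate = est, se = se[names(est)],
    fit_residual = sum(stats::resid(fit)^2),
    direction = if (est[["plateau"]] >= est[["y0"]]) "increasing" else "decreasing",
    k_identifiable = TRUE,
    converged = fit$convInfo$isConv %||% TRUE,
    data = points
  )
}

new_assoc_fit <- function(estimate, se, fit_residual, direction,
                          k_identifiable, converged, data) {
  structure(
    list(estimate = estimate, se = se, fit_residual = fit_residual,
         direction = direction, k_identifiable = k_identifiable,
         converged = converged, data = data),
    class = "assoc_fit"
  )
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat("<assoc_fit> one-phase association  y = y0 + (plateau - y0)(1 - exp(-k t))\n")
  cat(sprintf("  y0 = %.4f, plateau = %.4f, k = %.4g min^-1 (%s%s)\n",
              x$estimate[["y0"]], x$estimate[["plateau"]], x$estimate[["k"]],
              x$direction,
              if (x$k_identifiable) "" else ", k unidentifiable"))
  invisible(x)
}

#' @export
predict.assoc_fit <- function(object, t_min = NULL, ...) {
  t_min <- t_min %||% object$data$t_min
  e <- object$estimate
  if (!object$k_identifiable) return(rep(e[["y0"]], length(t_min)))
  one_phase_association(t_min, e[["y0"]], e[["plateau"]], e[["k"]])
}
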