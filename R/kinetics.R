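#' Empirical survival (1-CDF) curve of dwell times
#'
#' Builds the empirical survival function of a set of dwell times: at the
#' i-th sorted duration (1-based), survival `= 1 - i/n`. This right-
#' continuous convention makes the curve reach 0 at the longest dwell; the
#' exponential fit's free offset absorbs any plateau artifact.
#'
#' @param durations Positive dwell times in seconds (at least 10).
#' @return A tibble of class `fret_survival` with columns `duration_s`
#'   (sorted) and `survival`.
#' @examples
#' one_minus_cdf(c(1, 2, 3, 4) * 1.0)
#' @export
one_minus_cdf <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) < 10) {
    abort("need at least 10 dwell times for a survival curve",
          class = "smfret_insufficient_data")
  }
  if (any(durations <= 0)) {
    abort("dwell times must be positive", class = "smfret_invalid_parameter")
  }
  n <- length(durations)
  out <- tibble(duration_s = sort(durations),
                survival = 1 - seq_len(n) / n)
  class(out) <- c("fret_survival", class(out))
  out
}

#' Single-exponential fit to a survival curve
#'
#' Fits `y = y0 + A1 * exp(-k * t)` to a dwell-time survival curve by
#' nonlinear least squares (starting values `A1 = 1`, `y0 = 0`,
#' `k = 1/mean(duration)`), the standard route from a 1-CDF plot to a rate
#' constant. `fix_y0` pins the offset (e.g. at 0) instead of estimating it.
#'
#' @param curve A [one_minus_cdf()] result (or any tibble with `duration_s`
#'   and `survival`).
#' @param fix_y0 Optional fixed offset value.
#' @return Object of class `exp_fit` with `estimate` (`y0`, `A1`, `k` in
#'   s^-1), `se`, `fit_residual`, `n`, `converged`.
#' @examples
#' set.seed(1)
#' fit <- fit_single_exponential(one_minus_cdf(rexp(500, 0.2)))
#' glance(fit)
#' @export
fit_single_exponential <- function(curve, fix_y0 = NULL) {
  stopifnot(all(c("duration_s", "survival") %in% names(curve)))
  df <- tibble(t = curve$duration_s, y = curve$survival)
  k0 <- 1 / mean(df$t)
  fit <- tryCatch(
    if (is.null(fix_y0)) {
      minpack.lm::nlsLM(y ~ y0 + A1 * exp(-k * t), data = df,
                        start = list(y0 = 0, A1 = 1, k = k0),
                        lower = c(-1, 0, 1e-12),
                        control = nls.control(maxiter = 500, tol = 1e-10))
    } else {
      minpack.lm::nlsLM(y ~ A1 * exp(-k * t), data = mutate(df, y = .data$y - fix_y0),
                        start = list(A1 = 1, k = k0),
                        lower = c(0, 1e-12),
                        control = nls.control(maxiter = 500, tol = 1e-10))
    },
    error = function(e) {
      abort("single-exponential fit did not converge",
            class = "smfret_fit_failure", parent = e)
    }
  )
  p <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(p)), names(p)))
  est <- c(y0 = if (is.null(fix_y0)) p[["y0"]] else fix_y0,
           A1 = p[["A1"]], k = p[["k"]])
  ses <- c(y0 = if (is.null(fix_y0)) se[["y0"]] else 0,
           A1 = se[["A1"]], k = se[["k"]])
  structure(
    list(estimate = est, se = ses,
         fit_residual = sum(stats::resid(fit)^2),
         n = nrow(df), converged = fit$convInfo$isConv %||% TRUE,
         data = curve),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> y = y0 + A1 exp(-k t): k = %.4g +/- %.2g s^-1 (n = %d)\n",
              x$estimate[["k"]], x$se[["k"]], x$n))
  invisible(x)
}

#' Maximum-likelihood exponential rate (cross-check)
#'
#' The closed-form MLE of an exponential rate from uncensored dwells,
#' `k = 1 / mean(durations)`. Provided as an independent cross-check of
#' [fit_single_exponential()]; on clean single-exponential data the two
#' agree to within a few percent.
#'
#' @param durations Positive dwell times, seconds.
#' @return Rate in s^-1.
#' @export
fit_exponential_mle <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) < 2 || any(durations <= 0)) {
    abort("need >= 2 positive dwell times", class = "smfret_insufficient_data")
  }
  1 / mean(durations)
}

#' Decompose a composite exit rate by branch counts
#'
#' The bound-state exit rate is the sum of the dissociation and
#' clamp-formation rates, `k = k_minus1 + k2`, and the branch counts satisfy
#' `N2 / N_minus1 = k2 / k_minus1`. Exact algebra then gives
#' `k2 = k * N2 / (N2 + N_minus1)` and `k_minus1 = k * N_minus1 /
#' (N2 + N_minus1)` — no fitting is involved. Standard errors are propagated
#' by the delta method from the fit error on `k` and the binomial error of
#' the branch fraction.
#'
#' @param k Composite exit rate, s^-1 (from the t_SB survival fit).
#' @param n_clamp,n_dissoc Uncensored branch counts N2 and N-1.
#' @param k_se Optional standard error of `k` for error propagation.
#' @return One-row tibble: `k2`, `k_minus1`, `branch_fraction`, and (when
#'   `k_se` is supplied) `k2_se`, `k_minus1_se`.
#' @examples
#' decompose_rates(0.5, n_clamp = 30, n_dissoc = 20)
#' @export
decompose_rates <- function(k, n_clamp, n_dissoc, k_se = NULL) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0) {
    abort("`k` must be a single positive rate", class = "smfret_invalid_parameter")
  }
  n <- n_clamp + n_dissoc
  if (n <= 0) {
    abort("both branch counts are zero: decomposition undefined",
          class = "smfret_undefined_decomposition")
  }
  p <- n_clamp / n
  out <- tibble(k2 = k * p, k_minus1 = k * (1 - p), branch_fraction = p)
  if (!is.null(k_se)) {
    p_var <- p * (1 - p) / n
    out$k2_se <- sqrt(p^2 * k_se^2 + k^2 * p_var)
    out$k_minus1_se <- sqrt((1 - p)^2 * k_se^2 + k^2 * p_var)
  }
  out
}

#' Binding-event arrival rate
#'
#' The pseudo-first-order binding rate k1: detected binding events per
#' molecule per second of observation, at the experiment's fixed protein
#' concentration.
#'
#' @param events Event tibble from [segment_binding_events()] (every row,
#'   censored or not, is an arrival), or an event count.
#' @param n_molecules Number of molecules observed.
#' @param observation_time Donor-excitation observation time per molecule,
#'   seconds.
#' @return Rate in s^-1 (events per molecule per second).
#' @examples
#' estimate_k1(300, n_molecules = 100, observation_time = 60)
#' @export
estimate_k1 <- function(events, n_molecules, observation_time) {
  if (n_molecules <= 0 || !is.finite(observation_time) ||
      observation_time <= 0) {
    abort("n_molecules and observation_time must be positive",
          class = "smfret_invalid_parameter")
  }
  n_events <- if (is.numeric(events)) events else nrow(events)
  n_events / (n_molecules * observation_time)
}

#' Association/dissociation kinetics from on- and off-dwells
#'
#' The dissociation-only analysis: the bound-state dwell times `t_on` give
#' the dissociation rate `k_off`, and the waiting times between events
#' `t_off` give the pseudo-first-order association rate `k'_on`, each via a
#' survival curve and a single-exponential fit.
#'
#' @param ton Uncensored bound dwell times, seconds (>= 10).
#' @param toff Uncensored waiting times, seconds (>= 10).
#' @return One-row tibble: `k_off`, `k_off_se`, `k_on_pseudo`,
#'   `k_on_pseudo_se`, `n_on`, `n_off`.
#' @export
estimate_adp_kinetics <- function(ton, toff) {
  f_on <- fit_single_exponential(one_minus_cdf(ton))
  f_off <- fit_single_exponential(one_minus_cdf(toff))
  tibble(k_off = f_on$estimate[["k"]], k_off_se = f_on$se[["k"]],
         k_on_pseudo = f_off$estimate[["k"]], k_on_pseudo_se = f_off$se[["k"]],
         n_on = f_on$n, n_off = f_off$n)
}

#' Full rate set for one ATP-condition dataset
#'
#' Convenience assembly of the sliding-clamp analysis: fits the composite
#' exit rate `k` from uncensored specific-binding dwells, counts branches,
#' decomposes `k` into `k2` and `k_minus1`, and estimates the arrival rate
#' `k1`.
#'
#' @param events Event tibble from [segment_binding_events()].
#' @param n_molecules Molecules observed.
#' @param observation_time Donor-excitation seconds per molecule.
#' @param condition Label carried into the output.
#' @return One-row tibble with `condition`, `k`, `k_se`, `k1`, `k2`,
#'   `k_minus1`, their errors, the branch counts and `n_events`.
#' @export
summarize_rate_set <- function(events, n_molecules, observation_time,
                               condition = NA_character_) {
  ton <- events$t_sb[!events$censored]
  fit <- fit_single_exponential(one_minus_cdf(ton))
  br <- count_branches(events)
  dec <- decompose_rates(fit$estimate[["k"]], br$n_clamp, br$n_dissoc,
                         k_se = fit$se[["k"]])
  tibble(condition = condition,
         k = fit$estimate[["k"]], k_se = fit$se[["k"]],
         k1 = estimate_k1(events, n_molecules, observation_time),
         k2 = dec$k2, k2_se = dec$k2_se,
         k_minus1 = dec$k_minus1, k_minus1_se = dec$k_minus1_se,
         n_clamp = br$n_clamp, n_dissoc = br$n_dissoc,
         n_events = nrow(events))
}
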