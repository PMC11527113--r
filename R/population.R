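#' FRET classification windows
#'
#' A classification rule divides a FRET histogram into a donor-only artifact
#' region (`E <= lower`), an unwound window (`lower < E < upper`) and a wound
#' region (`E >= upper`). Values at or below `lower` are excluded from the
#' molecule total; the comparisons are strict, so a value exactly at a
#' threshold falls outside the unwound window.
#'
#' `rule_pam_proximal()` and `rule_pam_distal()` return the fixed windows
#' used for the two dCas9-gRNA mismatch geometries (0.14-0.47 and 0.18-0.51
#' FRET units); [thresholds_rule()] derives a rule from a fitted mixture's
#' intersection thresholds — the default route for new data.
#'
#' @param lower,upper Window bounds in FRET units, `0 <= lower < upper <= 1`.
#' @return A list of class `classification_rule`.
#' @export
classification_rule <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1 ||
      length(upper) != 1 || !is.finite(lower) || !is.finite(upper) ||
      lower < 0 || upper > 1 || lower >= upper) {
    abort("require 0 <= lower < upper <= 1", class = "smfret_invalid_parameter")
  }
  structure(list(lower = lower, upper = upper), class = "classification_rule")
}

#' @rdname classification_rule
#' @export
rule_pam_proximal <- function() classification_rule(0.14, 0.47)

#' @rdname classification_rule
#' @export
rule_pam_distal <- function() classification_rule(0.18, 0.51)

#' @rdname classification_rule
#' @param fit A [fit_three_gaussians()] result.
#' @export
thresholds_rule <- function(fit) {
  stopifnot(inherits(fit, "fret_mixture_fit"))
  classification_rule(max(0, fit$thresholds[["lower"]]),
                      min(1, fit$thresholds[["upper"]]))
}

#' Fit a sum of three Gaussians to a FRET histogram
#'
#' Bins the FRET values at `bin_width` and fits the binned density with
#' `w1*N(mu1, s1) + w2*N(mu2, s2) + w3*N(mu3, s3)` by nonlinear least
#' squares. The three components model the donor-only artifact peak and the
#' two signal populations (unwound / wound). Components are returned sorted
#' by mean, and the two intersection points between adjacent components are
#' derived as classification thresholds.
#'
#' @param values Numeric FRET values (>= 100; `NA` dropped).
#' @param bin_width Histogram bin width in FRET units (default 0.02).
#' @param init Optional numeric vector of 3 starting means; defaults to the
#'   10th/50th/90th percentiles of the data.
#' @param sd_floor Lower bound on component sds, preventing spike components.
#' @return An object of class `fret_mixture_fit`: a list with `components`
#'   (tibble `weight`, `mean`, `sd`), `thresholds` (named `lower`/`upper`),
#'   `threshold_fallback` flags, `fit_residual` (sum of squared density
#'   residuals), `histogram` (bin midpoints and densities) and `converged`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(2000, 0.05, 0.05), rnorm(2000, 0.35, 0.06), rnorm(2000, 0.65, 0.06))
#' fit <- fit_three_gaussians(x)
#' tidy(fit)
#' @export
fit_three_gaussians <- function(values, bin_width = 0.02, init = NULL,
                                sd_floor = 0.005) {
  values <- values[!is.na(values)]
  if (length(values) < 100) {
    abort("need at least 100 FRET values to fit a three-Gaussian mixture",
          class = "smfret_invalid_parameter")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be positive", class = "smfret_invalid_parameter")
  }
  if (sd(values) == 0) {
    abort("all FRET values are identical: histogram has zero variance",
          class = "smfret_fit_failure")
  }
  breaks <- seq(floor(min(values) / bin_width) * bin_width,
                ceiling(max(values) / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  df <- tibble(x = h$mids, y = h$density)

  mu0 <- init %||% unname(quantile(values, c(0.1, 0.5, 0.9)))
  if (length(mu0) != 3) {
    abort("`init` must supply 3 starting means", class = "smfret_invalid_parameter")
  }
  s0 <- max(sd(values) / 4, 2 * bin_width)
  start <- list(w1 = 1/3, w2 = 1/3, w3 = 1/3,
                m1 = mu0[1], m2 = mu0[2], m3 = mu0[3],
                s1 = s0, s2 = s0, s3 = s0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ w1 * dnorm(x, m1, s1) + w2 * dnorm(x, m2, s2) + w3 * dnorm(x, m3, s3),
      data = df, start = start,
      lower = c(0, 0, 0, rep(min(values) - bin_width, 3), rep(sd_floor, 3)),
      upper = c(Inf, Inf, Inf, rep(max(values) + bin_width, 3), rep(Inf, 3)),
      control = nls.control(maxiter = 500, tol = 1e-8)
    ),
    error = function(e) {
      abort("three-Gaussian fit did not converge",
            class = "smfret_fit_failure", parent = e,
            residual_history = df$y)
    }
  )
  p <- coef(fit)
  comp <- tibble(weight = unname(p[c("w1", "w2", "w3")]),
                 mean = unname(p[c("m1", "m2", "m3")]),
                 sd = unname(p[c("s1", "s2", "s3")])) |>
    arrange(.data$mean)
  if (any(diff(comp$mean) <= 0)) {
    abort("three-Gaussian fit collapsed onto coincident means",
          class = "smfret_fit_failure", residual_history = stats::resid(fit))
  }
  thr_lo <- gaussian_intersection(comp[1, ], comp[2, ])
  thr_hi <- gaussian_intersection(comp[2, ], comp[3, ])
  structure(
    list(components = comp,
         thresholds = c(lower = as.numeric(thr_lo), upper = as.numeric(thr_hi)),
         threshold_fallback = c(lower = attr(thr_lo, "fallback"),
                                upper = attr(thr_hi, "fallback")),
         fit_residual = sum(stats::resid(fit)^2),
         histogram = df,
         bin_width = bin_width,
         n_values = length(values),
         converged = fit$convInfo$isConv %||% TRUE),
    class = "fret_mixture_fit"
  )
}

#' @export
print.fret_mixture_fit <- function(x, ...) {
  cat("<fret_mixture_fit> three-Gaussian mixture\n")
  print(x$components)
  cat(sprintf("thresholds: %.3f / %.3f  (SSR %.3g, n = %d)\n",
              x$thresholds[["lower"]], x$thresholds[["upper"]],
              x$fit_residual, x$n_values))
  invisible(x)
}

#' Intersection point of two weighted Gaussian densities
#'
#' Solves `w1 * N(x; mu1, s1) = w2 * N(x; mu2, s2)` — a quadratic in `x`
#' after taking logs — and returns the root lying strictly between the two
#' means, which is the natural classification boundary between adjacent
#' FRET populations. When no root falls between the means (one component
#' dominates throughout), the sd-weighted midpoint
#' `(s2 * mu1 + s1 * mu2) / (s1 + s2)` is returned with attribute
#' `fallback = TRUE`.
#'
#' @param c1,c2 One-row data frames (or lists) with `weight`, `mean`, `sd`;
#'   `c1$mean < c2$mean`, both weights positive.
#' @return The intersection point (FRET units) with logical attribute
#'   `fallback`.
#' @export
gaussian_intersection <- function(c1, c2) {
  w1 <- c1$weight; m1 <- c1$mean; s1 <- c1$sd
  w2 <- c2$weight; m2 <- c2$mean; s2 <- c2$sd
  if (m1 == m2) {
    abort("components have equal means; no separating intersection exists",
          class = "smfret_invalid_parameter")
  }
  if (m1 > m2) {
    return(gaussian_intersection(c2, c1))
  }
  if (w1 <= 0 || w2 <= 0 || s1 <= 0 || s2 <= 0) {
    abort("component weights and sds must be positive",
          class = "smfret_invalid_parameter")
  }
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log((w1 * s2) / (w2 * s1))
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-300) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) >= 1) {
    x <- inside[1]
    attr(x, "fallback") <- FALSE
  } else {
    x <- (s2 * m1 + s1 * m2) / (s1 + s2)
    attr(x, "fallback") <- TRUE
  }
  x
}

#' Fraction of molecules in the unwound FRET window
#'
#' Computes the unwound fraction of a FRET population: the number of values
#' inside the unwound window `(lower, upper)` divided by the number of values
#' above `lower` (the molecule total). Values at or below `lower` belong to
#' the donor-only artifact peak and are excluded from both numerator and
#' denominator.
#'
#' @param values Numeric FRET values (`NA` dropped).
#' @param rule A [classification_rule()].
#' @return A one-row tibble: `f_unwound`, `n_unwound`, `n_wound`, `n_total`
#'   (denominator) and `n_excluded`.
#' @examples
#' fraction_unwound(c(0.05, 0.3, 0.4, 0.6), rule_pam_distal())
#' @export
fraction_unwound <- function(values, rule) {
  stopifnot(inherits(rule, "classification_rule"))
  values <- values[!is.na(values)]
  n_unwound <- sum(values > rule$lower & values < rule$upper)
  n_total <- sum(values > rule$lower)
  if (n_total == 0) {
    abort("no values above the lower threshold: unwound fraction is undefined",
          class = "smfret_undefined_fraction")
  }
  tibble(f_unwound = n_unwound / n_total,
         n_unwound = n_unwound,
         n_wound = n_total - n_unwound,
         n_total = n_total,
         n_excluded = length(values) - n_total)
}
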