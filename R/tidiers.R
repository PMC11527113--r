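#' Tidiers for smfret fit objects
#'
#' [generics::tidy()] returns one row per parameter (or per mixture
#' component); [generics::glance()] returns a one-row model summary;
#' [generics::augment()] on an `hmm_fit` returns the per-frame Viterbi path.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name smfret_tidiers
NULL

#' @rdname smfret_tidiers
#' @export
tidy.fret_mixture_fit <- function(x, ...) {
  mutate(x$components,
         component = c("donor_only", "unwound", "wound"),
         .before = 1)
}

#' @rdname smfret_tidiers
#' @export
glance.fret_mixture_fit <- function(x, ...) {
  tibble(threshold_lower = x$thresholds[["lower"]],
         threshold_upper = x$thresholds[["upper"]],
         fallback_lower = x$threshold_fallback[["lower"]],
         fallback_upper = x$threshold_fallback[["upper"]],
         fit_residual = x$fit_residual,
         n_values = x$n_values,
         converged = x$converged)
}

#' @rdname smfret_tidiers
#' @export
tidy.assoc_fit <- function(x, ...) {
  tibble(term = names(x$estimate),
         estimate = unname(x$estimate),
         std.error = unname(x$se))
}

#' @rdname smfret_tidiers
#' @export
glance.assoc_fit <- function(x, ...) {
  tibble(k_min = x$estimate[["k"]],
         k_per_s = x$estimate[["k"]] / 60,
         fit_residual = x$fit_residual,
         direction = x$direction,
         k_identifiable = x$k_identifiable,
         converged = x$converged,
         n_points = nrow(x$data))
}

#' @rdname smfret_tidiers
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = names(x$estimate),
         estimate = unname(x$estimate),
         std.error = unname(x$se))
}

#' @rdname smfret_tidiers
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(k = x$estimate[["k"]], k_se = x$se[["k"]],
         mean_dwell_s = 1 / x$estimate[["k"]],
         fit_residual = x$fit_residual, n = x$n, converged = x$converged)
}

#' @rdname smfret_tidiers
#' @export
tidy.hmm_fit <- function(x, ...) {
  tibble(state = seq_along(x$means) - 1L,
         mean = x$means, sd = x$sds)
}

#' @rdname smfret_tidiers
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood,
         n_iter = x$n_iter,
         n_states = length(x$means),
         converged = x$converged,
         degenerate = x$degenerate)
}

#' @rdname smfret_tidiers
#' @export
augment.hmm_fit <- function(x, ...) {
  x$path
}
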