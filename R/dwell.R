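#' Two-state hidden-Markov idealization of a FRET trajectory
#'
#' Fits a Gaussian-emission hidden Markov model to one molecule's FRET
#' trajectory by maximum likelihood (Baum-Welch expectation-maximization,
#' at most `max_iter` iterations, log-likelihood tolerance `tol`) and returns
#' the Viterbi state path. States are relabeled in increasing order of their
#' fitted emission means, so state `0` is always the lowest-FRET state.
#' Initialization is deterministic — state means at the 25th/75th (or
#' 25/50/75th) percentiles of the trajectory, a common variance, uniform
#' transition and initial probabilities — so the result is reproducible for
#' a given trajectory.
#'
#' @param traj A FRET trajectory tibble for a single molecule (columns
#'   `frame`, `time_s`, `fret`, as one molecule's rows from
#'   [compute_fret()]); `NA` frames are dropped. At least 10 frames.
#' @param n_states Number of states, 2 (default) or 3.
#' @param max_iter,tol EM stopping rule.
#' @return An object of class `hmm_fit`: `path` (tibble `frame`, `time_s`,
#'   `state` with 0-based labels), `means`, `sds`, `transition` matrix,
#'   `log_likelihood`, `n_iter`, `converged`, `degenerate`, and
#'   `frame_interval`.
#' @examples
#' cfg <- sim_config(two_state_kinetics(0.5, 0.5), n_molecules = 1,
#'                   schedule = excitation_schedule(
#'                     data.frame(start_frame = 0, end_frame = 400,
#'                                channel = "donor_ex"), 0.05),
#'                   seed = 2)
#' ts <- simulate_twostate_experiment(cfg)
#' fr <- compute_fret(ts$traces, 50, 50)
#' hmm_idealize(fr[fr$molecule == 1, ])
#' @export
hmm_idealize <- function(traj, n_states = 2, max_iter = 500, tol = 1e-6) {
  if (!n_states %in% c(2L, 3L)) {
    abort("`n_states` must be 2 or 3", class = "smfret_invalid_parameter")
  }
  stopifnot(all(c("frame", "fret") %in% names(traj)))
  if ("molecule" %in% names(traj) && length(unique(traj$molecule)) > 1) {
    abort("hmm_idealize() expects a single molecule's trajectory",
          class = "smfret_contract_violation")
  }
  keep <- !is.na(traj$fret)
  y <- traj$fret[keep]
  n <- length(y)
  if (n < 10) {
    abort("trajectory must have at least 10 usable frames",
          class = "smfret_contract_violation")
  }
  K <- n_states
  degenerate <- sd(y) == 0

  qs <- if (K == 2) c(0.25, 0.75) else c(0.25, 0.5, 0.75)
  mu <- unname(quantile(y, qs))
  sigma <- rep(max(sd(y) / 2, 1e-4), K)
  A <- matrix(1 / K, K, K)
  pi0 <- rep(1 / K, K)

  loglik <- -Inf
  converged <- FALSE
  iter <- 0
  if (!degenerate) {
    for (iter in seq_len(max_iter)) {
      B <- vapply(seq_len(K), function(k) dnorm(y, mu[k], sigma[k]),
                  numeric(n))
      B <- pmax(B, 1e-300)
      fb <- forward_backward(pi0, A, B)
      if (fb$loglik - loglik < tol && iter > 1) {
        loglik <- fb$loglik
        converged <- TRUE
        break
      }
      loglik <- fb$loglik
      g <- fb$gamma
      pi0 <- g[1, ] / sum(g[1, ])
      A <- fb$xi_sum / pmax(rowSums(fb$xi_sum), 1e-300)
      Ng <- colSums(g)
      mu <- colSums(g * y) / Ng
      sigma <- sqrt(colSums(g * (outer(y, mu, "-"))^2) / Ng)
      sigma <- pmax(sigma, 1e-4)
    }
    B <- vapply(seq_len(K), function(k) dnorm(y, mu[k], sigma[k]), numeric(n))
    B <- pmax(B, 1e-300)
    states <- viterbi(pi0, A, B)
  } else {
    states <- rep(1L, n)
    sigma <- rep(1e-4, K)
    converged <- TRUE
  }

  # relabel in increasing emission-mean order, 0-based
  ord <- order(mu)
  relabel <- match(seq_len(K), ord) - 1L
  path <- tibble(frame = traj$frame[keep],
                 time_s = traj$time_s[keep] %||% traj$frame[keep],
                 state = relabel[states])
  if (!degenerate && any(abs(diff(sort(mu))) < 1e-6)) degenerate <- TRUE

  structure(
    list(path = path, means = mu[ord], sds = sigma[ord],
         transition = A[ord, ord, drop = FALSE],
         log_likelihood = loglik, n_iter = iter,
         converged = converged || degenerate, degenerate = degenerate,
         frame_interval = attr(traj, "frame_interval")),
    class = "hmm_fit"
  )
}

# scaled forward-backward; B is n x K matrix of emission densities
forward_backward <- function(pi0, A, B) {
  n <- nrow(B); K <- ncol(B)
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K); scale <- numeric(n)
  a <- pi0 * B[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    b <- A %*% (B[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / scale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  for (t in 1:(n - 1)) {
    xi <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / scale[t + 1]
    xi_sum <- xi_sum + xi
  }
  list(loglik = sum(log(scale)), gamma = gamma, xi_sum = xi_sum)
}

viterbi <- function(pi0, A, B) {
  n <- nrow(B); K <- ncol(B)
  logA <- log(pmax(A, 1e-300))
  delta <- matrix(-Inf, n, K); psi <- matrix(0L, n, K)
  delta[1, ] <- log(pmax(pi0, 1e-300)) + log(B[1, ])
  for (t in 2:n) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + log(B[t, k])
    }
  }
  states <- integer(n)
  states[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) states[t] <- psi[t + 1, states[t + 1]]
  states
}

#' Threshold idealization of a FRET trajectory
#'
#' The simplest possible two-state idealization: frames with `fret > split`
#' are the high state (label 1), the rest the low state (label 0). Serves as
#' a transparent cross-check for [hmm_idealize()] on well-separated data.
#'
#' @inheritParams hmm_idealize
#' @param split FRET boundary between the two states.
#' @return A tibble `frame`, `time_s`, `state`.
#' @export
threshold_idealize <- function(traj, split) {
  keep <- !is.na(traj$fret)
  tibble(frame = traj$frame[keep], time_s = traj$time_s[keep],
         state = as.integer(traj$fret[keep] > split))
}

#' Extract dwell times from an idealized path
#'
#' Collapses an idealized state sequence into sojourns: one record per
#' maximal run of a constant state, with duration `run length x
#' frame_interval`. The first and last sojourns of a trace are censored by
#' the start and end of observation (flags `censored_left` /
#' `censored_right`); censored dwells are excluded from rate fits.
#'
#' @param path An `hmm_fit`, or a tibble with a `state` column (e.g. from
#'   [threshold_idealize()]).
#' @param frame_interval Frame duration in seconds (taken from an `hmm_fit`
#'   when available).
#' @return A tibble: `state`, `n_frames`, `duration_s`, `censored_left`,
#'   `censored_right`, `next_state` (`NA` at trace end).
#' @examples
#' extract_dwells(tibble::tibble(state = c(0, 0, 1, 1, 1, 0)),
#'                frame_interval = 0.05)
#' @export
extract_dwells <- function(path, frame_interval = NULL) {
  if (inherits(path, "hmm_fit")) {
    frame_interval <- frame_interval %||% path$frame_interval
    path <- path$path
  }
  if (is.null(frame_interval)) {
    abort("`frame_interval` is required", class = "smfret_invalid_parameter")
  }
  r <- rle(path$state)
  k <- length(r$lengths)
  tibble(
    state = r$values,
    n_frames = r$lengths,
    duration_s = r$lengths * frame_interval,
    censored_left = seq_len(k) == 1L,
    censored_right = seq_len(k) == k,
    next_state = c(r$values[-1], NA)
  )
}

#' Segment protein-binding events in an intensity trace
#'
#' Detects binding events in mismatch-binding movies as rises of the
#' background-subtracted total intensity (donor + acceptor during
#' donor-excitation frames) above `intensity_threshold` from darkness. Each
#' event's frames are split at `fret_split` into high-FRET (specific
#' mismatch binding) and low-FRET (sliding clamp) levels:
#'
#' * `t_sb` is the duration of the initial contiguous high-FRET segment;
#' * the outcome is `"clamp"` when that segment is immediately followed by at
#'   least `min_clamp_frames` low-FRET frames within the same event, and
#'   `"dissociated"` when the event ends from the high state (returns to
#'   darkness with no intervening low frames);
#' * `preceding_wait` is the darkness before the event (the waiting time
#'   between successive binding events).
#'
#' Events whose outcome cannot be decided are censored: an event truncated by
#' the trace end while still in its high segment, an event already bound at
#' the first frame (`t_sb` left-censored), or an event with fewer than
#' `min_clamp_frames` trailing low frames at the trace end. A clamp outcome
#' already established by `min_clamp_frames` low frames stays uncensored even
#' if the clamp sojourn itself is truncated. Rare events with no detectable
#' high-FRET frame are dropped (their bound dwell is below the frame time).
#'
#' @param traces A trace tibble (one or more molecules).
#' @param intensity_threshold Detection level for the background-subtracted
#'   total intensity; must be positive (a threshold at or below the
#'   background level would detect noise as binding).
#' @param fret_split Boundary between the low- and high-FRET levels. When
#'   `NULL`, derived per dataset as the two-Gaussian intersection of the
#'   event-frame FRET histogram.
#' @param background Per-channel background level.
#' @param gamma Detection-correction factor for the FRET ratio.
#' @param min_clamp_frames Low-FRET frames required to call a sliding clamp.
#' @return A tibble, one row per retained event: `molecule`, `event`,
#'   `t_start`, `t_sb`, `n_high_frames`, `outcome` (`"dissociated"`,
#'   `"clamp"` or `NA` when censored), `censored`, `preceding_wait`,
#'   `wait_censored`, `n_low_frames`. Attribute `fret_split` records the
#'   boundary used.
#' @export
segment_binding_events <- function(traces, intensity_threshold,
                                   fret_split = NULL, background = 0,
                                   gamma = 1, min_clamp_frames = 3L) {
  if (!is.numeric(intensity_threshold) || intensity_threshold <= 0) {
    abort("`intensity_threshold` must be positive (relative to background)",
          class = "smfret_configuration_error")
  }
  dt <- attr(traces, "frame_interval")
  if (is.null(dt)) {
    abort("traces must carry a `frame_interval` attribute",
          class = "smfret_contract_violation")
  }
  dx <- traces |>
    filter(.data$excitation == "donor_ex") |>
    mutate(
      total = .data$donor + .data$acceptor - 2 * background,
      on = .data$total > intensity_threshold,
      a = .data$acceptor - background,
      d = .data$donor - background,
      fret = ifelse(.data$a + gamma * .data$d > 0,
                    .data$a / (.data$a + gamma * .data$d), NA_real_)
    )

  if (is.null(fret_split)) {
    fret_split <- derive_fret_split(dx$fret[dx$on])
  }

  events <- dx |>
    group_by(.data$molecule) |>
    dplyr::group_map(~ segment_one_molecule(.x, .y$molecule, dt, fret_split,
                                            min_clamp_frames)) |>
    bind_rows()
  attr(events, "fret_split") <- fret_split
  events
}

derive_fret_split <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 100) {
    abort("too few event frames to derive `fret_split`; supply it explicitly",
          class = "smfret_configuration_error")
  }
  df_fit <- fit_two_gaussians(values)
  x <- gaussian_intersection(df_fit$components[1, ], df_fit$components[2, ])
  as.numeric(x)
}

# two-component analogue of fit_three_gaussians, used only to place the
# high/low boundary for event segmentation
fit_two_gaussians <- function(values, bin_width = 0.02) {
  breaks <- seq(floor(min(values) / bin_width) * bin_width,
                ceiling(max(values) / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  df <- tibble(x = h$mids, y = h$density)
  mu0 <- unname(quantile(values, c(0.15, 0.85)))
  s0 <- max(sd(values) / 3, 2 * bin_width)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ w1 * dnorm(x, m1, s1) + w2 * dnorm(x, m2, s2),
      data = df,
      start = list(w1 = 0.5, w2 = 0.5, m1 = mu0[1], m2 = mu0[2],
                   s1 = s0, s2 = s0),
      lower = c(0, 0, min(values), min(values), 0.005, 0.005),
      upper = c(Inf, Inf, max(values), max(values), Inf, Inf),
      control = nls.control(maxiter = 500, tol = 1e-8)
    ),
    error = function(e) {
      abort("two-Gaussian split derivation failed; supply `fret_split`",
            class = "smfret_configuration_error", parent = e)
    }
  )
  p <- coef(fit)
  comp <- tibble(weight = p[c("w1", "w2")], mean = p[c("m1", "m2")],
                 sd = p[c("s1", "s2")]) |>
    arrange(.data$mean)
  if (diff(comp$mean) < 0.05) {
    abort("event-frame FRET histogram is unimodal; supply `fret_split`",
          class = "smfret_configuration_error")
  }
  list(components = comp)
}

segment_one_molecule <- function(df, molecule, dt, fret_split,
                                 min_clamp_frames) {
  r <- rle(df$on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- which(r$values)
  if (length(on_idx) == 0) return(NULL)
  n_frames_total <- nrow(df)

  out <- purrr::map(seq_along(on_idx), function(j) {
    i <- on_idx[j]
    s <- starts[i]; e <- ends[i]
    high <- df$fret[s:e] > fret_split
    high[is.na(high)] <- FALSE
    left_truncated <- s == 1L
    right_truncated <- e == n_frames_total

    if (!high[1] && !left_truncated) {
      return(NULL) # bound dwell shorter than one frame; not measurable
    }
    n_high <- if (all(high)) length(high) else which(!high)[1] - 1L
    # contiguous low-FRET run immediately following the initial high segment
    low_run <- 0L
    if (n_high < length(high)) {
      post <- high[(n_high + 1):length(high)]
      low_run <- if (any(post)) which(post)[1] - 1L else length(post)
    }

    clamp <- low_run >= min_clamp_frames
    ends_high <- n_high == length(high)
    outcome <- if (clamp && !left_truncated) {
      "clamp" # established by >= min_clamp_frames low frames, even if the
              # clamp sojourn itself is later truncated
    } else if (!clamp && ends_high && !right_truncated && !left_truncated) {
      "dissociated"
    } else {
      NA_character_ # truncated high segment or ambiguous short low tail
    }
    censored <- is.na(outcome)

    prev_end <- if (j == 1) 0L else ends[on_idx[j - 1]]
    tibble(
      molecule = molecule,
      event = j,
      t_start = df$time_s[s],
      t_sb = n_high * dt,
      n_high_frames = n_high,
      outcome = outcome,
      censored = censored || is.na(outcome),
      preceding_wait = (s - 1L - prev_end) * dt,
      wait_censored = j == 1L, # movie start truncates the first wait
      n_low_frames = low_run
    )
  })
  bind_rows(out)
}

#' Count branch outcomes of binding events
#'
#' Tallies uncensored events by outcome: `n_clamp` (the branch-count N2,
#' specific binding followed by sliding-clamp formation) and `n_dissoc`
#' (N-1, specific binding that ended in dissociation). Censored events are
#' excluded from both counts.
#'
#' @param events Event tibble from [segment_binding_events()] (may be empty).
#' @return One-row tibble `n_clamp`, `n_dissoc`.
#' @export
count_branches <- function(events) {
  if (is.null(events) || nrow(events) == 0) {
    return(tibble(n_clamp = 0L, n_dissoc = 0L))
  }
  ok <- !events$censored & !is.na(events$outcome)
  tibble(n_clamp = sum(ok & events$outcome == "clamp"),
         n_dissoc = sum(ok & events$outcome == "dissociated"))
}
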