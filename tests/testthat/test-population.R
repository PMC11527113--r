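test_that("three-Gaussian fit recovers a well-separated mixture", {
  set.seed(21)
  x <- c(rnorm(50000 / 3, 0.05, 0.05), rnorm(50000 / 3, 0.35, 0.05),
         rnorm(50000 / 3, 0.65, 0.05))
  fit <- fit_three_gaussians(x)
  expect_equal(fit$components$mean, c(0.05, 0.35, 0.65), tolerance = 0.01 / 0.35)
  expect_true(all(diff(fit$components$mean) > 0))
  expect_lt(fit$thresholds[["lower"]], fit$thresholds[["upper"]])
})

test_that("degenerate histograms are explicit fit failures", {
  expect_error(fit_three_gaussians(rep(0.5, 500)),
               class = "smfret_fit_failure")
  expect_error(fit_three_gaussians(rnorm(50, 0.5, 0.1)),
               class = "smfret_invalid_parameter") # too few values
})

test_that("a two-component sample leaves one fitted weight near zero", {
  set.seed(22)
  x <- c(rnorm(25000, 0.2, 0.05), rnorm(25000, 0.6, 0.05))
  fit <- fit_three_gaussians(x)
  w <- sort(fit$components$weight)
  expect_lt(w[1] / sum(w), 0.02)
})

test_that("mixture parameter recovery holds across seeded replicates", {
  means_true <- c(0.05, 0.35, 0.65)
  for (seed in 1:20) {
    set.seed(seed)
    x <- c(rnorm(20000, means_true[1], 0.05),
           rnorm(15000, means_true[2], 0.05),
           rnorm(15000, means_true[3], 0.05))
    fit <- fit_three_gaussians(x)
    expect_true(all(abs(fit$components$mean - means_true) < 0.01))
    w <- fit$components$weight / sum(fit$components$weight)
    expect_true(all(abs(w - c(0.4, 0.3, 0.3)) < 0.03))
  }
})

test_that("gaussian_intersection solves the equal-density point", {
  mk <- function(w, m, s) tibble::tibble(weight = w, mean = m, sd = s)
  # symmetric case
  x <- gaussian_intersection(mk(1, 0, 0.1), mk(1, 1, 0.1))
  expect_equal(as.numeric(x), 0.5, tolerance = 1e-12)
  expect_false(attr(x, "fallback"))
  # equal sds, unequal weights: closed-form shift s^2 ln(w1/w2)/(m2 - m1)
  w1 <- 2; w2 <- 0.5; s <- 0.08; m1 <- 0.2; m2 <- 0.7
  x2 <- gaussian_intersection(mk(w1, m1, s), mk(w2, m2, s))
  expect_equal(as.numeric(x2),
               (m1 + m2) / 2 + s^2 * log(w1 / w2) / (m2 - m1),
               tolerance = 1e-12)
  # unequal sds: bisection oracle on the density difference
  c1 <- mk(1, 0.3, 0.05); c2 <- mk(1, 0.6, 0.10)
  f <- function(x) c1$weight * dnorm(x, c1$mean, c1$sd) -
    c2$weight * dnorm(x, c2$mean, c2$sd)
  oracle <- stats::uniroot(f, c(0.3 + 1e-9, 0.6 - 1e-9), tol = 1e-13)$root
  expect_equal(as.numeric(gaussian_intersection(c1, c2)), oracle,
               tolerance = 1e-9 / oracle)
  expect_error(gaussian_intersection(mk(1, 0.5, 0.1), mk(1, 0.5, 0.2)),
               class = "smfret_invalid_parameter")
})

test_that("quadratic intersection matches a bisection oracle on random components", {
  set.seed(33)
  mk <- function(w, m, s) tibble::tibble(weight = w, mean = m, sd = s)
  n_checked <- 0
  for (i in 1:1000) {
    m1 <- runif(1, 0, 0.5); m2 <- m1 + runif(1, 0.1, 0.5)
    c1 <- mk(runif(1, 0.1, 5), m1, runif(1, 0.02, 0.15))
    c2 <- mk(runif(1, 0.1, 5), m2, runif(1, 0.02, 0.15))
    f <- function(x) c1$weight * dnorm(x, c1$mean, c1$sd) -
      c2$weight * dnorm(x, c2$mean, c2$sd)
    x <- gaussian_intersection(c1, c2)
    if (f(m1 + 1e-12) * f(m2 - 1e-12) < 0) {
      oracle <- stats::uniroot(f, c(m1 + 1e-12, m2 - 1e-12), tol = 1e-13)$root
      expect_equal(as.numeric(x), oracle, tolerance = 1e-9)
      n_checked <- n_checked + 1
    } else {
      # no crossing between the means: the weighted-midpoint fallback applies
      expect_true(attr(x, "fallback"))
      expect_equal(as.numeric(x),
                   (c2$sd * m1 + c1$sd * m2) / (c1$sd + c2$sd))
    }
  }
  expect_gt(n_checked, 900)
})

test_that("fraction_unwound counts with strict thresholds", {
  rule <- classification_rule(0.18, 0.51)
  vals <- c(runif(10, 0, 0.17), runif(77, 0.19, 0.50), runif(23, 0.52, 0.9))
  fu <- fraction_unwound(vals, rule)
  expect_equal(fu$f_unwound, 0.77)
  expect_equal(fu$n_total, 100)
  expect_equal(fu$n_excluded, 10)
  # values exactly at a threshold are outside the window
  fu2 <- fraction_unwound(c(0.18, 0.51, 0.3), rule)
  expect_equal(fu2$n_unwound, 1)
  expect_equal(fu2$n_total, 2) # 0.18 is excluded from the total as well
  # all wound
  expect_equal(fraction_unwound(runif(50, 0.6, 0.9), rule)$f_unwound, 0)
  expect_error(fraction_unwound(runif(20, 0, 0.1), rule),
               class = "smfret_undefined_fraction")
})

test_that("moving values from wound into the window never lowers the fraction", {
  rule <- classification_rule(0.2, 0.5)
  set.seed(4)
  vals <- runif(200, 0.21, 0.9)
  f0 <- fraction_unwound(vals, rule)$f_unwound
  for (i in 1:10) {
    idx <- which(vals > 0.5)[1:5]
    vals[idx] <- runif(5, 0.25, 0.45)
    f1 <- fraction_unwound(vals, rule)$f_unwound
    expect_gte(f1, f0)
    expect_true(f1 >= 0 && f1 <= 1)
    f0 <- f1
  }
})

test_that("snapshot simulation recovers the generative unwound fraction with fixed windows", {
  kin <- snapshot_kinetics(k_assoc = 1, plateau = 0.45, y0 = 0.45)
  cfg <- sim_config(kin, n_molecules = 5000, seed = 14)
  snap <- simulate_snapshot_experiment(cfg, timepoints = 60)
  fu <- fraction_unwound(snap$fret, rule_pam_distal())
  expect_equal(fu$f_unwound, 0.45, tolerance = 0.02 / 0.45)
})
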