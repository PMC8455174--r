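test_that("the relative fit measure matches hand-computed cases", {
  expect_equal(as.numeric(relative_fit_measure(c(2, 4), c(1, 2))), 0.5)
  expect_equal(as.numeric(relative_fit_measure(c(1, 1), c(0, 2))), 1.0)
  expect_equal(as.numeric(relative_fit_measure(c(3, 7, 2), c(3, 7, 2))), 0)
  # without the root it is the mean of squared relative deviations
  expect_equal(as.numeric(relative_fit_measure(c(2, 4), c(1, 2),
                                               take_sqrt = FALSE)), 0.25)
})

test_that("zero-count bins are handled per policy and reported", {
  counts <- c(0, 2, 4)
  pred <- c(1, 1, 2)
  m <- relative_fit_measure(counts, pred)
  expect_equal(as.numeric(m), 0.5)        # zero bin dropped
  expect_equal(attr(m, "n_zero_bins"), 1L)
  m2 <- relative_fit_measure(counts, pred, zero_policy = "epsilon",
                             epsilon = 1)
  expect_equal(as.numeric(m2), sqrt(mean(c(0, 0.25, 0.25))))
  expect_error(relative_fit_measure(c(0, 0), c(1, 2)),
               class = "popsir_undefined_measure")
  expect_error(relative_fit_measure(c(1, 2), c(1, 2, 3)),
               class = "popsir_invalid_input")
})

test_that("noise-free deterministic input is recovered almost exactly", {
  series <- make_deterministic_series(beta = 0.4, gamma = 0.2, S0 = 5000,
                                      I0 = 1, edges = 0:120)
  fit <- fit_sir(series, n_starts = 20, seed = 1)
  g <- glance(fit)
  expect_true(fit$converged)
  expect_rel_equal(g$R0, 2, 0.05)
  expect_lt(g$fit_measure, 1e-3)
})

test_that("more multistarts never worsen the minimized residual", {
  series <- make_toy_series(c(3, 11, 25, 18, 7, 3, 1))
  sse <- vapply(c(1, 5, 12), function(n) {
    fit_sir(series, n_starts = n, seed = 4, polish_restarts = 0)$sse
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-9))
})

test_that("fits are scale-equivariant in the count scale", {
  series <- make_deterministic_series(edges = 0:90)
  f1 <- fit_sir(series, n_starts = 8, seed = 2)
  series_k <- dplyr::mutate(series, count = count * 10)
  f2 <- fit_sir(series_k, n_starts = 8, seed = 2)
  g1 <- glance(f1); g2 <- glance(f2)
  # beta, gamma, R0 and the fit measure are invariant; N scales with k
  expect_rel_equal(g2$beta, g1$beta, 1e-4)
  expect_rel_equal(g2$gamma, g1$gamma, 1e-4)
  expect_rel_equal(g2$R0, g1$R0, 1e-4)
  expect_rel_equal(g2$N, 10 * g1$N, 1e-4)
  expect_lt(abs(g2$fit_measure - g1$fit_measure), 1e-4)
})

test_that("fit_sir flags failure instead of raising, and validates inputs", {
  expect_error(fit_sir(make_toy_series(c(1, 2, 3))),
               class = "popsir_invalid_input")  # fewer bins than parameters
  zero <- make_toy_series(c(0, 0, 0, 0))
  expect_error(fit_sir(zero), class = "popsir_invalid_input")
})

test_that("fit_sir is deterministic given its seed", {
  series <- make_toy_series(c(3, 11, 25, 18, 7, 3, 1))
  f1 <- fit_sir(series, n_starts = 5, seed = 9)
  f2 <- fit_sir(series, n_starts = 5, seed = 9)
  expect_identical(glance(f1), glance(f2))
})

test_that("the 3-df spline reproduces data already in its span", {
  # constants lie in the natural-spline span
  const <- make_toy_series(c(5, 5, 5, 5, 5))
  fs <- fit_spline(const)
  expect_equal(fs$trajectory$predicted_count, rep(5, 5), tolerance = 1e-9)
  expect_equal(fs$fit_measure, 0, tolerance = 1e-9)
  expect_length(fs$coefficients, 3)

  # straight lines too (natural splines are linear beyond the boundary)
  lin <- make_toy_series(c(1, 2, 3, 4, 5, 6))
  fl <- fit_spline(lin)
  expect_equal(fl$fit_measure, 0, tolerance = 1e-8)

  expect_error(fit_spline(make_toy_series(c(1, 2, 3))),
               class = "popsir_invalid_input")
})

test_that("spline trajectories may go negative and lose to SIR on sharp peaks", {
  # sharply peaked epidemic (r * duration >> 1), noise-free
  series <- make_deterministic_series(beta = 2.0, gamma = 0.3, S0 = 5000,
                                      I0 = 1, edges = seq(0, 30, by = 0.5))
  fspl <- fit_spline(series)
  expect_true(is.finite(fspl$fit_measure))
  expect_true(any(fspl$trajectory$predicted_count < 0))
  fsir <- fit_sir(series, n_starts = 15, seed = 3)
  expect_lt(fsir$fit_measure, fspl$fit_measure)
})
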