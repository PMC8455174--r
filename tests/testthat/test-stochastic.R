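test_that("degenerate simulations behave exactly", {
  # no infectious seed: nothing ever happens
  ev <- gillespie_sir(sir_params(0.5, 0.25, 100, 0), t_max = 50, seed = 1)
  expect_equal(nrow(ev), 0)

  # no recovery: every susceptible is eventually infected, never more
  for (s in 1:5) {
    ev <- gillespie_sir(sir_params(0.8, 0, 5, 1), t_max = 1e4, seed = s)
    expect_equal(nrow(ev), 5)
    expect_true(all(diff(ev$time_days) >= 0))
  }

  expect_error(gillespie_sir(sir_params(0.5, 0.25, 10.5, 1), t_max = 10),
               class = "popsir_invalid_input")
  expect_error(gillespie_sir(sir_params(0.5, 0.25, 10, 1), t_max = -1),
               class = "popsir_invalid_input")
})

test_that("identical seeds reproduce identical event streams", {
  p <- sir_params(0.6, 0.2, 500, 2)
  a <- gillespie_sir(p, t_max = 100, seed = 77)
  b <- gillespie_sir(p, t_max = 100, seed = 77)
  expect_identical(serialize(a$time_days, NULL), serialize(b$time_days, NULL))
  c <- gillespie_sir(p, t_max = 100, seed = 78)
  expect_false(isTRUE(all.equal(a$time_days, c$time_days)))
})

test_that("mean attack rate matches the final-size relation", {
  # R0 = 2 with 10 seeds: extinction contributes < (1/2)^10
  p <- sir_params(0.4, 0.2, 990, 10)
  set.seed(202)
  sizes <- vapply(1:1000, function(i) {
    nrow(gillespie_sir(p, t_max = 500))
  }, numeric(1))
  frac <- sizes / p$S0
  z <- final_size(2)
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - z), 3 * se + 2^-10)
})

test_that("raising beta does not decrease the expected number of events", {
  n_rep <- 500
  n1 <- vapply(1:n_rep, function(k) {
    nrow(gillespie_sir(sir_params(0.3, 0.2, 195, 5), t_max = 200,
                       seed = 9000 + k))
  }, numeric(1))
  n2 <- vapply(1:n_rep, function(k) {
    nrow(gillespie_sir(sir_params(0.6, 0.2, 195, 5), t_max = 200,
                       seed = 9000 + k))
  }, numeric(1))
  wins <- sum(n2 > n1)
  trials <- sum(n2 != n1)
  test <- stats::binom.test(wins, trials, p = 0.5, alternative = "greater")
  expect_lt(test$p.value, 0.01)
})

test_that("the mean of many stochastic curves tracks the deterministic curve", {
  # matched initial conditions; replicates conditioned on >= 5% attack rate
  N <- 1e4; I0 <- 50
  p <- sir_params(0.4, 0.2, N - I0, I0)
  edges <- seq(0, 120, by = 1)
  set.seed(303)
  curves <- matrix(0, nrow = 200, ncol = length(edges) - 1)
  kept <- 0
  while (kept < 200) {
    ev <- gillespie_sir(p, t_max = 120)
    if (nrow(ev) < 0.05 * N) next
    kept <- kept + 1
    idx <- findInterval(ev$time_days, edges, rightmost.closed = TRUE)
    curves[kept, ] <- tabulate(idx, nbins = length(edges) - 1)
  }
  mean_curve <- colMeans(curves)
  det <- simulate_deterministic(p, edges)$incidence$predicted_count
  expect_lt(max(abs(mean_curve - det)), 0.05 * max(det))
})

test_that("catalogue generation is deterministic and anchored to its medians", {
  cfg <- genre_config("Dance", 3, median_R0 = 2.84,
                      median_infectious_period = 7.49, median_S0 = 500)
  cat3 <- generate_catalog(cfg, seed = 5, t_max = 200)
  expect_equal(nrow(cat3), 3)
  expect_equal(unique(cat3$genre), "Dance")
  expect_equal(length(unique(cat3$seed)), 3)
  cat3b <- generate_catalog(cfg, seed = 5, t_max = 200)
  expect_identical(cat3$events, cat3b$events)

  # zero spread: every song carries exactly the median parameters,
  # so beta = R0 * gamma exactly (Pop-genre anchor values)
  pop <- genre_config("Pop", 10, median_R0 = 35.03,
                      median_infectious_period = 20.62, median_S0 = 600,
                      sdlog_R0 = 0, sdlog_infectious_period = 0,
                      sdlog_S0 = 0)
  catp <- generate_catalog(pop, seed = 6, t_max = 60)
  expect_equal(unique(catp$R0_true), 35.03)
  expect_equal(unique(round(catp$beta, 3)), 1.699)
  expect_equal(median(catp$R0_true), 35.03)
})

test_that("the default catalogue blueprint spans the published genre table", {
  cfgs <- default_genre_configs()
  expect_length(cfgs, 11)
  expect_equal(sum(vapply(cfgs, `[[`, integer(1), "n_songs")), 828L)
  # at least one genre spreads faster than 5/day (r = beta - gamma) so
  # sub-daily aggregation is exercised downstream
  growth <- vapply(cfgs, function(cf) {
    (cf$median_R0 - 1) / cf$median_infectious_period
  }, numeric(1))
  expect_true(any(growth > 5))
})
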