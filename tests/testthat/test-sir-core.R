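test_that("parameter validation rejects invalid inputs", {
  expect_error(sir_params(-0.1, 0.2, 100, 1), class = "popsir_invalid_input")
  expect_error(sir_params(0.1, -0.2, 100, 1), class = "popsir_invalid_input")
  expect_error(sir_params(0.1, 0.2, 0, 1), class = "popsir_invalid_input")
  expect_error(sir_params(0.1, 0.2, 100, -1), class = "popsir_invalid_input")
  p <- sir_params(0.1, 0.2, 100, 1)
  expect_equal(p$R_init, 0)
  expect_equal(p$N, 101)
  expect_error(simulate_deterministic(p, c(0, 1, 1)),
               class = "popsir_invalid_input")
  expect_error(simulate_deterministic(p, 5),
               class = "popsir_invalid_input")
})

test_that("disease-free start stays at zero infection", {
  p <- sir_params(0.5, 0.25, 1000, 0)
  traj <- simulate_deterministic(p, seq(0, 50, by = 0.5))
  expect_equal(max(abs(traj$compartments$I)), 0, tolerance = 1e-10)
  expect_equal(max(abs(traj$incidence$predicted_count)), 0,
               tolerance = 1e-10)
})

test_that("with no transmission, I decays exponentially and S is constant", {
  p <- sir_params(0, 0.25, 100, 5)
  traj <- simulate_deterministic(p, 0:20)
  expect_equal(traj$compartments$I, 5 * exp(-0.25 * (0:20)),
               tolerance = 1e-7)
  expect_equal(traj$compartments$S, rep(100, 21), tolerance = 1e-8)
})

test_that("epidemic peak matches the closed-form peak condition", {
  # At the peak of I, S equals gamma/beta (in counts), and
  # I_peak = S0 + I0 - (gamma/beta) * (1 + log(beta * S0 / gamma)).
  p <- sir_params(0.5, 0.25, 999, 1)
  traj <- simulate_deterministic(p, seq(0, 60, by = 0.01))
  cmp <- traj$compartments
  k <- which.max(cmp$I)
  s_thresh <- p$gamma / p$beta * p$N   # 500 persons
  i_peak <- p$N - s_thresh * (1 + log(p$S0 / s_thresh))
  expect_equal(cmp$S[k], s_thresh, tolerance = 1e-2)
  expect_equal(max(cmp$I), i_peak, tolerance = 1e-5)
  expect_equal(round(max(cmp$I), 1), 153.9)
})

test_that("integrator agrees with an independent stiff-capable solver", {
  skip_if_not_installed("deSolve")
  p <- sir_params(2.5, 0.5, 9990, 10)
  edges <- seq(0, 30, by = 0.25)
  traj <- simulate_deterministic(p, edges)
  rhs <- function(t, y, parms) {
    inf <- parms$beta * y[1] * y[2]
    list(c(-inf, inf - parms$gamma * y[2], parms$gamma * y[2]))
  }
  ode <- deSolve::lsoda(c(p$S0, p$I0, 0) / p$N, edges, rhs,
                        list(beta = p$beta, gamma = p$gamma),
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(ode[, 2] * p$N - traj$compartments$S)), 1e-4 * p$N)
  expect_lt(max(abs(ode[, 3] * p$N - traj$compartments$I)), 1e-4 * p$N)
})

test_that("compartments are conserved and monotone across random parameters", {
  set.seed(101)
  for (rep in 1:25) {
    p <- sir_params(beta = exp(runif(1, log(0.05), log(20))),
                    gamma = exp(runif(1, log(0.01), log(2))),
                    S0 = round(runif(1, 50, 1e5)),
                    I0 = round(runif(1, 1, 50)))
    horizon <- min(365, 30 / max(p$gamma, 0.05))
    traj <- simulate_deterministic(p, seq(0, horizon, length.out = 80))
    cmp <- traj$compartments
    expect_lt(max(abs(cmp$S + cmp$I + cmp$R - p$N)) / p$N, 1e-6)
    expect_true(all(diff(cmp$S) <= 1e-9 * p$N))
    expect_true(all(diff(cmp$R) >= -1e-9 * p$N))
    expect_equal(traj$incidence$predicted_count, -diff(cmp$S))
  }
})

test_that("long-horizon cumulative incidence approaches S0 * Z", {
  p <- sir_params(0.4, 0.2, 10000, 10)
  horizon <- 0
  traj <- simulate_deterministic(p, seq(0, 400, by = 1))
  cmp <- traj$compartments
  stopifnot(min(cmp$I) < 1e-6 * p$N)  # epidemic has burnt out
  total <- sum(traj$incidence$predicted_count)
  expected <- p$S0 * final_size(p$beta / p$gamma)
  expect_rel_equal(total, expected, 0.005)
})

test_that("early growth of I is exponential at rate r = beta - gamma", {
  p <- sir_params(0.6, 0.2, 1e6, 10)
  # first 5% of the epidemic: S ~ S0, so I(t) ~ I0 * exp(r t)
  traj <- simulate_deterministic(p, seq(0, 18, by = 0.25))
  cmp <- traj$compartments
  early <- cmp[cmp$R < 0.05 * p$N, ]
  slope <- stats::coef(stats::lm(log(early$I) ~ early$time))[2]
  expect_rel_equal(unname(slope), p$beta - p$gamma, 0.05)
})

test_that("derived quantities follow the standard SIR relations", {
  p <- sir_params(0.55, 1 / 45.25, 4000, 1)
  d <- derive_quantities(p)
  expect_equal(d$R0, 0.55 * 45.25)
  expect_equal(d$r, 0.55 - 1 / 45.25)
  expect_equal(d$infectious_period, 45.25)
  expect_equal(d$doubling_time, log(2) / d$r)
  expect_equal(d$Z, final_size(d$R0))

  # threshold case: r = 0 means no doubling time and no epidemic
  d0 <- derive_quantities(sir_params(0.2, 0.2, 100, 1))
  expect_equal(d0$R0, 1)
  expect_true(is.na(d0$doubling_time))
  expect_equal(d0$Z, 0)

  expect_error(derive_quantities(sir_params(0.2, 0, 100, 1)),
               class = "popsir_invalid_input")

  # data-frame method appends columns row-wise
  df <- tibble::tibble(beta = c(0.4, 0.2), gamma = c(0.2, 0.1))
  dd <- derive_quantities(df)
  expect_equal(dd$R0, c(2, 2))
  expect_equal(nrow(dd), 2)
})
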