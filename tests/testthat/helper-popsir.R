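# Shared fixtures, all generated in code.

# A noise-free incidence series from the deterministic model.
make_deterministic_series <- function(beta = 0.4, gamma = 0.2, S0 = 5000,
                                      I0 = 1, edges = 0:120) {
  traj <- simulate_deterministic(sir_params(beta, gamma, S0, I0), edges)
  out <- traj$incidence
  names(out)[names(out) == "predicted_count"] <- "count"
  out
}

# A small well-formed observed series by hand.
make_toy_series <- function(counts = c(2, 5, 9, 6, 3, 1),
                            width = 1) {
  n <- length(counts)
  tibble::tibble(bin_start = (0:(n - 1)) * width, bin_end = (1:n) * width,
                 count = counts)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
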