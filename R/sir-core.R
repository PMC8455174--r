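#' SIR model parameters
#'
#' Bundle and validate the parameters of the
#' susceptible-infectious-recovered (SIR) model used throughout the
#' package. The dynamics are integrated in population proportions
#' (\eqn{S + I + R = 1} internally), so the transmission rate `beta` is the
#' effective contact rate per day and the force of infection is
#' \eqn{\beta S I / N}. Under this scaling the familiar parameter relations
#' hold exactly: basic reproduction number \eqn{R_0 = \beta/\gamma}, initial
#' growth rate \eqn{r = \beta - \gamma}, mean infectious period
#' \eqn{1/\gamma}.
#'
#' The initially recovered population is fixed at zero: every analysis in
#' this package starts from a wholly naive population at release time.
#'
#' @param beta Transmission rate (per day, >= 0).
#' @param gamma Recovery rate (per day, >= 0). `gamma = 0` is allowed for
#'   simulation (no recovery) but [derive_quantities()] requires
#'   `gamma > 0`.
#' @param S0 Initially susceptible count (persons, > 0).
#' @param I0 Initially infectious count (persons, >= 0).
#'
#' @return An object of class `sir_params`: a named list with elements
#'   `beta`, `gamma`, `S0`, `I0`, `R_init` (always 0) and `N = S0 + I0`.
#' @examples
#' p <- sir_params(beta = 0.4, gamma = 0.2, S0 = 5000, I0 = 1)
#' derive_quantities(p)
#' @export
sir_params <- function(beta, gamma, S0, I0) {
  for (nm in c("beta", "gamma", "S0", "I0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a single finite number."),
            class = "popsir_invalid_input")
    }
  }
  if (beta < 0) abort("`beta` must be >= 0.", class = "popsir_invalid_input")
  if (gamma < 0) abort("`gamma` must be >= 0.", class = "popsir_invalid_input")
  if (S0 <= 0) abort("`S0` must be > 0.", class = "popsir_invalid_input")
  if (I0 < 0) abort("`I0` must be >= 0.", class = "popsir_invalid_input")
  structure(
    list(beta = beta, gamma = gamma, S0 = S0, I0 = I0, R_init = 0,
         N = S0 + I0),
    class = "sir_params"
  )
}

#' @export
print.sir_params <- function(x, ...) {
  cat("<sir_params> beta =", format(x$beta), "/day, gamma =",
      format(x$gamma), "/day, S0 =", format(x$S0), ", I0 =",
      format(x$I0), "\n")
  invisible(x)
}

#' Deterministic SIR trajectory on a bin grid
#'
#' Integrates the SIR ordinary differential equations
#' \deqn{dS/dt = -\beta S I,\quad dI/dt = \beta S I - \gamma I,\quad
#'   dR/dt = \gamma I}
#' (in proportions; see [sir_params()]) with an adaptive Dormand-Prince
#' 5(4) scheme, and reports compartment sizes at every bin edge together
#' with the model-predicted event count per bin. The predicted count for a
#' bin is the incidence over that bin — the decrease of S — since a
#' download (or case report) is an event, not a state.
#'
#' @param params A [sir_params()] object.
#' @param bin_edges Strictly increasing numeric vector of bin boundaries
#'   (days), length >= 2. The initial condition holds at `bin_edges[1]`.
#' @param rtol,atol Relative and absolute solver tolerances.
#'
#' @return An object of class `sir_trajectory`: a list with
#'   * `compartments`: tibble with columns `time`, `S`, `I`, `R` (persons)
#'     at each bin edge,
#'   * `incidence`: tibble with columns `bin_start`, `bin_end`,
#'     `predicted_count`,
#'   * `params`: the input parameters.
#' @examples
#' p <- sir_params(beta = 0.5, gamma = 0.25, S0 = 999, I0 = 1)
#' traj <- simulate_deterministic(p, 0:100)
#' tidy(traj)
#' @export
simulate_deterministic <- function(params, bin_edges, rtol = 1e-8,
                                   atol = 1e-10) {
  stopifnot(inherits(params, "sir_params"))
  if (!is.numeric(bin_edges) || length(bin_edges) < 2L ||
      anyNA(bin_edges) || any(diff(bin_edges) <= 0)) {
    abort("`bin_edges` must be a strictly increasing numeric vector of length >= 2.",
          class = "popsir_invalid_input")
  }
  N <- params$N
  y <- .sir_integrate_cpp(params$beta, params$gamma,
                          params$S0 / N, params$I0 / N, 0,
                          as.numeric(bin_edges), rtol, atol)
  if (anyNA(y)) {
    abort("ODE integration failed (step size underflow or non-finite state).",
          class = "popsir_numerical_failure")
  }
  compartments <- tibble(
    time = as.numeric(bin_edges),
    S = y[, 1] * N, I = y[, 2] * N, R = y[, 3] * N
  )
  n <- length(bin_edges)
  incidence <- tibble(
    bin_start = compartments$time[-n],
    bin_end = compartments$time[-1],
    predicted_count = -diff(compartments$S)
  )
  structure(
    list(compartments = compartments, incidence = incidence, params = params),
    class = "sir_trajectory"
  )
}

#' @export
print.sir_trajectory <- function(x, ...) {
  cat("<sir_trajectory>", nrow(x$incidence), "bins over [",
      format(min(x$compartments$time)), ",",
      format(max(x$compartments$time)), "] days; total predicted events",
      format(sum(x$incidence$predicted_count)), "\n")
  invisible(x)
}

#' Final size of an SIR epidemic
#'
#' Solves the final size relation \eqn{Z = 1 - e^{-R_0 Z}} for the
#' proportion `Z` of the initially susceptible population that is
#' eventually infected. For \eqn{R_0 \le 1} the only root in \eqn{[0, 1)}
#' is 0; for \eqn{R_0 > 1} the unique positive root is found by bracketed
#' root-finding on \eqn{(0, 1)}.
#'
#' @param R0 Basic reproduction number(s), finite and >= 0. Vectorized.
#' @param tol Root-finding tolerance.
#' @return Final size(s) in `[0, 1)`.
#' @examples
#' final_size(4)    # 0.98 to two decimals
#' final_size(0.5)  # subcritical: 0
#' @export
final_size <- function(R0, tol = 1e-10) {
  if (!is.numeric(R0) || anyNA(R0) || any(!is.finite(R0)) || any(R0 < 0)) {
    abort("`R0` must be finite and >= 0.", class = "popsir_invalid_input")
  }
  vapply(R0, function(r0) {
    if (r0 <= 1) return(0)
    f <- function(z) z - 1 + exp(-r0 * z)
    upper <- 1 - 1e-12
    if (f(upper) <= 0) {
      # Root lies within 1e-12 of 1 (large R0): the fixed-point iteration
      # z <- 1 - exp(-R0 z) converges to machine precision in a few steps.
      z <- 1
      for (k in 1:8) z <- 1 - exp(-r0 * z)
      # exp(-R0) can underflow; keep the contract Z < 1 strict
      return(min(z, 1 - .Machine$double.eps / 2))
    }
    stats::uniroot(f, lower = 1e-12, upper = upper, tol = tol)$root
  }, numeric(1))
}

#' Invert the final size relation
#'
#' Given a final size `Z` in `[0, 1)`, returns the basic reproduction
#' number on the supercritical branch via the exact algebraic inverse
#' \eqn{R_0 = -\log(1 - Z)/Z}. `Z = 0` is compatible with any
#' \eqn{R_0 \le 1}; by convention the threshold value 1 is returned.
#'
#' @param Z Final size(s) in `[0, 1)`. Vectorized.
#' @param tol Unused (the inverse is closed-form); kept for interface
#'   symmetry with [final_size()].
#' @return Basic reproduction number(s) >= 1.
#' @examples
#' invert_final_size(0.98)  # about 3.99
#' @export
invert_final_size <- function(Z, tol = 1e-10) {
  if (!is.numeric(Z) || anyNA(Z) || any(Z < 0) || any(Z >= 1)) {
    abort("`Z` must lie in [0, 1): no finite R0 yields Z >= 1.",
          class = "popsir_invalid_input")
  }
  ifelse(Z == 0, 1, -log(1 - Z) / Z)
}

#' Derived epidemiological quantities
#'
#' Computes the interpretable quantities implied by SIR parameters: the
#' basic reproduction number \eqn{R_0 = \beta/\gamma}, initial growth rate
#' \eqn{r = \beta - \gamma} (per day), mean infectious period
#' \eqn{1/\gamma} (days), doubling time \eqn{\ln 2 / r} (days, `NA` unless
#' `r > 0`) and the final size `Z` from [final_size()].
#'
#' For a data frame the quantities are appended column-wise, so genre
#' tables can be built with the usual grouped verbs.
#'
#' @param x A [sir_params()] object, or a data frame with numeric columns
#'   `beta` and `gamma`.
#' @param ... Unused.
#' @return A tibble: one row per parameter set, with columns `R0`, `r`,
#'   `infectious_period`, `doubling_time`, `Z` (input columns are kept for
#'   data-frame input).
#' @examples
#' derive_quantities(sir_params(0.55, 1 / 45.25, 1000, 1))
#' @export
derive_quantities <- function(x, ...) UseMethod("derive_quantities")

#' @rdname derive_quantities
#' @export
derive_quantities.sir_params <- function(x, ...) {
  .derived_cols(x$beta, x$gamma)
}

#' @rdname derive_quantities
#' @export
derive_quantities.data.frame <- function(x, ...) {
  if (!all(c("beta", "gamma") %in% names(x))) {
    abort("`x` must have columns `beta` and `gamma`.",
          class = "popsir_invalid_input")
  }
  dplyr::bind_cols(as_tibble(x), .derived_cols(x$beta, x$gamma))
}

.derived_cols <- function(beta, gamma) {
  if (any(gamma <= 0)) {
    abort("`gamma` must be > 0 to derive epidemiological quantities.",
          class = "popsir_invalid_input")
  }
  R0 <- beta / gamma
  r <- beta - gamma
  tibble(
    R0 = R0,
    r = r,
    infectious_period = 1 / gamma,
    doubling_time = ifelse(r > 0, log(2) / r, NA_real_),
    Z = final_size(R0)
  )
}

#' @export
tidy.sir_trajectory <- function(x, ...) x$incidence

#' @export
glance.sir_trajectory <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      n_bins = nrow(x$incidence),
      total_predicted = sum(x$incidence$predicted_count)
    ),
    derive_quantities(x$params)
  )
}
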