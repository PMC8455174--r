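#' Aggregate an event stream into a binned series
#'
#' Counts events into time bins of width `base_bin` (1 day by default).
#' Some series rise so fast that daily bins obscure the initial growth:
#' when the peak daily count falls within the first `refine_window` days,
#' all bins up to and including the peak day are re-aggregated at
#' `fine_bin` resolution (1 hour by default) while later bins stay at
#' `base_bin`. The total event count is conserved under every rule
#' setting.
#'
#' @param events Numeric vector of event times (days since release), or
#'   an `event_stream` tibble from [gillespie_sir()].
#' @param base_bin Base bin width (days).
#' @param fine_bin Fine bin width (days) used near onset when refinement
#'   triggers.
#' @param refine_window Refinement triggers only if the peak base-scale
#'   bin starts within this many days of release.
#' @param refine Set `FALSE` to disable mixed-resolution aggregation.
#' @return A series tibble with columns `bin_start`, `bin_end`, `count`.
#'   An empty stream yields a zero-row tibble (flagged unfittable via
#'   attribute `fittable = FALSE`).
#' @examples
#' aggregate_events(c(0.1, 0.2, 1.5))  # counts 2, 1
#' @export
aggregate_events <- function(events, base_bin = 1, fine_bin = 1 / 24,
                             refine_window = 3, refine = TRUE) {
  if (is.data.frame(events)) events <- events$time_days
  if (length(events) == 0) {
    out <- tibble(bin_start = numeric(0), bin_end = numeric(0),
                  count = numeric(0))
    attr(out, "fittable") <- FALSE
    return(out)
  }
  if (any(events < 0) || anyNA(events)) {
    abort("Event times must be nonnegative and non-missing.",
          class = "popsir_invalid_input")
  }
  events <- sort(events)
  bin_count <- function(edges) {
    idx <- findInterval(events, edges, rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L
    tibble(bin_start = edges[-length(edges)], bin_end = edges[-1],
           count = tabulate(idx, nbins = length(edges) - 1L))
  }
  n_base <- max(1, ceiling(max(events) / base_bin + 1e-12))
  base_edges <- seq(0, n_base * base_bin, by = base_bin)
  daily <- bin_count(base_edges)
  if (refine) {
    peak <- which.max(daily$count)
    if (daily$bin_start[peak] < refine_window) {
      cut_at <- daily$bin_end[peak]
      fine_edges <- seq(0, cut_at, by = fine_bin)
      if (abs(fine_edges[length(fine_edges)] - cut_at) > 1e-12) {
        fine_edges <- c(fine_edges, cut_at)
      }
      edges <- unique(c(fine_edges, base_edges[base_edges > cut_at + 1e-12]))
      out <- bin_count(edges)
      attr(out, "fittable") <- TRUE
      return(out)
    }
  }
  attr(daily, "fittable") <- TRUE
  daily
}

#' Minimum admissible basic reproduction number
#'
#' The smallest final size consistent with an accepted series is the
#' least-downloaded song spreading through the largest conceivable
#' susceptible pool (the whole user base): `Z_min = min_downloads /
#' user_count`. Because the final size relation is strictly increasing in
#' R0, inverting it at `Z_min` gives the minimum admissible R0.
#'
#' @param user_count Largest conceivable susceptible population (persons).
#' @param min_downloads Smallest accepted total download count (events,
#'   `0 < min_downloads <= user_count`).
#' @return The minimum admissible basic reproduction number (>= 1).
#' @examples
#' compute_rmin(1000, 980)  # about 3.99
#' @export
compute_rmin <- function(user_count, min_downloads) {
  if (min_downloads <= 0 || min_downloads > user_count) {
    abort("Need 0 < min_downloads <= user_count.",
          class = "popsir_invalid_input")
  }
  invert_final_size(min_downloads / user_count)
}

#' Susceptible pool implied by total downloads and R0
#'
#' Reads the observed total download count as `Z * S0` and returns
#' `S0 = total_downloads / Z` with `Z` from [final_size()]. Defined only
#' for `R0 > 1` (otherwise `Z = 0`). The result is always at least
#' `total_downloads` since `Z <= 1`.
#'
#' @param total_downloads Total events observed for the series (> 0).
#' @param R0_est Estimated basic reproduction number (> 1). Vectorized
#'   over both arguments.
#' @return Implied initially susceptible population (persons).
#' @examples
#' susceptible_pool(5759, 2.84)
#' @export
susceptible_pool <- function(total_downloads, R0_est) {
  if (any(total_downloads <= 0)) {
    abort("`total_downloads` must be > 0.", class = "popsir_invalid_input")
  }
  if (any(R0_est <= 1)) {
    abort("`R0_est` must be > 1: the final size is zero at or below threshold.",
          class = "popsir_invalid_input")
  }
  total_downloads / final_size(R0_est)
}

#' Inclusion criteria for satisfactory SIR fits
#'
#' A fit is "well captured" when its relative fit measure is at most
#' `max_fit_measure` (11 in the study design) and its estimated basic
#' reproduction number is at least `r_min` (from [compute_rmin()]).
#'
#' @param max_fit_measure Upper threshold on the relative fit measure
#'   (> 0).
#' @param r_min Minimum admissible basic reproduction number (>= 1).
#' @return An `inclusion_criteria` list.
#' @export
inclusion_criteria <- function(max_fit_measure = 11, r_min = 1) {
  if (max_fit_measure <= 0) {
    abort("`max_fit_measure` must be > 0.", class = "popsir_invalid_input")
  }
  if (r_min < 1) {
    abort("`r_min` must be >= 1.", class = "popsir_invalid_input")
  }
  structure(list(max_fit_measure = max_fit_measure, r_min = r_min),
            class = "inclusion_criteria")
}

#' Apply inclusion criteria to a table of fits
#'
#' Flags each fit as well captured or excluded, recording which rule
#' fired: `"fit_measure"` (relative fit measure above threshold),
#' `"r_min"` (estimated R0 below the minimum), `"both"`, or
#' `"fit_failure"` for non-converged fits.
#'
#' @param fits A data frame with numeric columns `fit_measure` and `R0`
#'   (e.g. row-bound [glance()] output of [fit_sir()]), or a list of
#'   `sir_fit` objects.
#' @param criteria An [inclusion_criteria()] object.
#' @return The input rows as a tibble with logical `well_captured` and
#'   character `exclusion_reason` (`NA` for retained rows) appended.
#' @examples
#' fits <- tibble::tibble(fit_measure = c(2, 12), R0 = c(5, 5))
#' apply_inclusion(fits, inclusion_criteria(11, 3.99))
#' @export
apply_inclusion <- function(fits, criteria = inclusion_criteria()) {
  stopifnot(inherits(criteria, "inclusion_criteria"))
  if (is.list(fits) && !is.data.frame(fits) &&
      all(vapply(fits, inherits, logical(1), "popsir_fit"))) {
    fits <- dplyr::bind_rows(purrr::map(fits, glance))
  }
  fits <- as_tibble(fits)
  if (nrow(fits) == 0) {
    return(dplyr::mutate(fits, well_captured = logical(0),
                         exclusion_reason = character(0)))
  }
  if (!all(c("fit_measure", "R0") %in% names(fits))) {
    abort("`fits` needs columns `fit_measure` and `R0`.",
          class = "popsir_invalid_input")
  }
  bad_fit <- !is.finite(fits$fit_measure) | !is.finite(fits$R0)
  over <- !bad_fit & fits$fit_measure > criteria$max_fit_measure
  low <- !bad_fit & fits$R0 < criteria$r_min
  reason <- dplyr::case_when(
    bad_fit ~ "fit_failure",
    over & low ~ "both",
    over ~ "fit_measure",
    low ~ "r_min",
    TRUE ~ NA_character_
  )
  dplyr::mutate(fits, well_captured = is.na(reason),
                exclusion_reason = reason)
}

#' Genre-level medians of estimated and derived parameters
#'
#' Summarizes a fitted catalogue by genre: medians of the basic
#' reproduction number, mean infectious period, transmission rate, growth
#' rate, doubling time (computed per song, then medianed), download
#' count, final size and the calculated susceptible pool
#' `downloads / Z` (per song, `NA` where `R0 <= 1`).
#'
#' @param entries A data frame with one row per song: columns `genre`,
#'   `beta`, `gamma`, `downloads`.
#' @return A tibble with one row per genre (`n_songs` and the medians).
#'   Genres present as factor levels but empty are dropped with a
#'   warning.
#' @export
summarize_by_genre <- function(entries) {
  entries <- as_tibble(entries)
  req <- c("genre", "beta", "gamma", "downloads")
  if (!all(req %in% names(entries))) {
    abort(paste("`entries` needs columns", paste(req, collapse = ", ")),
          class = "popsir_invalid_input")
  }
  if (is.factor(entries$genre)) {
    empty <- setdiff(levels(entries$genre), unique(as.character(entries$genre)))
    if (length(empty)) {
      warn(paste("Omitting empty genres:", paste(empty, collapse = ", ")))
    }
    entries$genre <- as.character(entries$genre)
  }
  per_song <- derive_quantities(entries)
  per_song$S0_calc <- ifelse(per_song$R0 > 1,
                             per_song$downloads / per_song$Z, NA_real_)
  dplyr::summarise(
    dplyr::group_by(per_song, .data$genre),
    n_songs = dplyr::n(),
    R0 = median(.data$R0),
    infectious_period = median(.data$infectious_period),
    beta = median(.data$beta),
    r = median(.data$r),
    doubling_time = median(.data$doubling_time, na.rm = TRUE),
    downloads = median(.data$downloads),
    Z = median(.data$Z),
    S0_calc = median(.data$S0_calc, na.rm = TRUE),
    .groups = "drop"
  )
}

# Fit both models to one series and return a comparison row. Ties in the
# fit measure count as spline-better (conservative toward the mechanistic
# model).
.compare_one <- function(series, series_id, n_starts, seed, ...) {
  sir <- tryCatch(fit_sir(series, n_starts = n_starts, seed = seed, ...),
                  error = function(e) NULL)
  spl <- tryCatch(fit_spline(series), error = function(e) NULL)
  fm_sir <- if (!is.null(sir)) sir$fit_measure else NA_real_
  fm_spl <- if (!is.null(spl)) spl$fit_measure else NA_real_
  tibble(
    series_id = series_id,
    n_bins = nrow(series),
    downloads = sum(series$count),
    fit_measure_sir = fm_sir,
    fit_measure_spline = fm_spl,
    R0 = if (!is.null(sir)) sir$derived$R0 else NA_real_,
    sir_converged = !is.null(sir) && sir$converged,
    sir_better = !is.na(fm_sir) && !is.na(fm_spl) && fm_sir < fm_spl
  )
}

#' Build a comparison report from per-series rows
#'
#' @param rows Per-series tibble as produced inside
#'   [calibration_experiment()].
#' @param criteria The [inclusion_criteria()] applied.
#' @param n_unusable Number of series excluded before fitting.
#' @return A `comparison_report` with the rows (inclusion flags appended)
#'   and summary accessors via [glance()].
#' @export
comparison_report <- function(rows, criteria = inclusion_criteria(),
                              n_unusable = 0L) {
  rows <- apply_inclusion(
    dplyr::mutate(as_tibble(rows), fit_measure = .data$fit_measure_sir),
    criteria
  )
  rows$fit_measure <- NULL
  structure(list(rows = rows, criteria = criteria,
                 n_unusable = as.integer(n_unusable)),
            class = "comparison_report")
}

#' @export
glance.comparison_report <- function(x, ...) {
  rows <- x$rows
  wc <- rows$well_captured
  tibble(
    n_series = nrow(rows),
    n_unusable = x$n_unusable,
    n_well_captured = sum(wc),
    frac_well_captured = if (nrow(rows)) mean(wc) else NA_real_,
    frac_sir_better_overall = if (nrow(rows)) mean(rows$sir_better) else NA_real_,
    frac_sir_better_among_well_captured =
      if (any(wc)) mean(rows$sir_better[wc]) else NA_real_,
    median_fit_sir = median(rows$fit_measure_sir, na.rm = TRUE),
    median_fit_spline = median(rows$fit_measure_spline, na.rm = TRUE)
  )
}

#' @export
tidy.comparison_report <- function(x, ...) x$rows

#' @export
print.comparison_report <- function(x, ...) {
  g <- glance(x)
  cat("<comparison_report>", g$n_series, "series (", g$n_unusable,
      "unusable );", g$n_well_captured, "well captured (",
      sprintf("%.1f%%", 100 * g$frac_well_captured), ")\n")
  cat("  SIR better:", sprintf("%.1f%%", 100 * g$frac_sir_better_overall),
      "overall,",
      sprintf("%.1f%%", 100 * g$frac_sir_better_among_well_captured),
      "among well captured\n")
  cat("  median fit measure:", format(g$median_fit_sir, digits = 3),
      "(SIR) vs", format(g$median_fit_spline, digits = 3), "(spline)\n")
  invisible(x)
}

#' Simulation ensemble for the calibration arm
#'
#' Parameter ranges for the stochastic epidemics of the calibration
#' experiment: R0 and the infectious period are drawn log-uniformly, S0
#' uniformly, spanning the ranges observed across genres in the study
#' conditions; each epidemic starts from a single infectious individual.
#'
#' @param R0_range,infectious_period_range Log-uniform sampling ranges.
#' @param S0_range Uniform sampling range for the susceptible pool.
#' @param I0 Initial infectious count.
#' @param t_max Simulation horizon (days).
#' @return A `sim_ensemble` list.
#' @export
sim_ensemble <- function(R0_range = c(1.5, 100),
                         infectious_period_range = c(2, 200),
                         S0_range = c(500, 1e4), I0 = 1, t_max = 365) {
  structure(list(R0_range = R0_range,
                 infectious_period_range = infectious_period_range,
                 S0_range = S0_range, I0 = I0, t_max = t_max),
            class = "sim_ensemble")
}

# Draw one parameter set from the ensemble (uses the current RNG stream).
.draw_ensemble_params <- function(cfg) {
  R0 <- exp(runif(1, log(cfg$R0_range[1]), log(cfg$R0_range[2])))
  period <- exp(runif(1, log(cfg$infectious_period_range[1]),
                      log(cfg$infectious_period_range[2])))
  S0 <- round(runif(1, cfg$S0_range[1], cfg$S0_range[2]))
  sir_params(beta = R0 / period, gamma = 1 / period, S0 = S0, I0 = cfg$I0)
}

#' The mechanistic-vs-phenomenological calibration experiment
#'
#' Fits the SIR model and the 3-df cubic spline to every series of a
#' catalogue (arm A, song-structured data) and to `n_sims` fresh
#' stochastic epidemics drawn from `sim_config` (arm B, data known to be
#' generated by the SIR process), and reports the two arms side by side.
#' The interesting comparison is not whether the mechanistic model beats
#' the spline, but whether it does so *to the same extent* on both arms.
#'
#' Series too small to fit (fewer than `min_events` events or fewer than
#' 4 occupied bins) are recorded as unusable and excluded from the
#' denominators; their number is reported. Both inclusion rules are
#' applied to both arms with rule-level attribution. Per-series fit
#' failures propagate into the report rows rather than aborting the run.
#'
#' @param catalog Arm-A input: a catalogue tibble from
#'   [generate_catalog()] (list-column `events`), or a list of series
#'   tibbles, or `NULL` to run the simulation arm only.
#' @param n_sims Number of fresh stochastic epidemics for arm B.
#' @param sim_config A [sim_ensemble()].
#' @param seed Master seed; child seeds for each simulation and fit are
#'   derived from it.
#' @param criteria [inclusion_criteria()] applied to both arms.
#' @param n_starts Multistart budget per SIR fit.
#' @param min_events Series with fewer events are recorded as unusable.
#' @param ... Further arguments to [fit_sir()].
#' @return A `calibration_comparison`: list with `comparison_report`s
#'   `catalog` and `simulations` (either may be `NULL`); `glance()` gives
#'   a one-row-per-arm summary.
#' @export
calibration_experiment <- function(catalog = NULL, n_sims = 100,
                                   sim_config = sim_ensemble(), seed = 1L,
                                   criteria = inclusion_criteria(),
                                   n_starts = 100, min_events = 10, ...) {
  if (n_sims < 1 && is.null(catalog)) {
    abort("Nothing to do: no catalog and n_sims < 1.",
          class = "popsir_invalid_input")
  }
  set.seed(seed)
  fit_seeds_a <- integer(0)
  series_list <- list()
  if (!is.null(catalog)) {
    if (is.data.frame(catalog) && "events" %in% names(catalog)) {
      series_list <- purrr::map(catalog$events, aggregate_events)
      ids <- catalog$song_id %||% sprintf("series_%03d", seq_along(series_list))
    } else {
      series_list <- catalog
      ids <- names(series_list) %||%
        sprintf("series_%03d", seq_along(series_list))
      if (any(ids == "")) ids <- sprintf("series_%03d", seq_along(series_list))
    }
  } else {
    ids <- character(0)
  }

  run_arm <- function(series_list, ids) {
    usable <- vapply(series_list, function(s) {
      nrow(s) >= 4 && sum(s$count) >= min_events && sum(s$count > 0) >= 4
    }, logical(1))
    fit_seed <- sample.int(.Machine$integer.max - 1L,
                           max(1L, length(series_list)))
    rows <- purrr::map(which(usable), function(i) {
      .compare_one(series_list[[i]], ids[i], n_starts = n_starts,
                   seed = fit_seed[i], ...)
    })
    comparison_report(dplyr::bind_rows(rows), criteria,
                      n_unusable = sum(!usable))
  }

  report_a <- if (length(series_list)) run_arm(series_list, ids) else NULL

  report_b <- NULL
  if (n_sims >= 1) {
    sims <- purrr::map(seq_len(n_sims), function(i) {
      p <- .draw_ensemble_params(sim_config)
      ev <- .gillespie_sir_cpp(p$beta, p$gamma, as.integer(p$S0),
                               as.integer(p$I0), sim_config$t_max)
      aggregate_events(as.numeric(ev))
    })
    report_b <- run_arm(sims, sprintf("sim_%04d", seq_len(n_sims)))
  }

  structure(list(catalog = report_a, simulations = report_b, seed = seed),
            class = "calibration_comparison")
}

#' @export
glance.calibration_comparison <- function(x, ...) {
  arms <- purrr::compact(list(catalog = x$catalog,
                              simulations = x$simulations))
  dplyr::bind_rows(purrr::map(arms, glance), .id = "arm")
}

#' @export
print.calibration_comparison <- function(x, ...) {
  cat("<calibration_comparison>\n")
  if (!is.null(x$catalog)) { cat("-- catalog arm --\n"); print(x$catalog) }
  if (!is.null(x$simulations)) {
    cat("-- simulation arm --\n"); print(x$simulations)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
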