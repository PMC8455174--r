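#' Exact stochastic SIR simulation (Gillespie direct method)
#'
#' Simulates the continuous-time Markov jump process underlying the SIR
#' model: infection \eqn{S + I \to 2I} at rate \eqn{\beta S I / N} and
#' recovery \eqn{I \to R} at rate \eqn{\gamma I}, with
#' \eqn{N = S_0 + I_0}. Successive waiting times are exponential with the
#' correct total rate, i.e. downloads arrive as an inhomogeneous Poisson
#' process with no extra heterogeneity. Infection event times are the
#' simulated download times; the `I0` seed individuals are not counted as
#' events, so at most `S0` events can occur.
#'
#' @param params A [sir_params()] object with integer-valued `S0`, `I0`.
#' @param t_max Simulation horizon (days, > 0).
#' @param seed Optional integer seed (`set.seed()` is called when given);
#'   identical seeds give identical streams.
#' @param label Optional genre/series label stored on the result.
#'
#' @return An `event_stream`: a tibble with column `time_days` (sorted
#'   ascending), with attributes `truth` (the generating [sir_params()]),
#'   `seed` and `label`.
#' @examples
#' p <- sir_params(beta = 0.4, gamma = 0.2, S0 = 500, I0 = 5)
#' ev <- gillespie_sir(p, t_max = 200, seed = 1)
#' nrow(ev)
#' @export
gillespie_sir <- function(params, t_max, seed = NULL, label = NA_character_) {
  stopifnot(inherits(params, "sir_params"))
  if (params$S0 != round(params$S0) || params$I0 != round(params$I0)) {
    abort("Stochastic simulation requires integer-valued `S0` and `I0`.",
          class = "popsir_invalid_input")
  }
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max <= 0) {
    abort("`t_max` must be a single positive number.",
          class = "popsir_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  times <- .gillespie_sir_cpp(params$beta, params$gamma,
                              as.integer(round(params$S0)),
                              as.integer(round(params$I0)), t_max)
  out <- tibble(time_days = as.numeric(times))
  attr(out, "truth") <- params
  attr(out, "seed") <- seed
  attr(out, "label") <- label
  class(out) <- c("event_stream", class(out))
  out
}

#' Genre configuration for the synthetic catalogue
#'
#' Describes the sampling distribution of one genre's song parameters.
#' Per-song parameters are drawn log-normally around the genre medians:
#' `R0 = median_R0 * exp(sdlog_R0 * z)` and likewise for the infectious
#' period and `S0`; the transmission rate is then
#' `beta = R0 / infectious_period`. With all spreads zero every song takes
#' exactly the median parameters.
#'
#' @param name Genre label.
#' @param n_songs Number of songs to generate (>= 1).
#' @param median_R0 Median basic reproduction number (> 0).
#' @param median_infectious_period Median mean infectious period
#'   \eqn{1/\gamma} (days, > 0).
#' @param median_S0 Median initially susceptible population (> 0).
#' @param sdlog_R0,sdlog_infectious_period,sdlog_S0 Log-scale standard
#'   deviations of the per-song draws.
#' @param I0 Initially infectious seed count (positive integer).
#' @return A `genre_config` list.
#' @examples
#' genre_config("Pop", 10, median_R0 = 35.03,
#'              median_infectious_period = 20.62, median_S0 = 5592)
#' @export
genre_config <- function(name, n_songs, median_R0, median_infectious_period,
                         median_S0, sdlog_R0 = 0.5,
                         sdlog_infectious_period = 0.5, sdlog_S0 = 0.25,
                         I0 = 1) {
  if (!is.character(name) || length(name) != 1L) {
    abort("`name` must be a single string.", class = "popsir_invalid_input")
  }
  if (n_songs < 1 || n_songs != round(n_songs)) {
    abort("`n_songs` must be a positive integer.",
          class = "popsir_invalid_input")
  }
  if (median_R0 <= 0 || median_infectious_period <= 0 || median_S0 <= 0) {
    abort("Genre medians must be positive.", class = "popsir_invalid_input")
  }
  if (I0 < 1 || I0 != round(I0)) {
    abort("`I0` must be a positive integer.", class = "popsir_invalid_input")
  }
  structure(
    list(name = name, n_songs = as.integer(n_songs), median_R0 = median_R0,
         median_infectious_period = median_infectious_period,
         median_S0 = median_S0, sdlog_R0 = sdlog_R0,
         sdlog_infectious_period = sdlog_infectious_period,
         sdlog_S0 = sdlog_S0, I0 = as.integer(I0)),
    class = "genre_config"
  )
}

#' Default genre configurations
#'
#' A catalogue blueprint anchored to the genre-level medians of the study
#' conditions this package emulates: eleven genres whose median basic
#' reproduction number, mean infectious period and susceptible-pool size
#' match the published genre tables (e.g. Electronica with R0 = 3430 and
#' infectious period 199 days versus Pop with R0 = 35 and 20.6 days), with
#' song counts proportional to the published per-genre sample sizes.
#' Fast-spreading genres (Electronica, Rock, with growth rates above
#' 10/day) are included so sub-daily aggregation is exercised downstream.
#'
#' @param songs_scale Multiplier on the per-genre song counts (default 1
#'   reproduces the published sample sizes, 828 songs in total); counts are
#'   rounded up so every genre keeps at least one song.
#' @param sdlog Common log-scale spread applied to R0 and the infectious
#'   period (S0 uses half this spread).
#' @return A list of [genre_config()] objects.
#' @export
default_genre_configs <- function(songs_scale = 1, sdlog = 0.5) {
  anchors <- tibble(
    name = c("Bollywood", "Country and Western", "Dance", "Electronica",
             "Indie/Alternative", "Metal", "Pop", "Rap/Hip Hop", "Reggae",
             "Rock", "Soul/R&B/Funk"),
    n_songs = c(1, 5, 106, 11, 68, 10, 336, 104, 4, 109, 74),
    median_R0 = c(25.01, 4.77, 2.84, 3430.01, 25.20, 3.65, 35.03, 310.94,
                  5.64, 129.33, 31.27),
    median_period = c(45.25, 33.60, 7.49, 199.10, 39.75, 9.08, 20.62, 93.25,
                      10.76, 16.04, 42.10),
    median_S0 = c(4237, 4048, 6363, 4737, 6706, 5161, 5592, 4526, 4147,
                  5182, 5946)
  )
  purrr::pmap(anchors, function(name, n_songs, median_R0, median_period,
                                median_S0) {
    genre_config(name, max(1L, ceiling(n_songs * songs_scale)),
                 median_R0 = median_R0,
                 median_infectious_period = median_period,
                 median_S0 = median_S0, sdlog_R0 = sdlog,
                 sdlog_infectious_period = sdlog, sdlog_S0 = sdlog / 2)
  })
}

#' Generate a synthetic song-download catalogue
#'
#' Draws per-song SIR parameters from each genre's distribution and
#' simulates a download event stream for every song with
#' [gillespie_sir()]. Child seeds are derived deterministically from
#' `seed`, so the whole catalogue is reproducible from the master seed
#' alone.
#'
#' @param configs A [genre_config()] or list of them.
#' @param seed Master integer seed.
#' @param t_max Simulation horizon per song (days).
#' @return A tibble with one row per song: `song_id`, `genre`, the true
#'   generating parameters (`beta`, `gamma`, `S0`, `I0`), `seed`,
#'   `n_events`, total `downloads` (= `n_events`) and a list-column
#'   `events` of event-time vectors.
#' @examples
#' cfg <- genre_config("Dance", 3, 2.84, 7.49, 500)
#' cat3 <- generate_catalog(cfg, seed = 1, t_max = 200)
#' cat3$n_events
#' @export
generate_catalog <- function(configs, seed = 1L, t_max = 365) {
  if (inherits(configs, "genre_config")) configs <- list(configs)
  if (length(configs) == 0) {
    abort("`configs` must contain at least one genre.",
          class = "popsir_invalid_input")
  }
  stopifnot(all(vapply(configs, inherits, logical(1), "genre_config")))
  set.seed(seed)
  rows <- purrr::map(configs, function(cf) {
    n <- cf$n_songs
    R0 <- cf$median_R0 * exp(rnorm(n, 0, cf$sdlog_R0))
    period <- cf$median_infectious_period *
      exp(rnorm(n, 0, cf$sdlog_infectious_period))
    S0 <- pmax(cf$I0 + 1, round(cf$median_S0 * exp(rnorm(n, 0, cf$sdlog_S0))))
    child_seed <- sample.int(.Machine$integer.max - 1L, n)
    tibble(genre = cf$name, R0_true = R0, gamma = 1 / period,
           beta = R0 / period, S0 = as.numeric(S0),
           I0 = as.numeric(cf$I0), seed = child_seed)
  })
  catalog <- dplyr::bind_rows(rows)
  catalog$song_id <- sprintf("song_%03d", seq_len(nrow(catalog)))
  catalog$events <- purrr::pmap(
    catalog[c("beta", "gamma", "S0", "I0", "seed")],
    function(beta, gamma, S0, I0, seed) {
      gillespie_sir(sir_params(beta, gamma, S0, I0), t_max = t_max,
                    seed = seed)$time_days
    }
  )
  catalog$n_events <- lengths(catalog$events)
  catalog$downloads <- catalog$n_events
  dplyr::relocate(catalog, "song_id", "genre")
}

#' Write a catalogue's event streams and truth table to disk
#'
#' Writes one long CSV of events (`song_id`, `time_days`) and a JSON
#' sidecar of generating parameters and seeds, the on-disk interchange
#' format for synthetic catalogues.
#'
#' @param catalog A tibble from [generate_catalog()].
#' @param events_path Path for the events CSV.
#' @param truth_path Path for the JSON truth sidecar.
#' @return Invisibly, the two paths.
#' @export
write_catalog <- function(catalog, events_path, truth_path) {
  events <- tidyr::unnest(
    dplyr::select(catalog, "song_id", "events"),
    "events"
  )
  names(events)[names(events) == "events"] <- "time_days"
  readr::write_csv(events, events_path)
  truth <- dplyr::select(catalog, -"events")
  jsonlite::write_json(truth, truth_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(events_path, truth_path))
}
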