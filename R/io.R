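#' Read observed series from CSV
#'
#' Expects columns `bin_start`, `bin_end`, `count` (days, days,
#' nonnegative counts), and optionally `series_id` and `genre` for batch
#' files holding several series. Malformed rows are rejected with their
#' line numbers; unordered or overlapping bins raise a parse error naming
#' the offending line.
#'
#' @param path CSV file path.
#' @return A single series tibble, or (when `series_id` is present with
#'   more than one value) a named list of series tibbles.
#' @export
read_series <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("bin_start", "bin_end", "count")
  if (!all(req %in% names(raw))) {
    abort(paste0("`", path, "` must have columns ",
                 paste(req, collapse = ", "), "."),
          class = "popsir_parse_error")
  }
  raw$.line <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad <- !is.finite(raw$bin_start) | !is.finite(raw$bin_end) |
    !is.finite(raw$count) | raw$count < 0 | raw$bin_end <= raw$bin_start
  if (any(bad)) {
    abort(paste0("Malformed rows in `", path, "` at line(s) ",
                 paste(raw$.line[bad], collapse = ", "),
                 " (negative count, missing value, or bin_end <= bin_start)."),
          class = "popsir_parse_error")
  }
  check_one <- function(d) {
    d <- d[order(d$bin_start), ]
    if (nrow(d) > 1) {
      overlap <- which(d$bin_start[-1] < d$bin_end[-nrow(d)] - 1e-12)
      if (length(overlap)) {
        abort(paste0("Overlapping or unordered bins in `", path,
                     "` near line ", d$.line[overlap[1] + 1], "."),
              class = "popsir_parse_error")
      }
    }
    d$.line <- NULL
    as_tibble(d)
  }
  if ("series_id" %in% names(raw) && length(unique(raw$series_id)) > 1) {
    out <- lapply(split(raw, raw$series_id), check_one)
    return(out)
  }
  check_one(raw)
}

#' Write an observed series to CSV
#'
#' @param series A series tibble (`bin_start`, `bin_end`, `count`, plus
#'   any metadata columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path) {
  .validate_series(series)
  readr::write_csv(series, path)
  invisible(path)
}

#' Write a report to CSV or JSON
#'
#' Serializes a [comparison_report()], genre summary, or any tibble with
#' deterministic field ordering and numbers at 6 significant digits, so
#' repeated runs diff cleanly. Comparison reports are written as their
#' per-series rows (CSV) or rows plus summary (JSON).
#'
#' @param report A `comparison_report`, `calibration_comparison`, or data
#'   frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  round6 <- function(d) {
    dplyr::mutate(d, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  }
  if (inherits(report, "calibration_comparison")) {
    payload <- list(summary = round6(glance(report)),
                    rows = purrr::map(
                      purrr::compact(list(catalog = report$catalog,
                                          simulations = report$simulations)),
                      ~ round6(tidy(.x))
                    ))
    if (format == "csv") {
      readr::write_csv(payload$summary, path)
    } else {
      jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE, na = "null")
    }
    return(invisible(path))
  }
  d <- if (inherits(report, "comparison_report")) tidy(report) else
    as_tibble(report)
  d <- round6(d)
  if (format == "csv") {
    readr::write_csv(d, path, na = "")
  } else {
    jsonlite::write_json(d, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Run configuration
#'
#' Bundles everything a pipeline run depends on — master seed, inclusion
#' criteria, fitting settings, ensemble, and measure conventions — so a
#' run is reproducible from the configuration alone. [config_digest()]
#' hashes the canonical JSON serialization; two runs with equal digests
#' produce identical outputs.
#'
#' @param master_seed Integer master seed.
#' @param criteria An [inclusion_criteria()].
#' @param sim_config A [sim_ensemble()].
#' @param n_starts Multistart budget per SIR fit.
#' @param zero_policy,take_sqrt Fit-measure conventions (see
#'   [relative_fit_measure()]).
#' @param paths Named list of input/output locations.
#' @return A `run_config` list.
#' @export
run_config <- function(master_seed = 1L, criteria = inclusion_criteria(),
                       sim_config = sim_ensemble(), n_starts = 100,
                       zero_policy = "exclude", take_sqrt = TRUE,
                       paths = list()) {
  structure(
    list(master_seed = as.integer(master_seed),
         criteria = unclass(criteria), sim_config = unclass(sim_config),
         n_starts = n_starts, zero_policy = zero_policy,
         take_sqrt = take_sqrt, paths = paths),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
config_digest <- function(config) {
  digest::digest(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  digits = NA),
                 algo = "sha256")
}

#' @rdname run_config
#' @param path File path for JSON (de)serialization.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    master_seed = raw$master_seed,
    criteria = inclusion_criteria(raw$criteria$max_fit_measure,
                                  raw$criteria$r_min),
    sim_config = sim_ensemble(
      R0_range = raw$sim_config$R0_range,
      infectious_period_range = raw$sim_config$infectious_period_range,
      S0_range = raw$sim_config$S0_range,
      I0 = raw$sim_config$I0, t_max = raw$sim_config$t_max
    ),
    n_starts = raw$n_starts, zero_policy = raw$zero_policy,
    take_sqrt = raw$take_sqrt, paths = raw$paths
  )
}
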