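#' Modified Weir equation (no urinary nitrogen correction)
#'
#' Converts oxygen consumption and carbon dioxide production into a daily
#' resting energy expenditure using the abbreviated Weir form,
#' `1440 * (3.941 * VO2 + 1.106 * VCO2)`. The coefficients are read from the
#' versioned constants file bundled with the package, not hard-coded.
#'
#' @param vo2 oxygen consumption, L/min (vectorized)
#' @param vco2 carbon dioxide production, L/min (vectorized)
#' @param constants named constant vector as returned by
#'   [ree_constants()]; defaults to the bundled registry constants
#' @return REE in kcal/day
#' @examples
#' weir_ree(0.09, 0.07)  # ~622 kcal/day
#' @export
weir_ree <- function(vo2, vco2, constants = ree_constants()) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE))
    abort_domain("weir_ree: gas values must be non-negative")
  constants[["minutes_per_day"]] *
    (constants[["weir_vo2_kcal_per_l"]] * vo2 +
     constants[["weir_vco2_kcal_per_l"]] * vco2)
}

#' Respiratory quotient
#'
#' @param vco2 carbon dioxide production, L/min
#' @param vo2 oxygen consumption, L/min; must be positive
#' @return VCO2/VO2, dimensionless
#' @export
respiratory_quotient <- function(vco2, vo2) {
  if (any(vo2 <= 0, na.rm = TRUE))
    abort_domain("respiratory_quotient: vo2 must be positive")
  vco2 / vo2
}

#' Relative variation of a signal over a window
#'
#' The steady-state criterion bounds the "variation" of each channel over a
#' candidate window. The default statistic is range/mean; the coefficient of
#' variation (SD/mean) is available as an alternative.
#'
#' @param values numeric window
#' @param method `"range"` (max-min)/mean or `"cv"` sd/mean
#' @return variation as a proportion
#' @export
window_variation <- function(values, method = c("range", "cv")) {
  method <- match.arg(method)
  if (length(values) == 0) abort_domain("window_variation: empty window")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    abort_domain("window_variation: nonpositive window mean")
  if (method == "range") (max(values) - min(values)) / m else sd(values) / m
}

#' Construct a calorimetry series
#'
#' A minute-resolution indirect-calorimetry measurement: VO2, VCO2 and minute
#' ventilation sampled once per minute over (typically) 30 minutes.
#'
#' @param vo2,vco2,minute_ventilation per-minute gas channels, L/min
#' @return a `calorimetry_series` data.frame with a `minute` index from 0
#' @export
calorimetry_series <- function(vo2, vco2, minute_ventilation) {
  n <- length(vo2)
  if (length(vco2) != n || length(minute_ventilation) != n)
    abort_data("calorimetry_series: channels must have equal length")
  if (any(c(vo2, vco2, minute_ventilation) <= 0))
    abort_data("calorimetry_series: all gas values must be positive")
  structure(
    data.frame(minute = seq_len(n) - 1L, vo2 = vo2, vco2 = vco2,
               minute_ventilation = minute_ventilation),
    class = c("calorimetry_series", "data.frame"))
}

#' Read a breath-series CSV
#'
#' Expects columns `minute, vo2_l_min, vco2_l_min, minute_ventilation_l_min`
#' (the export format of [write_breath_series()]).
#'
#' @param path CSV file
#' @return a [calorimetry_series()]
#' @export
read_breath_series <- function(path) {
  d <- read.csv(path)
  need <- c("minute", "vo2_l_min", "vco2_l_min", "minute_ventilation_l_min")
  if (!all(need %in% names(d)))
    abort_data("breath-series CSV must have columns: %s",
               paste(need, collapse = ", "))
  d <- d[order(d$minute), ]
  calorimetry_series(d$vo2_l_min, d$vco2_l_min, d$minute_ventilation_l_min)
}

#' Write a breath-series CSV
#' @param series a [calorimetry_series()]
#' @param path output file
#' @export
write_breath_series <- function(series, path) {
  out <- data.frame(minute = series$minute,
                    vo2_l_min = series$vo2,
                    vco2_l_min = series$vco2,
                    minute_ventilation_l_min = series$minute_ventilation)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Find the steady-state window of a calorimetry series
#'
#' Scans every contiguous window of at least `min_len` minutes and keeps those
#' where the per-minute RQ varies by less than `rq_tol` and VO2, VCO2 and
#' minute ventilation each vary by less than `gas_tol` (variation per
#' [window_variation()]). Returns the longest qualifying window, the earliest
#' start breaking ties, or `NULL` when none qualifies.
#'
#' @param series a [calorimetry_series()]
#' @param min_len minimum window length in minutes (default 5)
#' @param rq_tol RQ variation bound (default 0.05)
#' @param gas_tol gas/ventilation variation bound (default 0.10)
#' @param method variation statistic, see [window_variation()]
#' @return a `steady_state_window` list (`start`, `end`, `mean_vo2`,
#'   `mean_vco2`, `rq`, `ree`) or `NULL`
#' @export
find_steady_state <- function(series, min_len = 5L, rq_tol = 0.05,
                              gas_tol = 0.10, method = c("range", "cv")) {
  method <- match.arg(method)
  t_len <- nrow(series)
  if (t_len < min_len) return(NULL)
  rq_series <- series$vco2 / series$vo2
  best <- NULL
  for (len in seq(t_len, min_len)) {
    for (start in seq_len(t_len - len + 1L)) {
      idx <- start:(start + len - 1L)
      ok <- window_variation(rq_series[idx], method) < rq_tol &&
        window_variation(series$vo2[idx], method) < gas_tol &&
        window_variation(series$vco2[idx], method) < gas_tol &&
        window_variation(series$minute_ventilation[idx], method) < gas_tol
      if (ok) { best <- c(start, len); break }
    }
    if (!is.null(best)) break  # windows scanned longest-first
  }
  if (is.null(best)) return(NULL)
  idx <- best[1]:(best[1] + best[2] - 1L)
  mean_vo2 <- mean(series$vo2[idx])
  mean_vco2 <- mean(series$vco2[idx])
  structure(list(
    start = series$minute[best[1]],
    end = series$minute[best[1] + best[2] - 1L],
    mean_vo2 = mean_vo2, mean_vco2 = mean_vco2,
    rq = mean_vco2 / mean_vo2,
    ree = weir_ree(mean_vo2, mean_vco2)
  ), class = "steady_state_window")
}

#' Summarize a calorimetry measurement into a validated gas record
#'
#' Applies the steady-state search and the RQ plausibility filter: a
#' measurement is valid only if a steady-state window exists and its RQ lies
#' in `rq_bounds` (bounds inclusive — only values strictly outside are
#' excluded).
#'
#' @inheritParams find_steady_state
#' @param rq_bounds physiologic RQ range, default `c(0.67, 1.3)`
#' @return a `gas_summary` list: `vo2`, `vco2`, `rq`, `ree`, `valid`,
#'   `exclusion_reason` (one of `none`, `no_steady_state`, `rq_out_of_range`)
#' @export
summarize_measurement <- function(series, rq_bounds = c(0.67, 1.3),
                                  min_len = 5L, rq_tol = 0.05,
                                  gas_tol = 0.10, method = c("range", "cv")) {
  method <- match.arg(method)
  win <- find_steady_state(series, min_len, rq_tol, gas_tol, method)
  if (is.null(win)) {
    return(structure(list(vo2 = NA_real_, vco2 = NA_real_, rq = NA_real_,
                          ree = NA_real_, valid = FALSE,
                          exclusion_reason = "no_steady_state",
                          window = NULL),
                     class = "gas_summary"))
  }
  reason <- if (win$rq < rq_bounds[1] || win$rq > rq_bounds[2])
    "rq_out_of_range" else "none"
  structure(list(vo2 = win$mean_vo2, vco2 = win$mean_vco2, rq = win$rq,
                 ree = win$ree, valid = reason == "none",
                 exclusion_reason = reason, window = win),
            class = "gas_summary")
}
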