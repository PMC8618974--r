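#' LMS z-score
#'
#' Growth-reference z-score under the Box-Cox (LMS) parameterization:
#' `((x/M)^L - 1)/(L*S)` for `L != 0` and `log(x/M)/S` for `L == 0`.
#'
#' @param x measurement (same units as `M`), positive
#' @param L Box-Cox power (dimensionless)
#' @param M reference median, positive
#' @param S reference coefficient of variation, positive
#' @return z-score
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0))
    abort_domain("lms_zscore: x, M, S must be positive")
  n <- max(length(x), length(L), length(M), length(S))
  L <- rep_len(L, n); boxcox <- abs(L) >= 1e-12
  out <- rep_len(log(x / M) / S, n)
  if (any(boxcox)) {
    full <- ((rep_len(x, n) / rep_len(M, n))^L - 1) / (L * rep_len(S, n))
    out[boxcox] <- full[boxcox]
  }
  out
}

#' Inverse of the LMS transform: measurement from z-score
#' @inheritParams lms_zscore
#' @param z z-score
#' @return measurement in the units of `M`
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0))
    abort_domain("lms_inverse: M, S must be positive")
  n <- max(length(z), length(L), length(M), length(S))
  L <- rep_len(L, n); boxcox <- abs(L) >= 1e-12
  out <- rep_len(M * exp(S * z), n)
  if (any(boxcox)) {
    full <- rep_len(M, n) *
      (1 + L * rep_len(S, n) * rep_len(z, n))^(1 / L)
    out[boxcox] <- full[boxcox]
  }
  out
}

#' Load a growth reference table
#'
#' The CSV schema is `metric, sex, grid_value, L, M, S`; the grid is age in
#' months except for `weight_for_length_height`, whose grid is length/height
#' in cm. The bundled table is a synthetic reference (smooth plausible
#' pediatric curves, labelled as such in its filename); real WHO tables in
#' the same schema can be dropped in.
#'
#' @param path CSV path; default the bundled synthetic reference
#' @return a `growth_reference` data.frame
#' @export
load_growth_reference <- function(path = picuree_extdata("lms_reference_synthetic.csv")) {
  ref <- read.csv(path)
  need <- c("metric", "sex", "grid_value", "L", "M", "S")
  if (!all(need %in% names(ref)))
    abort_config("growth reference CSV must have columns: %s",
                 paste(need, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0))
    abort_config("growth reference: M and S must be positive")
  structure(ref, class = c("growth_reference", "data.frame"))
}

#' Interpolate LMS parameters at an abscissa
#'
#' Piecewise-linear interpolation of L, M and S independently; exact at grid
#' points. Outside the reference grid the parameters are unavailable (this is
#' how age-limited references produce missing z-scores downstream).
#'
#' @param ref a [load_growth_reference()] table
#' @param metric one of `weight_for_age`, `height_for_age`,
#'   `weight_for_length_height`, `bmi_for_age`
#' @param sex `"male"` or `"female"`
#' @param at age in months, or length/height in cm for
#'   `weight_for_length_height`
#' @return named list `L`, `M`, `S`
#' @export
interpolate_lms <- function(ref, metric, sex, at) {
  sub <- ref[ref$metric == metric & ref$sex == sex, ]
  if (nrow(sub) == 0)
    abort_config("growth reference has no entries for %s/%s", metric, sex)
  sub <- sub[order(sub$grid_value), ]
  if (at < min(sub$grid_value) || at > max(sub$grid_value))
    stop(errorCondition(
      sprintf("%s/%s reference unavailable at %.2f", metric, sex, at),
      class = c("picuree_availability_error", "picuree_error")))
  list(L = approx(sub$grid_value, sub$L, at)$y,
       M = approx(sub$grid_value, sub$M, at)$y,
       S = approx(sub$grid_value, sub$S, at)$y)
}

zscore_or_na <- function(ref, metric, sex, at, x) {
  tryCatch({
    p <- interpolate_lms(ref, metric, sex, at)
    list(z = lms_zscore(x, p$L, p$M, p$S), reason = "available")
  }, picuree_availability_error = function(e)
    list(z = NA_real_, reason = "reference_out_of_range"))
}

#' Compute the four growth z-scores for one child
#'
#' Weight-for-age is computed only up to 10 years and weight-for-length/height
#' only up to 5 years (the availability limits of the WHO charts, which is why
#' those two z-scores carry structured missingness in cohorts spanning older
#' ages); height-for-age and BMI-for-age are always attempted.
#'
#' @param age years
#' @param sex `"male"` or `"female"`
#' @param weight kg
#' @param height cm
#' @param ref growth reference, default the bundled synthetic table
#' @return a `zscore_set` list: `z_wfa`, `z_hfa`, `z_wfh`, `z_bmi` and an
#'   `availability` character vector of reasons
#' @export
compute_zscores <- function(age, sex, weight, height,
                            ref = load_growth_reference()) {
  months <- age * 12
  z <- list(z_wfa = NA_real_, z_hfa = NA_real_, z_wfh = NA_real_,
            z_bmi = NA_real_)
  avail <- c(z_wfa = "age_over_10y", z_hfa = "available",
             z_wfh = "age_over_5y", z_bmi = "available")
  if (age <= 10) {
    r <- zscore_or_na(ref, "weight_for_age", sex, months, weight)
    z$z_wfa <- r$z; avail["z_wfa"] <- r$reason
  }
  r <- zscore_or_na(ref, "height_for_age", sex, months, height)
  z$z_hfa <- r$z; avail["z_hfa"] <- r$reason
  if (age <= 5) {
    r <- zscore_or_na(ref, "weight_for_length_height", sex, height, weight)
    z$z_wfh <- r$z; avail["z_wfh"] <- r$reason
  }
  r <- zscore_or_na(ref, "bmi_for_age", sex, months, bmi(weight, height))
  z$z_bmi <- r$z; avail["z_bmi"] <- r$reason
  structure(c(z, list(availability = avail)), class = "zscore_set")
}

#' Body mass index
#' @param weight kg
#' @param height cm
#' @return kg/m^2
#' @export
bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    abort_domain("bmi: weight and height must be positive")
  weight / (height / 100)^2
}

#' Classify nutritional status from growth z-scores
#'
#' WHO-style rules: stunting is height-for-age z < -2. For children under 5
#' years the weight-for-length/height z-score grades wasting (< -1 mild,
#' < -2 moderate, < -3 severe; strict inequalities) and defines overweight
#' (z > 2) and obesity (z > 3). From the 5th birthday the BMI-for-age z-score
#' is used instead, with overweight z > 1 and obesity z > 2. Obesity takes
#' precedence over overweight.
#'
#' @param age years
#' @param z a [compute_zscores()] result (or list with the same fields)
#' @return a `nutritional_status` list: `stunting` (logical), `wasting`
#'   (`none`/`mild`/`moderate`/`severe`), `weight_class`
#'   (`normal`/`overweight`/`obese`); fields are `NA` when the required
#'   z-score is missing
#' @export
classify_status <- function(age, z) {
  stunting <- if (is.na(z$z_hfa)) NA else z$z_hfa < -2
  zkey <- if (age < 5) z$z_wfh else z$z_bmi
  if (is.na(zkey)) {
    wasting <- NA_character_; weight_class <- NA_character_
  } else {
    wasting <- if (zkey < -3) "severe" else if (zkey < -2) "moderate"
      else if (zkey < -1) "mild" else "none"
    ow_cut <- if (age < 5) 2 else 1
    ob_cut <- if (age < 5) 3 else 2
    weight_class <- if (zkey > ob_cut) "obese"
      else if (zkey > ow_cut) "overweight" else "normal"
  }
  structure(list(stunting = stunting, wasting = wasting,
                 weight_class = weight_class),
            class = "nutritional_status")
}
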