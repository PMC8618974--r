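#' Specification of a synthetic PICU cohort
#'
#' Defines the generative model for a pediatric-intensive-care cohort with
#' known ground truth. The defaults are calibrated once so the generated
#' marginal moments match a published reference cohort of 257 critically ill
#' children (56.4% male, median age 2.4 y, mean weight 15.6 kg, mean VO2
#' 0.09 L/min, mean RQ 0.77, ~40% ventilated); see the methods vignette for
#' the calibration and for what the generator deliberately does not emulate.
#'
#' @param n cohort size
#' @param seed RNG seed (integer)
#' @param male_fraction probability of male sex
#' @param ethnicity_probs probabilities for
#'   caucasian/asian/south_american/african; must sum to 1
#' @param age_dist log-normal age model (years): `meanlog`, `sdlog`, and
#'   truncation `min`, `max`
#' @param anthro_model z-score draws feeding the LMS growth curves:
#'   `z_weight_mean/sd`, `z_height_mean/sd`, `z_corr` (weight-height z
#'   correlation), `z_trunc` (symmetric truncation)
#' @param ventilated_fraction probability of mechanical ventilation
#' @param gas_model allometric VO2 model: `allometric_coefficient` (L/min per
#'   kg^exponent), `allometric_exponent`, `vo2_noise_cv`, and the truncated
#'   normal RQ model `rq_mean` (pre-truncation location), `rq_sd`,
#'   `rq_bounds`
#' @param vitals_labs per-variable `c(mean, sd)` (units: bpm, mmHg, degC, %,
#'   g/dL, mg/dL); `crp` is `c(meanlog, sdlog)` of a log-normal (mg/dL)
#' @param missingness_rates default per-variable MCAR rates for
#'   [inject_missingness()]
#' @param ree_mechanism `"weir_exact"` (true REE is the Weir value of the
#'   generated gases) or `"covariate_driven"` (linear in weight, sex and
#'   body temperature, see `covariate_model`)
#' @param covariate_model coefficients of the covariate-driven mechanism:
#'   `intercept`, `weight` (kcal/day/kg), `male` (kcal/day), `temp`
#'   (kcal/day/degC above `temp_ref`), `noise_sd`
#' @param breath_model minute-series generator: within-window noise
#'   (`noise_vo2`, `noise_rq`, `noise_ve`, half-widths of uniform
#'   multiplicative noise), `drift_per_min` (compounded VO2 drift outside the
#'   steady window), `duration` minutes, `window` default steady window
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n = 257,
                        seed = 1L,
                        male_fraction = 0.564,
                        ethnicity_probs = c(caucasian = 0.80, asian = 0.08,
                                            south_american = 0.08, african = 0.04),
                        age_dist = list(meanlog = log(2.9), sdlog = 1.4,
                                        min = 0.1, max = 17.5),
                        anthro_model = list(z_weight_mean = -0.9, z_weight_sd = 1.4,
                                            z_height_mean = -1.2, z_height_sd = 1.6,
                                            z_corr = 0.7, z_trunc = 3.5),
                        ventilated_fraction = 0.395,
                        gas_model = list(allometric_coefficient = 0.01215,
                                         allometric_exponent = 0.75,
                                         vo2_noise_cv = 0.18,
                                         rq_mean = 0.6814, rq_sd = 0.12,
                                         rq_bounds = c(0.67, 1.3)),
                        vitals_labs = list(heart_rate = c(117.6, 30.3),
                                           sbp = c(103.5, 18.3),
                                           dbp = c(61.0, 14.9),
                                           body_temperature = c(36.6, 0.7),
                                           sat_o2 = c(97.7, 2.7),
                                           hemoglobin = c(9.9, 1.8),
                                           blood_glucose = c(106.4, 37.3),
                                           crp = c(log(2.3), 1.7)),
                        missingness_rates = c(heart_rate = 0.05, sbp = 0.06,
                                              dbp = 0.06, body_temperature = 0.05,
                                              sat_o2 = 0.04, hemoglobin = 0.10,
                                              blood_glucose = 0.08, crp = 0.12),
                        ree_mechanism = c("weir_exact", "covariate_driven"),
                        covariate_model = list(intercept = 0, weight = 55,
                                               male = 40, temp = 35,
                                               temp_ref = 36.6, noise_sd = 50),
                        breath_model = list(noise_vo2 = 0.01, noise_vco2 = 0.01,
                                            noise_ve = 0.02, drift_per_min = 0.06,
                                            duration = 30L, window = c(8L, 22L))) {
  spec <- list(n = n, seed = seed, male_fraction = male_fraction,
               ethnicity_probs = ethnicity_probs, age_dist = age_dist,
               anthro_model = anthro_model,
               ventilated_fraction = ventilated_fraction,
               gas_model = gas_model, vitals_labs = vitals_labs,
               missingness_rates = missingness_rates,
               ree_mechanism = match.arg(ree_mechanism),
               covariate_model = covariate_model, breath_model = breath_model)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  chk_prop <- function(x, nm) {
    if (any(x < 0) || any(x > 1)) abort_config("cohort spec: %s must be in [0, 1]", nm)
  }
  if (spec$n < 0 || spec$n != round(spec$n))
    abort_config("cohort spec: n must be a non-negative integer")
  chk_prop(spec$male_fraction, "male_fraction")
  chk_prop(spec$ventilated_fraction, "ventilated_fraction")
  chk_prop(spec$ethnicity_probs, "ethnicity_probs")
  if (abs(sum(spec$ethnicity_probs) - 1) > 1e-9)
    abort_config("cohort spec: ethnicity_probs must sum to 1")
  chk_prop(spec$gas_model$vo2_noise_cv, "gas_model$vo2_noise_cv")
  b <- spec$gas_model$rq_bounds
  if (length(b) != 2 || b[1] >= b[2])
    abort_config("cohort spec: gas_model$rq_bounds must satisfy low < high")
  chk_prop(spec$missingness_rates, "missingness_rates")
  invisible(spec)
}

# inverse-CDF truncated-normal draw (fixed number of uniforms: keeps the
# generator's RNG stream aligned regardless of bounds)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic PICU cohort
#'
#' Draws sex, ethnicity and ventilation status from the spec's probabilities;
#' age from a truncated log-normal; weight and height from the bundled LMS
#' growth curves at correlated per-child z draws; VO2 allometrically from
#' weight; RQ from a truncated normal; VCO2 as `RQ * VO2`. Growth z-scores
#' and nutritional-status classes are then recomputed from the generated
#' measurements exactly as they would be for real data. The true REE is
#' either the Weir value of the gases (`weir_exact`) or a documented linear
#' function of weight, sex and temperature (`covariate_driven`).
#'
#' @param spec a [cohort_spec()]
#' @param growth_ref growth reference for z-scores (default bundled table)
#' @return data.frame, one row per patient, with the full snake_case variable
#'   dictionary plus ground-truth columns `true_ree`, `steady_start`,
#'   `steady_end`; deterministic for a fixed spec
#' @export
generate_cohort <- function(spec, growth_ref = load_growth_reference()) {
  validate_cohort_spec(spec)
  n <- spec$n
  empty <- cohort_skeleton(0L)
  if (n == 0) return(empty)
  with_seed(spec$seed, {
    male <- as.integer(runif(n) < spec$male_fraction)
    eth <- sample(names(spec$ethnicity_probs), n, replace = TRUE,
                  prob = spec$ethnicity_probs)
    vent <- as.integer(runif(n) < spec$ventilated_fraction)
    ad <- spec$age_dist
    age <- exp(rtruncnorm(n, ad$meanlog, ad$sdlog, log(ad$min), log(ad$max)))

    am <- spec$anthro_model
    zt <- am$z_trunc
    zw <- rtruncnorm(n, am$z_weight_mean, am$z_weight_sd, -zt, zt)
    # correlated height z: conditional normal around the weight z
    zh_mean <- am$z_height_mean +
      am$z_corr * am$z_height_sd / am$z_weight_sd * (zw - am$z_weight_mean)
    zh_sd <- am$z_height_sd * sqrt(1 - am$z_corr^2)
    zh <- rtruncnorm(n, zh_mean, zh_sd, -zt, zt)

    months <- age * 12
    sex_chr <- ifelse(male == 1, "male", "female")
    weight <- height <- numeric(n)
    for (sx in c("male", "female")) {
      i <- which(sex_chr == sx)
      if (!length(i)) next
      wref <- growth_ref[growth_ref$metric == "weight_for_age" &
                           growth_ref$sex == sx, ]
      href <- growth_ref[growth_ref$metric == "height_for_age" &
                           growth_ref$sex == sx, ]
      wL <- approx(wref$grid_value, wref$L, months[i])$y
      wM <- approx(wref$grid_value, wref$M, months[i])$y
      wS <- approx(wref$grid_value, wref$S, months[i])$y
      hL <- approx(href$grid_value, href$L, months[i])$y
      hM <- approx(href$grid_value, href$M, months[i])$y
      hS <- approx(href$grid_value, href$S, months[i])$y
      weight[i] <- lms_inverse(zw[i], wL, wM, wS)
      height[i] <- lms_inverse(zh[i], hL, hM, hS)
    }

    gm <- spec$gas_model
    vo2 <- gm$allometric_coefficient * weight^gm$allometric_exponent *
      (1 + rnorm(n, 0, gm$vo2_noise_cv))
    vo2 <- pmax(vo2, 0.005)
    rq <- rtruncnorm(n, gm$rq_mean, gm$rq_sd,
                     gm$rq_bounds[1], gm$rq_bounds[2])
    vco2 <- rq * vo2

    vl <- spec$vitals_labs
    vitals <- list(
      heart_rate = rnorm(n, vl$heart_rate[1], vl$heart_rate[2]),
      sbp = rnorm(n, vl$sbp[1], vl$sbp[2]),
      dbp = rnorm(n, vl$dbp[1], vl$dbp[2]),
      body_temperature = rnorm(n, vl$body_temperature[1], vl$body_temperature[2]),
      sat_o2 = pmin(rnorm(n, vl$sat_o2[1], vl$sat_o2[2]), 100),
      hemoglobin = rnorm(n, vl$hemoglobin[1], vl$hemoglobin[2]),
      blood_glucose = rnorm(n, vl$blood_glucose[1], vl$blood_glucose[2]),
      crp = exp(rnorm(n, vl$crp[1], vl$crp[2]))
    )

    true_ree <- if (spec$ree_mechanism == "weir_exact") {
      weir_ree(vo2, vco2)
    } else {
      cm <- spec$covariate_model
      cm$intercept + cm$weight * weight + cm$male * male +
        cm$temp * (vitals$body_temperature - cm$temp_ref) +
        rnorm(n, 0, cm$noise_sd)
    }

    z <- lapply(seq_len(n), function(i)
      compute_zscores(age[i], sex_chr[i], weight[i], height[i], growth_ref))
    status <- lapply(seq_len(n), function(i) classify_status(age[i], z[[i]]))
    wasting <- vapply(status, function(s)
      if (is.na(s$wasting)) "none" else s$wasting, character(1))
    wclass <- vapply(status, function(s)
      if (is.na(s$weight_class)) "normal" else s$weight_class, character(1))
    stunt <- vapply(status, function(s)
      if (is.na(s$stunting)) 0L else as.integer(s$stunting), integer(1))

    win <- spec$breath_model$window
    data.frame(
      id = seq_len(n),
      male = male, female = 1L - male,
      caucasian = as.integer(eth == "caucasian"),
      asian = as.integer(eth == "asian"),
      south_american = as.integer(eth == "south_american"),
      african = as.integer(eth == "african"),
      mechanically_ventilated = vent,
      age = age, weight = weight, height = height,
      bmi = bmi(weight, height),
      z_bmi = vapply(z, function(x) x$z_bmi, numeric(1)),
      z_hfa = vapply(z, function(x) x$z_hfa, numeric(1)),
      z_wfa = vapply(z, function(x) x$z_wfa, numeric(1)),
      z_wfh = vapply(z, function(x) x$z_wfh, numeric(1)),
      normal_weight = as.integer(wclass == "normal"),
      overweight = as.integer(wclass == "overweight"),
      obese = as.integer(wclass == "obese"),
      stunting = stunt,
      wasting_none = as.integer(wasting == "none"),
      wasting_mild = as.integer(wasting == "mild"),
      wasting_moderate = as.integer(wasting == "moderate"),
      wasting_severe = as.integer(wasting == "severe"),
      vo2 = vo2, vco2 = vco2, rq = rq,
      heart_rate = vitals$heart_rate, sbp = vitals$sbp, dbp = vitals$dbp,
      body_temperature = vitals$body_temperature, sat_o2 = vitals$sat_o2,
      hemoglobin = vitals$hemoglobin, blood_glucose = vitals$blood_glucose,
      crp = vitals$crp,
      measured_ree = true_ree,
      true_ree = true_ree,
      steady_start = rep(win[1], n), steady_end = rep(win[2], n)
    )
  })
}

cohort_skeleton <- function(n) {
  cols <- c("id", "male", "female", "caucasian", "asian", "south_american",
            "african", "mechanically_ventilated", "age", "weight", "height",
            "bmi", "z_bmi", "z_hfa", "z_wfa", "z_wfh", "normal_weight",
            "overweight", "obese", "stunting", "wasting_none", "wasting_mild",
            "wasting_moderate", "wasting_severe", "vo2", "vco2", "rq",
            "heart_rate", "sbp", "dbp", "body_temperature", "sat_o2",
            "hemoglobin", "blood_glucose", "crp", "measured_ree", "true_ree",
            "steady_start", "steady_end")
  as.data.frame(setNames(lapply(cols, function(x) numeric(n)), cols))
}

#' Generate a minute-resolution breath series for one synthetic patient
#'
#' Produces a 30-minute series whose values inside the patient's true steady
#' window stay within the steady-state variation bounds (small uniform
#' multiplicative noise), while VO2 drifts multiplicatively outside the
#' window so that any window including off-steady minutes violates at least
#' the RQ criterion (VCO2 does not drift, so RQ moves with the drift).
#'
#' @param patient one row of a [generate_cohort()] data.frame
#' @param spec the [cohort_spec()] that produced the cohort
#' @param seed optional seed; defaults to a child seed of `spec$seed` and the
#'   patient id
#' @return a [calorimetry_series()]
#' @export
generate_breath_series <- function(patient, spec, seed = NULL) {
  bm <- spec$breath_model
  if (is.null(seed)) seed <- child_seed(spec$seed, patient$id)
  dur <- bm$duration
  w0 <- patient$steady_start; w1 <- patient$steady_end
  with_seed(seed, {
    minutes <- seq_len(dur) - 1L
    dist_out <- pmax(0, pmax(w0 - minutes, minutes - w1))
    drift <- (1 + bm$drift_per_min)^dist_out
    u <- function(half) if (half == 0) rep(1, dur) else
      1 + runif(dur, -half, half)
    # within the window: +/-1% noise keeps RQ variation < ~4% and each gas
    # channel < ~2%; the compounded VO2-only drift outside moves RQ by >= ~6%
    # for any window touching an off-steady minute
    vo2 <- patient$vo2 * drift * u(bm$noise_vo2)
    vco2 <- patient$rq * patient$vo2 * u(bm$noise_vco2)
    ve <- patient$vo2 * 25 * u(bm$noise_ve)
    calorimetry_series(vo2, vco2, ve)
  })
}

#' Inject MCAR missingness into a cohort
#'
#' Each targeted cell is set missing independently with its variable's rate.
#' Gas-exchange and core anthropometric/demographic fields are protected:
#' the reference cohort had complete data there, so targeting them is a
#' configuration error.
#'
#' @param cohort a cohort data.frame
#' @param rates named vector of per-variable missingness rates in `[0, 1]`;
#'   defaults to the spec defaults of [cohort_spec()]
#' @param seed RNG seed
#' @return the cohort with `NA`s injected; deterministic per seed
#' @export
inject_missingness <- function(cohort, rates = cohort_spec()$missingness_rates,
                               seed = 1L) {
  if (any(rates < 0) || any(rates > 1))
    abort_config("inject_missingness: rates must be in [0, 1]")
  protected <- c("id", "male", "female", "caucasian", "asian",
                 "south_american", "african", "mechanically_ventilated",
                 "age", "weight", "height", "bmi", "vo2", "vco2", "rq",
                 "measured_ree", "true_ree")
  bad <- intersect(names(rates), protected)
  if (length(bad))
    abort_config("inject_missingness: cannot target protected fields: %s",
                 paste(bad, collapse = ", "))
  unknown <- setdiff(names(rates), names(cohort))
  if (length(unknown))
    abort_config("inject_missingness: unknown variables: %s",
                 paste(unknown, collapse = ", "))
  with_seed(seed, {
    for (v in names(rates)) {
      hit <- runif(nrow(cohort)) < rates[[v]]
      cohort[[v]][hit] <- NA
    }
  })
  cohort
}

#' Write / read the cohort CSV (missing cells empty)
#' @param cohort cohort data.frame
#' @param path CSV path
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, na.strings = "")
}
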