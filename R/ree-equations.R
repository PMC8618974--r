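#' Load the predictive-equation registry
#'
#' The registry bundles coefficient bands for the linear equations
#' (Harris-Benedict and its infant variant, Schofield and Oxford in their
#' weight and weight+height forms, FAO/WHO/UNU), the Talbot lookup tables for
#' weight and for height, and the Weir/Mehta constants. Every row carries its
#' citation; units are fixed as weight kg, height cm, age years, output
#' kcal/day.
#'
#' @param dir directory holding `equation_registry.csv`,
#'   `talbot_tables.csv` and `equation_constants.csv`; defaults to the
#'   bundled registry
#' @return an `equation_registry` list with elements `specs`, `lookups`,
#'   `constants`, `version`
#' @export
load_equation_registry <- function(dir = dirname(picuree_extdata("equation_registry.csv"))) {
  specs <- read.csv(file.path(dir, "equation_registry.csv"))
  lookups <- read.csv(file.path(dir, "talbot_tables.csv"))
  cons <- read.csv(file.path(dir, "equation_constants.csv"))
  constants <- setNames(cons$value, cons$name)
  reg <- structure(list(specs = specs, lookups = lookups,
                        constants = constants,
                        version = as.character(constants[["registry_version"]])),
                   class = "equation_registry")
  validate_registry(reg)
  reg
}

registry_ids <- c("harris_benedict", "harris_benedict_infants", "schofield_w",
                  "schofield_wh", "oxford_w", "oxford_wh", "fao_who_unu",
                  "talbot_weight", "talbot_height", "mehta")

validate_registry <- function(reg) {
  have <- union(unique(reg$specs$id), unique(reg$lookups$id))
  have <- union(have, "mehta")  # mehta lives in the constants
  missing <- setdiff(registry_ids, have)
  if (length(missing))
    abort_config("equation registry is missing ids: %s",
                 paste(missing, collapse = ", "))
  if (!all(is.finite(c(reg$specs$intercept, reg$specs$coef_weight,
                       reg$specs$coef_height, reg$specs$coef_age))))
    abort_config("equation registry: non-finite coefficients")
  for (id in unique(reg$lookups$id)) {
    for (sx in unique(reg$lookups$sex[reg$lookups$id == id])) {
      tab <- reg$lookups[reg$lookups$id == id & reg$lookups$sex == sx, ]
      if (any(diff(tab$abscissa) <= 0) || any(tab$ree_kcal_day <= 0))
        abort_config("lookup table %s/%s: abscissa must increase, REE positive",
                     id, sx)
    }
  }
  invisible(reg)
}

#' Bundled Weir/Mehta constants
#' @param registry an [load_equation_registry()] result
#' @return named numeric vector
#' @export
ree_constants <- function(registry = NULL) {
  if (is.null(registry)) {
    cons <- read.csv(picuree_extdata("equation_constants.csv"))
    setNames(cons$value, cons$name)
  } else registry$constants
}

#' VCO2-based (Mehta) REE
#'
#' `REE = k * VCO2 * 1440` with `k` in kcal per litre of CO2 (default 5.534
#' from the registry constants). Validated in mechanically ventilated
#' children; callers should gate on ventilation status (see
#' [evaluate_equation()]).
#'
#' @param vco2 L/min
#' @param constants registry constants, see [ree_constants()]
#' @return kcal/day
#' @export
mehta_ree <- function(vco2, constants = ree_constants()) {
  if (any(vco2 < 0, na.rm = TRUE)) abort_domain("mehta_ree: vco2 must be >= 0")
  constants[["mehta_k_kcal_per_l_co2"]] * constants[["minutes_per_day"]] * vco2
}

#' Look up a Talbot-table REE
#'
#' @param table a lookup data.frame with columns `abscissa`, `ree_kcal_day`
#'   (one sex slice of the registry `lookups`)
#' @param value weight (kg) or height (cm)
#' @param policy `"nearest"` (ties to the lower abscissa; the tables are
#'   discrete in the original), `"linear"` interpolation, or `"strict"`
#'   (out-of-range is not applicable)
#' @return kcal/day, or `NA` when not applicable
#' @export
talbot_lookup <- function(table, value, policy = c("nearest", "linear", "strict")) {
  policy <- match.arg(policy)
  x <- table$abscissa; y <- table$ree_kcal_day
  if (policy == "strict" && (value < min(x) || value > max(x)))
    return(NA_real_)
  if (policy == "linear") {
    v <- min(max(value, min(x)), max(x))
    return(approx(x, y, v)$y)
  }
  y[which.min(abs(x - value))]  # which.min takes the first, i.e. lower, on ties
}

record_field <- function(record, field) {
  v <- record[[field]]
  if (is.null(v) || length(v) == 0) NA else v
}

#' Evaluate one predictive equation on a patient record
#'
#' Coefficient bands are selected by sex and half-open age interval
#' `[lo, hi)`. Talbot ids route to the lookup tables; `mehta` routes to
#' [mehta_ree()] and is applicable only to mechanically ventilated records.
#' Any missing required input yields `NA` (not applicable) rather than an
#' error.
#'
#' @param registry an [load_equation_registry()] result
#' @param id equation id (see `picuree:::registry_ids`)
#' @param record named list / one-row data.frame with snake_case fields
#'   (`age`, `weight`, `height`, `male`, `mechanically_ventilated`, `vco2`,
#'   ...)
#' @param talbot_policy lookup policy, see [talbot_lookup()]
#' @return kcal/day or `NA_real_` when not applicable
#' @export
evaluate_equation <- function(registry, id, record,
                              talbot_policy = c("nearest", "linear", "strict")) {
  talbot_policy <- match.arg(talbot_policy)
  id <- match.arg(id, registry_ids)
  age <- record_field(record, "age")
  male <- record_field(record, "male")
  sex <- if (is.na(male)) NA_character_ else if (male >= 0.5) "male" else "female"
  weight <- record_field(record, "weight")
  height <- record_field(record, "height")

  if (id == "mehta") {
    vent <- record_field(record, "mechanically_ventilated")
    vco2 <- record_field(record, "vco2")
    if (is.na(vent) || vent < 0.5 || is.na(vco2)) return(NA_real_)
    return(mehta_ree(vco2, registry$constants))
  }
  if (id == "talbot_weight") {
    if (is.na(weight)) return(NA_real_)
    tab <- registry$lookups[registry$lookups$id == id, ]
    return(talbot_lookup(tab, weight, talbot_policy))
  }
  if (id == "talbot_height") {
    if (is.na(height) || is.na(sex)) return(NA_real_)
    tab <- registry$lookups[registry$lookups$id == id &
                            registry$lookups$sex == sex, ]
    return(talbot_lookup(tab, height, talbot_policy))
  }
  spec <- registry$specs[registry$specs$id == id, ]
  if (is.na(sex) || is.na(age)) return(NA_real_)
  band <- spec[spec$sex == sex & age >= spec$age_lo_years &
                 age < spec$age_hi_years, ]
  if (nrow(band) == 0) return(NA_real_)
  band <- band[1, ]
  needs_w <- band$coef_weight != 0
  needs_h <- band$coef_height != 0
  if ((needs_w && is.na(weight)) || (needs_h && is.na(height))) return(NA_real_)
  band$intercept +
    band$coef_weight * ifelse(needs_w, weight, 0) +
    band$coef_height * ifelse(needs_h, height, 0) +
    band$coef_age * age
}

#' Evaluate every registry equation on a record
#'
#' Never raises on partial records: inapplicable or under-specified equations
#' come back as `NA`.
#'
#' @inheritParams evaluate_equation
#' @return named numeric vector over all ten equation ids
#' @export
evaluate_all <- function(registry, record,
                         talbot_policy = c("nearest", "linear", "strict")) {
  talbot_policy <- match.arg(talbot_policy)
  vapply(registry_ids, function(id)
    tryCatch(evaluate_equation(registry, id, record, talbot_policy),
             picuree_error = function(e) NA_real_),
    numeric(1))
}

#' Predict REE with every equation for a whole cohort
#'
#' @param registry equation registry
#' @param cohort cohort data.frame (one row per patient)
#' @param talbot_policy see [talbot_lookup()]
#' @return data.frame of predictions, one column per equation id
#' @export
predict_equations <- function(registry, cohort,
                              talbot_policy = c("nearest", "linear", "strict")) {
  talbot_policy <- match.arg(talbot_policy)
  out <- t(vapply(seq_len(nrow(cohort)), function(i)
    evaluate_all(registry, as.list(cohort[i, ]), talbot_policy),
    numeric(length(registry_ids))))
  as.data.frame(out)
}
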