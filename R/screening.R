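#' Default forced exclusions for the variable screening
#'
#' Variables excluded from modelling regardless of completeness: length of
#' stay (not available at prediction time), diagnosis/comorbidity/therapy/
#' nutrition descriptors (not reproducibly categorizable), and birth
#' variables (structurally incomplete).
#' @export
default_forced_exclusions <- function() {
  c("length_of_stay", "diagnosis", "comorbidities", "current_therapy",
    "current_nutrition", "gestational_age", "birth_weight")
}

#' Screen out incomplete and excluded variables
#'
#' Removes every column with at least one missing cell, plus the configured
#' forced exclusions, and reports each removal with its reason and missing
#' count.
#'
#' @param table cohort data.frame
#' @param forced_exclusions columns always removed when present
#' @return list `table` (reduced), `report` (data.frame `column`, `reason`,
#'   `n_missing`)
#' @export
drop_incomplete_variables <- function(table,
                                      forced_exclusions = default_forced_exclusions()) {
  report <- data.frame(column = character(0), reason = character(0),
                       n_missing = integer(0))
  for (v in names(table)) {
    nm <- sum(is.na(table[[v]]))
    if (v %in% forced_exclusions) {
      report <- rbind(report, data.frame(column = v, reason = "forced_exclusion",
                                         n_missing = nm))
    } else if (nm > 0) {
      report <- rbind(report, data.frame(column = v, reason = "missing_data",
                                         n_missing = nm))
    }
  }
  list(table = table[, setdiff(names(table), report$column), drop = FALSE],
       report = report)
}

pool_base21 <- c("male", "female", "caucasian", "asian", "south_american",
                 "african", "mechanically_ventilated", "age", "weight",
                 "height", "bmi", "z_bmi", "z_hfa", "normal_weight",
                 "overweight", "obese", "stunting", "wasting_none",
                 "wasting_mild", "wasting_moderate", "wasting_severe")
pool_functional8 <- c("heart_rate", "sbp", "dbp", "sat_o2",
                      "body_temperature", "crp", "hemoglobin",
                      "blood_glucose")

#' Candidate-variable pool for a dataset variant and gas-inclusion mode
#'
#' The demographic/anthropometric/status pool has 21 variables; the gas
#' block (`vo2`, `vco2`, `rq`) brings the primary variant to 24, and the 8
#' functional variables (vitals and blood values) extend it to 32. Gas
#' modes: `all`, `none`, or exactly one gas retained.
#'
#' @param variant `"ds1"` (24 variables with all gases) or `"ds2"` (32)
#' @param gas_mode `"all"`, `"none"`, `"vo2_only"`, `"vco2_only"`,
#'   `"rq_only"`
#' @return character vector of column names
#' @export
candidate_pool <- function(variant = c("ds1", "ds2"),
                           gas_mode = c("all", "none", "vo2_only",
                                        "vco2_only", "rq_only")) {
  variant <- match.arg(variant)
  gas_mode <- match.arg(gas_mode)
  base <- pool_base21
  if (variant == "ds2") base <- c(base, pool_functional8)
  gas <- switch(gas_mode,
                all = c("vo2", "vco2", "rq"),
                none = character(0),
                vo2_only = "vo2", vco2_only = "vco2", rq_only = "rq")
  c(base, gas)
}

expected_pool_size <- function(variant, gas_mode) {
  base <- if (variant == "ds1") 21L else 29L
  base + switch(gas_mode, all = 3L, none = 0L, 1L)
}
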