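#' Experiment configuration
#'
#' Bundles the dataset variant, gas-inclusion mode, GA and MLP settings for
#' one end-to-end analysis. Can be read from a YAML file whose top-level keys
#' mirror the constructor arguments (`ga:` and `mlp:` as nested maps).
#'
#' @param dataset_variant `"ds1"` or `"ds2"`
#' @param gas_mode gas-inclusion mode, see [candidate_pool()]
#' @param ga a [ga_config()]
#' @param mlp an [mlp_spec()]
#' @param target target column (default `measured_ree`)
#' @param seed master seed; overrides the GA/MLP seeds when given
#' @return an `experiment_config` list
#' @export
experiment_config <- function(dataset_variant = c("ds1", "ds2"),
                              gas_mode = c("all", "none", "vo2_only",
                                           "vco2_only", "rq_only"),
                              ga = ga_config(), mlp = mlp_spec(),
                              target = "measured_ree", seed = NULL) {
  dataset_variant <- match.arg(dataset_variant)
  gas_mode <- match.arg(gas_mode)
  if (!is.null(seed)) {
    ga$seed <- as.integer(child_seed(seed, 101) %% 2147483647)
    mlp$seed <- as.integer(child_seed(seed, 202) %% 2147483647)
  }
  structure(list(dataset_variant = dataset_variant, gas_mode = gas_mode,
                 ga = ga, mlp = mlp, target = target),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file
#' @return an [experiment_config()]
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ga <- do.call(ga_config, cfg$ga %||% list())
  mlp <- do.call(mlp_spec, cfg$mlp %||% list())
  experiment_config(dataset_variant = cfg$dataset_variant %||% "ds1",
                    gas_mode = cfg$gas_mode %||% "all",
                    ga = ga, mlp = mlp,
                    target = cfg$target %||% "measured_ree",
                    seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one end-to-end REE modelling experiment
#'
#' Pipeline: variable screening (drop anything with missing cells plus the
#' forced exclusions), candidate-pool construction for the variant and gas
#' mode (with a hard check of the expected pool size), GA input/split
#' selection, blind reversal prediction with the MLP, and the comparison
#' statistics for the neural model and for every registry equation (the
#' VCO2-based equation on the ventilated subgroup, the infant variant on its
#' age band). For the `ds2` variant, records are first restricted to those
#' complete on the functional variables, mirroring how a subgroup with
#' complete vitals/labs is analyzed.
#'
#' @param config an [experiment_config()]
#' @param cohort cohort data.frame (missingness allowed; drives screening)
#' @param registry an equation registry (default bundled)
#' @return a `run_report` list with selected variables, fit metrics (pooled
#'   and per-half for the neural model; per equation), the correlation
#'   profile, the neural fit curve, and the configuration echo
#' @export
run_experiment <- function(config, cohort,
                           registry = load_equation_registry()) {
  target <- config$target
  if (!target %in% names(cohort))
    abort_config("run_experiment: target column %s not in cohort", target)
  pool <- candidate_pool(config$dataset_variant, config$gas_mode)

  if (config$dataset_variant == "ds2") {
    keep <- complete.cases(cohort[, intersect(c(pool_base21, pool_functional8,
                                                "vo2", "vco2", "rq", target),
                                              names(cohort))])
    cohort <- cohort[keep, , drop = FALSE]
  }
  scr <- drop_incomplete_variables(cohort)
  missing_pool <- setdiff(pool, names(scr$table))
  if (length(missing_pool))
    abort_config("run_experiment: pool variables unavailable after screening: %s",
                 paste(missing_pool, collapse = ", "))
  if (length(pool) != expected_pool_size(config$dataset_variant, config$gas_mode))
    abort_config("run_experiment: pool size %d does not match the expected %d",
                 length(pool),
                 expected_pool_size(config$dataset_variant, config$gas_mode))

  y <- scr$table[[target]]
  X <- scr$table[, pool, drop = FALSE]
  # constant columns cannot enter the model (scaler would reject them)
  constant <- vapply(X, function(col) sd(col) == 0, logical(1))
  selection <- run_twist(X[, !constant, drop = FALSE], y, config$ga,
                         config$mlp)
  feats <- selection$selected_features
  blind <- reversal_blind_predict(X[, feats, drop = FALSE], y,
                                  selection$split_plan, config$mlp)
  ann_pooled <- compute_metrics(y, blind$predicted)
  half_a <- blind$fold == "B_to_A"   # records of half A, predicted blindly
  ann_halves <- list(A = compute_metrics(y, blind$predicted, half_a),
                     B = compute_metrics(y, blind$predicted, !half_a))
  avg_fields <- c("mae", "mre", "accuracy_abs", "accuracy_rel", "r2")
  ann_averaged <- setNames(lapply(avg_fields, function(f)
    mean(c(ann_halves$A[[f]], ann_halves$B[[f]]))), avg_fields)

  eq_pred <- predict_equations(registry, scr$table)
  eq_metrics <- lapply(names(eq_pred), function(id) {
    sub <- switch(id,
                  mehta = scr$table$mechanically_ventilated == 1,
                  harris_benedict_infants = scr$table$age < 1,
                  NULL)
    tryCatch(compute_metrics(y, eq_pred[[id]], sub),
             picuree_error = function(e) NULL)
  })
  names(eq_metrics) <- names(eq_pred)

  structure(list(
    config = config,
    n = nrow(scr$table),
    screening_report = scr$report,
    candidate_pool = pool,
    pool_size = length(pool),
    selection = selection,
    blind_predictions = blind,
    ann_metrics = list(pooled = ann_pooled, per_half = ann_halves,
                       averaged = ann_averaged),
    equation_metrics = eq_metrics,
    correlation_profile = correlation_profile(X, y),
    fit_curve = export_fit_curve(y, blind$predicted)
  ), class = "run_report")
}

#' Serialize a run report to JSON
#' @param report a [run_experiment()] result
#' @param path output file
#' @export
write_run_report <- function(report, path) {
  out <- report
  out$config <- lapply(unclass(out$config), function(x)
    if (is.list(x)) unclass(x) else x)
  out$selection <- unclass(out$selection)
  out$selection$config <- unclass(out$selection$config)
  out$ann_metrics$pooled <- unclass(out$ann_metrics$pooled)
  out$ann_metrics$per_half <- lapply(out$ann_metrics$per_half, unclass)
  out$equation_metrics <- lapply(out$equation_metrics, function(m)
    if (is.null(m)) NULL else unclass(m))
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = 10,
                       na = "null")
  invisible(path)
}
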