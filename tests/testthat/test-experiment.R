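test_that("candidate pools match the published variable counts", {
  expect_length(candidate_pool("ds1", "all"), 24)
  expect_length(candidate_pool("ds1", "none"), 21)
  expect_length(candidate_pool("ds1", "vo2_only"), 22)
  expect_length(candidate_pool("ds1", "vco2_only"), 22)
  expect_length(candidate_pool("ds1", "rq_only"), 22)
  expect_length(candidate_pool("ds2", "all"), 32)
  expect_length(candidate_pool("ds2", "none"), 29)
  expect_length(candidate_pool("ds2", "vco2_only"), 30)
  expect_true(all(candidate_pool("ds1", "all") %in% candidate_pool("ds2", "all")))
  expect_false("vo2" %in% candidate_pool("ds1", "vco2_only"))
})

small_experiment <- function(seed = 1, variant = "ds1", gas = "all") {
  experiment_config(variant, gas,
                    ga = ga_config(population_size = 8, generations = 4,
                                   seed = seed),
                    mlp = fast_mlp(seed = seed))
}

test_that("end-to-end experiment report is complete and self-consistent", {
  co <- cached_cohort(seed = 12)
  rep1 <- run_experiment(small_experiment(seed = 3), co)
  expect_s3_class(rep1, "run_report")
  expect_equal(rep1$pool_size, 24)
  expect_equal(rep1$n, 257)
  expect_true(length(rep1$selection$selected_features) >= 1)
  expect_equal(nrow(rep1$blind_predictions), 257)

  # machine-check the metric identities on every emitted FitMetrics
  check_identities <- function(m) {
    expect_equal(m$accuracy_abs, 100 * (1 - m$mae / m$mean_true),
                 tolerance = 1e-9)
    expect_equal(m$accuracy_rel, 100 * (1 - m$mre), tolerance = 1e-9)
    expect_equal(m$f_statistic, (m$sd_true / m$sd_pred)^2, tolerance = 1e-9)
  }
  check_identities(rep1$ann_metrics$pooled)
  for (m in rep1$equation_metrics) if (!is.null(m)) check_identities(m)

  # the VCO2 equation is scored on the ventilated subgroup only
  expect_equal(rep1$equation_metrics$mehta$n, sum(co$mechanically_ventilated))
  # averaged-over-halves reporting present alongside pooled
  expect_true(all(c("mae", "accuracy_abs", "r2") %in%
                    names(rep1$ann_metrics$averaged)))
})

test_that("equation metrics do not depend on the GA/MLP seeds", {
  co <- cached_cohort(seed = 12)[1:120, ]
  r1 <- run_experiment(small_experiment(seed = 1), co)
  r2 <- run_experiment(small_experiment(seed = 99), co)
  expect_equal(r1$equation_metrics, r2$equation_metrics)
})

test_that("experiment runs are deterministic: byte-identical JSON reports", {
  co <- cached_cohort(seed = 13)[1:100, ]
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_run_report(run_experiment(small_experiment(seed = 5), co), f1)
  write_run_report(run_experiment(small_experiment(seed = 5), co), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("missing pool columns raise a configuration error", {
  co <- cached_cohort(seed = 12)
  broken <- co[, setdiff(names(co), "rq")]
  expect_error(run_experiment(small_experiment(), broken),
               "rq", class = "picuree_config_error")
})

test_that("ds2 restricts to records complete on the functional variables", {
  co <- inject_missingness(cached_cohort(seed = 14),
                           c(crp = 0.2, hemoglobin = 0.1), seed = 2)
  rep2 <- run_experiment(small_experiment(seed = 2, variant = "ds2",
                                          gas = "vco2_only"), co)
  expect_equal(rep2$pool_size, 30)
  expect_lt(rep2$n, 257)
  expect_equal(rep2$n,
               sum(complete.cases(co[, c("crp", "hemoglobin")])))
})

test_that("CLI: simulate / equations / evaluate round trip with exit codes", {
  dir <- withr::local_tempdir()
  cohort_csv <- file.path(dir, "cohort.csv")
  code <- picuree_cli(c("simulate", "--seed", "4", "--out", cohort_csv))
  expect_equal(code, 0L)
  co <- read_cohort_csv(cohort_csv)
  expect_equal(nrow(co), 257)
  expect_true(anyNA(co$crp))    # spec default missingness applied

  pred_csv <- file.path(dir, "pred.csv")
  expect_equal(picuree_cli(c("equations", "--in", cohort_csv,
                             "--out", pred_csv)), 0L)
  pred <- read.csv(pred_csv)
  expect_equal(nrow(pred), 257)
  expect_true("talbot_weight" %in% names(pred))

  eval_csv <- file.path(dir, "eval.csv")
  write.csv(data.frame(a = c(1, 2, 3), b = c(1.1, 2.2, 2.9)), eval_csv,
            row.names = FALSE)
  out <- capture.output(code <- picuree_cli(c("evaluate", "--in", eval_csv,
                                              "--true-col", "a",
                                              "--pred-col", "b")))
  expect_equal(code, 0L)
  expect_true(any(grepl("^mae:", out)))

  expect_equal(picuree_cli(c("nonsense")), 2L)
  expect_equal(picuree_cli(c("simulate")), 2L)           # missing --out
  expect_equal(picuree_cli(c("evaluate", "--in", eval_csv,
                             "--true-col", "zz", "--pred-col", "b")), 3L)
})

test_that("YAML experiment config round trip", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.yaml")
  writeLines(c("dataset_variant: ds1", "gas_mode: vco2_only", "seed: 7",
               "ga:", "  population_size: 10", "  generations: 3",
               "mlp:", "  hidden_units: 4", "  max_epochs: 150"), cfg_path)
  cfg <- read_experiment_config(cfg_path)
  expect_equal(cfg$gas_mode, "vco2_only")
  expect_equal(cfg$ga$population_size, 10L)
  expect_equal(cfg$mlp$max_epochs, 150L)
})
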