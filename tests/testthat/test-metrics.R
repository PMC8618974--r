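test_that("two-sample F test: orientation, symmetry, worked values", {
  eq <- f_two_sample(10, 50, 10, 50)
  expect_equal(eq$f_statistic, 1)
  expect_equal(eq$f_pvalue, 1)
  ft <- f_two_sample(325.7, 257, 260.2, 257)
  expect_equal(round(ft$f_statistic, 3), 1.567)
  expect_lt(ft$f_pvalue, 0.001)
  expect_equal(round(f_two_sample(301.9, 102, 257.0, 102)$f_statistic, 3),
               1.380)
  expect_error(f_two_sample(0, 10, 1, 10), class = "picuree_domain_error")
})

test_that("fit metrics satisfy their defining identities", {
  set.seed(4)
  true <- runif(80, 300, 1200)
  pred <- true * runif(80, 0.7, 1.3)
  m <- compute_metrics(true, pred)
  # independent recomputation of every field
  expect_equal(m$mae, mean(abs(pred - true)))
  expect_equal(m$mre, mean(abs(pred - true) / true))
  expect_equal(m$accuracy_abs, 100 * (1 - m$mae / m$mean_true), tolerance = 1e-9)
  expect_equal(m$accuracy_rel, 100 * (1 - m$mre), tolerance = 1e-9)
  expect_equal(m$f_statistic, (m$sd_true / m$sd_pred)^2, tolerance = 1e-9)
  expect_equal(m$r2, cor(true, pred)^2)
  expect_equal(m$sd_true, sd(true))        # n-1 denominator

  ident <- compute_metrics(true, true)
  expect_equal(ident$mae, 0)
  expect_equal(ident$accuracy_abs, 100)
  expect_equal(ident$r2, 1)
  expect_equal(ident$f_statistic, 1)

  # subgroup restriction
  mask <- true > 700
  ms <- compute_metrics(true, pred, mask)
  expect_equal(ms$n, sum(mask))
  expect_equal(ms$mean_true, mean(true[mask]))

  flat <- compute_metrics(true, rep(500, 80))
  expect_true(flat$zero_variance_pred)
  expect_true(is.na(flat$f_statistic))
})

test_that("summary-only metrics reproduce printed-style cells", {
  m <- metrics_from_summary(mean_true = 623.3, sd_true = 325.7, n = 257,
                            mae = 244.2, mre = 0.610, sd_pred = 260.2)
  expect_equal(round(m$accuracy_abs, 1), 60.8)
  expect_equal(round(m$f_statistic, 3), 1.567)
  expect_lt(m$f_pvalue, 0.001)
  expect_equal(metrics_from_summary(623.3, 325.7, 257, mre = 0.058)$accuracy_rel,
               94.2)
})

test_that("correlation profile ranks and guards", {
  set.seed(6)
  n <- 1000
  t <- rnorm(n)
  d <- data.frame(same = t, noise = rnorm(n), flat = rep(1, n))
  cp <- correlation_profile(d, t)
  expect_equal(cp$r[cp$variable == "same"], 1)
  expect_lt(abs(cp$r[cp$variable == "noise"]), 0.1)
  expect_true(is.na(cp$r[cp$variable == "flat"]))
  expect_equal(cp$variable[1], "same")      # sorted descending

  co <- cached_cohort(seed = 1)
  cpc <- correlation_profile(co[, candidate_pool("ds1", "all")],
                             co$measured_ree)
  expect_true(all(c("vo2", "vco2") %in% cpc$variable[1:3]))
})

test_that("fit-curve export: tendency behavior and exact interpolation", {
  set.seed(8)
  true <- runif(40, 300, 900)
  fc <- export_fit_curve(true, true)
  expect_equal(fc$true, sort(true))
  # tendency is the least-squares degree-5 polynomial (independent refit)
  oracle <- unname(fitted(lm(sort(true) ~ poly(seq_len(40), 5, raw = TRUE))))
  expect_equal(fc$tendency, oracle, tolerance = 1e-8)
  expect_gt(cor(fc$tendency, fc$predicted), 0.99)

  fc2 <- export_fit_curve(true, rep(650, 40))
  expect_equal(fc2$tendency, rep(650, 40), tolerance = 1e-9)

  six <- export_fit_curve(c(5, 1, 4, 2, 6, 3), c(10, 40, 20, 60, 30, 50))
  expect_equal(six$tendency, six$predicted, tolerance = 1e-6)
})

test_that("variable screening removes incomplete and excluded columns", {
  co <- cached_cohort(seed = 2)[1:50, ]
  clean <- co[, setdiff(names(co), c("z_wfa", "z_wfh"))]
  scr <- drop_incomplete_variables(clean)
  expect_identical(scr$table, clean)
  expect_equal(nrow(scr$report), 0)

  one_na <- clean; one_na$crp[17] <- NA
  scr2 <- drop_incomplete_variables(one_na)
  expect_false("crp" %in% names(scr2$table))
  expect_equal(scr2$report$n_missing[scr2$report$column == "crp"], 1)

  with_los <- clean; with_los$length_of_stay <- 5
  scr3 <- drop_incomplete_variables(with_los)
  expect_false("length_of_stay" %in% names(scr3$table))
  expect_equal(scr3$report$reason[scr3$report$column == "length_of_stay"],
               "forced_exclusion")

  # complete synthetic cohort keeps the full 32-variable pool intact
  scr4 <- drop_incomplete_variables(co)
  expect_true(all(candidate_pool("ds2", "all") %in% names(scr4$table)))
})
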