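test_that("cohort generation: empty case, determinism, byte-identical export", {
  spec <- cohort_spec(n = 0)
  expect_equal(nrow(generate_cohort(spec)), 0)

  spec <- cohort_spec(n = 40, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, fa); write_cohort_csv(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("invalid specs raise configuration errors naming the field", {
  expect_error(cohort_spec(male_fraction = 1.2), "male_fraction",
               class = "picuree_config_error")
  expect_error(cohort_spec(ethnicity_probs = c(0.5, 0.2, 0.2, 0.2)),
               "ethnicity_probs", class = "picuree_config_error")
  expect_error(cohort_spec(n = -3), class = "picuree_config_error")
  gm <- cohort_spec()$gas_model; gm$rq_bounds <- c(1.3, 0.67)
  expect_error(cohort_spec(gas_model = gm), class = "picuree_config_error")
})

test_that("default cohort reproduces the reference marginal moments", {
  co <- cached_cohort(seed = 1)
  expect_equal(nrow(co), 257)
  # mean RQ within 3 Monte-Carlo SEs of 0.77 (SD 0.12, n 257)
  expect_lt(abs(mean(co$rq) - 0.77), 3 * 0.12 / sqrt(257))
  expect_true(all(co$rq >= 0.67 & co$rq <= 1.3))
  expect_true(all(co$male + co$female == 1))
  expect_true(all(co$caucasian + co$asian + co$south_american + co$african == 1))
  expect_true(all(co$wasting_none + co$wasting_mild + co$wasting_moderate +
                    co$wasting_severe == 1))
  expect_true(all(co$normal_weight + co$overweight + co$obese == 1))
  expect_equal(co$rq, co$vco2 / co$vo2, tolerance = 1e-9)
  expect_equal(co$bmi, co$weight / (co$height / 100)^2, tolerance = 1e-12)
})

test_that("weir_exact ground truth is the Weir value of the record gases", {
  co <- cached_cohort(seed = 2)
  expect_equal(co$true_ree, weir_ree(co$vo2, co$vco2), tolerance = 1e-9)
})

test_that("calibration: pooled moments across 20 seeds match the stated cohort", {
  # pooled mean over 20 cohorts within 3 SEs of the stated means,
  # SE = stated SD / sqrt(20 * 257)
  sums <- sapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(seed = s))
    c(w = mean(co$weight), vo2 = mean(co$vo2), vco2 = mean(co$vco2),
      rq = mean(co$rq))
  })
  pooled <- rowMeans(sums)
  se <- c(w = 12.2, vo2 = 0.05, vco2 = 0.04, rq = 0.12) / sqrt(20 * 257)
  target <- c(w = 15.6, vo2 = 0.09, vco2 = 0.07, rq = 0.77)
  for (v in names(target))
    expect_lt(abs(pooled[[v]] - target[[v]]), 3 * se[[v]],
              label = sprintf("|%s pooled - target|", v))
})

test_that("breath series: detector recovers the true steady window", {
  spec <- cohort_spec(seed = 5)
  co <- cached_cohort(seed = 5)
  for (i in c(1, 10, 25)) {
    s <- generate_breath_series(co[i, ], spec)
    expect_equal(nrow(s), 30)
    w <- find_steady_state(s)
    expect_false(is.null(w))
    # overlap with the true window of at least the minimum steady length
    expect_gte(min(w$end, co$steady_end[i]) -
                 max(w$start, co$steady_start[i]) + 1, 5)
  }
  # zero-noise configuration: every 5-minute window qualifies
  spec0 <- spec
  spec0$breath_model[c("noise_vo2", "noise_vco2", "noise_ve",
                       "drift_per_min")] <- list(0, 0, 0, 0)
  s0 <- generate_breath_series(co[1, ], spec0)
  expect_equal(window_variation(s0$vo2), 0)
  w0 <- find_steady_state(s0)
  expect_equal(c(w0$start, w0$end), c(0, 29))
  for (start in c(1, 13, 26)) {
    idx <- start:(start + 4)
    expect_lt(window_variation(s0$vo2[idx]), 1e-12)
  }
})

test_that("missingness injection is MCAR at the requested rates", {
  co <- cached_cohort(seed = 3)
  expect_identical(inject_missingness(co, c(crp = 0), seed = 1), co)
  all_gone <- inject_missingness(co, c(crp = 1), seed = 1)
  expect_true(all(is.na(all_gone$crp)))

  big <- generate_cohort(cohort_spec(n = 1000, seed = 9))
  hit <- inject_missingness(big, c(hemoglobin = 0.3), seed = 7)
  frac <- mean(is.na(hit$hemoglobin))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))

  expect_identical(inject_missingness(co, c(crp = 0.4), seed = 11),
                   inject_missingness(co, c(crp = 0.4), seed = 11))
  expect_error(inject_missingness(co, c(crp = 1.5)),
               class = "picuree_config_error")
  expect_error(inject_missingness(co, c(vo2 = 0.1)),
               class = "picuree_config_error")
})
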