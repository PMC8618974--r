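#' Two-sample F test for equality of variances
#'
#' Oriented as `(sd_true/sd_pred)^2` — the variance of the measured values
#' over the variance of the predictions — with a two-tailed p-value under
#' `F(n_true - 1, n_pred - 1)`.
#'
#' @param sd_true,sd_pred sample standard deviations (> 0)
#' @param n_true,n_pred sample sizes (>= 2)
#' @return list `f_statistic`, `f_pvalue`
#' @export
f_two_sample <- function(sd_true, n_true, sd_pred, n_pred = n_true) {
  if (sd_true <= 0 || sd_pred <= 0)
    abort_domain("f_two_sample: standard deviations must be positive")
  if (n_true < 2 || n_pred < 2)
    abort_domain("f_two_sample: need n >= 2 in both samples")
  f <- (sd_true / sd_pred)^2
  p <- 2 * min(pf(f, n_true - 1, n_pred - 1),
               1 - pf(f, n_true - 1, n_pred - 1))
  list(f_statistic = f, f_pvalue = min(p, 1))
}

#' Agreement metrics for one prediction method
#'
#' Computes the comparison suite used throughout: MAE, mean relative error
#' (mean of `|pred - true|/true`), the two accuracy percentages
#' (`100*(1 - MAE/mean(true))` and `100*(1 - MRE)`), squared Pearson
#' correlation, and the two-sample F test on the SDs. Pairs with a missing
#' prediction (e.g. an equation not applicable to a record) are dropped and
#' `n` reports the pairs actually used.
#'
#' @param true measured REE, kcal/day
#' @param pred predicted REE, kcal/day (same length)
#' @param subgroup optional logical mask restricting both vectors (used for
#'   ventilated-only or infant-only rows)
#' @return a `fit_metrics` list
#' @export
compute_metrics <- function(true, pred, subgroup = NULL) {
  if (length(true) != length(pred))
    abort_data("compute_metrics: length mismatch")
  if (!is.null(subgroup)) { true <- true[subgroup]; pred <- pred[subgroup] }
  keep <- !is.na(true) & !is.na(pred)
  true <- true[keep]; pred <- pred[keep]
  n <- length(true)
  if (n < 2) abort_data("compute_metrics: need at least 2 complete pairs")
  mae <- mean(abs(pred - true))
  mre <- mean(abs(pred - true) / true)
  sd_true <- sd(true); sd_pred <- sd(pred)
  ftest <- if (sd_pred > 0) f_two_sample(sd_true, n, sd_pred, n)
           else list(f_statistic = NA_real_, f_pvalue = NA_real_)
  structure(list(
    n = n,
    mean_true = mean(true), sd_true = sd_true,
    mean_pred = mean(pred), sd_pred = sd_pred,
    mae = mae, mre = mre,
    accuracy_abs = 100 * (1 - mae / mean(true)),
    accuracy_rel = 100 * (1 - mre),
    r2 = if (sd_pred > 0) cor(true, pred)^2 else NA_real_,
    f_statistic = ftest$f_statistic, f_pvalue = ftest$f_pvalue,
    zero_variance_pred = sd_pred == 0
  ), class = "fit_metrics")
}

#' Metrics recomputable from printed summary statistics alone
#'
#' The accuracy percentages and the F statistic are identities in the
#' summary quantities (mean and SD of the measured values, MAE, mean
#' relative error, SD of the predictions), so they can be recomputed from a
#' published summary row without patient-level data.
#'
#' @param mean_true,sd_true measured-REE mean and SD, kcal/day
#' @param n sample size
#' @param mae mean absolute error, kcal/day (optional)
#' @param mre mean relative error, proportion (optional)
#' @param sd_pred prediction SD, kcal/day (optional)
#' @param n_pred prediction sample size (default `n`)
#' @return list with `accuracy_abs`, `accuracy_rel`, `f_statistic`,
#'   `f_pvalue` (fields are `NA` when their inputs were not supplied)
#' @export
metrics_from_summary <- function(mean_true, sd_true, n, mae = NA, mre = NA,
                                 sd_pred = NA, n_pred = n) {
  out <- list(accuracy_abs = NA_real_, accuracy_rel = NA_real_,
              f_statistic = NA_real_, f_pvalue = NA_real_)
  if (!is.na(mae)) out$accuracy_abs <- 100 * (1 - mae / mean_true)
  if (!is.na(mre)) out$accuracy_rel <- 100 * (1 - mre)
  if (!is.na(sd_pred)) {
    ft <- f_two_sample(sd_true, n, sd_pred, n_pred)
    out$f_statistic <- ft$f_statistic
    out$f_pvalue <- ft$f_pvalue
  }
  out
}

#' Pearson correlation of every candidate variable with the target
#'
#' @param table data.frame of candidate variables (numeric columns)
#' @param target numeric target vector (measured REE)
#' @param min_pairs minimum complete pairs per variable (default 3)
#' @return data.frame `variable`, `r`, `n`, sorted by `r` descending;
#'   constant variables get `NA`
#' @export
correlation_profile <- function(table, target, min_pairs = 3L) {
  table <- as.data.frame(table)
  rows <- lapply(names(table), function(v) {
    x <- table[[v]]
    keep <- !is.na(x) & !is.na(target)
    n <- sum(keep)
    r <- if (n < min_pairs || sd(x[keep]) == 0 || sd(target[keep]) == 0)
      NA_real_ else cor(x[keep], target[keep])
    data.frame(variable = v, r = r, n = n)
  })
  out <- do.call(rbind, rows)
  out[order(-out$r, na.last = TRUE), ]
}

#' Export a sorted fit curve with its polynomial tendency line
#'
#' Records are sorted by measured REE; the tendency line is the degree-5
#' least-squares polynomial of the predictions against the sorted rank.
#'
#' @param true measured REE
#' @param pred predicted REE
#' @param degree polynomial degree (default 5)
#' @return data.frame `rank`, `true`, `predicted`, `tendency`
#' @export
export_fit_curve <- function(true, pred, degree = 5L) {
  n <- length(true)
  if (n < degree + 1) abort_data("export_fit_curve: need n >= degree + 1")
  o <- order(true)
  d <- data.frame(rank = seq_len(n), true = true[o], predicted = pred[o])
  fit <- lm(predicted ~ poly(rank, degree, raw = TRUE), data = d)
  d$tendency <- as.vector(predict(fit))
  d
}
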