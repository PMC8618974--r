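#' Multi-layer perceptron specification
#'
#' One hidden layer of `hidden_units` neurons (default 4) with a linear
#' output, trained by full-batch Adam on z-standardized inputs and target,
#' with early stopping on a held-out slice of the training rows.
#'
#' @param hidden_units hidden-layer width (>= 1)
#' @param activation hidden activation, `"tanh"` or `"logistic"`
#' @param max_epochs training epochs cap
#' @param learning_rate Adam step size
#' @param early_stop_patience epochs without validation improvement before
#'   stopping
#' @param val_fraction fraction of the training rows held out as the
#'   early-stopping monitor (0 disables early stopping)
#' @param n_restarts independent weight initializations; the restart with the
#'   best monitor loss is kept (full-batch training in a small network can
#'   stall in poor local optima)
#' @param seed integer seed controlling weight init and the monitor split
#' @return an `mlp_spec` list
#' @export
mlp_spec <- function(hidden_units = 4L, activation = c("tanh", "logistic"),
                     max_epochs = 600L, learning_rate = 0.02,
                     early_stop_patience = 150L, val_fraction = 0.1,
                     n_restarts = 3L, seed = 1L) {
  activation <- match.arg(activation)
  if (hidden_units < 1) abort_config("mlp_spec: hidden_units must be >= 1")
  if (max_epochs < 1) abort_config("mlp_spec: max_epochs must be >= 1")
  if (n_restarts < 1) abort_config("mlp_spec: n_restarts must be >= 1")
  structure(list(hidden_units = as.integer(hidden_units),
                 activation = activation,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "mlp_spec")
}

#' Fit / apply a z-standardization scaler
#'
#' @param data numeric matrix or data.frame (columns = features)
#' @return `fit_scaler`: a `scaling_params` list with per-column `center` and
#'   `scale`; constant columns are rejected by name
#' @export
fit_scaler <- function(data) {
  m <- as.matrix(data)
  if (nrow(m) < 2) abort_config("fit_scaler: need at least 2 rows")
  center <- colMeans(m)
  scale <- apply(m, 2, sd)
  bad <- colnames(m)[!is.finite(scale) | scale <= 0]
  if (length(bad))
    abort_config("fit_scaler: constant column(s): %s", paste(bad, collapse = ", "))
  structure(list(center = center, scale = scale), class = "scaling_params")
}

#' @rdname fit_scaler
#' @param params a `scaling_params` object
#' @param invert undo the standardization instead of applying it
#' @export
apply_scaler <- function(data, params, invert = FALSE) {
  m <- as.matrix(data)
  if (invert) sweep(sweep(m, 2, params$scale, "*"), 2, params$center, "+")
  else sweep(sweep(m, 2, params$center, "-"), 2, params$scale, "/")
}

#' Train the MLP regressor
#'
#' Standardizes `X` and `y` with scalers fit on these rows only, then trains
#' the C++ core. Deterministic for a fixed spec seed.
#'
#' @param X numeric matrix / data.frame of predictors
#' @param y numeric target (kcal/day)
#' @param spec an [mlp_spec()]
#' @return a `picuree_mlp` model usable with [predict()]
#' @export
train_mlp <- function(X, y, spec = mlp_spec()) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) abort_data("train_mlp: NA in inputs")
  if (nrow(X) < 10) abort_config("train_mlp: need at least 10 records")
  if (ncol(X) < 1) abort_config("train_mlp: need at least 1 feature")
  x_scaler <- fit_scaler(X)
  y_scaler <- fit_scaler(matrix(y, dimnames = list(NULL, "y")))
  Xs <- apply_scaler(X, x_scaler)
  ys <- as.vector(apply_scaler(matrix(y), y_scaler))
  act <- ifelse(spec$activation == "tanh", 0L, 1L)
  best <- NULL; best_loss <- Inf
  for (r in seq_len(spec$n_restarts)) {
    fit <- mlp_train_cpp(Xs, ys, spec$hidden_units, act,
                         spec$max_epochs, spec$learning_rate,
                         spec$early_stop_patience, spec$val_fraction,
                         as.integer(child_seed(spec$seed, r)) %% 2147483647L)
    loss <- fit$val_mse
    if (is.na(loss)) {  # no monitor split: compare on the training loss
      res <- mlp_predict_cpp(Xs, fit$W1, fit$b1, fit$w2, fit$b2, act) - ys
      loss <- mean(res^2)
    }
    if (loss < best_loss) { best_loss <- loss; best <- fit }
  }
  structure(list(fit = best, x_scaler = x_scaler, y_scaler = y_scaler,
                 features = colnames(X), spec = spec),
            class = "picuree_mlp")
}

#' @export
predict.picuree_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X)))
    X <- X[, object$features, drop = FALSE]
  Xs <- apply_scaler(X, object$x_scaler)
  ys <- mlp_predict_cpp(Xs, object$fit$W1, object$fit$b1, object$fit$w2,
                        object$fit$b2,
                        ifelse(object$spec$activation == "tanh", 0L, 1L))
  as.vector(apply_scaler(matrix(ys), object$y_scaler, invert = TRUE))
}

#' Reversal protocol: one blind prediction per record
#'
#' Trains on half A (scaler and weights fit on A only) to predict half B,
#' then swaps, so every record receives exactly one out-of-sample prediction.
#'
#' @param X predictor matrix / data.frame over all records
#' @param y target vector
#' @param split_plan logical vector (`TRUE` = half A) covering all records
#' @param spec an [mlp_spec()]
#' @return data.frame with `index`, `fold` (`"A_to_B"`/`"B_to_A"`),
#'   `predicted` — ordered as the input records
#' @export
reversal_blind_predict <- function(X, y, split_plan, spec = mlp_spec()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(split_plan) != n)
    abort_config("reversal_blind_predict: split_plan must cover all records")
  split_plan <- as.logical(split_plan)
  if (!any(split_plan) || all(split_plan))
    abort_config("reversal_blind_predict: both halves must be nonempty")
  pred <- numeric(n)
  fold <- character(n)
  one_fold <- function(train, k) {
    # features constant within this training half carry no signal for this
    # fold and would break the scaler; drop them fold-locally
    Xt <- X[train, , drop = FALSE]
    keep <- apply(Xt, 2, sd) > 0
    if (!any(keep))
      abort_config("reversal_blind_predict: no non-constant features in a half")
    spec_k <- spec; spec_k$seed <- as.integer(child_seed(spec$seed, k))
    fit <- train_mlp(Xt[, keep, drop = FALSE], y[train], spec_k)
    predict(fit, X[!train, keep, drop = FALSE])
  }
  pred[!split_plan] <- one_fold(split_plan, 1L)
  fold[!split_plan] <- "A_to_B"
  pred[split_plan] <- one_fold(!split_plan, 2L)
  fold[split_plan] <- "B_to_A"
  data.frame(index = seq_len(n), fold = fold, predicted = pred)
}
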