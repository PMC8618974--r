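#' Genetic-algorithm configuration for the input/split selector
#'
#' The selector jointly evolves a feature mask and a two-way record split.
#' The underlying evolutionary engine of the original system is proprietary;
#' this is a standard elitist GA (tournament selection, uniform crossover,
#' per-bit mutation) implementing the same contract: minimize the variable
#' count while preserving blind predictive performance, and keep the two
#' halves distributionally matched.
#'
#' @param population_size chromosomes per generation
#' @param generations GA iterations
#' @param crossover_rate probability of uniform crossover
#' @param mutation_rate per-bit flip probability; `NULL` = 1/chromosome-length
#' @param elitism_count chromosomes copied unchanged each generation (>= 1)
#' @param tournament_size selection tournament size
#' @param seed integer seed
#' @param fitness `"neg_mae"` (negative blind MAE) or `"accuracy_rel"`
#' @param distribution_penalty_weight weight of the split-mismatch penalty;
#'   units of the fitness score per unit of mean distribution distance
#' @param feature_penalty optional per-selected-feature fitness penalty
#'   (explicit parsimony pressure; default 0, parsimony is implicit)
#' @param split_balance_tol allowed half-size imbalance as a fraction of the
#'   equal split (default 0.10)
#' @param staged optimize the split first with all features, then the mask
#'   with the split frozen, instead of the joint chromosome
#' @return a `ga_config` list
#' @export
ga_config <- function(population_size = 50L, generations = 100L,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      elitism_count = 2L, tournament_size = 3L, seed = 1L,
                      fitness = c("neg_mae", "accuracy_rel"),
                      distribution_penalty_weight = 1.0,
                      feature_penalty = 0,
                      split_balance_tol = 0.10, staged = FALSE) {
  fitness <- match.arg(fitness)
  if (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1))
    abort_config("ga_config: mutation_rate must be in [0, 1]")
  if (crossover_rate < 0 || crossover_rate > 1)
    abort_config("ga_config: crossover_rate must be in [0, 1]")
  if (elitism_count < 1 || elitism_count >= population_size)
    abort_config("ga_config: need 1 <= elitism_count < population_size")
  if (distribution_penalty_weight < 0)
    abort_config("ga_config: distribution_penalty_weight must be >= 0")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed), fitness = fitness,
                 distribution_penalty_weight = distribution_penalty_weight,
                 feature_penalty = feature_penalty,
                 split_balance_tol = split_balance_tol,
                 staged = staged),
            class = "ga_config")
}

# exact two-sample Kolmogorov-Smirnov statistic (statistic only; ties
# handled by evaluating the ECDF difference after each distinct value)
ks_statistic <- function(a, b) {
  vals <- c(a, b)
  o <- order(vals)
  step <- c(rep(1 / length(a), length(a)), rep(-1 / length(b), length(b)))[o]
  cdf_diff <- cumsum(step)
  distinct <- c(diff(vals[o]) != 0, TRUE)
  max(abs(cdf_diff[distinct]))
}

is_binary <- function(x) all(x %in% c(0, 1))

#' Distribution mismatch between the two halves of a split
#'
#' Mean over variables of the two-sample KS statistic (continuous variables)
#' or the absolute proportion difference (binary variables). Zero iff the
#' halves have identical empirical distributions on every variable.
#'
#' @param data data.frame / matrix of the variables to match
#' @param split_assignment logical vector, `TRUE` = half A
#' @return nonnegative scalar
#' @export
distribution_similarity <- function(data, split_assignment) {
  split_assignment <- as.logical(split_assignment)
  if (!any(split_assignment) || all(split_assignment))
    abort_domain("distribution_similarity: both halves must be nonempty")
  data <- as.data.frame(data)
  per_var <- vapply(data, function(col) {
    a <- col[split_assignment]; b <- col[!split_assignment]
    if (is_binary(col)) abs(mean(a) - mean(b)) else ks_statistic(a, b)
  }, numeric(1))
  mean(per_var)
}

repair_chromosome <- function(chrom, n, tol) {
  if (!any(chrom$mask))
    chrom$mask[sample.int(length(chrom$mask), 1)] <- TRUE
  lo <- ceiling(n / 2 * (1 - tol)); hi <- floor(n / 2 * (1 + tol))
  na <- sum(chrom$split)
  while (na < lo) {
    chrom$split[sample(which(!chrom$split), 1)] <- TRUE; na <- na + 1
  }
  while (na > hi) {
    chrom$split[sample(which(chrom$split), 1)] <- FALSE; na <- na - 1
  }
  chrom
}

random_chromosome <- function(p, n, tol) {
  repair_chromosome(list(mask = runif(p) < 0.5,
                         split = sample(rep(c(TRUE, FALSE), length.out = n))),
                    n, tol)
}

#' Fitness of one chromosome: blind cross-predictive score minus penalties
#'
#' Trains the MLP on half A restricted to the masked features, scores on half
#' B, and vice versa (the reversal protocol); the fitness is the mean of the
#' two blind scores minus `distribution_penalty_weight` times the
#' distribution mismatch of the split (computed over all candidate variables
#' plus the target) and minus any per-feature parsimony penalty. Degenerate
#' masks (a selected feature constant within a training half) score `-Inf`.
#'
#' @param chromosome list with `mask` (logical over features) and `split`
#'   (logical over records)
#' @param X candidate-feature matrix
#' @param y target vector
#' @param config a [ga_config()]
#' @param mlp an [mlp_spec()]
#' @return scalar fitness (larger is better)
#' @export
evaluate_fitness <- function(chromosome, X, y, config, mlp = mlp_spec()) {
  X <- as.matrix(X)
  mask <- chromosome$mask; split <- chromosome$split
  Xm <- X[, mask, drop = FALSE]
  score_half <- function(train_idx, test_idx, k) {
    Xt <- Xm[train_idx, , drop = FALSE]
    keep <- apply(Xt, 2, sd) > 0  # constant-in-half features carry no signal
    if (!any(keep)) return(NA_real_)
    spec <- mlp; spec$seed <- as.integer(child_seed(mlp$seed, k))
    fit <- tryCatch(train_mlp(Xt[, keep, drop = FALSE], y[train_idx], spec),
                    picuree_error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- predict(fit, Xm[test_idx, keep, drop = FALSE])
    err <- abs(pred - y[test_idx])
    switch(config$fitness,
           neg_mae = -mean(err),
           accuracy_rel = 100 * (1 - mean(err / abs(y[test_idx]))))
  }
  s1 <- score_half(which(split), which(!split), 1L)
  s2 <- score_half(which(!split), which(split), 2L)
  if (is.na(s1) || is.na(s2)) return(-Inf)
  penalty <- config$distribution_penalty_weight *
    distribution_similarity(cbind(as.data.frame(X), .target = y), split)
  mean(c(s1, s2)) - penalty - config$feature_penalty * sum(mask)
}

tournament_pick <- function(fitnesses, k) {
  cand <- sample.int(length(fitnesses), k, replace = TRUE)
  cand[which.max(fitnesses[cand])]
}

#' One GA generation: elitism, tournament selection, crossover, mutation
#'
#' @param population list of chromosomes
#' @param fitnesses numeric vector aligned with `population`
#' @param config a [ga_config()]
#' @param freeze `"none"`, `"split"` or `"mask"` — part of the chromosome
#'   held fixed (used by the staged mode)
#' @return list of chromosomes of the same size
#' @export
evolve <- function(population, fitnesses, config, freeze = "none") {
  pop_n <- length(population)
  n <- length(population[[1]]$split)
  p <- length(population[[1]]$mask)
  len <- p + n
  mut <- if (is.null(config$mutation_rate)) 1 / len else config$mutation_rate
  elite_idx <- order(fitnesses, decreasing = TRUE)[seq_len(config$elitism_count)]
  nxt <- population[elite_idx]
  while (length(nxt) < pop_n) {
    pa <- population[[tournament_pick(fitnesses, config$tournament_size)]]
    pb <- population[[tournament_pick(fitnesses, config$tournament_size)]]
    child <- pa
    if (runif(1) < config$crossover_rate) {
      take_b <- runif(p) < 0.5
      child$mask[take_b] <- pb$mask[take_b]
      take_b <- runif(n) < 0.5
      child$split[take_b] <- pb$split[take_b]
    }
    if (freeze != "mask")
      child$mask <- xor(child$mask, runif(p) < mut)
    if (freeze != "split")
      child$split <- xor(child$split, runif(n) < mut)
    if (freeze == "mask") child$mask <- pa$mask
    if (freeze == "split") child$split <- pa$split
    nxt[[length(nxt) + 1]] <- repair_chromosome(child, n,
                                                config$split_balance_tol)
  }
  nxt
}

ga_loop <- function(population, X, y, config, mlp, generations, freeze,
                    cache) {
  best <- NULL; best_fit <- -Inf; trajectory <- numeric(0)
  key_of <- function(ch) paste(c(ch$mask, ch$split), collapse = "")
  for (g in seq_len(generations)) {
    fitnesses <- vapply(population, function(ch) {
      k <- key_of(ch)
      if (!is.null(cache[[k]])) return(cache[[k]])
      f <- evaluate_fitness(ch, X, y, config, mlp)
      cache[[k]] <- f
      f
    }, numeric(1))
    gen_best <- which.max(fitnesses)
    if (fitnesses[gen_best] > best_fit) {
      best_fit <- fitnesses[gen_best]; best <- population[[gen_best]]
    }
    trajectory <- c(trajectory, best_fit)
    if (g < generations) population <- evolve(population, fitnesses, config,
                                              freeze)
  }
  list(best = best, best_fit = best_fit, trajectory = trajectory,
       population = population)
}

#' Run the joint input-selection / split-matching GA
#'
#' @param X data.frame / matrix of candidate variables (columns named)
#' @param y target vector (measured REE, kcal/day)
#' @param config a [ga_config()]
#' @param mlp an [mlp_spec()] used inside the fitness function
#' @return a `selection_result` list: `selected_features`, `split_plan`
#'   (logical, `TRUE` = half A), `fitness_trajectory` (best-so-far per
#'   generation, non-decreasing), `final_fitness`, `config`
#' @export
run_twist <- function(X, y, config = ga_config(), mlp = mlp_spec()) {
  X <- as.data.frame(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 20) abort_config("run_twist: need at least 20 records")
  if (p < 1) abort_config("run_twist: need at least 1 candidate variable")
  if (length(y) != n) abort_config("run_twist: y must match rows of X")
  cache <- new.env(parent = emptyenv())
  with_seed(config$seed, {
    population <- replicate(config$population_size,
                            random_chromosome(p, n, config$split_balance_tol),
                            simplify = FALSE)
    if (config$staged) {
      g1 <- max(1L, config$generations %/% 2L)
      population <- lapply(population, function(ch) {
        ch$mask <- rep(TRUE, p); ch
      })
      stage1 <- ga_loop(population, X, y, config, mlp, g1, "mask", cache)
      population <- lapply(stage1$population, function(ch) {
        ch$split <- stage1$best$split; ch
      })
      stage2 <- ga_loop(population, X, y, config, mlp,
                        config$generations - g1 + 1L, "split", cache)
      res <- stage2
      res$trajectory <- c(stage1$trajectory, stage2$trajectory[-1])
    } else {
      res <- ga_loop(population, X, y, config, mlp, config$generations,
                     "none", cache)
    }
    structure(list(selected_features = colnames(X)[res$best$mask],
                   split_plan = res$best$split,
                   fitness_trajectory = cummax(res$trajectory),
                   final_fitness = res$best_fit,
                   config = config),
              class = "selection_result")
  })
}
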