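test_that("distribution similarity: zero on identical halves, KS/proportion parts", {
  d <- data.frame(x = rnorm(30), b = rbinom(30, 1, 0.4))
  dup <- rbind(d, d)
  split <- c(rep(TRUE, 30), rep(FALSE, 30))
  expect_equal(distribution_similarity(dup, split), 0)

  bin <- data.frame(b = c(rep(0, 10), rep(1, 10)))
  expect_equal(distribution_similarity(bin, rep(c(TRUE, FALSE), each = 10)), 1)

  six <- data.frame(v = 1:6)
  expect_equal(distribution_similarity(six, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 1)

  expect_error(distribution_similarity(d, rep(TRUE, 30)),
               class = "picuree_domain_error")
})

test_that("KS statistic agrees with a brute-force double loop", {
  brute <- function(a, b) {
    grid <- c(a, b)
    max(sapply(grid, function(g) abs(mean(a <= g) - mean(b <= g))))
  }
  set.seed(5)
  for (i in 1:10) {
    a <- sample(round(rnorm(12), 1))          # ties on purpose
    b <- sample(round(rnorm(15, 0.3), 1))
    expect_equal(picuree:::ks_statistic(a, b), brute(a, b))
  }
})

test_that("fitness: learnable identity scores near-perfect, penalties bite", {
  set.seed(2)
  n <- 60
  X <- data.frame(x = runif(n, 10, 20), junk = rnorm(n))
  y <- X$x
  chrom <- list(mask = c(TRUE, FALSE),
                split = rep(c(TRUE, FALSE), length.out = n))
  cfg <- ga_config(seed = 1, distribution_penalty_weight = 0)
  f <- evaluate_fitness(chrom, X, y, cfg, mlp_spec(seed = 1))
  expect_gt(f, -0.05 * sd(y))   # neg-MAE close to the 0 optimum

  # a deliberately skewed split is strictly worse once the penalty is on
  skew <- list(mask = c(TRUE, FALSE),
               split = c(rep(TRUE, n / 2), rep(FALSE, n / 2)))
  X_ord <- X[order(X$x), , drop = FALSE]; y_ord <- X_ord$x
  cfg_pen <- ga_config(seed = 1, distribution_penalty_weight = 10)
  f0 <- evaluate_fitness(skew, X_ord, y_ord, cfg, fast_mlp(seed = 1))
  fp <- evaluate_fitness(skew, X_ord, y_ord, cfg_pen, fast_mlp(seed = 1))
  expect_lt(fp, f0)

  # masks without informative features score significantly worse (5 seeds)
  co <- cached_cohort(seed = 8)[1:120, ]
  Xg <- co[, c("vo2", "vco2", "caucasian")]
  diffs <- sapply(1:5, function(s) {
    sp <- rep(c(TRUE, FALSE), 60)
    full <- evaluate_fitness(list(mask = c(TRUE, TRUE, FALSE), split = sp),
                             Xg, co$true_ree, cfg, fast_mlp(seed = s))
    none <- evaluate_fitness(list(mask = c(FALSE, FALSE, TRUE), split = sp),
                             Xg, co$true_ree, cfg, fast_mlp(seed = s))
    full - none
  })
  expect_true(all(diffs > 0))
})

test_that("GA generation operator: no-op settings, elitism, determinism", {
  set.seed(3)
  n <- 20; p <- 4
  pop <- replicate(6, picuree:::random_chromosome(p, n, 0.1), simplify = FALSE)
  fit <- c(5, 3, 8, 1, 2, 7)
  cfg <- ga_config(population_size = 6, generations = 2, crossover_rate = 0,
                   mutation_rate = 0, elitism_count = 2, seed = 1)
  nxt <- evolve(pop, fit, cfg)
  keys <- sapply(pop, function(ch) paste(c(ch$mask, ch$split), collapse = ""))
  expect_true(all(sapply(nxt, function(ch)
    paste(c(ch$mask, ch$split), collapse = "") %in% keys)))
  # elites are the two best, unchanged
  expect_identical(nxt[[1]], pop[[3]])
  expect_identical(nxt[[2]], pop[[6]])

  set.seed(7); a <- evolve(pop, fit, cfg)
  set.seed(7); b <- evolve(pop, fit, cfg)
  expect_identical(a, b)
})

test_that("run_twist: reproducible, monotone trajectory, balanced split", {
  co <- cached_cohort(seed = 9)[1:60, ]
  X <- co[, c("vo2", "vco2", "weight", "crp")]
  y <- co$true_ree
  cfg <- ga_config(population_size = 8, generations = 5, seed = 21)
  r1 <- run_twist(X, y, cfg, fast_mlp(seed = 2))
  r2 <- run_twist(X, y, cfg, fast_mlp(seed = 2))
  expect_identical(r1, r2)
  expect_false(is.unsorted(r1$fitness_trajectory))
  expect_length(r1$fitness_trajectory, 5)
  na <- sum(r1$split_plan)
  expect_true(na >= 0.45 * 60 && na <= 0.55 * 60)
  expect_true(all(r1$selected_features %in% names(X)))

  # single-candidate run selects that candidate
  r3 <- run_twist(X[, "vo2", drop = FALSE], y,
                  ga_config(population_size = 6, generations = 2, seed = 1),
                  fast_mlp(seed = 1))
  expect_equal(r3$selected_features, "vo2")

  expect_error(run_twist(X[1:10, ], y[1:10], cfg),
               class = "picuree_config_error")
})

test_that("distribution penalty yields better-matched splits than random", {
  co <- cached_cohort(seed = 10)[1:60, ]
  X <- co[, c("weight", "vo2")]
  y <- co$true_ree
  sims <- sapply(1:10, function(s) {
    r <- run_twist(X, y, ga_config(population_size = 8, generations = 4,
                                   seed = s, distribution_penalty_weight = 5),
                   fast_mlp(seed = s))
    set.seed(s)
    rand <- sample(rep(c(TRUE, FALSE), 30))
    c(ga = distribution_similarity(cbind(X, y), r$split_plan),
      random = distribution_similarity(cbind(X, y), rand))
  })
  expect_lte(mean(sims["ga", ]), mean(sims["random", ]))
})
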