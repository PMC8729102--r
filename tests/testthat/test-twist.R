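test_that("the backprop net separates a separable toy problem", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100, -2, 0.5), 50, 2),
             matrix(rnorm(100, 2, 0.5), 50, 2))
  y <- rep(c(0, 1), each = 50)
  fit <- train_mlp(X, y, mlp_spec(epochs = 500, seed = 3))
  expect_equal(mean(predict(fit, X, type = "class") == y), 1)
  # sine preset behaves the same on this task
  fit_s <- train_mlp(X, y, mlp_preset_sine())
  expect_gt(mean(predict(fit_s, X, type = "class") == y), 0.95)
  expect_error(train_mlp(X, rep(0, 100)), "single class")
})

test_that("training is deterministic given the seed", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4); y <- rbinom(50, 1, 0.5)
  f1 <- train_mlp(X, y, mlp_spec(seed = 7))
  f2 <- train_mlp(X, y, mlp_spec(seed = 7))
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$W2, f2$W2)
  f3 <- train_mlp(X, y, mlp_spec(seed = 8))
  expect_false(identical(f1$W1, f3$W1))
})

test_that("held-out accuracy under permuted labels stays near chance", {
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(400 * 4), 400, 4)
    y <- rbinom(400, 1, 0.5)
    tr <- sample(400, 200)
    fit <- train_mlp(X[tr, ], y[tr], mlp_spec(epochs = 100, seed = s))
    mean(predict(fit, X[-tr, ], type = "class") == y[-tr])
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("ROC AUC follows the rank formulation with half-credit ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("ab/ba fitness is the mean of the two half evaluations", {
  set.seed(3)
  X <- matrix(rnorm(80), 40, 2); colnames(X) <- c("a", "b")
  y <- rep(c(0, 1), 20)
  cand <- list(mask = c(TRUE, TRUE), split = rep(c(TRUE, FALSE), each = 20))
  f <- evaluate_ab_ba(cand, X, y, mlp_spec(epochs = 50, seed = 1))
  expect_gte(f, 0); expect_lte(f, 1)
  # identical halves with a deterministic learner give symmetric fitness
  Xd <- rbind(X[1:20, ], X[1:20, ])
  yd <- c(y[1:20], y[1:20])
  cd <- list(mask = c(TRUE, TRUE), split = rep(c(TRUE, FALSE), each = 20))
  fit_a <- train_mlp(Xd[1:20, ], yd[1:20], mlp_spec(epochs = 50, seed = 1))
  acc_ab <- mean((predict(fit_a, Xd[21:40, ]) > 0.5) == (yd[21:40] == 1))
  fit_b <- train_mlp(Xd[21:40, ], yd[21:40], mlp_spec(epochs = 50, seed = 1))
  acc_ba <- mean((predict(fit_b, Xd[1:20, ]) > 0.5) == (yd[1:20] == 1))
  expect_equal(acc_ab, acc_ba)
  expect_equal(evaluate_ab_ba(cd, Xd, yd, mlp_spec(epochs = 50, seed = 1)),
               (acc_ab + acc_ba) / 2)
  # a split half lacking a class is penalised to zero
  bad <- list(mask = c(TRUE, TRUE),
              split = y == 1)
  expect_message(f0 <- evaluate_ab_ba(bad, X, y, mlp_spec(epochs = 10)),
                 "lacks")
  expect_equal(f0, 0)
})

test_that("all-noise features score near chance under ab/ba", {
  set.seed(4)
  X <- matrix(rnorm(400 * 3), 400, 3)
  y <- rbinom(400, 1, 0.5)
  cand <- list(mask = rep(TRUE, 3), split = rep(c(TRUE, FALSE), 200))
  f <- evaluate_ab_ba(cand, X, y, mlp_spec(epochs = 80, seed = 2))
  expect_gt(f, 0.38); expect_lt(f, 0.62)
})

test_that("the GA respects its contracts: elitism, fixed point, degenerate input", {
  dat <- make_planted_logistic(n = 80, p_inf = 2, p_noise = 2, beta = 2,
                               seed = 5)
  tw <- twist_run(dat$X, dat$y,
                  ga = ga_spec(population_size = 8, generations = 6, seed = 5),
                  mlp = mlp_spec(epochs = 40, seed = 1))
  expect_true(all(diff(tw$history) >= 0))      # elite never decreases
  expect_gte(sum(tw$mask), 1)
  # single feature: no search, that feature is the mask
  tw1 <- twist_run(dat$X[, 1, drop = FALSE], dat$y,
                   ga = ga_spec(population_size = 4, generations = 2, seed = 1),
                   mlp = mlp_spec(epochs = 30, seed = 1))
  expect_equal(unname(tw1$mask), TRUE)
  expect_error(twist_run(dat$X[1:10, ], dat$y[1:10]), "20 records")
  expect_error(ga_spec(population_size = 1), "population_size")
  expect_error(ga_spec(mutation_rate = 1.5), "rates")
})

test_that("selection beats the all-features baseline on planted data", {
  dat <- make_planted_logistic(n = 200, p_inf = 2, p_noise = 6, beta = 2,
                               seed = 6)
  mlp <- mlp_spec(epochs = 50, seed = 1)
  tw <- twist_run(dat$X, dat$y,
                  ga = ga_spec(population_size = 10, generations = 8, seed = 6),
                  mlp = mlp)
  base <- list(mask = rep(TRUE, ncol(dat$X)),
               split = rep(c(TRUE, FALSE), length.out = nrow(dat$X)))
  f_base <- evaluate_ab_ba(base, dat$X, dat$y, mlp)
  expect_gte(tw$fitness, f_base)
})

test_that("twist results are reproducible for a fixed seed", {
  dat <- make_planted_logistic(n = 100, p_inf = 2, p_noise = 3, seed = 7)
  ga <- ga_spec(population_size = 6, generations = 4, seed = 11)
  mlp <- mlp_spec(epochs = 30, seed = 2)
  t1 <- twist_run(dat$X, dat$y, ga, mlp)
  t2 <- twist_run(dat$X, dat$y, ga, mlp)
  expect_identical(t1$mask, t2$mask)
  expect_identical(t1$fitness, t2$fitness)
  expect_identical(t1$history, t2$history)
})
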