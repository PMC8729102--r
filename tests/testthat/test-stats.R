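test_that("Mann-Whitney U and exact enumeration match hand results", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-9)
  # identical multisets sit at the null centre
  r2 <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r2$statistic, 3 * 3 / 2)
  # agreement with wilcox.test on tie-free data
  set.seed(1)
  x <- rnorm(4); y <- rnorm(5)
  ours <- mann_whitney(x, y, method = "exact")
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney detects a one-SD shift with high power", {
  set.seed(2)
  rej <- mean(vapply(1:400, function(i) {
    mann_whitney(rnorm(50), rnorm(50, 1))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.9)
})

test_that("tests are invariant to observation order", {
  set.seed(3)
  x <- rnorm(12); y <- rnorm(15)
  expect_equal(mann_whitney(x, y)$p_value,
               mann_whitney(sample(x), sample(y))$p_value)
  expect_equal(pearson_r(x[1:12], y[1:12])$statistic,
               pearson_r(rev(x[1:12]), rev(y[1:12]))$statistic)
})

test_that("Friedman matches hand-ranked arithmetic and its edge cases", {
  m <- matrix(c(1, 2, 3, 2, 4, 6, 1, 5, 9), 3, 3, byrow = TRUE)
  r <- friedman(m)
  expect_equal(r$statistic, 6)
  expect_equal(r$df, 2)
  # fully tied rows carry no information
  expect_equal(friedman(matrix(5, 3, 3))$statistic, 0)
  # rank-based: invariant to monotone transforms of each row
  expect_equal(friedman(exp(m))$statistic, r$statistic)
  expect_error(friedman(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(friedman(matrix(1:3, 1, 3)), "2 subjects")
})

test_that("logistic regression yields Wald ORs and guards its domain", {
  set.seed(4)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.9 * x))
  fit <- logistic_fit(data.frame(x = x), y)
  co <- fit$coef[fit$coef$term == "x", ]
  expect_true(co$ci_lo <= co$or && co$or <= co$ci_hi)
  expect_equal(co$or, exp(co$estimate))
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(co$estimate), unname(coef(ref)["x"]), tolerance = 1e-8)
  expect_error(logistic_fit(data.frame(z = rep(1, n)), y), "constant")
  expect_error(logistic_fit(data.frame(a = x, b = 2 * x), y),
               "rank deficient")
  # perfect separation is reported with the covariate name
  xs <- c(rnorm(50, -4), rnorm(50, 4))
  ys <- rep(c(0, 1), each = 50)
  expect_error(logistic_fit(data.frame(sep = xs), ys), "sep")
})

test_that("a single binary covariate reproduces the 2x2 odds ratio", {
  a <- 18; b <- 32; c <- 7; d <- 43
  x <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  fit <- logistic_fit(data.frame(exposed = x), y)
  or_glm <- unname(fit$coef$or[fit$coef$term == "exposed"])
  or_tab <- two_by_two_or(a, b, c, d)$statistic
  expect_equal(or_glm, or_tab, tolerance = 1e-6)
})

test_that("2x2 odds ratios follow Woolf with Haldane correction", {
  expect_equal(two_by_two_or(10, 5, 5, 10)$statistic, 4)
  expect_equal(two_by_two_or(7, 7, 7, 7)$statistic, 1)
  r0 <- two_by_two_or(0, 12, 9, 30)
  expect_equal(r0$statistic, (0.5 * 30.5) / (12.5 * 9.5))
  expect_error(two_by_two_or(0, 0, 5, 5), "undefined")
  expect_error(two_by_two_or(0, 5, 0, 5), "undefined")
  ci <- two_by_two_or(10, 5, 5, 10)$coef
  expect_true(ci$ci_lo <= 4 && 4 <= ci$ci_hi)
})

test_that("Pearson correlation matches hand arithmetic and its domain", {
  expect_equal(pearson_r(1:10, 1:10)$statistic, 1)
  expect_equal(pearson_r(1:10, -(1:10))$statistic, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$statistic, 0.8)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("roc_auc equals the normalised Mann-Whitney U statistic", {
  set.seed(5)
  for (r in 1:5) {
    sc <- round(runif(30), 2)   # include ties
    lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    u <- mann_whitney(sc[lb == 1], sc[lb == 0])$statistic
    expect_equal(roc_auc(sc, lb), u / (sum(lb == 1) * sum(lb == 0)))
  }
})

test_that("drop-out group comparisons split the cohort as labelled", {
  co <- synthetic_flowchart_cohort()
  cmp12 <- dropout_comparison(co, grouping = "m12", vars = c("bmi", "fai"))
  expect_equal(nrow(cmp12), 2)
  expect_true(all(cmp12$p >= 0 & cmp12$p <= 1))
  tt <- dropout_two_by_two(co)
  expect_equal(sum(tt$table), 99)  # 108 minus 9 pregnancies
})
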