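# Classical inference stages. Two-sided p-values throughout, no
# multiplicity correction (none is used in the analysis protocol this
# package implements). Confidence intervals on odds ratios are Wald
# intervals.

fit_result <- function(statistic, p_value, df = NULL, coef = NULL,
                       method = NULL) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = df, coef = coef, method = method),
            class = "pcos_fit")
}

#' @export
print.pcos_fit <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n",
              x$method %||% "test", x$statistic, x$p_value,
              if (!is.null(x$df)) sprintf(", df = %g", x$df) else ""))
  if (!is.null(x$coef)) print(x$coef)
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U counts the pairs where an `x` outranks a `y` (ties one half). The
#' p-value is by exhaustive enumeration of all group assignments when
#' `n1 + n2 <= 10` (valid with ties), and by the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @param method `"auto"` (enumeration for small samples), `"exact"`, or
#'   `"normal"`.
#' @return A `pcos_fit` with the U statistic and two-sided p-value.
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0)
    stop_domain("mann_whitney: both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto") method <- if (n <= 10) "exact" else "normal"
  if (method == "exact") {
    combs <- combn(n, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) { p <- 1 } else {
      # continuity-corrected z, as usual for the discrete U distribution
      z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
  }
  fit_result(U, p, method = sprintf("Mann-Whitney (%s)", method))
}

#' Friedman rank test for correlated samples
#'
#' Two-way rank analysis of variance across within-subject conditions,
#' with the standard tie correction (delegated to
#' [stats::friedman.test()]). Rows whose conditions are all tied carry no
#' rank information; a matrix in which every row is constant returns
#' statistic 0.
#'
#' @param matrix Numeric matrix, subjects x conditions (>= 2 each), no
#'   missing cells (listwise deletion is the caller's job).
#' @return A `pcos_fit` with the chi-square statistic, df = k - 1.
#' @export
friedman <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_domain("friedman: need >= 2 subjects and >= 2 conditions")
  if (any(is.na(m)))
    stop_domain("friedman: missing cells are not allowed")
  if (all(apply(m, 1, function(r) max(r) == min(r))))
    return(fit_result(0, 1, df = ncol(m) - 1, method = "Friedman"))
  ft <- stats::friedman.test(m)
  fit_result(ft$statistic, ft$p.value, df = unname(ft$parameter),
             method = "Friedman")
}

#' Multivariate logistic regression with odds ratios
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()], log-likelihood tolerance 1e-8) with per-covariate odds
#' ratios, Wald 95% confidence intervals and Wald p-values. Constant or
#' collinear covariates and perfectly separating fits raise errors naming
#' the covariate.
#'
#' @param X Covariate data frame or matrix.
#' @param y Binary 0/1 outcome with both classes, `length(y) > ncol(X)`.
#' @param conf_level Confidence level for the Wald intervals.
#' @return A `pcos_fit`; `$coef` is a tibble (term, estimate, se, or,
#'   ci_lo, ci_hi, p) including the intercept.
#' @export
logistic_fit <- function(X, y, conf_level = 0.95) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop_domain("logistic_fit: y must be binary with both classes")
  if (length(y) <= ncol(X))
    stop_domain("logistic_fit: need more observations than covariates")
  for (nm in names(X)) {
    v <- X[[nm]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop_domain("logistic_fit: covariate '%s' is constant", nm)
  }
  mm <- stats::model.matrix(~ ., X)
  if (qr(mm)$rank < ncol(mm))
    stop_domain("logistic_fit: covariates are rank deficient (collinear)")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = X,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  if (sep_warn) {
    est <- sm[-1, "Estimate"]
    sds <- vapply(X, function(v) sd(as.numeric(v)), numeric(1))
    worst <- names(which.max(abs(est * sds)))
    if (max(abs(est * sds)) > 10)
      stop_domain("logistic_fit: perfect separation on covariate '%s'", worst)
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  coef_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    or = exp(sm[, "Estimate"]),
    ci_lo = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_hi = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p = sm[, "Pr(>|z|)"]
  )
  fit_result(fit$deviance, NA_real_, df = fit$df.residual, coef = coef_tbl,
             method = "logistic regression (IRLS)")
}

#' Odds ratio of a 2x2 risk table
#'
#' Counts are exposed/unexposed (rows) by event/no-event: `a` exposed
#' events, `b` exposed non-events, `c` unexposed events, `d` unexposed
#' non-events. OR = ad/bc with a Woolf (log) confidence interval; when
#' any cell is zero the Haldane-Anscombe 0.5 correction is added to every
#' cell. A zero row or column leaves the OR undefined (error).
#'
#' @param a,b,c,d Non-negative counts.
#' @param conf_level Confidence level.
#' @return A `pcos_fit`; `$coef` holds the OR and its Wald interval.
#' @export
two_by_two_or <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop_domain("two_by_two_or: counts must be >= 0")
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop_domain("two_by_two_or: a zero row or column leaves the OR undefined")
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  zstat <- log(or) / se
  coef_tbl <- tibble::tibble(
    term = "exposure", estimate = log(or), se = se, or = unname(or),
    ci_lo = unname(exp(log(or) - z * se)),
    ci_hi = unname(exp(log(or) + z * se)),
    p = unname(min(1, 2 * pnorm(-abs(zstat)))))
  fit_result(unname(or), coef_tbl$p, coef = coef_tbl,
             method = "2x2 odds ratio (Woolf)")
}

#' Pearson product-moment correlation
#'
#' With a t-approximation p-value; equals the point-biserial correlation
#' when one input is binary. Delegates to [stats::cor.test()].
#'
#' @param x,y Numeric vectors, `n >= 3`, neither constant.
#' @return A `pcos_fit` with the correlation as statistic.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_domain("pearson_r: need paired samples with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop_domain("pearson_r: constant input")
  ct <- stats::cor.test(x, y)
  fit_result(unname(ct$estimate), ct$p.value,
             df = unname(ct$parameter), method = "Pearson r")
}

#' Baseline comparison of completers and discontinuers
#'
#' Mann-Whitney comparison of baseline parameters between the women who
#' stayed on treatment and those who discontinued. Two published-style
#' groupings are supported: `"m6"` compares patients assessed at 6 months
#' with first-interval drop-outs, `"m12"` compares 12-month completers
#' with all discontinuers; pregnancies are excluded from both.
#'
#' @param cohort A `pcos_cohort`.
#' @param grouping `"m12"` (default) or `"m6"`.
#' @param vars Baseline variables to compare.
#' @return A tibble: variable, group means/SDs, and Mann-Whitney p.
#' @export
dropout_comparison <- function(cohort, grouping = c("m12", "m6"),
                               vars = c("weight_kg", "bmi", "glucose",
                                        "insulin", "homa_ir", "tc", "ldl",
                                        "hdl", "tg", "whr", "t_ngml", "shbg",
                                        "fai", "a4", "dheas", "fg", "lh_fsh",
                                        "menses6", "afc")) {
  grouping <- match.arg(grouping)
  cohort <- derive_indices(cohort)
  m0 <- cohort[cohort$visit == "m0" & cohort$status != "pregnant", ]
  dropped <- m0$status %in% c("dropout_side_effects", "dropout_no_benefit",
                              "lost_followup")
  grp <- if (grouping == "m6") {
    # 6-month framing: everyone assessed at m6 vs first-interval drop-outs
    ifelse(dropped & m0$dropout_interval == "m0_m6", "dropout", "on_treatment")
  } else {
    # 12-month framing: completers vs all discontinuers
    ifelse(dropped, "dropout", "on_treatment")
  }
  rows <- lapply(vars, function(v) {
    x <- m0[[v]][grp == "on_treatment"]; yv <- m0[[v]][grp == "dropout"]
    x <- x[!is.na(x)]; yv <- yv[!is.na(yv)]
    if (!length(x) || !length(yv)) return(NULL)
    mw <- mann_whitney(x, yv, method = "normal")
    tibble::tibble(variable = v,
                   mean_on_treatment = mean(x), sd_on_treatment = sd(x),
                   mean_dropout = mean(yv), sd_dropout = sd(yv),
                   p = mw$p_value)
  })
  dplyr::bind_rows(rows)
}

#' Drop-out risk table for low baseline testosterone
#'
#' Builds the 2x2 table (baseline T below `t_cutoff` x drop-out) over
#' non-pregnant patients and returns its odds ratio.
#'
#' @param cohort A `pcos_cohort`.
#' @param t_cutoff Testosterone threshold in ng/mL (default 0.90).
#' @return A `pcos_fit` from [two_by_two_or()], with the table in
#'   `$table`.
#' @export
dropout_two_by_two <- function(cohort, t_cutoff = 0.90) {
  m0 <- cohort[cohort$visit == "m0" & cohort$status != "pregnant", ]
  low <- m0$t_ngml < t_cutoff
  drop <- m0$status %in% c("dropout_side_effects", "dropout_no_benefit",
                           "lost_followup")
  res <- two_by_two_or(sum(low & drop), sum(low & !drop),
                       sum(!low & drop), sum(!low & !drop))
  res$table <- c(a = sum(low & drop), b = sum(low & !drop),
                 c = sum(!low & drop), d = sum(!low & !drop))
  res
}
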