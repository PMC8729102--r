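test_that("cutoffs are sample medians with degenerate flagging", {
  df <- tibble::tibble(fai = c(1, 2, 3, 4), glucose = c(90, 90, 90, 90))
  ct <- compute_cutoffs(df, vars = c("fai", "glucose"))
  expect_equal(ct$cutoff[ct$variable == "fai"], 2.5)
  expect_true(ct$degenerate[ct$variable == "glucose"])
  expect_equal(ct$cutoff[ct$variable == "glucose"], 90)
  expect_warning(
    compute_cutoffs(tibble::tibble(fai = 1:4, tg = NA_real_),
                    vars = c("fai", "tg")), "all-missing")
})

test_that("study-style medians reproduce the published map thresholds", {
  # engineered baseline whose per-variable medians sit at the published
  # HIGH/LOW captions: FAI 9, FG 12, HOMA 4, TRIGL 110, GLIC 90, DHEA 270,
  # BMI 32, CYCL 2
  n <- 30
  mk <- function(med, spread) med + spread * scale(seq_len(n))[, 1]
  df <- tibble::tibble(
    fai = mk(9, 3), fg = round(mk(12, 4)), homa_ir = mk(4, 1),
    tg = mk(110, 30), glucose = mk(90, 8), dheas = mk(270, 60),
    bmi = mk(32, 4), menses6 = round(mk(2, 1)))
  ct <- compute_cutoffs(df, vars = names(df))
  expect_equal(setNames(ct$cutoff, ct$variable),
               c(fai = 9, fg = 12, homa_ir = 4, tg = 110, glucose = 90,
                 dheas = 270, bmi = 32, menses6 = 2))
  expect_equal(ct$high_label[ct$variable == "menses6"], "CYCL_HIGH")
})

test_that("dichotomization assigns HIGH strictly above the cutoff, ties LOW", {
  co <- tiny_cohort(list(P1 = c("m0", "m6"), P2 = c("m0", "m6"),
                         P3 = c("m0", "m6")),
                    bmi = list(P1 = list(m0 = 33, m6 = 31),
                               P2 = list(m0 = 33, m6 = 33),
                               P3 = list(m0 = 34, m6 = 30)),
                    fai = list(P1 = list(m0 = 13, m6 = 11),
                               P2 = list(m0 = 8, m6 = 9),
                               P3 = list(m0 = 13, m6 = 10)),
                    status = list(P1 = "dropout_no_benefit",
                                  P2 = "dropout_no_benefit",
                                  P3 = "dropout_no_benefit"),
                    interval = list(P1 = "m6_m12", P2 = "m6_m12",
                                    P3 = "m6_m12"))
  co <- derive_indices(co)
  ct <- compute_cutoffs(co[co$visit == "m0", ],
                        vars = c("fai", "menses6", "glucose"))
  X <- dichotomize_matrix(co, ct, outcome = "bmi", visit = "m6")
  # FAI cutoff is 13 (median of 13, 8, 13): P2 below -> LOW, ties -> LOW
  expect_equal(unname(X[, "FAI_HIGH"]), c(0, 0, 0))
  expect_equal(unname(X[, "FAI_LOW"]), c(1, 1, 1))
  # complementarity per variable and for the outcome pole
  for (v in c("FAI", "CYCL", "GLIC"))
    expect_equal(unname(X[, paste0(v, "_HIGH")] + X[, paste0(v, "_LOW")]),
                 rep(1, 3))
  expect_equal(unname(X[, "RESPONDER"] + X[, "NON_RESPONDER"]), rep(1, 3))
  expect_equal(unname(X[, "RESPONDER"]), c(1, 0, 1))
})

test_that("published caption semantics hold: FAI 13 vs cutoff 9 is HIGH, menses 1 vs 2 is LOW", {
  df <- tibble::tibble(fai = c(13, 5), menses6 = c(1, 4))
  ct <- tibble::tibble(variable = c("fai", "menses6"), cutoff = c(9, 2),
                       high_label = c("FAI_HIGH", "CYCL_HIGH"),
                       low_label = c("FAI_LOW", "CYCL_LOW"),
                       degenerate = FALSE)
  hi <- as.integer(df$fai > ct$cutoff[1])
  expect_equal(hi, c(1, 0))
  expect_equal(as.integer(df$menses6[1] <= ct$cutoff[2]), 1L)  # CYCL_LOW
})

test_that("already-binary data with cutoff 0 reproduces itself as HIGH", {
  x <- c(0, 1, 1, 0, 1)
  hi <- as.integer(x > 0)
  expect_equal(hi, x)
  expect_equal(1L - hi, as.integer(!x))
})
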