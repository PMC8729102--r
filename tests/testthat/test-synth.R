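test_that("generation is deterministic and n-invariant in its prefixes", {
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "ground_truth") <- NULL
    rownames(x) <- NULL
    x
  }
  c1 <- generate_cohort(cohort_config(n = 60, seed = 11))
  c2 <- generate_cohort(cohort_config(n = 60, seed = 11))
  expect_identical(strip(c1), strip(c2))
  c3 <- generate_cohort(cohort_config(n = 90, seed = 11))
  shared <- intersect(unique(c1$patient_id), unique(c3$patient_id))
  expect_equal(strip(c1[c1$patient_id %in% shared, ]),
               strip(c3[c3$patient_id %in% shared, ]))
  expect_false(identical(strip(c1),
                         strip(generate_cohort(cohort_config(n = 60, seed = 12)))))
})

test_that("baseline marginals recover their target moments", {
  cfg <- cohort_config(n = 4000, seed = 21)
  bl <- generate_baseline(cfg)
  bl$whr <- bl$waist / bl$hip
  bl$lh_fsh <- bl$lh / bl$fsh
  spec <- cfg$baseline_spec
  for (k in seq_len(nrow(spec))) {
    x <- bl[[spec$var[k]]]
    expect_lt(abs(mean(x) - spec$mean[k]), 3 * spec$sd[k] / sqrt(cfg$n))
  }
  # weight mean within 2 SE of the target; HOMA-IR median near its target
  expect_lt(abs(mean(bl$weight_kg) - 87.2), 2 * 18.18 / sqrt(cfg$n))
  bl <- derive_indices(bl)
  expect_lt(abs(median(bl$homa_ir) - 4), 0.2)
})

test_that("an infeasible correlation matrix is rejected with its pairs", {
  cs <- tibble::tribble(~var1, ~var2, ~rho,
                        "glucose", "insulin", 0.99,
                        "glucose", "tg", 0.99,
                        "insulin", "tg", -0.99)
  cfg <- cohort_config(n = 10, seed = 1, correlation_spec = cs)
  expect_error(generate_baseline(cfg), "positive definite")
  expect_error(cohort_config(correlation_spec = tibble::tibble(
    var1 = "glucose", var2 = "insulin", rho = 1.2)), "rho")
})

test_that("planted response model drives the responder rate and its null", {
  cfg <- cohort_config(n = 3000, seed = 31)
  lg <- generate_longitudinal(generate_baseline(cfg), cfg)
  gt <- ground_truth(lg)
  expect_gt(mean(gt$responder_bmi), 0.4)
  expect_lt(mean(gt$responder_bmi), 0.6)
  # responders get a planted BMI drop of at least 1 by construction
  d <- derive_indices(lg)
  b0 <- d$bmi[d$visit == "m0"]; b6 <- d$bmi[d$visit == "m6"]
  drop6 <- (b0 - b6)[gt$responder_bmi]
  expect_true(all(drop6 >= 1 - 1e-9))
  # null model: response independent of the dichotomized baseline
  cfg0 <- cohort_config(n = 1500, seed = 32,
                        response_model_bmi = c(b0 = 0, cycl_low = 0,
                                               fai_high = 0, fg_high = 0,
                                               homa_high = 0))
  lg0 <- generate_longitudinal(generate_baseline(cfg0), cfg0)
  gt0 <- ground_truth(lg0)
  m0 <- derive_indices(lg0[lg0$visit == "m0", ])
  tab <- table(m0$menses6 <= 2, gt0$responder_bmi)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("drop-out process matches its planted odds ratio and edge cases", {
  co <- generate_cohort(cohort_config(n = 5000, seed = 41))
  m0 <- co[co$visit == "m0", ]
  low <- m0$t_ngml < 0.90
  dr <- m0$status %in% dropped_status
  or_emp <- (sum(low & dr) * sum(!low & !dr)) / (sum(low & !dr) * sum(!low & dr))
  expect_lt(abs(or_emp - 6.5) / 6.5, 0.2)
  # null coefficient: OR near 1
  cfg0 <- cohort_config(n = 5000, seed = 42,
                        dropout_model = list(gamma0 = log(0.25),
                                             gamma_lowT = 0, t_cutoff = 0.9))
  co0 <- generate_cohort(cfg0)
  m00 <- co0[co0$visit == "m0", ]
  low0 <- m00$t_ngml < 0.9; dr0 <- m00$status %in% dropped_status
  or0 <- (sum(low0 & dr0) * sum(!low0 & !dr0)) /
    (sum(low0 & !dr0) * sum(!low0 & dr0))
  expect_lt(abs(log(or0)), log(1.35))
  # zero pregnancy rate yields no pregnant records
  cop <- generate_cohort(cohort_config(n = 400, seed = 43, pregnancy_rate = 0))
  expect_false(any(cop$status == "pregnant"))
  # drop-outs are truncated at their interval
  first <- m0$patient_id[m0$dropout_interval == "m0_m6"]
  expect_true(all(co$visit[co$patient_id %in% first] == "m0"))
})

test_that("the generated cohort passes full structural validation", {
  co <- generate_cohort(cohort_config(n = 200, seed = 51))
  expect_s3_class(co, "pcos_cohort")
  expect_silent(as_cohort(tibble::as_tibble(co)))
})
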