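test_that("FAI follows the T x 347 / SHBG definition and its domain", {
  expect_equal(compute_fai(0.60, 34.7), 6.00, tolerance = 1e-12)
  expect_equal(compute_fai(0, 25), 0)
  expect_equal(compute_fai(0.70, 23.1), 10.52, tolerance = 1e-3)
  expect_error(compute_fai(0.5, 0), "SHBG")
  expect_error(compute_fai(-0.1, 20), "testosterone")
  # homogeneous of degree 1 in the numerator hormone
  t0 <- runif(20, 0.1, 2); s0 <- runif(20, 5, 60)
  expect_equal(compute_fai(2 * t0, s0), 2 * compute_fai(t0, s0))
})

test_that("HOMA-IR follows the glucose x 0.05551 x insulin / 22.5 formula", {
  expect_equal(compute_homa_ir(90, 18), 90 * 0.05551 * 18 / 22.5)
  expect_equal(compute_homa_ir(90, 18), 3.9967, tolerance = 1e-4)
  expect_equal(compute_homa_ir(123, 0), 0)
  expect_equal(compute_homa_ir(91.64, 21.03), 4.7546, tolerance = 1e-4)
  expect_error(compute_homa_ir(-1, 10), "glucose")
  g <- runif(20, 60, 120); i <- runif(20, 2, 40)
  expect_equal(compute_homa_ir(g, 2 * i), 2 * compute_homa_ir(g, i))
})

test_that("the derived panel computes BMI, WHR and LH/FSH with strict domains", {
  row <- list(weight_kg = 87.2, glucose = 90, insulin = 18, waist = 100,
              hip = 100, t_ngml = 0.6, shbg = 34.7, lh = 1.44 * 5, fsh = 5)
  d <- compute_derived(row, height_m = 1.63)
  expect_equal(d$bmi, 32.82, tolerance = 1e-3)
  expect_equal(d$whr, 1.0)
  expect_equal(d$lh_fsh, 1.44)
  expect_error(compute_derived(row, height_m = 0), "height")
  row$hip <- 0
  expect_error(compute_derived(row, 1.63), "hip")
})

test_that("derive_indices propagates missing inputs as NA, never zero", {
  co <- tiny_cohort(list(P1 = "m0"), status = list(P1 = "lost_followup"))
  co$shbg <- NA_real_
  d <- derive_indices(co)
  expect_true(is.na(d$fai))
  expect_false(is.na(d$bmi))
})

test_that("responder labels honour the delta >= 1 boundary and eligibility", {
  mk <- function(bmi0, bmi6) tiny_cohort(
    list(P1 = c("m0", "m6")),
    bmi = list(P1 = list(m0 = bmi0, m6 = bmi6)),
    status = list(P1 = "dropout_no_benefit"),
    interval = list(P1 = "m6_m12"))
  expect_true(label_outcomes(mk(32.8, 31.8))$bmi_responder_m6)   # delta = 1.0
  expect_false(label_outcomes(mk(32.8, 31.9))$bmi_responder_m6)  # delta = 0.9
  # FAI below 6 at baseline: never eligible, label undefined
  co <- tiny_cohort(list(P1 = c("m0", "m6")),
                    fai = list(P1 = list(m0 = 5.9, m6 = 3.0)),
                    status = list(P1 = "dropout_no_benefit"),
                    interval = list(P1 = "m6_m12"))
  lab <- label_outcomes(co)
  expect_false(lab$fai_eligible)
  expect_true(is.na(lab$fai_responder_m6))
  # missing visit leaves the label absent, not FALSE
  co2 <- tiny_cohort(list(P1 = "m0"), status = list(P1 = "lost_followup"))
  expect_true(is.na(label_outcomes(co2)$bmi_responder_m6))
})

test_that("increasing the BMI drop never flips responder to non-responder", {
  drops <- sort(runif(15, 0, 3))
  resp <- vapply(drops, function(dl) {
    co <- tiny_cohort(list(P1 = c("m0", "m6")),
                      bmi = list(P1 = list(m0 = 33, m6 = 33 - dl)),
                      status = list(P1 = "dropout_no_benefit"),
                      interval = list(P1 = "m6_m12"))
    label_outcomes(co)$bmi_responder_m6
  }, logical(1))
  expect_true(all(diff(as.integer(resp)) >= 0))
})

test_that("flow report percentages recompute from their own fractions", {
  fr <- flow_report(synthetic_flowchart_cohort(), n_screened = 136)
  r <- fr$rates
  expect_equal(r$percent, round(100 * r$numerator / r$denominator, 1))
  expect_true(all(r$numerator <= r$denominator))
  expect_error(flow_report(tibble::tibble()), "empty")
})

test_that("cohort CSV I/O round-trips and rejects malformed input", {
  co <- tiny_cohort(list(P1 = c("m0", "m6", "m12"), P2 = "m0",
                         P3 = c("m0", "m6")))
  co$extra_note <- paste0("note", seq_len(nrow(co)))  # unknown column survives
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(as.data.frame(back)[names(co)], as.data.frame(co),
               tolerance = 1e-12)

  # m6 without m0 violates the visit-prefix invariant
  bad <- co[!(co$patient_id == "P3" & co$visit == "m0"), ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, f2)
  expect_error(read_cohort_csv(f2), "m0")

  # non-numeric cell is reported with its row
  txt <- readr::read_file(f)
  writeLines(sub("87.2", "oops", sub("^(P1,m0[^\n]*)", "\\1", txt)), f2)
  raw <- readr::read_csv(f, show_col_types = FALSE)
  raw$glucose[2] <- "not-a-number"
  readr::write_csv(raw, f2)
  expect_error(read_cohort_csv(f2), "row")

  # empty file
  f3 <- withr::local_tempfile(fileext = ".csv")
  file.create(f3)
  expect_error(read_cohort_csv(f3), "empty")

  # duplicate patient-visit
  dup <- dplyr::bind_rows(co, co[1, ])
  readr::write_csv(dup, f2)
  expect_error(read_cohort_csv(f2), "duplicate")
})

test_that("structural invariants are enforced by as_cohort", {
  co <- tiny_cohort(list(P1 = c("m0", "m6", "m12")))
  bad <- co; bad$status <- "dropout_no_benefit"  # yet m12 present, not pregnant
  expect_error(as_cohort(bad), "inconsistent")
  bad2 <- co; bad2$menses6 <- 9
  expect_error(as_cohort(bad2), "menses6")
  bad3 <- co; bad3$insulin[1] <- -2
  expect_error(as_cohort(bad3), "insulin")
})
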