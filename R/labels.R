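#' Treatment-response outcome labels
#'
#' The two primary outcomes are a BMI reduction of at least
#' `delta_bmi` kg/m^2 in overweight/obese women (BMI >= `overweight_cutoff`
#' at m0) and an FAI decrease of at least `delta_fai` percentage points in
#' hyperandrogenemic women (FAI >= `fai_cutoff` at m0). The m6 label
#' compares m6 with m0. The m12 label measures *further* improvement,
#' comparing m12 with m6, and is defined for patients who still meet the
#' eligibility criterion at m6. A missing visit leaves the label `NA`
#' (undefined), never `FALSE`.
#'
#' @param cohort A `pcos_cohort` (derived indices are added if absent).
#' @param overweight_cutoff BMI eligibility cutoff, kg/m^2 (default 25,
#'   the WHO overweight threshold).
#' @param fai_cutoff FAI eligibility cutoff, percent (default 6).
#' @param delta_bmi,delta_fai Required improvement per interval.
#' @return A tibble with one row per patient: `patient_id`,
#'   `bmi_eligible`, `fai_eligible`, `bmi_eligible_m6`, `fai_eligible_m6`
#'   (re-assessed eligibility at m6, the m12 denominators), and the four
#'   responder flags `bmi_responder_m6`, `bmi_responder_m12`,
#'   `fai_responder_m6`, `fai_responder_m12` (logical, `NA` = undefined).
#' @export
label_outcomes <- function(cohort, overweight_cutoff = 25, fai_cutoff = 6,
                           delta_bmi = 1, delta_fai = 1) {
  if (!"bmi" %in% names(cohort)) cohort <- derive_indices(cohort)
  wide <- function(var) {
    out <- list()
    for (v in visit_levels) {
      sub <- cohort[cohort$visit == v, c("patient_id", var)]
      out[[v]] <- setNames(sub[[var]], sub$patient_id)
    }
    out
  }
  ids <- unique(cohort$patient_id)
  bmi <- wide("bmi"); fai <- wide("fai")
  at <- function(m, v) unname(m[[v]][ids])

  resp <- function(x0, x1, elig, delta) {
    # small epsilon so a drop of exactly delta counts despite FP round-trips
    ifelse(is.na(elig) | !elig | is.na(x0) | is.na(x1),
           NA, (x0 - x1) >= delta - 1e-9)
  }
  bmi_elig <- !is.na(at(bmi, "m0")) & at(bmi, "m0") >= overweight_cutoff
  fai_elig <- !is.na(at(fai, "m0")) & at(fai, "m0") >= fai_cutoff
  bmi_elig6 <- !is.na(at(bmi, "m6")) & at(bmi, "m6") >= overweight_cutoff
  fai_elig6 <- !is.na(at(fai, "m6")) & at(fai, "m6") >= fai_cutoff

  tibble::tibble(
    patient_id = ids,
    bmi_eligible = bmi_elig,
    fai_eligible = fai_elig,
    bmi_eligible_m6 = bmi_elig6,
    fai_eligible_m6 = fai_elig6,
    bmi_responder_m6 = resp(at(bmi, "m0"), at(bmi, "m6"), bmi_elig, delta_bmi),
    bmi_responder_m12 = resp(at(bmi, "m6"), at(bmi, "m12"), bmi_elig6, delta_bmi),
    fai_responder_m6 = resp(at(fai, "m0"), at(fai, "m6"), fai_elig, delta_fai),
    fai_responder_m12 = resp(at(fai, "m6"), at(fai, "m12"), fai_elig6, delta_fai)
  )
}

#' Study-flow accounting
#'
#' Tallies the flow of a cohort through the two treatment intervals:
#' retention, drop-outs by reason and interval, pregnancies, and
#' intention-to-treat response rates. Response denominators are the
#' patients eligible at the start of the interval (m0 eligibility for the
#' m6 rate; re-assessed m6 eligibility, among patients assessed at m6, for
#' the m12 "further improvement" rate); patients lost during the interval
#' count as non-responders. Percentages are reported to one decimal with
#' round-half-even.
#'
#' @param cohort A `pcos_cohort`.
#' @param n_screened Optional count of potentially eligible women screened
#'   before enrolment; enables the eligibility rate.
#' @param ... Passed to [label_outcomes()].
#' @return An object of class `pcos_flow_report`: a list with `counts`
#'   (named integers) and `rates` (tibble name/numerator/denominator/
#'   percent).
#' @export
flow_report <- function(cohort, n_screened = NULL, ...) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop_domain("flow_report: empty cohort")
  cohort <- derive_indices(cohort)
  labels <- label_outcomes(cohort, ...)
  m0 <- cohort[cohort$visit == "m0", ]
  n <- nrow(m0)
  n_m6 <- sum(cohort$visit == "m6")
  n_m12 <- sum(cohort$visit == "m12")

  cnt <- function(status, interval = NULL) {
    sel <- m0$status == status
    if (!is.null(interval)) sel <- sel & m0$dropout_interval == interval
    sum(sel)
  }
  counts <- c(
    enrolled = n, assessed_m6 = n_m6, assessed_m12 = n_m12,
    completed = cnt("completed"),
    dropout_side_effects_m0_m6 = cnt("dropout_side_effects", "m0_m6"),
    dropout_no_benefit_m0_m6 = cnt("dropout_no_benefit", "m0_m6"),
    lost_followup_m0_m6 = cnt("lost_followup", "m0_m6"),
    pregnant_m0_m6 = cnt("pregnant", "m0_m6"),
    dropout_side_effects_m6_m12 = cnt("dropout_side_effects", "m6_m12"),
    dropout_no_benefit_m6_m12 = cnt("dropout_no_benefit", "m6_m12"),
    lost_followup_m6_m12 = cnt("lost_followup", "m6_m12"),
    pregnant_m6_m12 = cnt("pregnant", "m6_m12")
  )
  lost1 <- sum(counts[c("dropout_side_effects_m0_m6", "dropout_no_benefit_m0_m6",
                        "lost_followup_m0_m6", "pregnant_m0_m6")])
  if (n - lost1 != n_m6)
    stop_domain("flow_report: first-interval losses (%d) inconsistent with m6 count (%d of %d)",
                lost1, n_m6, n)
  lost2 <- sum(counts[c("dropout_side_effects_m6_m12", "dropout_no_benefit_m6_m12",
                        "lost_followup_m6_m12", "pregnant_m6_m12")])
  if (n_m6 - lost2 != n_m12)
    stop_domain("flow_report: second-interval losses inconsistent with m12 count")

  rate <- function(name, num, den) {
    tibble::tibble(name = name, numerator = num, denominator = den,
                   percent = percent1(num, den))
  }
  nT <- function(x) sum(x %in% TRUE)
  side <- cnt("dropout_side_effects")
  non_side <- cnt("dropout_no_benefit") + cnt("lost_followup")
  rates <- dplyr::bind_rows(
    if (!is.null(n_screened)) rate("eligibility", n, n_screened),
    rate("retention_m6", n_m6, n),
    rate("retention_m12", n_m12, n),
    rate("side_effect_discontinuation", side, n),
    rate("non_side_effect_discontinuation", non_side, n),
    rate("pregnancy", cnt("pregnant"), n),
    rate("bmi_response_m6", nT(labels$bmi_responder_m6), sum(labels$bmi_eligible)),
    rate("fai_response_m6", nT(labels$fai_responder_m6), sum(labels$fai_eligible)),
    rate("bmi_further_response_m12", nT(labels$bmi_responder_m12),
         sum(labels$bmi_eligible_m6)),
    rate("fai_further_response_m12", nT(labels$fai_responder_m12),
         sum(labels$fai_eligible_m6))
  )
  structure(list(counts = as.list(counts), rates = rates),
            class = "pcos_flow_report")
}

#' @export
print.pcos_flow_report <- function(x, ...) {
  cat("Study flow report\n")
  cat(sprintf("  enrolled %d, assessed m6 %d, assessed m12 %d\n",
              x$counts$enrolled, x$counts$assessed_m6, x$counts$assessed_m12))
  r <- x$rates
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-32s %3d / %3d  (%.1f%%)\n", r$name[i], r$numerator[i],
                r$denominator[i], r$percent[i]))
  invisible(x)
}

#' Serialise a flow report to JSON
#'
#' @param report A `pcos_flow_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_report_json <- function(report, path) {
  stopifnot(inherits(report, "pcos_flow_report"))
  jsonlite::write_json(list(counts = report$counts, rates = report$rates),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
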