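# Median dichotomization into paired HIGH/LOW nodes, the nominal input
# representation for the auto-contractive map. Each continuous variable
# becomes two complementary nodes (both polarities appear in the
# connectivity maps); ties at the cutoff go LOW, so HIGH always means
# strictly above the median.

# Field-style node names for the variables that appear in the maps.
node_label_map <- c(
  menses6 = "CYCL", fai = "FAI", fg = "FG", homa_ir = "HOMA", tg = "TRIGL",
  glucose = "GLIC", dheas = "DHEA", bmi = "BMI", insulin = "INS",
  weight_kg = "WEIGHT", whr = "WHR", t_ngml = "T", shbg = "SHBG", a4 = "A4",
  lh_fsh = "LHFSH", tc = "TC", ldl = "LDL", hdl = "HDL", afc = "AFC",
  age = "AGE"
)

#' Default variable set for the connectivity-map analyses
#'
#' The baseline clinical features (raw and derived) that are dichotomized
#' and fed to the auto-contractive map.
#' @return A character vector of cohort/derived column names.
#' @export
scm_variables <- function() {
  c("menses6", "fai", "fg", "homa_ir", "tg", "glucose", "dheas", "bmi",
    "insulin", "whr", "t_ngml", "shbg", "a4", "lh_fsh", "afc", "age")
}

#' Median cutoffs for HIGH/LOW dichotomization
#'
#' For each variable, the cutoff is the sample median (mean of the two
#' central order statistics for even n) over the supplied baseline rows.
#' A variable with all values missing is excluded with a warning; a
#' constant variable keeps its value as cutoff and is flagged degenerate.
#'
#' @param baseline A data frame of baseline (m0) rows, with derived
#'   indices present (see [derive_indices()]).
#' @param vars Variables to dichotomize (default [scm_variables()]).
#' @return A tibble of class `pcos_cutoffs`: variable, cutoff,
#'   high_label, low_label, degenerate.
#' @export
compute_cutoffs <- function(baseline, vars = scm_variables()) {
  missing_vars <- setdiff(vars, names(baseline))
  if (length(missing_vars))
    stop_domain("compute_cutoffs: variable(s) not in table: %s",
                paste(missing_vars, collapse = ", "))
  rows <- list()
  for (v in vars) {
    x <- baseline[[v]][!is.na(baseline[[v]])]
    if (length(x) == 0) {
      warning(sprintf("variable '%s' is all-missing; excluded", v),
              call. = FALSE)
      next
    }
    if (length(x) < 2)
      stop_domain("compute_cutoffs: need >= 2 observations for '%s'", v)
    lab <- if (v %in% names(node_label_map)) node_label_map[[v]] else toupper(v)
    rows[[v]] <- tibble::tibble(
      variable = v, cutoff = median(x),
      high_label = paste0(lab, "_HIGH"), low_label = paste0(lab, "_LOW"),
      degenerate = max(x) == min(x)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(c(out$high_label, out$low_label)))
    stop_domain("compute_cutoffs: node names not unique")
  structure(out, class = c("pcos_cutoffs", class(out)))
}

#' Dichotomize a cohort into a binary node matrix
#'
#' Builds the patient-by-node 0/1 matrix fed to the auto-contractive map:
#' for every variable a `*_HIGH` node (value strictly above the cutoff)
#' and its complement `*_LOW` (at or below — ties go LOW), plus the
#' outcome pole pair `RESPONDER` / `NON_RESPONDER` taken from the outcome
#' labels. Only patients whose responder label for the chosen outcome and
#' visit is defined are included; rows missing any variable are excluded
#' with a message.
#'
#' @param cohort A `pcos_cohort`.
#' @param cutoffs A [compute_cutoffs()] table.
#' @param outcome `"bmi"` or `"fai"`.
#' @param visit `"m6"` or `"m12"` (the visit at which response is
#'   assessed; predictors are always the baseline values).
#' @param labels Optional precomputed [label_outcomes()] table.
#' @return A binary matrix (patients x nodes) with patient ids as row
#'   names and a `cutoffs` attribute.
#' @export
dichotomize_matrix <- function(cohort, cutoffs, outcome = c("bmi", "fai"),
                               visit = c("m6", "m12"),
                               labels = label_outcomes(cohort)) {
  outcome <- match.arg(outcome)
  visit <- match.arg(visit)
  cohort <- derive_indices(cohort)
  lab_col <- sprintf("%s_responder_%s", outcome, visit)
  keep <- labels$patient_id[!is.na(labels[[lab_col]])]
  if (length(keep) == 0)
    stop_domain("dichotomize_matrix: no patient has a defined %s label at %s",
                outcome, visit)
  m0 <- cohort[cohort$visit == "m0" & cohort$patient_id %in% keep, ]
  vals <- m0[, cutoffs$variable, drop = FALSE]
  complete <- complete.cases(vals)
  if (any(!complete))
    message(sprintf("dichotomize_matrix: excluded %d patient(s) with missing variables: %s",
                    sum(!complete),
                    paste(m0$patient_id[!complete], collapse = ", ")))
  m0 <- m0[complete, ]
  vals <- vals[complete, , drop = FALSE]

  nvar <- nrow(cutoffs)
  X <- matrix(0L, nrow(m0), 2 * nvar + 2)
  cn <- character(2 * nvar + 2)
  for (k in seq_len(nvar)) {
    hi <- as.integer(vals[[cutoffs$variable[k]]] > cutoffs$cutoff[k])
    X[, 2 * k - 1] <- hi
    X[, 2 * k] <- 1L - hi
    cn[2 * k - 1] <- cutoffs$high_label[k]
    cn[2 * k] <- cutoffs$low_label[k]
  }
  resp <- labels[[lab_col]][match(m0$patient_id, labels$patient_id)]
  X[, 2 * nvar + 1] <- as.integer(resp)
  X[, 2 * nvar + 2] <- 1L - as.integer(resp)
  cn[2 * nvar + 1] <- "RESPONDER"
  cn[2 * nvar + 2] <- "NON_RESPONDER"
  dimnames(X) <- list(m0$patient_id, cn)
  attr(X, "cutoffs") <- cutoffs
  X
}

#' Write a cutoff table to CSV
#' @param cutoffs A `pcos_cutoffs` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutoffs_csv <- function(cutoffs, path) {
  readr::write_csv(as.data.frame(cutoffs), path)
  invisible(path)
}
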