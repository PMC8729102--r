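#' Cohort table schema
#'
#' A cohort is a tibble with one row per patient-visit. Mandatory columns
#' (units in parentheses): `patient_id`, `visit` (m0/m6/m12), `age` (years),
#' `height_m` (m), `weight_kg` (kg), `glucose` (mg/dL), `insulin` (uU/mL),
#' `tg`, `tc`, `ldl`, `hdl` (mg/dL), `waist`, `hip` (cm), `t_ngml` (ng/mL),
#' `shbg` (nmol/L), `dheas` (ug/dL), `a4` (ng/mL), `fg` (Ferriman-Gallwey
#' score), `lh`, `fsh` (IU/L), `menses6` (menses per 6 months, 0-6), `afc`
#' (antral follicles, both ovaries), `pcom` (0/1), `status`
#' (completed / dropout_side_effects / dropout_no_benefit / lost_followup /
#' pregnant), `dropout_interval` (none / m0_m6 / m6_m12). Extra columns are
#' carried along untouched.
#'
#' @name cohort-schema
NULL

visit_levels <- c("m0", "m6", "m12")
status_levels <- c("completed", "dropout_side_effects", "dropout_no_benefit",
                   "lost_followup", "pregnant")
interval_levels <- c("none", "m0_m6", "m6_m12")

cohort_numeric_cols <- c(
  "age", "height_m", "weight_kg", "glucose", "insulin", "tg", "tc", "ldl",
  "hdl", "waist", "hip", "t_ngml", "shbg", "dheas", "a4", "fg", "lh", "fsh",
  "menses6", "afc", "pcom"
)

cohort_columns <- c("patient_id", "visit", cohort_numeric_cols,
                    "status", "dropout_interval")

#' Validate and classify a cohort table
#'
#' Checks the longitudinal invariants: m0 present for every patient, a
#' visit present only if all earlier visits are present, no duplicate
#' (patient, visit) pairs, non-negative measurements, `menses6 <= 6`,
#' `fg <= 36`, and `status == "completed"` exactly for non-pregnant
#' patients with an m12 visit.
#'
#' @param df A data frame following the cohort schema.
#' @return The validated cohort as a tibble of class `pcos_cohort`.
#' @export
as_cohort <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols))
    stop_domain("cohort is missing mandatory column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop_domain("cohort has no rows")
  if (!all(df$visit %in% visit_levels))
    stop_domain("visit must be one of %s", paste(visit_levels, collapse = "/"))
  if (!all(df$status %in% status_levels))
    stop_domain("unknown status value(s): %s",
                paste(unique(setdiff(df$status, status_levels)), collapse = ", "))
  if (!all(df$dropout_interval %in% interval_levels))
    stop_domain("unknown dropout_interval value(s)")

  key <- paste(df$patient_id, df$visit)
  if (anyDuplicated(key))
    stop_domain("duplicate (patient, visit) row(s): %s",
                paste(unique(key[duplicated(key)]), collapse = ", "))

  for (cl in cohort_numeric_cols) {
    bad <- !is.na(df[[cl]]) & df[[cl]] < 0
    if (any(bad))
      stop_domain("negative values in column '%s'", cl)
  }
  if (any(df$menses6 > 6, na.rm = TRUE))
    stop_domain("menses6 must be <= 6")
  if (any(df$fg > 36, na.rm = TRUE))
    stop_domain("fg (Ferriman-Gallwey) must be <= 36")

  by_pat <- split(df$visit, df$patient_id)
  for (pid in names(by_pat)) {
    vs <- by_pat[[pid]]
    if (!"m0" %in% vs)
      stop_domain("patient %s has no m0 visit", pid)
    if ("m12" %in% vs && !"m6" %in% vs)
      stop_domain("patient %s has m12 without m6", pid)
  }
  st <- df[df$visit == "m0", c("patient_id", "status")]
  has_m12 <- tapply(df$visit == "m12", df$patient_id, any)
  for (k in seq_len(nrow(st))) {
    pid <- st$patient_id[k]
    completed <- isTRUE(has_m12[[pid]]) && st$status[k] != "pregnant"
    if (completed != (st$status[k] == "completed"))
      stop_domain("patient %s: status '%s' inconsistent with visits",
                  pid, st$status[k])
  }
  class(df) <- unique(c("pcos_cohort", class(df)))
  df
}

#' Read a cohort from CSV
#'
#' One row per patient-visit, UTF-8, dot decimal separator. Unknown
#' columns are preserved. Parse failures (missing mandatory column,
#' non-numeric cell, duplicate patient-visit, longitudinal invariant
#' violations) raise an error naming the offending row or column.
#'
#' @param path Path to a CSV file following the cohort schema.
#' @return A `pcos_cohort` tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_domain("no such file: %s", path)
  if (file.size(path) == 0) stop_domain("empty cohort file: %s", path)
  hdr <- names(suppressMessages(
    readr::read_csv(path, n_max = 0, show_col_types = FALSE)))
  if (length(hdr) == 0) stop_domain("empty cohort file: %s", path)
  missing_cols <- setdiff(cohort_columns, hdr)
  if (length(missing_cols))
    stop_domain("cohort CSV is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  types <- do.call(readr::cols, c(
    list(patient_id = readr::col_character(),
         visit = readr::col_character(),
         status = readr::col_character(),
         dropout_interval = readr::col_character()),
    setNames(rep(list(readr::col_double()), length(cohort_numeric_cols)),
             cohort_numeric_cols)
  ))
  df <- suppressWarnings(suppressMessages(
    readr::read_csv(path, col_types = types, progress = FALSE)))
  pr <- readr::problems(df)
  if (nrow(pr) > 0)
    stop_domain("cohort CSV parse error at row(s) %s (column %s): %s",
                paste(unique(pr$row), collapse = ", "),
                paste(unique(pr$col), collapse = ", "),
                pr$expected[1])
  as_cohort(df)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]; the round trip is lossless (numeric
#' values are written at full precision, extra columns are kept).
#'
#' @param cohort A `pcos_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "pcos_cohort") || is.data.frame(cohort))
  ord <- c(cohort_columns, setdiff(names(cohort), cohort_columns))
  readr::write_csv(cohort[, ord], path)
  invisible(path)
}
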