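#' Free androgen index
#'
#' FAI (%) = total testosterone (ng/mL) x 347 / SHBG (nmol/L). Values of 6%
#' or more define biochemical hyperandrogenemia in this pipeline.
#'
#' @param t_ngml Total testosterone in ng/mL (non-negative).
#' @param shbg Sex hormone binding globulin in nmol/L (strictly positive).
#' @return FAI as a percent, same length as the inputs.
#' @examples
#' compute_fai(0.60, 34.7)  # exactly the 6% eligibility threshold
#' @export
compute_fai <- function(t_ngml, shbg) {
  if (any(!is.finite(shbg) | shbg <= 0))
    stop_domain("compute_fai: SHBG must be > 0 nmol/L")
  if (any(!is.finite(t_ngml) | t_ngml < 0))
    stop_domain("compute_fai: testosterone must be >= 0 ng/mL")
  t_ngml * 347 / shbg
}

#' Homeostatic model assessment of insulin resistance
#'
#' HOMA-IR = glucose (mg/dL) x 0.05551 x insulin (uU/mL) / 22.5. The
#' 0.05551 factor converts glucose from mg/dL to mmol/L.
#'
#' @param glucose Fasting glucose in mg/dL (non-negative).
#' @param insulin Fasting insulin in uU/mL (non-negative).
#' @return Dimensionless HOMA-IR, same length as the inputs.
#' @examples
#' compute_homa_ir(90, 18)  # baseline medians; rounds to the cutoff 4
#' @export
compute_homa_ir <- function(glucose, insulin) {
  if (any(!is.finite(glucose) | glucose < 0))
    stop_domain("compute_homa_ir: glucose must be >= 0 mg/dL")
  if (any(!is.finite(insulin) | insulin < 0))
    stop_domain("compute_homa_ir: insulin must be >= 0 uU/mL")
  glucose * 0.05551 * insulin / 22.5
}

#' Derived panel for a single visit
#'
#' Computes the derived indices used throughout the analysis: BMI
#' (kg/m^2), waist/hip ratio, FAI, HOMA-IR and the LH/FSH ratio.
#'
#' @param visit A one-row data frame (or named list) with fields
#'   `weight_kg`, `glucose`, `insulin`, `waist`, `hip`, `t_ngml`, `shbg`,
#'   `lh`, `fsh`.
#' @param height_m Height in metres (time-invariant, strictly positive).
#' @return A one-row tibble with columns `bmi`, `whr`, `fai`, `homa_ir`,
#'   `lh_fsh`.
#' @export
compute_derived <- function(visit, height_m) {
  v <- as.list(visit)
  if (!is.finite(height_m) || height_m <= 0)
    stop_domain("compute_derived: height_m must be > 0")
  if (!is.finite(v$hip) || v$hip <= 0)
    stop_domain("compute_derived: hip must be > 0")
  if (!is.finite(v$fsh) || v$fsh <= 0)
    stop_domain("compute_derived: fsh must be > 0")
  tibble::tibble(
    bmi = v$weight_kg / height_m^2,
    whr = v$waist / v$hip,
    fai = compute_fai(v$t_ngml, v$shbg),
    homa_ir = compute_homa_ir(v$glucose, v$insulin),
    lh_fsh = v$lh / v$fsh
  )
}

#' Add derived index columns to a cohort table
#'
#' Vectorised companion to [compute_derived()]: appends `bmi`, `whr`,
#' `fai`, `homa_ir` and `lh_fsh` columns. A visit lacking (or carrying an
#' invalid value for) any input of an index gets `NA` for that index;
#' missingness propagates, it is never coerced to zero.
#'
#' @param cohort A cohort table (one row per patient-visit).
#' @return The cohort with five extra columns.
#' @export
derive_indices <- function(cohort) {
  safe_div <- function(num, den) {
    out <- ifelse(is.finite(num) & is.finite(den) & den > 0 & num >= 0,
                  num / den, NA_real_)
    as.numeric(out)
  }
  cohort$bmi <- safe_div(cohort$weight_kg, cohort$height_m^2)
  cohort$whr <- safe_div(cohort$waist, cohort$hip)
  cohort$fai <- safe_div(cohort$t_ngml * 347, cohort$shbg)
  cohort$homa_ir <- safe_div(cohort$glucose * 0.05551 * cohort$insulin, 22.5)
  cohort$lh_fsh <- safe_div(cohort$lh, cohort$fsh)
  cohort
}
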