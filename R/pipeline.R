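#' Pipeline run configuration
#'
#' Exactly one input mode: a cohort CSV path, or the synthetic generator
#' (the default). The seed propagates to every stochastic stage.
#'
#' @param csv Optional path to a cohort CSV; overrides the generator.
#' @param generator A [cohort_config()] used when `csv` is `NULL`.
#' @param seed Integer seed for the run (forwarded to the generator and
#'   the evolutionary search).
#' @param out_dir Output directory (created if missing).
#' @param scm_visits Named map of outcome to the visit at which its
#'   connectivity map is built (BMI response polarises at m6, FAI
#'   response at m12 in the analysis this package implements).
#' @param autocm_C Contraction parameter (`NULL` = number of nodes).
#' @param autocm_tol,autocm_max_epochs Auto-CM training controls.
#' @param ga,mlp Specs for the TWIST stage.
#' @param twist_outcome Outcome optimised by the TWIST stage.
#' @param min_n Minimum analysis set size for the SCM and TWIST stages;
#'   below it those stages are skipped with a warning.
#' @param n_screened Optional screened count for the eligibility rate.
#' @param verbose Log stage progress.
#' @return A list of class `pcos_run_config`.
#' @export
run_config <- function(csv = NULL, generator = cohort_config(), seed = 1,
                       out_dir = tempfile("pcosmet_run_"),
                       scm_visits = c(bmi = "m6", fai = "m12"),
                       autocm_C = NULL, autocm_tol = 1e-6,
                       autocm_max_epochs = 10000,
                       ga = ga_spec(), mlp = mlp_spec(),
                       twist_outcome = "bmi", min_n = 20,
                       n_screened = NULL, verbose = TRUE) {
  if (!is.null(csv) && !file.exists(csv))
    stop_domain("run_config: csv file not found: %s", csv)
  generator$seed <- as.integer(seed)
  ga$seed <- as.integer(seed)
  mlp$seed <- as.integer(seed)
  structure(list(csv = csv, generator = generator, seed = as.integer(seed),
                 out_dir = out_dir, scm_visits = scm_visits,
                 autocm_C = autocm_C, autocm_tol = autocm_tol,
                 autocm_max_epochs = autocm_max_epochs, ga = ga, mlp = mlp,
                 twist_outcome = twist_outcome, min_n = min_n,
                 n_screened = n_screened, verbose = verbose),
            class = "pcos_run_config")
}

#' Run the full analysis pipeline
#'
#' Generate-or-ingest, derive indices, label outcomes, flow report,
#' median dichotomization, semantic connectivity maps for both outcomes,
#' TWIST feature selection, and the drop-out statistics. Writes
#' `cohort.csv`, `flow_report.json`, `cutoffs.csv`, `scm_bmi.graphml`,
#' `scm_fai.graphml`, `pole_priorities.json`, `twist_results.json`,
#' `dropout_stats.json` and a `manifest.json` (config hash, seed,
#' versions) into the output directory. Identical config and seed produce
#' byte-identical numeric outputs; a failing stage aborts with the stage
#' name, preserving the outputs already written.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly; the loaded/generated
#'   cohort and in-memory results are attached as attributes.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "pcos_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("stage %-16s ...", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("stage %-16s done (%.1fs)", name, proc.time()[["elapsed"]] - t0)
    out
  }
  results <- list()

  cohort <- stage("input", {
    if (!is.null(config$csv)) read_cohort_csv(config$csv)
    else generate_cohort(config$generator)
  })
  cohort <- stage("derive", derive_indices(cohort))
  labels <- stage("label", label_outcomes(cohort))
  flow <- stage("flow_report", {
    fr <- flow_report(cohort, n_screened = config$n_screened)
    write_flow_report_json(fr, file.path(config$out_dir, "flow_report.json"))
    fr
  })
  write_cohort_csv(cohort[, !vapply(cohort, is.list, logical(1))],
                   file.path(config$out_dir, "cohort.csv"))

  m0 <- cohort[cohort$visit == "m0", ]
  cutoffs <- stage("cutoffs", {
    ct <- compute_cutoffs(m0)
    write_cutoffs_csv(ct, file.path(config$out_dir, "cutoffs.csv"))
    ct
  })

  scms <- list()
  priorities <- list()
  for (oc in names(config$scm_visits)) {
    visit <- config$scm_visits[[oc]]
    lab_col <- sprintf("%s_responder_%s", oc, visit)
    n_avail <- sum(!is.na(labels[[lab_col]]))
    if (n_avail < config$min_n) {
      warning(sprintf("SCM stage for %s skipped: %d labelled patients < min_n %d",
                      oc, n_avail, config$min_n), call. = FALSE)
      next
    }
    scms[[oc]] <- stage(paste0("scm_", oc), {
      X <- dichotomize_matrix(cohort, cutoffs, outcome = oc, visit = visit,
                              labels = labels)
      scm <- build_scm(X, C = config$autocm_C %||% ncol(X),
                       max_epochs = config$autocm_max_epochs,
                       tol = config$autocm_tol)
      write_scm_graphml(scm, file.path(config$out_dir,
                                       sprintf("scm_%s.graphml", oc)))
      scm
    })
    priorities[[oc]] <- scms[[oc]]$priorities
  }
  jsonlite::write_json(priorities,
                       file.path(config$out_dir, "pole_priorities.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  oc <- config$twist_outcome
  visit <- config$scm_visits[[oc]]
  lab_col <- sprintf("%s_responder_%s", oc, visit)
  ok <- !is.na(labels[[lab_col]])
  twist <- NULL
  if (sum(ok) < config$min_n) {
    warning(sprintf("TWIST stage skipped: %d labelled patients < min_n %d",
                    sum(ok), config$min_n), call. = FALSE)
  } else {
    twist <- stage("twist", {
      ids <- labels$patient_id[ok]
      feats <- m0[match(ids, m0$patient_id), scm_variables()]
      keep <- complete.cases(feats)
      tw <- twist_run(as.matrix(feats[keep, ]),
                      as.numeric(labels[[lab_col]][ok][keep]),
                      ga = config$ga, mlp = config$mlp)
      jsonlite::write_json(
        list(outcome = oc, visit = visit,
             features = tw$features, mask = as.list(tw$mask),
             fitness = tw$fitness, history = tw$history, roc = tw$roc),
        file.path(config$out_dir, "twist_results.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      tw
    })
  }

  m0d <- derive_indices(m0[m0$status != "pregnant", ])
  dropped <- m0d$status %in% c("dropout_side_effects", "dropout_no_benefit",
                               "lost_followup")
  dropout <- NULL
  if (length(unique(dropped)) < 2 || nrow(m0d) < config$min_n) {
    warning("drop-out stage skipped: no variation in drop-out status or too few patients",
            call. = FALSE)
  } else {
    dropout <- stage("dropout_stats", {
    covs <- m0d[, c("t_ngml", "shbg", "fai", "dheas", "fg", "homa_ir",
                    "lh_fsh", "a4", "menses6")]
    covs <- covs[, vapply(covs, function(v)
      length(unique(v[!is.na(v)])) > 1, logical(1)), drop = FALSE]
    lf <- logistic_fit(covs, as.numeric(dropped))
    tt <- dropout_two_by_two(cohort)
    pr <- pearson_r(m0d$t_ngml, as.numeric(dropped))
    cmp <- dropout_comparison(cohort)
    readr::write_csv(cmp, file.path(config$out_dir,
                                    "dropout_comparison.csv"))
    out <- list(
      logistic = lf$coef,
      low_t_table = as.list(tt$table),
      low_t_or = list(or = tt$statistic, ci_lo = tt$coef$ci_lo,
                      ci_hi = tt$coef$ci_hi, p = tt$p_value),
      t_dropout_correlation = list(r = pr$statistic, p = pr$p_value))
    jsonlite::write_json(out, file.path(config$out_dir, "dropout_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
    })
  }

  manifest <- list(
    seed = config$seed,
    input_mode = if (is.null(config$csv)) "synthetic" else "csv",
    config_hash = unname(tools::md5sum(
      local({
        f <- tempfile(fileext = ".json")
        cfg <- config
        cfg$out_dir <- NULL; cfg$verbose <- NULL
        jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA,
                             force = TRUE)
        f
      }))),
    package_version = as.character(utils::packageVersion("pcosmet")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- config$out_dir
  attr(out, "cohort") <- cohort
  attr(out, "flow") <- flow
  attr(out, "scms") <- scms
  attr(out, "twist") <- twist
  attr(out, "dropout") <- dropout
  invisible(out)
}
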