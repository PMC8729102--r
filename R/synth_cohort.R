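# Synthetic cohort generator.
#
# Baseline marginals are moment-matched to the published baseline summary
# of the study population (mean, SD, median targets); skewed positive
# variables (insulin, triglycerides, testosterone, SHBG, DHEAS, LH/FSH)
# use log-normal marginals, the rest truncated Gaussians whose truncated
# mean/SD are matched numerically. Dependence is imposed with a Gaussian
# copula. Treatment response and drop-out are planted through logistic
# models on dichotomized baseline indicators so that downstream recovery
# of the planted structure is testable.

default_baseline_spec <- function() {
  tibble::tribble(
    ~var,        ~mean,  ~sd,    ~median, ~lower, ~upper, ~dist,       ~integer,
    "age",       28.38,  5.53,   NA,      18,     Inf,    "normal",    FALSE,
    "height_m",  1.63,   0.06,   NA,      1.40,   Inf,    "normal",    FALSE,
    "weight_kg", 87.2,   18.18,  84,      40,     Inf,    "normal",    FALSE,
    "glucose",   91.64,  9.66,   90,      50,     Inf,    "normal",    FALSE,
    "insulin",   21.03,  11.6,   18,      0,      Inf,    "lognormal", FALSE,
    "tg",        121.6,  61.9,   110,     0,      Inf,    "lognormal", FALSE,
    "tc",        189.9,  32.5,   185,     80,     Inf,    "normal",    FALSE,
    "ldl",       120.8,  26.8,   120,     30,     Inf,    "normal",    FALSE,
    "hdl",       44.1,   8.9,    43,      15,     Inf,    "normal",    FALSE,
    "whr",       0.91,   0.10,   0.91,    0.55,   1.40,   "normal",    FALSE,
    "hip",       110,    10,     NA,      70,     Inf,    "normal",    FALSE,
    "t_ngml",    0.70,   0.31,   0.60,    0,      Inf,    "lognormal", FALSE,
    "shbg",      23.1,   10.4,   22,      0,      Inf,    "lognormal", FALSE,
    "dheas",     291.7,  125.4,  270,     0,      Inf,    "lognormal", FALSE,
    "a4",        4.02,   0.65,   4,       1,      Inf,    "normal",    FALSE,
    "fg",        12.5,   6.9,    12,      0,      36,     "normal",    TRUE,
    "lh_fsh",    1.44,   0.9,    1.25,    0,      Inf,    "lognormal", FALSE,
    "fsh",       5.5,    1.5,    NA,      1,      Inf,    "normal",    FALSE,
    "menses6",   2.0,    1.7,    2,       0,      6,      "normal",    TRUE,
    "afc",       41,     9,      40,      4,      Inf,    "normal",    TRUE
  )
}

default_correlation_spec <- function() {
  tibble::tribble(
    ~var1,       ~var2,      ~rho,
    "weight_kg", "insulin",  0.4,
    "glucose",   "insulin",  0.3,
    "t_ngml",    "shbg",    -0.35,
    "menses6",   "t_ngml",  -0.3
  )
}

# Planted dichotomization thresholds: the published medians that define the
# HIGH/LOW node captions (ties go LOW, so e.g. CYCL LOW means menses6 <= 2).
default_reference_cutoffs <- function() {
  c(menses6 = 2, fai = 9, fg = 12, homa_ir = 4, tg = 110, glucose = 90,
    dheas = 270, bmi = 32)
}

#' Configuration for the synthetic cohort generator
#'
#' The defaults encode the study conditions the pipeline was designed for:
#' baseline marginals matched to the published baseline table, a BMI
#' response model whose planted coefficients decrease over oligo-amenorrhea
#' (CYCL LOW), hyperandrogenemia (FAI HIGH), hirsutism (FG HIGH) and
#' insulin resistance (HOMA HIGH), an FAI response model over the six
#' published FAI-map predictors, and a drop-out model with a planted odds
#' ratio `exp(gamma_lowT)` for baseline testosterone below 0.90 ng/mL.
#'
#' @param n Number of patients (>= 2).
#' @param seed Integer seed; every stochastic stage derives per-patient
#'   substreams from it, so cohort prefixes are invariant to `n`.
#' @param baseline_spec Tibble of per-variable marginal targets
#'   (var/mean/sd/median/lower/upper/dist/integer).
#' @param correlation_spec Tibble (var1, var2, rho) of Gaussian-copula
#'   correlations between drawn variables; |rho| < 1.
#' @param response_model_bmi,response_model_fai Named coefficient vectors
#'   (`b0` plus indicator coefficients) of the planted logistic response
#'   models on dichotomized baseline indicators.
#' @param b0_shift_m12_bmi,b0_shift_m12_fai Intercept shifts for the
#'   second-interval ("further improvement") response draws.
#' @param dropout_model List with `gamma0`, `gamma_lowT` and `t_cutoff`
#'   (ng/mL) for the planted drop-out logistic model.
#' @param p_first_interval Probability a drop-out occurs in m0-m6 rather
#'   than m6-m12.
#' @param dropout_reason_probs Probabilities of the three drop-out reasons.
#' @param pregnancy_rate Per-interval pregnancy probability among women on
#'   treatment.
#' @param pcom_rate Baseline prevalence of polycystic ovarian morphology.
#' @param reference_cutoffs Named thresholds used to dichotomize baseline
#'   indicators inside the planted response models.
#' @return A list of class `pcos_generator_config`.
#' @export
cohort_config <- function(
    n = 108, seed = 1,
    baseline_spec = default_baseline_spec(),
    correlation_spec = default_correlation_spec(),
    response_model_bmi = c(b0 = -2.05, cycl_low = 1.6, fai_high = 1.2,
                           fg_high = 0.8, homa_high = 0.5),
    response_model_fai = c(b0 = -2.6, cycl_low = 1.6, fai_high = 1.2,
                           dhea_low = 0.9, bmi_high = 0.7, trigl_high = 0.5,
                           glic_low = 0.3),
    b0_shift_m12_bmi = -0.8, b0_shift_m12_fai = -0.1,
    dropout_model = list(gamma0 = log(0.111), gamma_lowT = log(6.5),
                         t_cutoff = 0.90),
    p_first_interval = 21 / 46,
    dropout_reason_probs = c(dropout_side_effects = 14 / 46,
                             dropout_no_benefit = 21 / 46,
                             lost_followup = 11 / 46),
    pregnancy_rate = 0.045,
    pcom_rate = 0.73,
    reference_cutoffs = default_reference_cutoffs()) {
  if (!is.numeric(n) || n < 2) stop_domain("cohort_config: n must be >= 2")
  if (any(baseline_spec$sd < 0)) stop_domain("cohort_config: sds must be >= 0")
  if (any(abs(correlation_spec$rho) >= 1))
    stop_domain("cohort_config: correlations must satisfy |rho| < 1")
  bad <- setdiff(c(correlation_spec$var1, correlation_spec$var2),
                 baseline_spec$var)
  if (length(bad))
    stop_domain("cohort_config: correlation on unknown variable(s): %s",
                paste(bad, collapse = ", "))
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         baseline_spec = baseline_spec, correlation_spec = correlation_spec,
         response_model_bmi = response_model_bmi,
         response_model_fai = response_model_fai,
         b0_shift_m12_bmi = b0_shift_m12_bmi,
         b0_shift_m12_fai = b0_shift_m12_fai,
         dropout_model = dropout_model,
         p_first_interval = p_first_interval,
         dropout_reason_probs = dropout_reason_probs,
         pregnancy_rate = pregnancy_rate, pcom_rate = pcom_rate,
         reference_cutoffs = reference_cutoffs),
    class = "pcos_generator_config")
}

# Moments of a doubly truncated normal.
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  da <- dnorm(al); db <- dnorm(be)
  m <- mu + sigma * (da - db) / Z
  t1 <- ifelse(is.finite(al), al * da, 0)
  t2 <- ifelse(is.finite(be), be * db, 0)
  v <- sigma^2 * (1 + (t1 - t2) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Find (mu, sigma) so the truncated normal hits the target mean/sd.
solve_truncnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), a, b)
    if (!all(is.finite(mm))) return(1e6)
    ((mm["mean"] - target_mean) / target_sd)^2 +
      ((mm["sd"] - target_sd) / target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Per-variable quantile transforms for the Gaussian copula.
marginal_quantile_funs <- function(spec) {
  funs <- list()
  for (k in seq_len(nrow(spec))) {
    row <- spec[k, ]
    if (row$dist == "lognormal") {
      if (!is.na(row$median) && row$mean > row$median) {
        # match the stated median exactly and the mean through the shape
        # (the SD is then implied by the log-normal form)
        meanlog <- log(row$median)
        sdlog <- sqrt(2 * log(row$mean / row$median))
      } else {
        sdlog <- sqrt(log(1 + (row$sd / row$mean)^2))
        meanlog <- log(row$mean) - sdlog^2 / 2
      }
      funs[[row$var]] <- local({
        ml <- meanlog; sl <- sdlog
        function(u) stats::qlnorm(u, ml, sl)
      })
    } else {
      pars <- solve_truncnorm(row$mean, row$sd, row$lower, row$upper)
      funs[[row$var]] <- local({
        mu <- pars["mu"]; sg <- pars["sigma"]
        a <- row$lower; b <- row$upper
        function(u) {
          pl <- pnorm(a, mu, sg); pu <- pnorm(b, mu, sg)
          qnorm(pl + u * (pu - pl), mu, sg)
        }
      })
    }
  }
  funs
}

copula_cholesky <- function(spec, corr) {
  vars <- spec$var
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  for (k in seq_len(nrow(corr))) {
    R[corr$var1[k], corr$var2[k]] <- corr$rho[k]
    R[corr$var2[k], corr$var1[k]] <- corr$rho[k]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop_domain("correlation matrix not positive definite; check pairs: %s",
                paste(paste(corr$var1, corr$var2, sep = "-"), collapse = ", "))
  chol(R)
}

#' Generate the baseline (m0) visits of a synthetic cohort
#'
#' Draws the baseline table from moment-matched marginals coupled by a
#' Gaussian copula, enforcing physical bounds. Deterministic given the
#' seed; patient `i` always receives the same draws regardless of `n`.
#'
#' @param config A [cohort_config()].
#' @return A tibble of m0 rows with a `ground_truth` attribute (see
#'   [ground_truth()]).
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "pcos_generator_config"))
  spec <- config$baseline_spec
  ch <- copula_cholesky(spec, config$correlation_spec)
  qf <- marginal_quantile_funs(spec)
  k <- nrow(spec)
  n <- config$n
  draws <- matrix(NA_real_, n, k, dimnames = list(NULL, spec$var))
  pcom <- integer(n)
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, 1L, i))
    z <- drop(rnorm(k) %*% ch)
    u <- pnorm(z)
    draws[i, ] <- vapply(seq_len(k), function(j) qf[[spec$var[j]]](u[j]),
                         numeric(1))
    pcom[i] <- as.integer(runif(1) < config$pcom_rate)
  }
  for (j in seq_len(k)) {
    if (spec$integer[j]) draws[, j] <- round(draws[, j])
    draws[, j] <- pmin(pmax(draws[, j], spec$lower[j]), spec$upper[j])
  }
  d <- tibble::as_tibble(draws)
  cohort <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    visit = "m0",
    age = d$age, height_m = d$height_m, weight_kg = d$weight_kg,
    glucose = d$glucose, insulin = d$insulin, tg = d$tg, tc = d$tc,
    ldl = d$ldl, hdl = d$hdl,
    waist = d$whr * d$hip, hip = d$hip,
    t_ngml = d$t_ngml, shbg = d$shbg, dheas = d$dheas, a4 = d$a4, fg = d$fg,
    lh = d$lh_fsh * d$fsh, fsh = d$fsh,
    menses6 = d$menses6, afc = d$afc, pcom = pcom,
    status = "completed", dropout_interval = "none"
  )
  attr(cohort, "ground_truth") <- list(
    seed = config$seed,
    response_model_bmi = config$response_model_bmi,
    response_model_fai = config$response_model_fai,
    dropout_model = config$dropout_model
  )
  cohort
}

#' Planted ground truth of a synthetic cohort
#'
#' Returns the generator's hidden state (planted coefficients, responder
#' indicators, drop-out latents). Stored alongside the cohort for recovery
#' tests; it is never consumed by the analysis pipeline itself.
#'
#' @param cohort A synthetic cohort.
#' @return A list, or `NULL` for non-synthetic cohorts.
#' @export
ground_truth <- function(cohort) attr(cohort, "ground_truth")

planted_indicators <- function(m0, cutoffs) {
  m0 <- derive_indices(m0)
  list(
    cycl_low = m0$menses6 <= cutoffs[["menses6"]],
    fai_high = m0$fai > cutoffs[["fai"]],
    fg_high = m0$fg > cutoffs[["fg"]],
    homa_high = m0$homa_ir > cutoffs[["homa_ir"]],
    trigl_high = m0$tg > cutoffs[["tg"]],
    glic_low = m0$glucose <= cutoffs[["glucose"]],
    dhea_low = m0$dheas <= cutoffs[["dheas"]],
    bmi_high = m0$bmi > cutoffs[["bmi"]]
  )
}

response_probability <- function(beta, ind, b0_shift = 0) {
  eta <- beta[["b0"]] + b0_shift
  for (nm in setdiff(names(beta), "b0")) eta <- eta + beta[[nm]] * ind[[nm]]
  plogis(eta)
}

# Shared m0->m6 / m6->m12 evolution of one patient's non-outcome variables.
shift_visit <- function(prev, second) {
  s <- function(mu, sd) rnorm(1, if (second) mu * 0.5 else mu, sd)
  v <- prev
  v$glucose <- max(prev$glucose + s(-3.7, 3), 50)
  v$insulin <- max(prev$insulin + s(-5.2, 3), 1)
  v$tc <- max(prev$tc + s(-1.3, 8), 80)
  v$ldl <- max(prev$ldl + s(-5.5, 8), 30)
  v$hdl <- max(prev$hdl + s(1.6, 3), 15)
  v$tg <- max(prev$tg + s(-4, 15), 30)
  whr <- min(max(prev$waist / prev$hip + s(-0.02, 0.03), 0.55), 1.4)
  v$waist <- whr * prev$hip
  v$dheas <- max(prev$dheas + s(-13, 40), 30)
  v$a4 <- max(prev$a4 + s(-0.13, 0.3), 0.5)
  v$fg <- min(max(round(prev$fg + s(-0.2, 1)), 0), 36)
  v$menses6 <- min(max(round(prev$menses6 + s(1.5, 1)), 0), 6)
  v$afc <- max(round(prev$afc + s(-2, 3)), 2)
  lr <- max(prev$lh / prev$fsh + s(-0.25, 0.3), 0.1)
  v$lh <- lr * prev$fsh
  v
}

#' Extend a baseline cohort with m6 and m12 visits
#'
#' Responder status for each outcome and interval is drawn from the
#' planted logistic models on dichotomized baseline indicators. Responders
#' receive a BMI drop of at least 1 kg/m^2 (respectively an FAI drop of at
#' least 1 percentage point, realised through an SHBG rise and a
#' testosterone fall); non-responders drift with small noise. The
#' remaining variables shift in the direction observed under treatment.
#'
#' @param cohort_m0 Output of [generate_baseline()].
#' @param config The same [cohort_config()].
#' @return A tibble with m0, m6 and m12 rows for every patient and an
#'   enriched `ground_truth` attribute.
#' @export
generate_longitudinal <- function(cohort_m0, config) {
  stopifnot(inherits(config, "pcos_generator_config"))
  m0 <- cohort_m0[cohort_m0$visit == "m0", ]
  ind <- planted_indicators(m0, config$reference_cutoffs)
  n <- nrow(m0)
  p_bmi <- response_probability(config$response_model_bmi, ind)
  p_fai <- response_probability(config$response_model_fai, ind)
  p_bmi2 <- response_probability(config$response_model_bmi, ind,
                                 config$b0_shift_m12_bmi)
  p_fai2 <- response_probability(config$response_model_fai, ind,
                                 config$b0_shift_m12_fai)

  resp_bmi <- resp_fai <- resp_bmi2 <- resp_fai2 <- logical(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, 2L, i))
    resp_bmi[i] <- runif(1) < p_bmi[i]
    resp_fai[i] <- runif(1) < p_fai[i]
    resp_bmi2[i] <- runif(1) < p_bmi2[i]
    resp_fai2[i] <- runif(1) < p_fai2[i]
    base <- as.list(m0[i, ])
    h2 <- base$height_m^2
    evolve <- function(prev, rb, rf, second) {
      v <- shift_visit(prev, second)
      scale <- if (second) 0.6 else 1
      dbmi <- if (rb) -(1 + abs(rnorm(1, scale * 1.0, 0.6)))
              else rnorm(1, 0.15 * scale, 0.7)
      v$weight_kg <- max(prev$weight_kg + dbmi * h2, 35)
      fai_prev <- compute_fai(prev$t_ngml, prev$shbg)
      if (rf) {
        dfai <- 1 + abs(rnorm(1, scale * 1.2, 0.8))
        fai_new <- max(fai_prev - dfai, 0.3)
        v$shbg <- prev$shbg * (1 + abs(rnorm(1, 0.15, 0.08)))
      } else {
        fai_new <- max(fai_prev + rnorm(1, -0.3, 1.2), 0.3)
        v$shbg <- prev$shbg * max(1 + rnorm(1, 0.04, 0.08), 0.5)
      }
      v$t_ngml <- fai_new * v$shbg / 347
      v$pcom <- as.integer(runif(1) < (if (second) 0.63 else 0.52))
      v
    }
    v6 <- evolve(base, resp_bmi[i], resp_fai[i], FALSE)
    v6$visit <- "m6"
    v12 <- evolve(v6, resp_bmi2[i], resp_fai2[i], TRUE)
    v12$visit <- "m12"
    rows[[i]] <- dplyr::bind_rows(tibble::as_tibble(v6), tibble::as_tibble(v12))
  }
  out <- dplyr::bind_rows(m0, dplyr::bind_rows(rows))
  out <- out[order(out$patient_id, match(out$visit, visit_levels)), ]
  truth <- attr(cohort_m0, "ground_truth") %||% list()
  truth$responder_bmi <- setNames(resp_bmi, m0$patient_id)
  truth$responder_fai <- setNames(resp_fai, m0$patient_id)
  truth$responder_bmi_m12 <- setNames(resp_bmi2, m0$patient_id)
  truth$responder_fai_m12 <- setNames(resp_fai2, m0$patient_id)
  truth$response_prob_bmi <- setNames(p_bmi, m0$patient_id)
  attr(out, "ground_truth") <- truth
  out
}

#' Apply the planted drop-out and pregnancy process
#'
#' Drop-out is drawn per patient from a logistic model in the indicator
#' `baseline T < t_cutoff` with planted odds ratio `exp(gamma_lowT)`;
#' drop-outs are truncated at their interval (m0-m6 drop-outs keep only
#' m0, m6-m12 drop-outs keep m0 and m6), reasons follow a fixed
#' multinomial, and pregnancies are removed per interval at
#' `pregnancy_rate`.
#'
#' @param cohort Output of [generate_longitudinal()].
#' @param config The same [cohort_config()].
#' @return A validated `pcos_cohort`; the `ground_truth` attribute gains
#'   the drop-out latents.
#' @export
generate_dropout <- function(cohort, config) {
  stopifnot(inherits(config, "pcos_generator_config"))
  dm <- config$dropout_model
  m0 <- cohort[cohort$visit == "m0", ]
  n <- nrow(m0)
  low_t <- m0$t_ngml < dm$t_cutoff
  p_drop <- plogis(dm$gamma0 + dm$gamma_lowT * low_t)
  status <- rep("completed", n)
  interval <- rep("none", n)
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, 3L, i))
    if (runif(1) < p_drop[i]) {
      interval[i] <- if (runif(1) < config$p_first_interval) "m0_m6" else "m6_m12"
      status[i] <- sample(names(config$dropout_reason_probs), 1,
                          prob = config$dropout_reason_probs)
    } else if (runif(1) < config$pregnancy_rate) {
      status[i] <- "pregnant"; interval[i] <- "m0_m6"
    } else if (runif(1) < config$pregnancy_rate) {
      status[i] <- "pregnant"; interval[i] <- "m6_m12"
    }
  }
  keep <- rep(TRUE, nrow(cohort))
  idx <- match(cohort$patient_id, m0$patient_id)
  keep[interval[idx] == "m0_m6" & cohort$visit != "m0"] <- FALSE
  keep[interval[idx] == "m6_m12" & cohort$visit == "m12"] <- FALSE
  out <- cohort[keep, ]
  idx2 <- match(out$patient_id, m0$patient_id)
  out$status <- status[idx2]
  out$dropout_interval <- interval[idx2]
  truth <- attr(cohort, "ground_truth") %||% list()
  truth$dropout_prob <- setNames(p_drop, m0$patient_id)
  truth$low_t <- setNames(low_t, m0$patient_id)
  truth$status <- setNames(status, m0$patient_id)
  out <- as_cohort(out)
  attr(out, "ground_truth") <- truth
  out
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: baseline, longitudinal follow-up, then drop-out
#' and pregnancy truncation.
#'
#' @param config A [cohort_config()].
#' @return A validated `pcos_cohort` with a `ground_truth` attribute.
#' @export
generate_cohort <- function(config = cohort_config()) {
  generate_dropout(generate_longitudinal(generate_baseline(config), config),
                   config)
}
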