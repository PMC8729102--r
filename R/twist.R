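# TWIST-style evolutionary optimization: a genetic algorithm evolves, at
# the same time, a feature mask and an A/B record split; fitness is the
# ab/ba cross-validated performance of the backprop classifier (train on
# A test on B, train on B test on A, averaged). The published system
# couples a proprietary evolutionary engine to the networks; a standard
# elitist GA (tournament selection of size 2, uniform crossover, bit-flip
# mutation, split repaired to 40-60% balance) approximates it here — the
# validated surface is recovery of planted informative features, not
# equivalence with the original software.

#' Specification for the evolutionary search
#'
#' @param population_size Number of candidates (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Probabilities in `[0, 1]`.
#' @param elitism_count Candidates copied unchanged each generation.
#' @param seed Seed for the whole search.
#' @return A list of class `ga_spec`.
#' @export
ga_spec <- function(population_size = 50, generations = 100,
                    crossover_rate = 0.8, mutation_rate = 0.02,
                    elitism_count = 2, seed = 1) {
  if (population_size < 2) stop_domain("ga_spec: population_size must be >= 2")
  rates <- c(crossover_rate, mutation_rate)
  if (any(rates < 0 | rates > 1)) stop_domain("ga_spec: rates must be in [0,1]")
  if (elitism_count < 0 || elitism_count >= population_size)
    stop_domain("ga_spec: elitism_count must be in [0, population_size)")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed)),
            class = "ga_spec")
}

# Repair a candidate in place: at least one feature; split within 40-60%
# balance; both outcome classes on both sides (penalised later if
# impossible).
repair_candidate <- function(cand, y) {
  if (!any(cand$mask)) cand$mask[sample(length(cand$mask), 1)] <- TRUE
  n <- length(cand$split)
  lo <- ceiling(0.4 * n); hi <- floor(0.6 * n)
  nA <- sum(cand$split)
  while (nA < lo) {
    i <- sample(which(!cand$split), 1); cand$split[i] <- TRUE; nA <- nA + 1
  }
  while (nA > hi) {
    i <- sample(which(cand$split), 1); cand$split[i] <- FALSE; nA <- nA - 1
  }
  for (cls in c(0, 1)) {
    inA <- cand$split & y == cls
    inB <- !cand$split & y == cls
    if (!any(inA) && any(inB)) cand$split[sample(which(inB), 1)] <- TRUE
    if (!any(inB) && any(inA)) cand$split[sample(which(inA), 1)] <- FALSE
  }
  cand
}

split_valid <- function(split, y) {
  all(vapply(c(0, 1), function(cls)
    any(split & y == cls) && any(!split & y == cls), logical(1)))
}

#' ab/ba cross-validated fitness of a candidate
#'
#' Trains the classifier on half A of the candidate's split and scores it
#' on half B, then the reverse; fitness is the mean of the two metrics. A
#' split leaving a class absent from either half scores 0 (penalty).
#'
#' @param candidate List with `mask` (logical over features) and `split`
#'   (logical, `TRUE` = half A).
#' @param X Feature matrix.
#' @param y Binary 0/1 outcome.
#' @param spec An [mlp_spec()] for the fitness networks.
#' @param metric `"accuracy"` (default) or `"auc"`.
#' @return Scalar fitness.
#' @export
evaluate_ab_ba <- function(candidate, X, y, spec = mlp_spec(),
                           metric = c("accuracy", "auc")) {
  metric <- match.arg(metric)
  if (!any(candidate$mask))
    stop_domain("evaluate_ab_ba: candidate selects no features")
  if (!split_valid(candidate$split, y)) {
    message("evaluate_ab_ba: a split half lacks an outcome class; fitness 0")
    return(0)
  }
  Xm <- X[, candidate$mask, drop = FALSE]
  half <- function(train_idx, test_idx) {
    fit <- train_mlp(Xm[train_idx, , drop = FALSE], y[train_idx], spec)
    sc <- predict(fit, Xm[test_idx, , drop = FALSE])
    if (metric == "auc") roc_auc(sc, y[test_idx])
    else mean((sc > 0.5) == (y[test_idx] == 1))
  }
  A <- which(candidate$split); B <- which(!candidate$split)
  (half(A, B) + half(B, A)) / 2
}

#' Run the TWIST-style evolutionary feature selection
#'
#' @param X Feature matrix (>= 2 columns) with column names; >= 20 rows.
#' @param y Binary 0/1 outcome.
#' @param ga An [ga_spec()].
#' @param mlp An [mlp_spec()] used for every fitness evaluation.
#' @param metric Fitness metric, `"accuracy"` or `"auc"`.
#' @return Object of class `twist_result`: `mask` (logical, named),
#'   `features` (selected names), `split` (logical, `TRUE` = A),
#'   `fitness`, `history` (best fitness per generation, non-decreasing),
#'   `roc` (list `auc_ab`, `auc_ba`, `auc_mean`) of the final model under
#'   ab/ba.
#' @export
twist_run <- function(X, y, ga = ga_spec(), mlp = mlp_spec(),
                      metric = c("accuracy", "auc")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (nrow(X) < 20) stop_domain("twist_run: need at least 20 records")
  if (ncol(X) < 1) stop_domain("twist_run: need at least 1 feature")
  stopifnot(inherits(ga, "ga_spec"), inherits(mlp, "mlp_spec"))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)

  cache <- new.env(parent = emptyenv())
  fit_of <- function(cand) {
    key <- paste(c(cand$mask, cand$split), collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- if (split_valid(cand$split, y))
      evaluate_ab_ba(cand, X, y, mlp, metric) else 0
    cache[[key]] <- f
    f
  }

  with_seed(ga$seed, {
    if (p == 1) {
      cand <- repair_candidate(
        list(mask = TRUE, split = runif(n) < 0.5), y)
      f <- fit_of(cand)
      return(structure(list(
        mask = setNames(TRUE, colnames(X)), features = colnames(X),
        split = cand$split, fitness = f, history = f,
        roc = final_roc(cand, X, y, mlp)), class = "twist_result"))
    }
    pop <- lapply(seq_len(ga$population_size), function(i)
      repair_candidate(list(mask = runif(p) < 0.5, split = runif(n) < 0.5), y))
    fitness <- vapply(pop, fit_of, numeric(1))
    history <- numeric(ga$generations)
    for (g in seq_len(ga$generations)) {
      ord <- order(fitness, decreasing = TRUE)
      new_pop <- pop[ord[seq_len(ga$elitism_count)]]
      while (length(new_pop) < ga$population_size) {
        pick <- function() {
          ij <- sample(ga$population_size, 2)
          pop[[ij[which.max(fitness[ij])]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- p1
        if (runif(1) < ga$crossover_rate) {
          mm <- runif(p) < 0.5
          ms <- runif(n) < 0.5
          child$mask <- ifelse(mm, p1$mask, p2$mask)
          child$split <- ifelse(ms, p1$split, p2$split)
        }
        if (ga$mutation_rate > 0) {
          child$mask <- xor(child$mask, runif(p) < ga$mutation_rate)
          child$split <- xor(child$split, runif(n) < ga$mutation_rate)
        }
        new_pop[[length(new_pop) + 1]] <- repair_candidate(child, y)
      }
      pop <- new_pop
      fitness <- vapply(pop, fit_of, numeric(1))
      history[g] <- max(fitness)
    }
    best <- pop[[which.max(fitness)]]
    history <- cummax(history)  # elite track
    structure(list(
      mask = setNames(best$mask, colnames(X)),
      features = colnames(X)[best$mask],
      split = best$split,
      fitness = max(fitness),
      history = history,
      roc = final_roc(best, X, y, mlp)), class = "twist_result")
  })
}

final_roc <- function(cand, X, y, mlp) {
  Xm <- X[, cand$mask, drop = FALSE]
  A <- which(cand$split); B <- which(!cand$split)
  if (!split_valid(cand$split, y))
    return(list(auc_ab = NA_real_, auc_ba = NA_real_, auc_mean = NA_real_))
  sc_b <- predict(train_mlp(Xm[A, , drop = FALSE], y[A], mlp),
                  Xm[B, , drop = FALSE])
  sc_a <- predict(train_mlp(Xm[B, , drop = FALSE], y[B], mlp),
                  Xm[A, , drop = FALSE])
  ab <- roc_auc(sc_b, y[B]); ba <- roc_auc(sc_a, y[A])
  list(auc_ab = ab, auc_ba = ba, auc_mean = (ab + ba) / 2)
}

#' @export
print.twist_result <- function(x, ...) {
  cat(sprintf("TWIST selection: %d/%d features, fitness %.3f, mean AUC %.3f\n",
              sum(x$mask), length(x$mask), x$fitness, x$roc$auc_mean))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Planted logistic benchmark data
#'
#' Generates standard-normal features of which the first `p_inf` carry a
#' common logistic coefficient `beta` and the remaining `p_noise` are
#' pure noise; used for feature-recovery experiments.
#'
#' @param n Records.
#' @param p_inf Informative features.
#' @param p_noise Noise features.
#' @param beta Logistic coefficient of each informative feature.
#' @param seed Seed.
#' @return List with `X` (named columns `inf1..`, `noise1..`) and `y`.
#' @export
make_planted_logistic <- function(n = 600, p_inf = 4, p_noise = 8,
                                  beta = 1.5, seed = 1) {
  with_seed(seed, {
    X <- matrix(rnorm(n * (p_inf + p_noise)), n)
    colnames(X) <- c(paste0("inf", seq_len(p_inf)),
                     paste0("noise", seq_len(p_noise)))
    eta <- X[, seq_len(p_inf), drop = FALSE] %*% rep(beta, p_inf)
    y <- as.numeric(runif(n) < plogis(drop(eta)))
    list(X = X, y = y)
  })
}
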