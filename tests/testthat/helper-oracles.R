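# Independent oracles and small fixture builders used across the suite.

# Brute-force minimum spanning tree: enumerate all (N-1)-edge subsets of
# the complete graph in increasing total weight and return the weight of
# the first that spans. Independent of the Kruskal implementation.
bruteforce_mst_weight <- function(d) {
  N <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  nE <- length(w)
  combos <- utils::combn(nE, N - 1)
  tot <- colSums(matrix(w[combos], nrow = N - 1))
  ord <- order(tot)
  spanning <- function(edges) {
    parent <- seq_len(N)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in edges) {
      ri <- find(idx[e, 1]); rj <- find(idx[e, 2])
      if (ri == rj) return(FALSE)
      parent[ri] <- rj
    }
    TRUE
  }
  for (k in ord) if (spanning(combos[, k])) return(tot[k])
  stop("no spanning tree found")
}

random_distance_matrix <- function(N) {
  m <- matrix(0, N, N)
  m[upper.tri(m)] <- round(runif(N * (N - 1) / 2), 3)
  m <- m + t(m)
  dimnames(m) <- list(LETTERS[seq_len(N)], LETTERS[seq_len(N)])
  m
}

# Minimal hand-built cohort: `visits` is a named list patient -> visit
# vector; values can be overridden per patient via `...` functions.
tiny_cohort <- function(visits, bmi = NULL, fai = NULL,
                        status = NULL, interval = NULL) {
  rows <- list()
  for (pid in names(visits)) {
    for (v in visits[[pid]]) {
      b <- if (is.null(bmi)) 33 else bmi[[pid]][[v]]
      f <- if (is.null(fai)) 13 else fai[[pid]][[v]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = pid, visit = v, age = 28, height_m = 1.6,
        weight_kg = b * 1.6^2, glucose = 90, insulin = 18, tg = 110,
        tc = 185, ldl = 120, hdl = 43, waist = 100, hip = 110,
        t_ngml = f * 34.7 / 347, shbg = 34.7, dheas = 270, a4 = 4, fg = 12,
        lh = 7, fsh = 5.5, menses6 = 2, afc = 40, pcom = 1,
        status = if (is.null(status)) {
          if ("m12" %in% visits[[pid]]) "completed" else "dropout_no_benefit"
        } else status[[pid]],
        dropout_interval = if (is.null(interval)) {
          if ("m12" %in% visits[[pid]]) "none"
          else if ("m6" %in% visits[[pid]]) "m6_m12" else "m0_m6"
        } else interval[[pid]]
      )
    }
  }
  as_cohort(dplyr::bind_rows(rows))
}

dropped_status <- c("dropout_side_effects", "dropout_no_benefit",
                    "lost_followup")
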