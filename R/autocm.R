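# Auto-contractive map (Auto-CM): an unsupervised three-layer network
# whose converged weights encode many-to-many association strengths.
# For a record x (entries in [0,1]):
#   hidden   h_i  = x_i (1 - v_i/C)
#   net_j    = sum_i h_i (1 - W_ij/C)
#   output   out_j = h_j (1 - net_j/C)
# with contraction updates
#   dv_i   = x_i (x_i - h_i) (1 - v_i/C)
#   dW_ij  = h_i (h_j - out_j) (1 - W_ij/C)
# The W rule credits the contraction (h_j - out_j) of the receiving node
# to each sender in proportion to its own activation, mirroring the v
# rule; since h_j - out_j = h_j net_j / C >= 0, a weight only grows when
# both nodes fire together, which is what makes the converged W a
# many-to-many association measure.
# Training is batch: deltas are averaged over all records of an epoch and
# applied once, which makes the result invariant to row order and keeps
# the step size independent of n. Initialization is a uniform small
# positive constant (zero is a fixed point of the dv rule, so the weights
# must start off the origin); there is no randomness, so training is
# fully deterministic. The monotone weights v grow towards C, shutting
# the hidden layer down, and the matrix W freezes at values that rank
# co-occurring node pairs highest.

#' Train an auto-contractive map
#'
#' @param X Binary (or `[0,1]`) matrix, patients x nodes, with column
#'   names. At least 2 columns.
#' @param C Contraction parameter (> 0); defaults to the number of nodes,
#'   the usual convention.
#' @param max_epochs Epoch cap.
#' @param tol Convergence threshold on the energy
#'   `sum(|dv|) + sum(|dW|)` of an epoch.
#' @param init Initial value for all weights (small positive).
#' @return An object of class `autocm`: list with `C`, `v` (length N),
#'   `W` (N x N), `epochs`, `energy` (per-epoch trajectory), `converged`.
#' @export
train_autocm <- function(X, C = ncol(X), max_epochs = 10000, tol = 1e-6,
                         init = C * 1e-3) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop_domain("train_autocm: need at least 2 nodes")
  if (any(!is.finite(X)) || any(X < 0 | X > 1))
    stop_domain("train_autocm: X entries must lie in [0, 1]")
  if (!is.numeric(C) || C <= 0) stop_domain("train_autocm: C must be > 0")
  n <- nrow(X); N <- ncol(X)
  v <- rep(init, N)
  W <- matrix(init, N, N, dimnames = list(colnames(X), colnames(X)))
  energy <- numeric(0)
  converged <- FALSE
  for (ep in seq_len(max_epochs)) {
    h <- X * rep(1 - v / C, each = n)
    net <- h %*% (1 - W / C)
    out <- h * (1 - net / C)
    dv <- colMeans(X * (X - h)) * (1 - v / C)
    dW <- crossprod(h, h - out) / n * (1 - W / C)
    v <- v + dv
    W <- W + dW
    energy[ep] <- sum(abs(dv)) + sum(abs(dW))
    if (energy[ep] < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("auto-CM did not reach tol %.1e in %d epochs (energy %.3e)",
                    tol, max_epochs, energy[length(energy)]), call. = FALSE)
  structure(list(C = C, v = v, W = W, epochs = length(energy),
                 energy = energy, converged = converged,
                 labels = colnames(X)),
            class = "autocm")
}

#' @export
print.autocm <- function(x, ...) {
  cat(sprintf("Auto-CM model: %d nodes, C = %.3g, %d epochs (%s)\n",
              length(x$v), x$C, x$epochs,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Transform trained Auto-CM weights into node distances
#'
#' Higher association weight means smaller distance:
#' `d_ij = C - (W_ij + W_ji)/2` off the diagonal, `d_ii = 0`. The
#' spanning-tree filter operates on these unrescaled distances; a min-max
#' rescaled copy in `[0,1]` is attached as the `"scaled"` attribute for
#' layout purposes (all 0.5, with a warning, when the off-diagonal is
#' constant).
#'
#' @param model A trained [train_autocm()] model.
#' @return A symmetric non-negative distance matrix with node labels.
#' @export
weights_to_distances <- function(model) {
  stopifnot(inherits(model, "autocm"))
  if (model$epochs == 0) stop_domain("weights_to_distances: untrained model")
  S <- (model$W + t(model$W)) / 2
  d <- model$C - S
  diag(d) <- 0
  off <- d[upper.tri(d)]
  scaled <- d
  if (max(off) == min(off)) {
    warning("degenerate distance matrix: all off-diagonal distances equal; scaled copy set to 0.5",
            call. = FALSE)
    scaled[upper.tri(scaled) | lower.tri(scaled)] <- 0.5
  } else {
    resc <- (d - min(off)) / (max(off) - min(off))
    scaled <- resc
    diag(scaled) <- 0
  }
  attr(d, "scaled") <- scaled
  d
}
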