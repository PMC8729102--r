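#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with deterministic tie-breaking: edges are sorted
#' by (weight, node_i, node_j) with node labels compared
#' lexicographically, so equal-weight inputs always yield the same tree.
#' Infinite entries mark absent edges.
#'
#' @param d Symmetric non-negative matrix with node labels as dimnames
#'   (labels default to V1..VN).
#' @return A tibble (from, to, weight) of the N-1 tree edges, ordered as
#'   selected.
#' @export
minimum_spanning_tree <- function(d) {
  d <- as.matrix(d)
  N <- nrow(d)
  if (N < 2) stop_domain("minimum_spanning_tree: need N >= 2")
  if (any(is.na(d)) || any(d < 0, na.rm = TRUE))
    stop_domain("minimum_spanning_tree: entries must be non-negative")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop_domain("minimum_spanning_tree: matrix must be symmetric")
  labels <- rownames(d) %||% paste0("V", seq_len(N))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  finite <- is.finite(w)
  iu <- iu[finite, , drop = FALSE]; w <- w[finite]
  # normalize undirected edges so the lexicographically smaller label is 'from'
  li <- labels[iu[, 1]]; lj <- labels[iu[, 2]]
  swap <- li > lj
  from <- ifelse(swap, lj, li); to <- ifelse(swap, li, lj)
  ord <- order(w, from, to)
  iu <- iu[ord, , drop = FALSE]; w <- w[ord]
  from <- from[ord]; to <- to[ord]

  parent <- seq_len(N)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sel <- integer(0)
  for (e in seq_along(w)) {
    ri <- find(iu[e, 1]); rj <- find(iu[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      sel <- c(sel, e)
      if (length(sel) == N - 1) break
    }
  }
  if (length(sel) != N - 1)
    stop_domain("minimum_spanning_tree: graph is not connected")
  tibble::tibble(from = from[sel], to = to[sel], weight = w[sel])
}
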