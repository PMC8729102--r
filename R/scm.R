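#' Build a semantic connectivity map
#'
#' Composes the data-mining stage: auto-contractive map training on the
#' binary node matrix, weight-to-distance transformation, and the
#' minimum-spanning-tree filter. Pole priorities order the nodes by their
#' separation from the outcome pole in the tree: number of tree edges on
#' the path, ties broken by summed path weight, then label.
#'
#' @param X Binary node matrix (see [dichotomize_matrix()]).
#' @param C Contraction parameter, default number of nodes.
#' @param outcome_pole Column of `X` to use as pole (default
#'   `"RESPONDER"`).
#' @param max_epochs,tol Training controls, see [train_autocm()].
#' @return Object of class `pcos_scm`: list with `model`, `distances`,
#'   `mst_edges`, `graph` (igraph), `pole`, `priorities` (tibble node /
#'   hops / path_weight, ordered by priority).
#' @export
build_scm <- function(X, C = ncol(X), outcome_pole = "RESPONDER",
                      max_epochs = 10000, tol = 1e-6) {
  if (!outcome_pole %in% colnames(X))
    stop_domain("build_scm: pole '%s' is not a column of X", outcome_pole)
  model <- train_autocm(X, C = C, max_epochs = max_epochs, tol = tol)
  d <- weights_to_distances(model)
  edges <- minimum_spanning_tree(d)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  hops <- igraph::distances(g, v = outcome_pole, weights = NA)[1, ]
  wsum <- igraph::distances(g, v = outcome_pole,
                            weights = igraph::E(g)$weight)[1, ]
  nodes <- setdiff(names(hops), outcome_pole)
  pr <- tibble::tibble(node = nodes,
                       hops = as.integer(hops[nodes]),
                       path_weight = unname(wsum[nodes]))
  pr <- pr[order(pr$hops, pr$path_weight, pr$node), ]
  structure(list(model = model, distances = d, mst_edges = edges, graph = g,
                 pole = outcome_pole, priorities = pr),
            class = "pcos_scm")
}

#' @export
print.pcos_scm <- function(x, ...) {
  cat(sprintf("Semantic connectivity map: %d nodes, pole '%s'\n",
              length(x$model$v), x$pole))
  cat("Closest nodes to the pole:\n")
  print(utils::head(x$priorities, 8))
  invisible(x)
}

#' Export a semantic connectivity map
#'
#' Writes the tree as GraphML or DOT (via igraph), the distance matrix as
#' CSV, or the pole priorities as JSON.
#'
#' @param scm A `pcos_scm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @name scm-export
NULL

#' @rdname scm-export
#' @export
write_scm_graphml <- function(scm, path) {
  igraph::write_graph(scm$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname scm-export
#' @export
write_scm_dot <- function(scm, path) {
  igraph::write_graph(scm$graph, path, format = "dot")
  invisible(path)
}

#' @rdname scm-export
#' @export
write_scm_distances_csv <- function(scm, path) {
  d <- as.data.frame(scm$distances)
  d <- cbind(node = rownames(scm$distances), d)
  readr::write_csv(d, path)
  invisible(path)
}

#' @rdname scm-export
#' @export
write_pole_priorities_json <- function(scm, path) {
  jsonlite::write_json(list(pole = scm$pole, priorities = scm$priorities),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
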