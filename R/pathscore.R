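# Path-weighted association scoring: the core computation.
#
# A circRNA-disease pair is scored by enumerating every node-simple path of
# at most `eta` edges connecting them in the final heterogeneous network and
# summing, over these paths, the product of the traversed edge weights
# divided by an exponential length penalty alpha * exp(length). Longer paths
# therefore contribute exponentially less; paths longer than `eta` are not
# considered at all. Enumeration is a depth-first search that marks nodes on
# entry and unmarks them on backtrack, visiting neighbors in ascending node
# index, so the output path order is lexicographic and deterministic.

#' Enumerate bounded-length simple paths between a circRNA and a disease
#'
#' Returns exactly the set of node-simple paths (no repeated node) from
#' `circ` to `disease` with at most `eta` edges, each traversed edge having
#' positive weight in the final network. Every node-type sequence the graph
#' permits is admitted (e.g. for `eta = 3`: c-d, c-c-d, c-d-d, c-c-c-d,
#' c-c-d-d, c-d-d-d); the bound on edges is the only restriction. Paths are
#' returned in lexicographic order of their node index sequences.
#'
#' @param net a `"hetnet"` of stage `"final"` (see [apply_threshold()]).
#' @param circ,disease endpoint identifiers.
#' @param eta maximum number of edges per path (default 3).
#' @return list of paths; each path is a list with `nodes` (character ids,
#'   from `circ` to `disease`), `weights` (traversed edge weights) and
#'   `length` (number of edges).
#' @export
enumerate_paths <- function(net, circ, disease, eta = 3) {
  stopifnot(inherits(net, "hetnet"))
  .check(identical(net$stage, "final"),
         "network must be thresholded first (see apply_threshold)")
  .check(is.numeric(eta) && length(eta) == 1L && eta >= 1,
         "eta must be a positive integer")
  eta <- as.integer(eta)
  s <- match(circ, net$circ_ids)
  .check(!is.na(s), "unknown circRNA id: %s", circ)
  d <- match(disease, net$disease_ids)
  .check(!is.na(d), "unknown disease id: %s", disease)
  adj <- .hetnet_adjacency(net)
  target <- adj$n_circ + d
  paths <- list()
  visited <- logical(adj$n)
  visited[s] <- TRUE
  dfs <- function(node, depth, nodes, weights) {
    nbrs <- adj$nbr[[node]]
    ws <- adj$wts[[node]]
    for (k in seq_along(nbrs)) {
      nb <- nbrs[k]
      if (nb == target) {
        paths[[length(paths) + 1L]] <<- list(
          nodes = adj$node_ids[c(nodes, nb)],
          weights = c(weights, ws[k]),
          length = depth + 1L
        )
      } else if (depth + 1L < eta && !visited[nb]) {
        visited[nb] <<- TRUE
        dfs(nb, depth + 1L, c(nodes, nb), c(weights, ws[k]))
        visited[nb] <<- FALSE
      }
    }
  }
  dfs(s, 0L, s, numeric(0))
  paths
}

#' Score of a single path
#'
#' The product of the edge weights along the path; lies in `(0, 1]` since
#' every retained edge weight is in `(0, 1]`.
#'
#' @param path a path as returned by [enumerate_paths()], or a numeric vector
#'   of edge weights.
#' @return the weight product.
#' @export
path_score <- function(path) {
  w <- if (is.list(path)) path$weights else path
  stopifnot(is.numeric(w), length(w) >= 1L)
  prod(w)
}

#' Exponential path-length penalty
#'
#' `alpha * exp(length)`: each path's weight product is divided by this
#' factor, so a path one edge longer contributes a factor `e` less. `alpha`
#' rescales all contributions uniformly and therefore never changes the
#' ranking of pairs (nor any ROC/AUC computed from it).
#'
#' @param length path length in edges (`>= 1`).
#' @param alpha positive constraint factor (default 1).
#' @return the penalty `alpha * exp(length)`.
#' @export
path_decay <- function(length, alpha = 1) {
  .check(all(length >= 1), "path length must be >= 1")
  .check(is.numeric(alpha) && length(alpha) == 1L && alpha > 0,
         "alpha must be a positive scalar")
  alpha * exp(length)
}

#' Path-weighted association score of one circRNA-disease pair
#'
#' Sums `path_score(p) / path_decay(length(p), alpha)` over all node-simple
#' paths of at most `eta` edges between the endpoints; 0 when no such path
#' exists.
#'
#' @inheritParams enumerate_paths
#' @param alpha positive constraint factor of the length penalty.
#' @return a non-negative score.
#' @export
association_score <- function(net, circ, disease, alpha = 1, eta = 3) {
  .check(is.numeric(alpha) && length(alpha) == 1L && alpha > 0,
         "alpha must be a positive scalar")
  paths <- enumerate_paths(net, circ, disease, eta)
  if (!length(paths)) return(0)
  # alpha is factored out of the sum so that scores are exactly linear in
  # 1/alpha (one correctly-rounded division; rankings provably unaffected)
  sum(vapply(paths, function(p) prod(p$weights) / exp(p$length), 0)) / alpha
}

#' Path-weighted score matrix over all circRNA-disease pairs
#'
#' Computes [association_score()] for every pair in one depth-first traversal
#' per circRNA: starting from each circRNA node, the search walks all simple
#' paths of at most `eta` edges, and every time it stands on a disease node
#' it credits the current weight product (divided by the length penalty) to
#' that pair. This is exactly the sum over all simple paths ending at each
#' disease.
#'
#' @inheritParams association_score
#' @return numeric matrix (diseases x circRNAs) of non-negative scores, with
#'   identifiers as dimnames and attributes `alpha` and `eta`.
#' @export
score_matrix <- function(net, alpha = 1, eta = 3) {
  stopifnot(inherits(net, "hetnet"))
  .check(identical(net$stage, "final"),
         "network must be thresholded first (see apply_threshold)")
  .check(is.numeric(eta) && length(eta) == 1L && eta >= 1,
         "eta must be a positive integer")
  .check(is.numeric(alpha) && length(alpha) == 1L && alpha > 0,
         "alpha must be a positive scalar")
  eta <- as.integer(eta)
  adj <- .hetnet_adjacency(net)
  nc <- adj$n_circ
  nd <- adj$n_dis
  scores <- matrix(0, nd, nc, dimnames = list(net$disease_ids, net$circ_ids))
  decay <- exp(seq_len(eta)) # length penalty; alpha is factored out below
  visited <- logical(adj$n)
  col <- numeric(nd)
  dfs <- function(node, depth, prodw) {
    nbrs <- adj$nbr[[node]]
    ws <- adj$wts[[node]]
    d1 <- depth + 1L
    for (k in seq_along(nbrs)) {
      nb <- nbrs[k]
      if (visited[nb]) next
      p <- prodw * ws[k]
      if (nb > nc) col[nb - nc] <<- col[nb - nc] + p / decay[d1]
      if (d1 < eta) {
        visited[nb] <<- TRUE
        dfs(nb, d1, p)
        visited[nb] <<- FALSE
      }
    }
  }
  for (j in seq_len(nc)) {
    col[] <- 0
    visited[] <- FALSE
    visited[j] <- TRUE
    dfs(j, 0L, 1)
    scores[, j] <- col
  }
  # exactly linear in 1/alpha: a single division preserves all score ranks
  scores <- scores / alpha
  attr(scores, "alpha") <- alpha
  attr(scores, "eta") <- eta
  scores
}
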