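# Heterogeneous network assembly and edge-weight thresholding.
#
# The network has two node layers (circRNAs, diseases) and three edge blocks:
# circRNA-circRNA (integrated circRNA similarity), disease-disease
# (integrated disease similarity) and circRNA-disease (the bipartite
# association network). Similarity diagonals are masked at assembly: the
# path scorer only walks node-simple paths, so self-loops are never
# meaningful, and masking them keeps every traversal contract local.

#' Assemble the heterogeneous circRNA-disease network
#'
#' Combines the integrated circRNA similarity matrix, the integrated disease
#' similarity matrix and the association matrix into one undirected weighted
#' heterogeneous network (stage `"initial"`). Association edges built from a
#' binary matrix get weight 1; a pre-weighted bipartite block in `[0, 1]` is
#' also accepted, which is convenient for constructing worked examples.
#'
#' @param circ_sim symmetric circRNA similarity matrix (circRNAs x circRNAs).
#' @param dis_sim symmetric disease similarity matrix (diseases x diseases).
#' @param association matrix (diseases x circRNAs) with entries in `[0, 1]`;
#'   typically binary (see [build_association_matrix()]).
#' @return an object of class `"hetnet"`: list with `circ_ids`,
#'   `disease_ids`, weight blocks `circ_circ`, `dis_dis`, `circ_dis`
#'   (diseases x circRNAs), `stage` and, after thresholding, `gamma`.
#' @export
hetnet <- function(circ_sim, dis_sim, association) {
  circ_sim <- as.matrix(circ_sim)
  dis_sim <- as.matrix(dis_sim)
  association <- as.matrix(association) * 1.0
  .check(nrow(circ_sim) == ncol(circ_sim) && nrow(dis_sim) == ncol(dis_sim),
         "similarity blocks must be square")
  .check(ncol(association) == nrow(circ_sim) &&
           nrow(association) == nrow(dis_sim),
         "dimension mismatch: association is %dx%d but similarities are %d circRNAs, %d diseases",
         nrow(association), ncol(association), nrow(circ_sim), nrow(dis_sim))
  for (blk in list(circ_sim, dis_sim, association)) {
    .check(all(blk >= 0 & blk <= 1), "all edge weights must lie in [0, 1]")
  }
  .check(max(abs(circ_sim - t(circ_sim))) < 1e-12 &&
           max(abs(dis_sim - t(dis_sim))) < 1e-12,
         "similarity blocks must be symmetric")
  circ_ids <- colnames(association)
  disease_ids <- rownames(association)
  if (is.null(circ_ids)) circ_ids <- paste0("c", seq_len(ncol(association)))
  if (is.null(disease_ids)) disease_ids <- paste0("d", seq_len(nrow(association)))
  diag(circ_sim) <- 0 # self-loops masked from traversal
  diag(dis_sim) <- 0
  dimnames(circ_sim) <- list(circ_ids, circ_ids)
  dimnames(dis_sim) <- list(disease_ids, disease_ids)
  dimnames(association) <- list(disease_ids, circ_ids)
  structure(list(circ_ids = circ_ids, disease_ids = disease_ids,
                 circ_circ = circ_sim, dis_dis = dis_sim,
                 circ_dis = association, stage = "initial", gamma = NA_real_),
            class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  nc <- length(x$circ_ids); nd <- length(x$disease_ids)
  cat(sprintf("Heterogeneous network (%s): %d circRNAs, %d diseases\n",
              x$stage, nc, nd))
  cat(sprintf("  circRNA-circRNA edges: %d\n", sum(x$circ_circ > 0) / 2))
  cat(sprintf("  disease-disease edges: %d\n", sum(x$dis_dis > 0) / 2))
  cat(sprintf("  association edges:     %d\n", sum(x$circ_dis > 0)))
  if (!is.na(x$gamma)) cat(sprintf("  weight threshold gamma: %g\n", x$gamma))
  invisible(x)
}

#' Prune weak edges from the heterogeneous network
#'
#' Small weights are likely noise; every weight strictly below the threshold
#' `gamma` is set to 0 (edge removed) and weights `>= gamma` are kept
#' unchanged, uniformly across all three blocks. Association edges of weight
#' 1 always survive since `gamma <= 1`. The default `gamma = 0.5` is the
#' method's standard operating point. Idempotent at fixed `gamma`.
#'
#' @param net a `"hetnet"`.
#' @param gamma threshold in `[0, 1]`.
#' @return the pruned network, stage `"final"`.
#' @export
apply_threshold <- function(net, gamma = 0.5) {
  stopifnot(inherits(net, "hetnet"))
  .check(is.numeric(gamma) && length(gamma) == 1L && gamma >= 0 && gamma <= 1,
         "gamma must be a single value in [0, 1]")
  for (blk in c("circ_circ", "dis_dis", "circ_dis")) {
    w <- net[[blk]]
    w[w < gamma] <- 0
    net[[blk]] <- w
  }
  net$stage <- "final"
  net$gamma <- gamma
  net
}

#' Export the network as an edge list
#'
#' One row per undirected edge: `source_id, target_id, weight, edge_type`
#' with `edge_type` one of `"circRNA-circRNA"`, `"disease-disease"`,
#' `"circRNA-disease"`. Within-layer edges are reported once (upper
#' triangle).
#'
#' @param net a `"hetnet"`.
#' @return data frame edge list.
#' @export
as_edge_list <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  edges <- list()
  cc <- which(upper.tri(net$circ_circ) & net$circ_circ > 0, arr.ind = TRUE)
  if (nrow(cc)) {
    edges$cc <- data.frame(source_id = net$circ_ids[cc[, 1]],
                           target_id = net$circ_ids[cc[, 2]],
                           weight = net$circ_circ[cc],
                           edge_type = "circRNA-circRNA")
  }
  dd <- which(upper.tri(net$dis_dis) & net$dis_dis > 0, arr.ind = TRUE)
  if (nrow(dd)) {
    edges$dd <- data.frame(source_id = net$disease_ids[dd[, 1]],
                           target_id = net$disease_ids[dd[, 2]],
                           weight = net$dis_dis[dd],
                           edge_type = "disease-disease")
  }
  cd <- which(net$circ_dis > 0, arr.ind = TRUE)
  if (nrow(cd)) {
    edges$cd <- data.frame(source_id = net$circ_ids[cd[, 2]],
                           target_id = net$disease_ids[cd[, 1]],
                           weight = net$circ_dis[cd],
                           edge_type = "circRNA-disease")
  }
  if (!length(edges)) {
    return(data.frame(source_id = character(0), target_id = character(0),
                      weight = numeric(0), edge_type = character(0)))
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

# Combined adjacency for traversal: nodes 1..n_circ are circRNAs,
# n_circ+1..n_circ+n_dis are diseases. Neighbor lists are in ascending node
# index so depth-first enumeration is deterministic (lexicographic).
.hetnet_adjacency <- function(net) {
  nc <- length(net$circ_ids)
  nd <- length(net$disease_ids)
  n <- nc + nd
  a <- matrix(0, n, n)
  a[seq_len(nc), seq_len(nc)] <- net$circ_circ
  a[nc + seq_len(nd), nc + seq_len(nd)] <- net$dis_dis
  a[seq_len(nc), nc + seq_len(nd)] <- t(net$circ_dis)
  a[nc + seq_len(nd), seq_len(nc)] <- net$circ_dis
  nbr <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(a[i, ] > 0)
    nbr[[i]] <- js
    wts[[i]] <- a[i, js]
  }
  list(nbr = nbr, wts = wts, n_circ = nc, n_dis = nd, n = n,
       node_ids = c(net$circ_ids, net$disease_ids))
}
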