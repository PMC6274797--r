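# Similarity layer: annotation-based Jaccard similarity, Gaussian interaction
# profile (GIP) kernel similarity on association profiles, and their fusion.

#' Jaccard index of two term sets
#'
#' `|A intersect B| / |A union B|`. When both sets are empty the index is
#' defined here as 0: an entity with no annotations carries no evidence of
#' similarity, and a 0 correctly routes the pair to the GIP kernel fallback
#' during integration.
#'
#' @param set_a,set_b atomic vectors treated as sets (duplicates ignored).
#' @return a score in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d")) # 0.5
jaccard <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- length(a) + length(b) - sum(a %in% b)
  if (u == 0L) return(0)
  sum(a %in% b) / u
}

#' Pairwise Jaccard similarity matrix from an annotation catalog
#'
#' Builds the circRNA semantic similarity matrix (from GO-term sets of target
#' genes) or the disease functional similarity matrix (from gene annotation
#' sets): entry (i, j) is the Jaccard index of the two entities' term sets.
#' Entities absent from the catalog are treated as having an empty set, so
#' their rows are zero off-diagonal and their pairs fall back to the GIP
#' kernel at integration time. Diagonal entries are 1 for annotated entities
#' and 0 for empty-set entities; self-similarity is never traversed by the
#' path scorer, and integration restores a unit diagonal.
#'
#' @param catalog named list of term vectors (see [read_annotation_catalog()]).
#' @param ids ordered character vector of entity ids for rows/columns.
#' @return symmetric numeric matrix with entries in `[0, 1]` and `ids` as
#'   dimnames.
#' @export
annotation_similarity_matrix <- function(catalog, ids) {
  .check(!anyDuplicated(ids), "duplicate entity ids")
  n <- length(ids)
  sets <- lapply(ids, function(id) {
    s <- catalog[[id]]
    if (is.null(s)) character(0) else unique(s)
  })
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (length(sets[[i]]) > 0L) sim[i, i] <- 1
    for (j in seq_len(n)[-seq_len(i)]) {
      sim[i, j] <- sim[j, i] <- jaccard(sets[[i]], sets[[j]])
    }
  }
  sim
}

#' GIP kernel bandwidth
#'
#' The kernel bandwidth is the raw bandwidth `gamma_prime` normalized by the
#' mean squared Euclidean norm of the association profiles:
#' `gamma = gamma_prime / mean_i(||p_i||^2)`. The mean runs over all entities,
#' including those with all-zero profiles.
#'
#' @param profiles binary matrix, one association profile per row.
#' @param gamma_prime positive raw bandwidth (default 1, the standard
#'   operating point).
#' @return the bandwidth, a positive scalar.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  .check(is.numeric(gamma_prime) && length(gamma_prime) == 1L && gamma_prime > 0,
         "gamma_prime must be a positive scalar")
  profiles <- as.matrix(profiles)
  .check(nrow(profiles) >= 1L, "need at least one profile")
  mean_sq_norm <- mean(rowSums(profiles^2))
  .check(mean_sq_norm > 0,
         "degenerate bandwidth: all association profiles are zero")
  gamma_prime / mean_sq_norm
}

#' Gaussian interaction profile (GIP) kernel similarity matrix
#'
#' Computes `K(i, j) = exp(-gamma * ||p_i - p_j||^2)` over binary association
#' profiles, where a circRNA's profile is its column of the association
#' matrix (its pattern over diseases) and a disease's profile is its row (its
#' pattern over circRNAs). The bandwidth comes from [gip_bandwidth()]. The
#' kernel encodes the guilt-by-association assumption that entities with
#' similar association patterns are functionally similar.
#'
#' If the association matrix is entirely zero the bandwidth is undefined; the
#' identity kernel is returned with a warning (no evidence, no off-diagonal
#' similarity), which keeps cross-validation on tiny inputs from crashing.
#'
#' @param association binary matrix, diseases x circRNAs, with dimnames.
#' @param axis `"circRNA"` (kernel over columns) or `"disease"` (over rows).
#' @param gamma_prime positive raw bandwidth, see [gip_bandwidth()].
#' @return symmetric numeric matrix, entries in `(0, 1]`, unit diagonal;
#'   positive semidefinite.
#' @export
gip_kernel_matrix <- function(association, axis = c("circRNA", "disease"),
                              gamma_prime = 1) {
  axis <- match.arg(axis)
  m <- as.matrix(association)
  .check(all(m %in% c(0, 1)), "association matrix must be binary")
  profiles <- if (axis == "circRNA") t(m) else m
  ids <- rownames(profiles)
  n <- nrow(profiles)
  if (all(profiles == 0)) {
    warning("all-zero association matrix: GIP bandwidth degenerate, ",
            "returning identity kernel")
    k <- diag(1, n, n)
    dimnames(k) <- list(ids, ids)
    return(k)
  }
  gamma <- gip_bandwidth(profiles, gamma_prime)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0 # numerical noise from the cross product
  k <- exp(-gamma * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  dimnames(k) <- list(ids, ids)
  k
}

#' Integrate an annotation similarity matrix with its GIP fallback
#'
#' Fuses the sparse annotation-based similarity (primary) with the dense GIP
#' kernel similarity (fallback): each entry keeps the primary value where it
#' is nonzero and takes the fallback value otherwise. This fills the holes
#' left by entities with missing or non-overlapping annotations.
#'
#' @param primary,fallback square numeric matrices over the same ids (checked
#'   via dimnames).
#' @return the integrated similarity matrix.
#' @export
integrate_similarity <- function(primary, fallback) {
  .check(is.matrix(primary) && is.matrix(fallback) &&
           identical(dim(primary), dim(fallback)),
         "similarity matrices must have identical shape")
  .check(identical(dimnames(primary), dimnames(fallback)),
         "similarity matrices must cover the same ids in the same order")
  out <- primary
  zero <- primary == 0
  out[zero] <- fallback[zero]
  out
}
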