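# Independent brute-force oracles. These deliberately share no code with the
# package internals: path enumeration expands all node sequences level by
# level and filters, instead of a marking depth-first search; AUC counts
# concordant positive/negative pairs instead of sweeping thresholds.

# Full (n_circ + n_dis) x (n_circ + n_dis) adjacency of a hetnet,
# circRNAs first.
oracle_adjacency <- function(net) {
  nc <- length(net$circ_ids)
  nd <- length(net$disease_ids)
  a <- matrix(0, nc + nd, nc + nd)
  a[seq_len(nc), seq_len(nc)] <- net$circ_circ
  a[nc + seq_len(nd), nc + seq_len(nd)] <- net$dis_dis
  a[nc + seq_len(nd), seq_len(nc)] <- net$circ_dis
  a[seq_len(nc), nc + seq_len(nd)] <- t(net$circ_dis)
  diag(a) <- 0
  a
}

# All simple paths from `from` to `to` with <= eta edges, as a list of node
# index sequences, by exhaustive expansion of all node sequences.
oracle_paths <- function(a, from, to, eta) {
  n <- nrow(a)
  found <- list()
  frontier <- list(from)
  for (step in seq_len(eta)) {
    nxt <- list()
    for (s in frontier) {
      last <- s[length(s)]
      for (v in seq_len(n)) {
        if (v %in% s || a[last, v] <= 0) next
        ext <- c(s, v)
        if (v == to) found[[length(found) + 1L]] <- ext
        else nxt[[length(nxt) + 1L]] <- ext
      }
    }
    frontier <- nxt
  }
  found
}

oracle_pair_score <- function(a, from, to, eta, alpha) {
  paths <- oracle_paths(a, from, to, eta)
  if (!length(paths)) return(0)
  sum(vapply(paths, function(s) {
    w <- vapply(seq_len(length(s) - 1L), function(i) a[s[i], s[i + 1L]], 0)
    prod(w) / (alpha * exp(length(s) - 1L))
  }, 0))
}

oracle_score_matrix <- function(net, alpha = 1, eta = 3) {
  a <- oracle_adjacency(net)
  nc <- length(net$circ_ids)
  nd <- length(net$disease_ids)
  out <- matrix(0, nd, nc, dimnames = list(net$disease_ids, net$circ_ids))
  for (j in seq_len(nc)) {
    for (i in seq_len(nd)) {
      out[i, j] <- oracle_pair_score(a, j, nc + i, eta, alpha)
    }
  }
  out
}

# AUC as the Mann-Whitney statistic: fraction of (positive, negative) pairs
# where the positive outranks the negative, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Brute-force pairwise Jaccard matrix over a catalog.
oracle_jaccard_matrix <- function(catalog, ids) {
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- unique(catalog[[ids[i]]])
      b <- unique(catalog[[ids[j]]])
      inter <- length(intersect(a, b))
      uni <- length(union(a, b))
      out[i, j] <- if (uni == 0) 0 else inter / uni
    }
  }
  out
}
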