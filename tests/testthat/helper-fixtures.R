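# Fixtures built in code.

# Worked-example network: five circRNAs, three diseases, ten edges. The
# query pair (c1, d2) is connected by exactly three simple paths of at most
# three edges: c1-c4-d2, c1-c3-d1-d2 and c1-c5-d3-d2; the four-edge route
# c1-c2-c5-d3-d2 exceeds the bound. Edge weights:
#   c1-c3 0.9, c1-c4 0.8, c1-c5 0.7, c3-d1 0.9, c4-d2 0.6, c5-d3 0.8,
#   d1-d2 0.9, d3-d2 0.7, plus c1-c2 0.9 and c2-c5 0.8.
toy_network <- function(gamma = 0.5) {
  circ <- paste0("c", 1:5)
  dis <- paste0("d", 1:3)
  cc <- matrix(0, 5, 5, dimnames = list(circ, circ))
  cc["c1", "c3"] <- cc["c3", "c1"] <- 0.9
  cc["c1", "c4"] <- cc["c4", "c1"] <- 0.8
  cc["c1", "c5"] <- cc["c5", "c1"] <- 0.7
  cc["c1", "c2"] <- cc["c2", "c1"] <- 0.9
  cc["c2", "c5"] <- cc["c5", "c2"] <- 0.8
  dd <- matrix(0, 3, 3, dimnames = list(dis, dis))
  dd["d1", "d2"] <- dd["d2", "d1"] <- 0.9
  dd["d3", "d2"] <- dd["d2", "d3"] <- 0.7
  cd <- matrix(0, 3, 5, dimnames = list(dis, circ))
  cd["d1", "c3"] <- 0.9
  cd["d2", "c4"] <- 0.6
  cd["d3", "c5"] <- 0.8
  apply_threshold(hetnet(cc, dd, cd), gamma)
}

# hand value of the worked example score for (c1, d2) at alpha = 1
toy_expected_score <- function() {
  0.8 * 0.6 / exp(2) + 0.9 * 0.9 * 0.9 / exp(3) + 0.7 * 0.8 * 0.7 / exp(3)
}

# Random small heterogeneous network (thresholded), for oracle comparisons.
random_network <- function(n_circ, n_dis, seed, edge_prob = 0.5, gamma = 0) {
  set.seed(seed)
  cc <- matrix(0, n_circ, n_circ)
  cc[upper.tri(cc)] <- stats::runif(n_circ * (n_circ - 1) / 2) *
    stats::rbinom(n_circ * (n_circ - 1) / 2, 1, edge_prob)
  cc <- cc + t(cc)
  dd <- matrix(0, n_dis, n_dis)
  dd[upper.tri(dd)] <- stats::runif(n_dis * (n_dis - 1) / 2) *
    stats::rbinom(n_dis * (n_dis - 1) / 2, 1, edge_prob)
  dd <- dd + t(dd)
  cd <- matrix(stats::rbinom(n_dis * n_circ, 1, edge_prob), n_dis, n_circ)
  dimnames(cc) <- list(paste0("c", 1:n_circ), paste0("c", 1:n_circ))
  dimnames(dd) <- list(paste0("d", 1:n_dis), paste0("d", 1:n_dis))
  dimnames(cd) <- list(paste0("d", 1:n_dis), paste0("c", 1:n_circ))
  apply_threshold(hetnet(cc, dd, cd), gamma)
}

# Random annotation catalog over a fixed vocabulary.
random_catalog <- function(ids, seed, n_terms = 12, max_size = 6,
                           empty_prob = 0.2) {
  set.seed(seed)
  vocab <- paste0("t", seq_len(n_terms))
  out <- list()
  for (id in ids) {
    if (stats::runif(1) < empty_prob) next
    out[[id]] <- sample(vocab, sample.int(max_size, 1))
  }
  out
}

# Small handmade association table: 3 diseases x 4 circRNAs, every disease
# with at least two associations.
handmade_table <- function() {
  association_table(data.frame(
    circRNA_id = c("c1", "c2", "c1", "c3", "c4", "c2", "c4"),
    disease_id = c("dA", "dA", "dB", "dB", "dB", "dC", "dC")
  ))
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
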