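test_that("worked example yields exactly three bounded-length simple paths", {
  net <- toy_network()
  paths <- enumerate_paths(net, "c1", "d2", eta = 3)
  nodes <- lapply(paths, `[[`, "nodes")
  expect_equal(nodes, list(c("c1", "c3", "d1", "d2"),
                           c("c1", "c4", "d2"),
                           c("c1", "c5", "d3", "d2"))) # lexicographic order
  # the four-edge route through c2 is excluded by the length bound
  expect_false(any(vapply(nodes, identical, NA, c("c1", "c2", "c5", "d3", "d2"))))
  expect_equal(vapply(paths, `[[`, 0L, "length"), c(3L, 2L, 3L))
  # raising the bound admits it
  paths4 <- enumerate_paths(net, "c1", "d2", eta = 4)
  expect_true(any(vapply(lapply(paths4, `[[`, "nodes"), identical, NA,
                         c("c1", "c2", "c5", "d3", "d2"))))
})

test_that("path enumeration handles direct edges and unknown endpoints", {
  cc <- matrix(0, 1, 1, dimnames = list("c1", "c1"))
  dd <- matrix(0, 1, 1, dimnames = list("d1", "d1"))
  m <- matrix(1, 1, 1, dimnames = list("d1", "c1"))
  net <- apply_threshold(hetnet(cc, dd, m), 0.5)
  paths <- enumerate_paths(net, "c1", "d1", eta = 3)
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$length, 1L)
  expect_equal(paths[[1]]$weights, 1)
  expect_error(enumerate_paths(net, "c9", "d1"), "unknown circRNA")
  expect_error(enumerate_paths(net, "c1", "dX"), "unknown disease")
})

test_that("path enumeration equals brute-force enumeration on random graphs", {
  for (seed in 1:20) {
    n_circ <- sample(2:5, 1)
    n_dis <- sample(2:3, 1)
    net <- random_network(n_circ, n_dis, seed = seed, gamma = 0)
    a <- oracle_adjacency(net)
    circ <- sample(net$circ_ids, 1)
    dis <- sample(net$disease_ids, 1)
    got <- enumerate_paths(net, circ, dis, eta = 3)
    want <- oracle_paths(a, match(circ, net$circ_ids),
                         n_circ + match(dis, net$disease_ids), eta = 3)
    ids <- c(net$circ_ids, net$disease_ids)
    got_keys <- sort(vapply(got, function(p) paste(p$nodes, collapse = ">"), ""))
    want_keys <- sort(vapply(want, function(s) paste(ids[s], collapse = ">"), ""))
    expect_identical(got_keys, want_keys)
  }
})

test_that("path score is the edge-weight product and decay is alpha e^len", {
  expect_equal(path_score(c(0.8, 0.5)), 0.4)
  expect_equal(path_score(1), 1)
  expect_equal(path_score(c(0.9, 0.9, 0.9)), 0.729)
  expect_equal(path_decay(1), exp(1))
  expect_equal(path_decay(3), exp(3))
  expect_equal(path_decay(2, alpha = 2), 2 * path_decay(2, alpha = 1))
  expect_error(path_decay(0), ">= 1")
  expect_error(path_decay(2, alpha = 0), "positive")
})

test_that("association scores sum decayed path products", {
  net <- toy_network()
  expect_equal(association_score(net, "c1", "d2"), toy_expected_score())
  # single direct edge of weight w scores w / e
  cc <- matrix(0, 1, 1, dimnames = list("c1", "c1"))
  dd <- matrix(0, 1, 1, dimnames = list("d1", "d1"))
  m <- matrix(1, 1, 1, dimnames = list("d1", "c1"))
  single <- apply_threshold(hetnet(cc, dd, m), 0.5)
  expect_equal(association_score(single, "c1", "d1"), 1 / exp(1))
  # disconnected pair scores zero
  m0 <- matrix(0, 1, 1, dimnames = list("d1", "c1"))
  none <- apply_threshold(hetnet(cc, dd, m0), 0.5)
  expect_equal(association_score(none, "c1", "d1"), 0)
})

test_that("score matrix equals the per-pair score and the brute-force oracle", {
  for (seed in 1:25) {
    net <- random_network(sample(2:5, 1), sample(2:3, 1), seed = seed,
                          gamma = sample(c(0, 0.25, 0.5), 1))
    s <- score_matrix(net, alpha = 1, eta = 3)
    expect_equal(s, oracle_score_matrix(net, alpha = 1, eta = 3),
                 tolerance = 1e-12,
                 ignore_attr = TRUE)
    # spot-check one pair against the targeted scorer
    circ <- sample(net$circ_ids, 1)
    dis <- sample(net$disease_ids, 1)
    expect_equal(s[dis, circ], association_score(net, circ, dis))
  }
})

test_that("alpha rescales every score by the same constant", {
  net <- toy_network()
  s1 <- score_matrix(net, alpha = 1)
  s2 <- score_matrix(net, alpha = 2)
  s05 <- score_matrix(net, alpha = 0.5)
  expect_equal(unname(s2), unname(s1) / 2, ignore_attr = TRUE)
  expect_equal(unname(s05), unname(s1) * 2, ignore_attr = TRUE)
})

test_that("scores respond monotonically to edge additions and removals", {
  net <- random_network(5, 3, seed = 42, gamma = 0.25)
  s <- score_matrix(net)
  # removing an edge never increases any score
  less <- net
  nz <- which(less$circ_circ > 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    i <- nz[1, 1]; j <- nz[1, 2]
    less$circ_circ[i, j] <- less$circ_circ[j, i] <- 0
    expect_true(all(score_matrix(less) <= s + 1e-15))
  }
  # adding an edge never decreases any score
  more <- net
  z <- which(upper.tri(more$dis_dis) & more$dis_dis == 0, arr.ind = TRUE)
  if (nrow(z) > 0) {
    i <- z[1, 1]; j <- z[1, 2]
    more$dis_dis[i, j] <- more$dis_dis[j, i] <- 0.8
    expect_true(all(score_matrix(more) >= s - 1e-15))
  }
})

test_that("no contributing path exceeds the length bound", {
  net <- random_network(5, 3, seed = 9, gamma = 0)
  for (eta in 1:3) {
    for (dis in net$disease_ids) {
      lens <- vapply(enumerate_paths(net, net$circ_ids[1], dis, eta),
                     `[[`, 0L, "length")
      expect_true(all(lens <= eta))
    }
  }
})

test_that("path enumeration agrees with igraph's simple-path enumeration", {
  net <- random_network(4, 3, seed = 77, gamma = 0)
  a <- oracle_adjacency(net)
  g <- igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected")
  for (dis in net$disease_ids) {
    target <- 4 + match(dis, net$disease_ids)
    ig <- igraph::all_simple_paths(g, from = 1, to = target, cutoff = 3)
    got <- enumerate_paths(net, net$circ_ids[1], dis, eta = 3)
    expect_equal(length(got), length(ig))
  }
})
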