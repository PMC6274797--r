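test_that("jaccard index handles overlap, identity, disjoint and empty sets", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
  expect_equal(jaccard(character(0), c("a")), 0)
  # duplicates are ignored (set semantics)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "b")), 0.5)
})

test_that("annotation similarity matrix matches the brute-force oracle", {
  for (seed in 1:5) {
    ids <- paste0("e", 1:6)
    cat <- random_catalog(ids, seed = seed)
    sim <- annotation_similarity_matrix(cat, ids)
    expect_identical(sim, oracle_jaccard_matrix(cat, ids))
    expect_true(isSymmetric(sim))
    expect_true(all(sim >= 0 & sim <= 1))
  }
})

test_that("entities with empty annotation sets get zero similarity rows", {
  cat <- list(a = c("t1", "t2"), b = c("t1", "t2"))
  sim <- annotation_similarity_matrix(cat, c("a", "b", "c"))
  expect_equal(sim["a", "b"], 1) # identical nonempty sets
  expect_equal(sim["c", "a"], 0)
  expect_equal(sim["c", "c"], 0) # unannotated: no self-evidence either
  expect_equal(sim["a", "a"], 1)
})

test_that("GIP bandwidth follows the mean-squared-norm normalization", {
  expect_equal(gip_bandwidth(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(gip_bandwidth(rbind(c(1, 1, 0))), 0.5)
  # linear in the raw bandwidth
  p <- rbind(c(1, 0, 1), c(1, 1, 0))
  expect_equal(gip_bandwidth(p, 2), 2 * gip_bandwidth(p, 1))
  expect_error(gip_bandwidth(rbind(c(0, 0))), "degenerate")
  expect_error(gip_bandwidth(p, -1), "positive")
})

test_that("GIP kernel gives exp(-gamma * squared profile distance)", {
  # two circRNAs with orthogonal unit profiles: bandwidth 1, distance^2 = 2
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("d1", "d2"), c("c1", "c2")))
  kc <- gip_kernel_matrix(m, "circRNA")
  expect_equal(kc["c1", "c2"], exp(-2))
  expect_equal(diag(kc), c(c1 = 1, c2 = 1))
  # identical profiles score 1
  m2 <- matrix(c(1L, 1L, 1L, 1L), 2, 2,
               dimnames = list(c("d1", "d2"), c("c1", "c2")))
  expect_equal(gip_kernel_matrix(m2, "circRNA")["c1", "c2"], 1)
})

test_that("GIP kernels are symmetric, unit-diagonal, in (0,1] and PSD", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(stats::rbinom(12, 1, 0.4), 4, 3,
                dimnames = list(paste0("d", 1:4), paste0("c", 1:3)))
    if (all(m == 0)) m[1, 1] <- 1L
    for (axis in c("circRNA", "disease")) {
      k <- gip_kernel_matrix(m, axis)
      expect_true(isSymmetric(k))
      expect_true(all(k > 0 & k <= 1))
      expect_equal(unname(diag(k)), rep(1, nrow(k)))
      expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-9)
    }
  }
})

test_that("all-zero association matrix yields the identity kernel with a warning", {
  m <- matrix(0L, 2, 3, dimnames = list(paste0("d", 1:2), paste0("c", 1:3)))
  expect_warning(k <- gip_kernel_matrix(m, "circRNA"), "identity")
  expect_equal(unname(k), diag(3))
})

test_that("integration keeps nonzero primary entries and falls back elsewhere", {
  ids <- c("a", "b")
  p <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(ids, ids))
  f <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(ids, ids))
  expect_equal(integrate_similarity(p, f)["a", "b"], 0.2)
  p0 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(ids, ids))
  f3 <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(ids, ids))
  expect_equal(integrate_similarity(p0, f3)["a", "b"], 0.3)
  # all-zero primary returns the fallback wholesale
  z <- matrix(0, 2, 2, dimnames = list(ids, ids))
  expect_identical(integrate_similarity(z, f), f)
  # id mismatch refused
  f_bad <- f
  dimnames(f_bad) <- list(c("a", "x"), c("a", "x"))
  expect_error(integrate_similarity(p, f_bad), "same ids")
})

test_that("integration is idempotent", {
  for (seed in 1:5) {
    set.seed(seed)
    ids <- paste0("e", 1:5)
    p <- matrix(stats::runif(25) * stats::rbinom(25, 1, 0.4), 5, 5)
    p <- (p + t(p)) / 2
    f <- matrix(stats::runif(25), 5, 5)
    f <- (f + t(f)) / 2
    dimnames(p) <- dimnames(f) <- list(ids, ids)
    once <- integrate_similarity(p, f)
    expect_identical(integrate_similarity(once, f), once)
  }
})
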