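test_that("ROC handles separation, ties and the textbook example", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # pos {0.9, 0.4}, neg {0.6, 0.1}: 3 of 4 pairs concordant
  expect_equal(roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_curve(c(1, 2), c(1, 1)), "one positive and one negative")
})

test_that("ROC points sweep from (0,0) to (1,1) monotonically", {
  set.seed(4)
  scores <- round(stats::runif(60), 1) # force ties
  labels <- stats::rbinom(60, 1, 0.4)
  roc <- roc_curve(scores, labels)
  p <- roc$points
  expect_equal(p$FPR[1], 0)
  expect_equal(p$TPR[1], 0)
  expect_equal(p$FPR[nrow(p)], 1)
  expect_equal(p$TPR[nrow(p)], 1)
  expect_true(all(diff(p$FPR) >= 0))
  expect_true(all(diff(p$TPR) >= 0))
})

test_that("trapezoidal AUC equals concordant-pair counting on random data", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:200, 1)
    scores <- sample(round(stats::runif(n), sample(1:3, 1))) # tie-rich
    labels <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_curve(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a tie-rich sample", {
  set.seed(8)
  scores <- round(stats::runif(100), 1)
  labels <- stats::rbinom(100, 1, 0.5)
  expect_equal(roc_curve(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("leave-one-out bookkeeping: folds, skips, degenerate inputs", {
  # one disease, two circRNAs, both associated: 2 folds, nothing skipped,
  # but no negative pair exists so AUC is undefined
  tab <- association_table(data.frame(circRNA_id = c("c1", "c2"),
                                      disease_id = c("dA", "dA")))
  expect_warning(cv <- pwcda_cv(tab, scheme = "loocv"), "no negative")
  expect_equal(cv$n_folds, 2L)
  expect_length(cv$skipped_diseases, 0L)
  expect_equal(sum(cv$labeled$label == "positive"), 2L)
  expect_true(is.na(cv$auc))

  # a disease with a single association is skipped and reported
  tab2 <- association_table(data.frame(
    circRNA_id = c("c1", "c2", "c3"),
    disease_id = c("dA", "dA", "dB")
  ))
  cv2 <- pwcda_cv(tab2, scheme = "loocv")
  expect_equal(cv2$skipped_diseases, "db")
  expect_equal(sum(cv2$labeled$label == "positive"), 2L)

  # every disease single-association: no eligible test pair
  tab3 <- association_table(data.frame(circRNA_id = c("c1", "c2"),
                                       disease_id = c("dA", "dB")))
  expect_error(pwcda_cv(tab3, scheme = "loocv"), "no eligible test pair")
})

test_that("k-fold folds partition the positives and respect the seed", {
  tab <- handmade_table()
  cv_a <- pwcda_cv(tab, scheme = "kfold", k = 3, seed = 42)
  cv_b <- pwcda_cv(tab, scheme = "kfold", k = 3, seed = 42)
  expect_identical(cv_a$labeled, cv_b$labeled)
  expect_identical(cv_a$auc, cv_b$auc)
  # every positive tested exactly once
  expect_equal(sum(cv_a$labeled$label == "positive"), nrow(tab$pairs))
  expect_error(pwcda_cv(tab, scheme = "kfold", k = 100), "exceeds")
  expect_error(pwcda_cv(tab, scheme = "kfold", k = 1), ">= 2")
})

test_that("k = n positives reduces to association-level leave-one-out", {
  tab <- handmade_table() # every disease has >= 2 associations: no skips
  n_pos <- nrow(tab$pairs)
  loo <- pwcda_cv(tab, scheme = "loocv")
  kf <- pwcda_cv(tab, scheme = "kfold", k = n_pos, seed = 3)
  key <- function(cv) {
    pos <- cv$labeled[cv$labeled$label == "positive", ]
    pos <- pos[order(pos$disease_id, pos$circRNA_id), ]
    pos$score
  }
  expect_equal(key(kf), key(loo))
})

test_that("cross-validated AUC is invariant to alpha", {
  d <- generate_synthetic(synthetic_spec(n_circ = 15, n_dis = 6, seed = 2))
  aucs <- vapply(c(0.5, 1, 2), function(a) {
    pwcda_cv(d$table, d$circ_catalog, d$disease_catalog,
             scheme = "kfold", k = 4, seed = 9, alpha = a)$auc
  }, 0)
  expect_identical(aucs[1], aucs[2])
  expect_identical(aucs[2], aucs[3])
})

test_that("planted associations are recovered above the chance baseline", {
  d <- generate_synthetic(synthetic_spec(n_circ = 20, n_dis = 8, seed = 5))
  cv <- pwcda_cv(d$table, d$circ_catalog, d$disease_catalog, scheme = "loocv")
  expect_gt(cv$auc, 0.5)
  kf <- pwcda_cv(d$table, d$circ_catalog, d$disease_catalog,
                 scheme = "kfold", k = 5, seed = 1)
  expect_gt(kf$auc, 0.5)
})
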