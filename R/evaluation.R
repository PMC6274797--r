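# Cross-validation over known associations, with per-fold network
# rebuilding, ROC construction and AUC.
#
# Protocol: the annotation-based Jaccard similarities never touch the
# association matrix, so they are computed once; the GIP kernels, the
# integrated similarities and the thresholded network are recomputed per
# fold from the training associations only (scoring a held-out edge with a
# kernel that saw it would leak the label). Negative pairs (absent from the
# full known-association set) are never held out; they are scored once under
# the all-data model. Each held-out positive is scored under its own
# training model and pooled with the negatives for the ROC.

#' ROC curve and AUC from labeled scores
#'
#' Sweeps the classification threshold over the distinct score values
#' (descending); at each threshold a pair is called associated when its score
#' is `>= threshold`, giving one `(FPR, TPR)` point with
#' `TPR = TP / (TP + FN)` and `FPR = FP / (TN + FP)`. The AUC is the
#' trapezoidal area under the sweep, which equals the Mann-Whitney statistic
#' with ties counted 1/2.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels logical (or 0/1) vector, `TRUE` for known (positive) pairs;
#'   at least one positive and one negative are required.
#' @return an object of class `"roc_curve"`: list with `points` (data frame
#'   `threshold, FPR, TPR`, starting at `(Inf, 0, 0)` and ending at
#'   `(min score, 1, 1)`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  .check(n_pos >= 1L && n_neg >= 1L,
         "ROC needs at least one positive and one negative (got %d/%d)",
         n_pos, n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_tie <- cumsum(rle(s)$lengths) # one point per distinct score
  tpr <- cumsum(y)[last_of_tie] / n_pos
  fpr <- cumsum(!y)[last_of_tie] / n_neg
  points <- data.frame(threshold = c(Inf, s[last_of_tie]),
                       FPR = c(0, fpr), TPR = c(0, tpr))
  auc <- sum(diff(points$FPR) *
               (points$TPR[-1] + points$TPR[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

# Rebuild the full model network from a (training) association matrix.
# Jaccard similarities cs/ds are fold-independent and passed in precomputed.
.build_network <- function(m, cs, ds, gamma = 0.5,
                           gamma_prime_circ = 1, gamma_prime_disease = 1) {
  kc <- gip_kernel_matrix(m, "circRNA", gamma_prime_circ)
  kd <- gip_kernel_matrix(m, "disease", gamma_prime_disease)
  ics <- integrate_similarity(cs, kc)
  ids <- integrate_similarity(ds, kd)
  apply_threshold(hetnet(ics, ids, m), gamma)
}

.cv_labeled <- function(disease_ids, circ_ids, pos_idx, pos_scores, m_full,
                        full_scores) {
  neg <- which(m_full == 0, arr.ind = TRUE)
  out <- data.frame(disease_id = disease_ids[pos_idx[, 1]],
                    circRNA_id = circ_ids[pos_idx[, 2]],
                    score = pos_scores, label = "positive")
  if (nrow(neg) > 0) {
    out <- rbind(out, data.frame(disease_id = disease_ids[neg[, 1]],
                                 circRNA_id = circ_ids[neg[, 2]],
                                 score = full_scores[neg],
                                 label = "negative"))
  }
  out
}

#' Cross-validated evaluation of path-weighted association prediction
#'
#' Estimates how well the method recovers held-out known associations.
#' Two schemes:
#'
#' * `"loocv"`: each known association is held out in turn; the training
#'   association matrix has that single entry zeroed, the GIP kernels,
#'   integrated similarities and thresholded network are rebuilt from the
#'   training data only, and the held-out pair's score under that model is
#'   recorded as a positive. Diseases with exactly one known association are
#'   skipped (no training signal for that disease) and reported in
#'   `skipped_diseases`.
#' * `"kfold"`: the known associations are partitioned uniformly at random
#'   (under `seed`) into `k` folds; per fold all test entries are zeroed at
#'   once, the model is rebuilt, and each test positive is scored.
#'
#' In both schemes the negatives are all pairs absent from the full known
#' set, scored once under the all-data model; ROC and AUC are computed on the
#' pooled records. If the input has no negative pair (every entry of the
#' association matrix is 1) the fold bookkeeping still runs but `roc` is
#' `NULL` and `auc` is `NA`, with a warning.
#'
#' @param associations an `"association_table"` (or data frame of records,
#'   coerced via [association_table()]).
#' @param circ_annotations,disease_annotations annotation catalogs (named
#'   lists of term vectors); default empty, in which case all similarity is
#'   GIP-based.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k number of folds for `"kfold"` (default 5).
#' @param seed integer seed for the fold assignment (k-fold only; LOOCV is
#'   deterministic).
#' @param alpha,eta path-scoring parameters, see [score_matrix()].
#' @param gamma edge-weight threshold, see [apply_threshold()].
#' @param gamma_prime_circ,gamma_prime_disease raw GIP bandwidths, see
#'   [gip_bandwidth()].
#' @return an object of class `"pwcda_cv"`: list with `scheme`, `k`, `seed`,
#'   `labeled` (data frame `disease_id, circRNA_id, score, label`), `roc`
#'   (a `"roc_curve"` or `NULL`), `auc`, `skipped_diseases` (LOOCV),
#'   `n_folds` and `params`.
#' @export
pwcda_cv <- function(associations,
                     circ_annotations = list(), disease_annotations = list(),
                     scheme = c("loocv", "kfold"), k = 5, seed = 1,
                     alpha = 1, eta = 3, gamma = 0.5,
                     gamma_prime_circ = 1, gamma_prime_disease = 1) {
  scheme <- match.arg(scheme)
  if (!inherits(associations, "association_table")) {
    associations <- association_table(associations)
  }
  m_full <- build_association_matrix(associations)
  n_pos <- sum(m_full)
  .check(n_pos >= 2L, "cross-validation needs at least 2 known associations")
  cs <- annotation_similarity_matrix(circ_annotations, associations$circ_ids)
  ds <- annotation_similarity_matrix(disease_annotations,
                                     associations$disease_ids)
  rebuild <- function(m) {
    .build_network(m, cs, ds, gamma, gamma_prime_circ, gamma_prime_disease)
  }
  full_net <- rebuild(m_full)
  full_scores <- score_matrix(full_net, alpha, eta)
  pos_all <- which(m_full == 1, arr.ind = TRUE)

  skipped <- character(0)
  if (scheme == "loocv") {
    deg <- rowSums(m_full)
    eligible <- deg[pos_all[, 1]] >= 2L
    skipped <- rownames(m_full)[deg == 1L]
    test_idx <- pos_all[eligible, , drop = FALSE]
    .check(nrow(test_idx) >= 1L,
           "no eligible test pair: every disease has a single association")
    folds <- as.list(seq_len(nrow(test_idx)))
  } else {
    .check(k >= 2L, "k must be >= 2")
    .check(k <= n_pos, "k (%d) exceeds the number of known associations (%d)",
           k, n_pos)
    test_idx <- pos_all
    assignment <- with_preserved_seed(seed, {
      sample(rep(seq_len(k), length.out = nrow(test_idx)))
    })
    folds <- split(seq_len(nrow(test_idx)), assignment)
    # folds must partition the positives: disjoint and exhaustive
    stopifnot(identical(sort(unlist(folds, use.names = FALSE)),
                        seq_len(nrow(test_idx))))
  }

  pos_scores <- numeric(nrow(test_idx))
  for (f in folds) {
    m_train <- m_full
    m_train[test_idx[f, , drop = FALSE]] <- 0L
    stopifnot(all(m_train[test_idx[f, , drop = FALSE]] == 0L)) # leakage guard
    net <- rebuild(m_train)
    for (r in f) {
      pos_scores[r] <- association_score(
        net,
        circ = associations$circ_ids[test_idx[r, 2]],
        disease = associations$disease_ids[test_idx[r, 1]],
        alpha = alpha, eta = eta
      )
    }
  }

  labeled <- .cv_labeled(associations$disease_ids, associations$circ_ids,
                         test_idx, pos_scores, m_full, full_scores)
  key <- paste(labeled$disease_id, labeled$circRNA_id)
  stopifnot(!anyDuplicated(key))
  roc <- NULL
  auc <- NA_real_
  if (any(labeled$label == "negative")) {
    roc <- roc_curve(labeled$score, labeled$label == "positive")
    auc <- roc$auc
  } else {
    warning("no negative pairs: every circRNA-disease pair is a known ",
            "association; ROC/AUC undefined")
  }
  structure(list(
    scheme = scheme,
    k = if (scheme == "kfold") as.integer(k) else NA_integer_,
    seed = if (scheme == "kfold") as.integer(seed) else NA_integer_,
    labeled = labeled, roc = roc, auc = auc,
    skipped_diseases = skipped, n_folds = length(folds),
    params = list(alpha = alpha, eta = eta, gamma = gamma,
                  gamma_prime_circ = gamma_prime_circ,
                  gamma_prime_disease = gamma_prime_disease)
  ), class = "pwcda_cv")
}

#' @export
print.pwcda_cv <- function(x, ...) {
  lab <- if (x$scheme == "kfold") {
    sprintf("%d-fold cross-validation (seed %d)", x$k, x$seed)
  } else "leave-one-out cross-validation"
  cat(sprintf("Path-weighted association prediction, %s\n", lab))
  cat(sprintf("  %d test positives in %d folds, %d negatives\n",
              sum(x$labeled$label == "positive"), x$n_folds,
              sum(x$labeled$label == "negative")))
  if (length(x$skipped_diseases)) {
    cat(sprintf("  %d diseases skipped (single known association)\n",
                length(x$skipped_diseases)))
  }
  cat(sprintf("  AUC = %s\n",
              if (is.na(x$auc)) "NA (no negatives)" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' @export
summary.pwcda_cv <- function(object, ...) {
  pos <- object$labeled$score[object$labeled$label == "positive"]
  neg <- object$labeled$score[object$labeled$label == "negative"]
  out <- list(scheme = object$scheme, k = object$k, seed = object$seed,
              auc = object$auc, n_pos = length(pos), n_neg = length(neg),
              n_skipped = length(object$skipped_diseases),
              median_pos_score = stats::median(pos),
              median_neg_score = if (length(neg)) stats::median(neg) else NA_real_,
              params = object$params)
  class(out) <- "summary.pwcda_cv"
  out
}

#' @export
print.summary.pwcda_cv <- function(x, ...) {
  cat(sprintf("Cross-validation summary (%s%s)\n", x$scheme,
              if (x$scheme == "kfold") sprintf(", k=%d, seed=%d", x$k, x$seed) else ""))
  cat(sprintf("  positives tested: %d (diseases skipped: %d)\n", x$n_pos,
              x$n_skipped))
  cat(sprintf("  negatives: %d\n", x$n_neg))
  cat(sprintf("  median score, positives: %.4g; negatives: %.4g\n",
              x$median_pos_score, x$median_neg_score))
  cat(sprintf("  AUC: %s\n",
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  cat(sprintf("  parameters: alpha=%g, eta=%d, gamma=%g\n",
              x$params$alpha, x$params$eta, x$params$gamma))
  invisible(x)
}

#' Plot a cross-validated ROC curve
#'
#' @param x a `"pwcda_cv"` object with a non-`NULL` ROC.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pwcda_cv <- function(x, ...) {
  .check(!is.null(x$roc), "no ROC available (no negative pairs)")
  p <- x$roc$points
  graphics::plot(p$FPR, p$TPR, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (%s), AUC = %.3f", x$scheme, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
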