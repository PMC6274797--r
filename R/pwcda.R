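# Model-fitting front end: one call builds the similarity matrices, the
# thresholded heterogeneous network and the full score matrix.

#' Fit a path-weighted circRNA-disease association model
#'
#' Runs the full pipeline on a set of verified associations and (optional)
#' annotation catalogs:
#'
#' 1. build the binary association matrix M (diseases x circRNAs);
#' 2. compute annotation-based Jaccard similarities for circRNAs (GO-term
#'    sets) and diseases (gene-annotation sets);
#' 3. compute GIP kernel similarities from the association profiles and
#'    integrate them as fallback wherever the Jaccard similarity is zero;
#' 4. assemble the heterogeneous network and prune edges below `gamma`;
#' 5. score every circRNA-disease pair by summing weight products over all
#'    simple paths of at most `eta` edges, each divided by the exponential
#'    length penalty `alpha * exp(length)`.
#'
#' @param associations an `"association_table"` or a data frame with columns
#'   `circRNA_id`, `disease_id` (coerced via [association_table()]).
#' @param circ_annotations named list mapping circRNA ids to GO-term sets;
#'   empty by default (all circRNA similarity then comes from the GIP
#'   kernel).
#' @param disease_annotations named list mapping disease ids to gene
#'   annotation sets; empty by default.
#' @param alpha positive constraint factor of the length penalty (default 1).
#'   Rescales all scores by `1/alpha`, never the ranking.
#' @param eta maximum path length in edges (default 3).
#' @param gamma edge-weight threshold in `[0, 1]` (default 0.5).
#' @param gamma_prime_circ,gamma_prime_disease raw GIP bandwidths (default 1).
#' @return an object of class `"pwcda"`: list with the association `table`,
#'   matrix `M`, similarity matrices `CS`, `DS`, `KC`, `KD`, `ICS`, `IDS`,
#'   the final `network`, the `scores` matrix (diseases x circRNAs) and
#'   `params`.
#' @seealso [pwcda_cv()] for cross-validated evaluation, [predict.pwcda()]
#'   for ranked candidate lists.
#' @export
#' @examples
#' dataset <- generate_synthetic(synthetic_spec(n_circ = 12, n_dis = 6))
#' fit <- pwcda(dataset$table, dataset$circ_catalog, dataset$disease_catalog)
#' fit
#' head(predict(fit), 5)
pwcda <- function(associations,
                  circ_annotations = list(), disease_annotations = list(),
                  alpha = 1, eta = 3, gamma = 0.5,
                  gamma_prime_circ = 1, gamma_prime_disease = 1) {
  if (!inherits(associations, "association_table")) {
    associations <- association_table(associations)
  }
  m <- build_association_matrix(associations)
  cs <- annotation_similarity_matrix(circ_annotations, associations$circ_ids)
  ds <- annotation_similarity_matrix(disease_annotations,
                                     associations$disease_ids)
  kc <- gip_kernel_matrix(m, "circRNA", gamma_prime_circ)
  kd <- gip_kernel_matrix(m, "disease", gamma_prime_disease)
  ics <- integrate_similarity(cs, kc)
  ids <- integrate_similarity(ds, kd)
  network <- apply_threshold(hetnet(ics, ids, m), gamma)
  scores <- score_matrix(network, alpha, eta)
  structure(list(
    table = associations, M = m,
    CS = cs, DS = ds, KC = kc, KD = kd, ICS = ics, IDS = ids,
    network = network, scores = scores,
    params = list(alpha = alpha, eta = eta, gamma = gamma,
                  gamma_prime_circ = gamma_prime_circ,
                  gamma_prime_disease = gamma_prime_disease)
  ), class = "pwcda")
}

#' @export
print.pwcda <- function(x, ...) {
  cat("Path-weighted circRNA-disease association model\n")
  cat(sprintf("  %d circRNAs, %d diseases, %d known associations\n",
              length(x$table$circ_ids), length(x$table$disease_ids),
              sum(x$M)))
  cat(sprintf("  parameters: alpha=%g, eta=%d, gamma=%g\n",
              x$params$alpha, x$params$eta, x$params$gamma))
  cat(sprintf("  network edges after thresholding: %d circRNA-circRNA, %d disease-disease, %d association\n",
              sum(x$network$circ_circ > 0) / 2,
              sum(x$network$dis_dis > 0) / 2, sum(x$network$circ_dis > 0)))
  invisible(x)
}

# fraction of off-diagonal entries that are nonzero
.offdiag_density <- function(m) {
  n <- nrow(m)
  if (n < 2) return(0)
  (sum(m != 0) - sum(diag(m) != 0)) / (n * (n - 1))
}

#' @export
summary.pwcda <- function(object, ...) {
  out <- list(
    n_circ = length(object$table$circ_ids),
    n_dis = length(object$table$disease_ids),
    n_assoc = sum(object$M),
    jaccard_density_circ = .offdiag_density(object$CS),
    jaccard_density_dis = .offdiag_density(object$DS),
    integrated_density_circ = .offdiag_density(object$ICS),
    integrated_density_dis = .offdiag_density(object$IDS),
    edge_density_circ = .offdiag_density(object$network$circ_circ),
    edge_density_dis = .offdiag_density(object$network$dis_dis),
    score_range = range(object$scores),
    params = object$params
  )
  class(out) <- "summary.pwcda"
  out
}

#' @export
print.summary.pwcda <- function(x, ...) {
  cat("Path-weighted association model summary\n")
  cat(sprintf("  entities: %d circRNAs, %d diseases; %d known associations\n",
              x$n_circ, x$n_dis, x$n_assoc))
  cat(sprintf("  Jaccard similarity coverage (nonzero off-diagonal): circRNA %.1f%%, disease %.1f%%\n",
              100 * x$jaccard_density_circ, 100 * x$jaccard_density_dis))
  cat(sprintf("  after GIP integration: circRNA %.1f%%, disease %.1f%%\n",
              100 * x$integrated_density_circ, 100 * x$integrated_density_dis))
  cat(sprintf("  edge density after threshold (gamma=%g): circRNA %.1f%%, disease %.1f%%\n",
              x$params$gamma, 100 * x$edge_density_circ,
              100 * x$edge_density_dis))
  cat(sprintf("  score range: [%.4g, %.4g]\n",
              x$score_range[1], x$score_range[2]))
  invisible(x)
}

#' Ranked candidate associations from a fitted model
#'
#' Flattens the fitted score matrix into a ranked prediction list (descending
#' score, deterministic tie-break by disease then circRNA id), flagging known
#' associations, optionally restricted to one disease.
#'
#' @param object a fitted `"pwcda"` model.
#' @param disease optional disease id; restrict the ranking to that disease's
#'   candidate circRNAs.
#' @param n return at most the top `n` rows (default all).
#' @param ... unused.
#' @return data frame `rank, disease_id, circRNA_id, score, known`.
#' @export
predict.pwcda <- function(object, disease = NULL, n = Inf, ...) {
  ranked <- rank_predictions(object$scores, known = object$M)
  if (!is.null(disease)) {
    disease <- normalize_id(disease)
    .check(disease %in% object$table$disease_ids, "unknown disease id: %s",
           disease)
    ranked <- ranked[ranked$disease_id == disease, , drop = FALSE]
    ranked$rank <- seq_len(nrow(ranked))
    rownames(ranked) <- NULL
  }
  utils::head(ranked, n)
}
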