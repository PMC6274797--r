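# Readers and writers for the plain delimited-text formats the pipeline uses,
# plus construction of the binary association matrix.
#
# File formats:
#   * association file: columns `circRNA_id, disease_id[, species]`,
#     `#` comment lines ignored;
#   * annotation file:  columns `entity_id, term_id`;
#   * score matrix:     header = `disease_id` + circRNA ids, one row per disease;
#   * ranked predictions: `rank, disease_id, circRNA_id, score[, known]`;
#   * ROC points:       `threshold, FPR, TPR`.

# Split non-comment, non-blank lines of a delimited file, keeping original
# line numbers for error messages.
.read_delim_lines <- function(path, delimiter) {
  .check(file.exists(path), "file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(fields = strsplit(raw[keep], delimiter, fixed = TRUE),
       lineno = which(keep))
}

#' Read raw circRNA-disease association records
#'
#' Reads a delimited association file into a data frame of raw records,
#' without normalization or de-duplication. Lines starting with `#` and
#' blank lines are skipped. Each data line must have at least two fields
#' (circRNA id, disease id); an optional third field is a species tag.
#'
#' @param path path to the association file.
#' @param delimiter single-character field separator (default `","`).
#' @return a data frame with columns `circRNA_id`, `disease_id`, `species`
#'   (`NA` where the file has no third field).
#' @seealso [association_table()], [read_association_table()],
#'   [filter_by_species()]
#' @export
read_association_records <- function(path, delimiter = ",") {
  parsed <- .read_delim_lines(path, delimiter)
  .check(length(parsed$fields) > 0L, "empty association file: %s", path)
  nf <- lengths(parsed$fields)
  if (any(nf < 2L)) {
    bad <- parsed$lineno[which(nf < 2L)[1L]]
    stop(sprintf("malformed association line %d in %s: fewer than 2 fields",
                 bad, path), call. = FALSE)
  }
  data.frame(
    circRNA_id = vapply(parsed$fields, `[`, "", 1L),
    disease_id = vapply(parsed$fields, `[`, "", 2L),
    species = vapply(parsed$fields,
                     function(f) if (length(f) >= 3L) f[3L] else NA_character_,
                     ""),
    stringsAsFactors = FALSE
  )
}

#' Filter association records by species
#'
#' Keeps only records whose species field matches `species`
#' (case-insensitively) and rebuilds the association table from the
#' survivors.
#'
#' @param records data frame of raw records as returned by
#'   [read_association_records()]; must carry a usable `species` column.
#' @param species species name to keep, e.g. `"human"`.
#' @return an [association_table()] built from the matching records.
#' @export
filter_by_species <- function(records, species) {
  .check(is.data.frame(records) && "species" %in% names(records) &&
           !all(is.na(records$species)),
         "records carry no species column; skip species filtering")
  keep <- !is.na(records$species) &
    normalize_id(records$species) == normalize_id(species)
  .check(any(keep), "no records match species '%s'; downstream needs >= 1 pair",
         species)
  association_table(records[keep, , drop = FALSE])
}

#' Build an association table from raw records
#'
#' Normalizes identifiers (trim + case-fold), collapses duplicate pairs, and
#' fixes the identifier ordering as first appearance in the input. The result
#' is the in-memory form of the verified circRNA-disease association list.
#'
#' @param records data frame with columns `circRNA_id` and `disease_id`
#'   (extra columns are ignored).
#' @return an object of class `"association_table"`: a list with
#'   `circ_ids`, `disease_ids` (character, first-appearance order) and
#'   `pairs` (data frame of integer indices `disease`, `circ`, one row per
#'   unique verified pair, in first-appearance order).
#' @export
association_table <- function(records) {
  .check(is.data.frame(records) &&
           all(c("circRNA_id", "disease_id") %in% names(records)),
         "records must have columns circRNA_id and disease_id")
  .check(nrow(records) > 0L, "association table needs at least one record")
  circ <- normalize_id(records$circRNA_id)
  dis <- normalize_id(records$disease_id)
  .check(all(nzchar(circ)) && all(nzchar(dis)),
         "empty identifier after normalization")
  keep <- !duplicated(paste(dis, circ, sep = "\r"))
  circ <- circ[keep]
  dis <- dis[keep]
  circ_ids <- unique(circ)
  disease_ids <- unique(dis)
  out <- list(
    circ_ids = circ_ids,
    disease_ids = disease_ids,
    pairs = data.frame(disease = match(dis, disease_ids),
                       circ = match(circ, circ_ids))
  )
  class(out) <- "association_table"
  out
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Association table: %d verified pairs, %d circRNAs, %d diseases\n",
              nrow(x$pairs), length(x$circ_ids), length(x$disease_ids)))
  invisible(x)
}

#' Read an association file into an association table
#'
#' Convenience wrapper: [read_association_records()] followed by optional
#' [filter_by_species()] and [association_table()].
#'
#' @inheritParams read_association_records
#' @param species optional species to keep (see [filter_by_species()]);
#'   `NULL` keeps all records.
#' @return an `"association_table"`.
#' @export
read_association_table <- function(path, delimiter = ",", species = NULL) {
  records <- read_association_records(path, delimiter)
  if (is.null(species)) association_table(records)
  else filter_by_species(records, species)
}

#' Write an association table
#'
#' Writes one `circRNA_id<delim>disease_id` line per verified pair, preceded
#' by a `#` comment header. Pair order is preserved, so reading the file back
#' reproduces the same table (same identifier ordering).
#'
#' @param table an `"association_table"`.
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "association_table"))
  lines <- c(paste0("# circRNA_id", delimiter, "disease_id"),
             paste0(table$circ_ids[table$pairs$circ], delimiter,
                    table$disease_ids[table$pairs$disease]))
  writeLines(lines, path)
  invisible(path)
}

#' Build the binary association matrix
#'
#' Converts an association table into the adjacency matrix M of the bipartite
#' association network: rows are diseases, columns are circRNAs, and
#' `M[i, j] = 1` exactly when disease i and circRNA j are a verified pair.
#'
#' @param table an `"association_table"`.
#' @return an integer matrix (diseases x circRNAs) with 0/1 entries and
#'   identifiers as dimnames; its entry sum equals the number of pairs.
#' @export
build_association_matrix <- function(table) {
  stopifnot(inherits(table, "association_table"))
  m <- matrix(0L, nrow = length(table$disease_ids),
              ncol = length(table$circ_ids),
              dimnames = list(table$disease_ids, table$circ_ids))
  m[cbind(table$pairs$disease, table$pairs$circ)] <- 1L
  m
}

#' Read an annotation catalog
#'
#' Reads a two-column delimited file (`entity_id, term_id`) into a catalog
#' mapping each entity to its finite set of annotation terms: GO terms of
#' target genes for circRNAs, gene annotations for diseases. Duplicate
#' (entity, term) lines collapse (set semantics). Entities never mentioned in
#' the file get no entry; callers treat absent entities as having an empty
#' term set. An empty file is a valid, empty catalog (all similarities then
#' fall back to the GIP kernel).
#'
#' @inheritParams read_association_records
#' @return a named list of character vectors (sorted unique term ids per
#'   entity), entity ids normalized.
#' @export
read_annotation_catalog <- function(path, delimiter = ",") {
  parsed <- .read_delim_lines(path, delimiter)
  if (length(parsed$fields) == 0L) return(structure(list(), names = character(0)))
  nf <- lengths(parsed$fields)
  if (any(nf < 2L)) {
    bad <- parsed$lineno[which(nf < 2L)[1L]]
    stop(sprintf("malformed annotation line %d in %s: fewer than 2 fields",
                 bad, path), call. = FALSE)
  }
  entity <- normalize_id(vapply(parsed$fields, `[`, "", 1L))
  term <- trimws(vapply(parsed$fields, `[`, "", 2L))
  lapply(split(term, factor(entity, levels = unique(entity))),
         function(t) sort(unique(t)))
}

#' Write an annotation catalog
#'
#' Inverse of [read_annotation_catalog()]: one `entity_id<delim>term_id` line
#' per (entity, term) membership.
#'
#' @param catalog named list of character term vectors.
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_annotation_catalog <- function(catalog, path, delimiter = ",") {
  lines <- c(paste0("# entity_id", delimiter, "term_id"))
  for (id in names(catalog)) {
    terms <- sort(unique(catalog[[id]]))
    if (length(terms)) lines <- c(lines, paste0(id, delimiter, terms))
  }
  writeLines(lines, path)
  invisible(path)
}

# full-precision decimal rendering so write/read round-trips are exact
.format_full <- function(x) sprintf("%.17g", x)

#' Write a score matrix
#'
#' Writes a (diseases x circRNAs) score matrix as delimited text: header row
#' `disease_id` + circRNA ids, then one row per disease. Values are written
#' at full double precision so a write/read round trip is exact.
#'
#' @param scores numeric matrix with disease ids as rownames and circRNA ids
#'   as colnames.
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path, delimiter = ",") {
  stopifnot(is.matrix(scores), !is.null(dimnames(scores)),
            all(is.finite(scores)))
  header <- paste(c("disease_id", colnames(scores)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(scores)), function(i) {
    paste(c(rownames(scores)[i], .format_full(scores[i, ])),
          collapse = delimiter)
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#'
#' @inheritParams read_association_records
#' @return numeric matrix with dimnames (diseases x circRNAs).
#' @export
read_score_matrix <- function(path, delimiter = ",") {
  parsed <- .read_delim_lines(path, delimiter)
  .check(length(parsed$fields) >= 2L, "score matrix file %s has no data rows", path)
  header <- parsed$fields[[1L]]
  circ_ids <- header[-1L]
  body <- parsed$fields[-1L]
  vals <- t(vapply(body, function(f) as.numeric(f[-1L]),
                   numeric(length(circ_ids))))
  # t(vapply) yields 1 x n for a single-row file only when length > 1; fix shape
  if (length(body) == 1L) vals <- matrix(as.numeric(body[[1L]][-1L]), nrow = 1L)
  dimnames(vals) <- list(vapply(body, `[`, "", 1L), circ_ids)
  vals
}

#' Rank all disease-circRNA pairs by predicted score
#'
#' Flattens a score matrix into a ranked prediction list, sorted by
#' descending score; ties are broken by (disease id, circRNA id) lexicographic
#' order so output is deterministic.
#'
#' @param scores numeric matrix (diseases x circRNAs) with dimnames.
#' @param known optional binary matrix of the same shape flagging verified
#'   associations; adds a `known` column.
#' @return data frame `rank, disease_id, circRNA_id, score[, known]`.
#' @export
rank_predictions <- function(scores, known = NULL) {
  stopifnot(is.matrix(scores), !is.null(dimnames(scores)))
  df <- data.frame(
    disease_id = rep(rownames(scores), times = ncol(scores)),
    circRNA_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores)
  )
  if (!is.null(known)) {
    stopifnot(identical(dim(known), dim(scores)))
    df$known <- as.integer(as.vector(known) != 0)
  }
  ord <- order(-df$score, df$disease_id, df$circRNA_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Write ranked predictions
#'
#' @param predictions data frame from [rank_predictions()].
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_ranked_predictions <- function(predictions, path, delimiter = ",") {
  cols <- names(predictions)
  lines <- c(paste(cols, collapse = delimiter),
             do.call(paste, c(lapply(cols, function(cn) {
               v <- predictions[[cn]]
               if (is.numeric(v) && cn == "score") .format_full(v) else as.character(v)
             }), sep = delimiter)))
  writeLines(lines, path)
  invisible(path)
}

#' Write ROC points
#'
#' Writes the `(threshold, FPR, TPR)` sweep of a ROC curve as delimited text.
#'
#' @param roc a `"roc_curve"` object from [roc_curve()].
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path, delimiter = ",") {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  lines <- c(paste(c("threshold", "FPR", "TPR"), collapse = delimiter),
             paste(.format_full(p$threshold), .format_full(p$FPR),
                   .format_full(p$TPR), sep = delimiter))
  writeLines(lines, path)
  invisible(path)
}
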