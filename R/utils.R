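# Internal helpers shared across modules.

#' Normalize an entity identifier
#'
#' Trims surrounding whitespace and case-folds to lower case. Each distinct
#' normalized string is treated as one entity; no alias resolution is
#' attempted (alias tables live in external databases, not here).
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized identifiers.
#' @keywords internal
normalize_id <- function(x) {
  tolower(trimws(as.character(x)))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded internals never perturb the user's random stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stopifnot with a formatted message
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
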