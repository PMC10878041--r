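# Internal validation and seeding helpers.

# Coerce an OTU table to a validated integer count matrix (OTUs x samples).
# Accepts a matrix or a data.frame whose first column holds OTU ids (or with
# OTU ids as row names).
as_count_matrix <- function(x, arg = "cm") {
  if (is.data.frame(x)) {
    if (ncol(x) >= 2 && (is.character(x[[1]]) || is.factor(x[[1]]))) {
      ids <- as.character(x[[1]])
      x <- as.matrix(x[, -1, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric OTU x sample matrix or data frame.", arg))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("OTU_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  validate_counts(x, arg)
  storage.mode(x) <- "integer"
  x
}

validate_counts <- function(x, arg = "cm") {
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("`%s` has duplicated OTU identifiers.", arg))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("`%s` has duplicated sample identifiers.", arg))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", arg))
  if (any(x < 0)) abort(sprintf("`%s` contains negative counts.", arg))
  nonint <- which(abs(x - round(x)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint) > 0) {
    abort(sprintf(
      "`%s` contains non-integer counts, e.g. %s at OTU '%s', sample '%s'.",
      arg, format(x[nonint[1, 1], nonint[1, 2]]),
      rownames(x)[nonint[1, 1]], colnames(x)[nonint[1, 2]]
    ))
  }
  invisible(x)
}

check_scalar_number <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", arg,
                  format(lower), format(upper)))
  }
  invisible(x)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is left untouched. Seeds are explicit arguments throughout the
# package, never global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) check_scalar_number(seed, "seed")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(seed)
  expr
}

# Deterministic substream seeds derived from one master seed, so that
# per-pair or per-replicate work is reproducible regardless of evaluation
# order. Kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
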