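#' Read an OTU count table
#'
#' Reads an OTU abundance table (OTUs as rows, samples as columns) from a
#' tab-separated file or a BIOM-JSON (format 1.0) file and returns a
#' validated integer count matrix.
#'
#' The TSV dialect is: first column OTU identifiers, header row sample
#' identifiers, UTF-8, tab-separated; lines starting with `#` are ignored.
#' Cells must be non-negative whole numbers; duplicated identifiers,
#' negative, non-numeric or fractional cells are format errors.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"biom"` for BIOM-JSON.
#' @return An integer matrix with OTU row names and sample column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("otu_id\tS1\tS2", "OTU_1\t5\t0", "OTU_2\t1\t2"), tf)
#' read_otu_table(tf)
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  if (format == "tsv") {
    df <- tryCatch(
      read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                 check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) abort(sprintf("Cannot parse '%s': %s", path, conditionMessage(e)))
    )
    if (nrow(df) == 0 || ncol(df) < 2) {
      abort(sprintf("'%s' holds no OTU table (need an id column and >= 1 sample).", path))
    }
    ids <- as.character(df[[1]])
    m <- df[, -1, drop = FALSE]
    bad <- !vapply(m, is.numeric, logical(1))
    if (any(bad)) {
      col <- names(m)[which(bad)[1]]
      abort(sprintf("Sample column '%s' in '%s' contains non-numeric values.", col, path))
    }
    m <- as.matrix(m)
    rownames(m) <- ids
    as_count_matrix(m, arg = path)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Reading BIOM files requires the 'biomformat' package.")
    }
    b <- tryCatch(biomformat::read_biom(path),
                  error = function(e) abort(sprintf("Cannot parse BIOM file '%s': %s",
                                                    path, conditionMessage(e))))
    m <- as(biomformat::biom_data(b), "matrix")
    as_count_matrix(m, arg = path)
  }
}

#' Write an OTU count table to TSV
#'
#' @param cm OTU x sample count matrix.
#' @param path Output path.
#' @param id_column Name of the identifier column (default `"otu_id"`).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(cm, path, id_column = "otu_id") {
  cm <- as_count_matrix(cm)
  df <- data.frame(id = rownames(cm), cm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to an even depth
#'
#' Randomly subsamples each sample column without replacement
#' (hypergeometrically) down to `depth` reads, the normalisation applied to
#' amplicon libraries before diversity and assembly analyses. Samples with
#' fewer than `depth` reads are dropped with a warning.
#'
#' @param cm OTU x sample count matrix.
#' @param depth Target depth (positive integer).
#' @param seed Integer seed; identical `(cm, depth, seed)` give identical
#'   output. The caller's RNG state is not disturbed.
#' @return A count matrix whose retained columns each sum to `depth`.
#'   OTUs reduced to zero total count are kept (rows are not dropped), so
#'   OTU universes stay aligned across categories.
#' @examples
#' cm <- matrix(c(10L, 5L, 0L, 8L), 2, dimnames = list(c("a", "b"), c("S1", "S2")))
#' colSums(rarefy(cm, depth = 8, seed = 1))
#' @export
rarefy <- function(cm, depth, seed = NULL) {
  cm <- as_count_matrix(cm)
  check_scalar_number(depth, "depth", lower = 1)
  depth <- as.integer(depth)
  keep <- colSums(cm) >= depth
  if (!any(keep)) abort("All samples are below the rarefaction depth.")
  if (!all(keep)) {
    warn(sprintf("Dropping %d sample(s) below depth %d: %s",
                 sum(!keep), depth, paste(colnames(cm)[!keep], collapse = ", ")))
    cm <- cm[, keep, drop = FALSE]
  }
  out <- with_seed(seed, {
    # vegan advises when a table has no singletons; counts are already
    # validated as raw integers here, so that advisory is noise
    withCallingHandlers(
      t(vegan::rrarefy(t(cm), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  storage.mode(out) <- "integer"
  out
}

#' Convert counts to relative abundances
#'
#' @param cm OTU x sample count matrix.
#' @return A numeric matrix of the same shape; each column sums to 1.
#' @export
to_relative <- function(cm) {
  cm <- as_count_matrix(cm)
  cs <- colSums(cm)
  if (any(cs == 0)) {
    abort(sprintf("Sample(s) with zero total count: %s",
                  paste(colnames(cm)[cs == 0], collapse = ", ")))
  }
  sweep(cm, 2, cs, "/")
}

#' Read a rooted Newick phylogeny
#'
#' Wraps [ape::read.tree()] with the validation the null models need: unique
#' tip labels and non-negative branch lengths on every edge.
#'
#' @param path Newick file.
#' @param require_branch_lengths Reject trees with missing branch lengths
#'   (default `TRUE`); phylogenetic distances are meaningless without them.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path, require_branch_lengths = TRUE) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(sprintf("Cannot parse Newick file '%s': %s",
                                                     path, conditionMessage(e))))
  if (is.null(tree)) abort(sprintf("Cannot parse Newick file '%s'.", path))
  validate_tree(tree, require_branch_lengths = require_branch_lengths)
  tree
}

validate_tree <- function(tree, require_branch_lengths = TRUE) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object.")
  if (anyDuplicated(tree$tip.label)) abort("Tree has duplicated tip labels.")
  if (any(!nzchar(tree$tip.label))) abort("Tree has unlabeled tips.")
  if (is.null(tree$edge.length)) {
    if (require_branch_lengths) abort("Tree has no branch lengths.")
  } else if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("Tree has missing or negative branch lengths.")
  }
  invisible(tree)
}

#' Write result tables to TSV
#'
#' @param x A data frame (e.g. a tidied fit or a process partition).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Rarefaction depths used for the cave amplicon libraries
#'
#' Documented presets: the sequencing depths the source study rarefied each
#' marker's library to. They are configuration values only; [rarefy()] takes
#' any depth.
#'
#' @return A named integer vector (bacteria, archaea, microeukaryotes, fungi).
#' @export
rarefaction_presets <- function() {
  c(bacteria = 12105L, archaea = 6209L, microeukaryotes = 31981L,
    fungi = 25821L)
}
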