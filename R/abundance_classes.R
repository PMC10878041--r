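#' Abundance category levels
#'
#' @return Character vector of the five category labels, in decision order.
#' @export
abundance_categories <- function() {
  c("always_rare", "conditionally_rare", "moderate", "dominant", "unclassified")
}

#' Classify OTUs into abundance categories
#'
#' Assigns each OTU to one of four abundance categories widely used to split
#' the rare biosphere from the abundant community, based on its per-sample
#' relative abundances across all samples (both sampling dates combined):
#'
#' * **always_rare** — below `rare_cut` (default 0.01%) in every sample;
#' * **dominant** — at or above `abundant_cut` (default 1%) in every sample,
#'   or strongly fluctuating (below `rare_cut` in some samples and at or
#'   above `abundant_cut` in others);
#' * **moderate** — between `rare_cut` and `abundant_cut` in every sample;
#' * **conditionally_rare** — never reaching `abundant_cut`, and below
#'   `rare_cut` in some samples but at most a fraction `max_rare_fraction`
#'   (default 1/3) of them;
#' * **unclassified** — profiles the four rules do not cover (e.g. below
#'   `rare_cut` in more than a third of samples without ever reaching
#'   `abundant_cut`). An explicit bucket keeps the partition auditable
#'   instead of silently forcing a label.
#'
#' Rules are checked in the order always_rare, dominant, moderate,
#' conditionally_rare, so a >=1% spike always wins over the
#' conditionally-rare rule.
#'
#' @param ra OTU x sample relative-abundance matrix (columns sum to 1), as
#'   returned by [to_relative()]; a count matrix is converted automatically.
#' @param rare_cut Rarity threshold as a proportion (default `1e-4`, i.e.
#'   0.01%); comparisons with it are strict (`<`).
#' @param abundant_cut Abundance threshold as a proportion (default `1e-2`);
#'   "at or above" is inclusive (`>=`).
#' @param max_rare_fraction Largest tolerated fraction of samples below
#'   `rare_cut` for a conditionally rare OTU (default 1/3, inclusive).
#' @return A tibble with columns `otu_id`, `category` (factor over
#'   [abundance_categories()]), `min_abund`, `max_abund`,
#'   `frac_below_rare_cut`; thresholds are attached as attribute
#'   `"thresholds"`.
#' @examples
#' ra <- matrix(c(0.5, 0.5, 0.9, 0.1), 2,
#'              dimnames = list(c("a", "b"), c("S1", "S2")))
#' classify_otus(ra)
#' @export
classify_otus <- function(ra, rare_cut = 1e-4, abundant_cut = 1e-2,
                          max_rare_fraction = 1 / 3) {
  if (is.null(dim(ra)) || nrow(ra) == 0 || ncol(ra) == 0) {
    abort("`ra` must be a non-empty OTU x sample matrix.")
  }
  check_scalar_number(rare_cut, "rare_cut", lower = 0, upper = 1)
  check_scalar_number(abundant_cut, "abundant_cut", lower = 0, upper = 1)
  check_scalar_number(max_rare_fraction, "max_rare_fraction", 0, 1)
  if (rare_cut >= abundant_cut) abort("`rare_cut` must be below `abundant_cut`.")
  ra <- as.matrix(ra)
  if (max(ra) > 1 + 1e-9) ra <- to_relative(ra)
  if (is.null(rownames(ra))) rownames(ra) <- paste0("OTU_", seq_len(nrow(ra)))

  mn <- apply(ra, 1, min)
  mx <- apply(ra, 1, max)
  frac_rare <- rowMeans(ra < rare_cut)

  category <- dplyr::case_when(
    mx < rare_cut ~ "always_rare",
    mn >= abundant_cut ~ "dominant",
    mn < rare_cut & mx >= abundant_cut ~ "dominant",
    mn >= rare_cut & mx < abundant_cut & frac_rare == 0 ~ "moderate",
    mx < abundant_cut & frac_rare > 0 & frac_rare <= max_rare_fraction ~
      "conditionally_rare",
    .default = "unclassified"
  )

  out <- tibble::tibble(
    otu_id = rownames(ra),
    category = factor(category, levels = abundance_categories()),
    min_abund = unname(mn),
    max_abund = unname(mx),
    frac_below_rare_cut = unname(frac_rare)
  )
  attr(out, "thresholds") <- list(rare_cut = rare_cut,
                                  abundant_cut = abundant_cut,
                                  max_rare_fraction = max_rare_fraction)
  out
}

#' Subset a count table to one abundance category
#'
#' @param cm OTU x sample count matrix.
#' @param assignment Tibble from [classify_otus()], derived from the same OTU
#'   universe.
#' @param category One of [abundance_categories()], or `"all"` for the whole
#'   table.
#' @return The count matrix restricted to OTUs with the requested label, with
#'   a logical attribute `"empty_samples"` flagging samples whose column sum
#'   dropped to zero.
#' @export
subset_by_category <- function(cm, assignment, category) {
  cm <- as_count_matrix(cm)
  if (identical(category, "all")) return(cm)
  if (!category %in% abundance_categories()) {
    abort(sprintf("Unknown category '%s'.", category))
  }
  if (!all(c("otu_id", "category") %in% names(assignment))) {
    abort("`assignment` must come from classify_otus().")
  }
  if (!setequal(assignment$otu_id, rownames(cm))) {
    abort("`assignment` was derived from a different OTU universe than `cm`.")
  }
  ids <- assignment$otu_id[assignment$category == category]
  out <- cm[rownames(cm) %in% ids, , drop = FALSE]
  attr(out, "empty_samples") <- colSums(out) == 0
  out
}

#' Minimum-richness gate for the null models
#'
#' The phylogenetic and Raup-Crick null models are only run on tables with at
#' least `min_otus` OTUs; smaller categories are reported as not available.
#'
#' @param cm OTU x sample count matrix (or anything with rows).
#' @param min_otus Minimum OTU count (default 6).
#' @return `TRUE` iff the table holds at least `min_otus` OTUs.
#' @export
check_min_otus <- function(cm, min_otus = 6) {
  n <- if (is.null(dim(cm))) length(cm) else nrow(cm)
  n >= min_otus
}
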