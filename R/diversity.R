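#' Chao1 richness estimate
#'
#' Bias-corrected by default:
#' \eqn{S_{chao1} = S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, which stays
#' defined when no doubletons are observed. The classic estimator
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} is available with
#' `bias_corrected = FALSE`.
#'
#' @param counts Non-negative integer vector of per-OTU counts in one sample.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return The estimated richness (never below observed richness).
#' @examples
#' chao1(c(1, 1, 2)) # 3 + 2*1 / (2*2) = 3.5
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_abundance_vector(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' Shannon diversity H'
#'
#' \eqn{H' = -\sum_i p_i \ln p_i} over taxa with nonzero abundance.
#'
#' @param counts Non-negative abundance vector with positive sum.
#' @return Shannon entropy in nats.
#' @export
shannon <- function(counts) {
  counts <- check_abundance_vector(counts)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Simpson diversity 1 - D
#'
#' \eqn{1 - D = 1 - \sum_i p_i^2}.
#'
#' @inheritParams shannon
#' @return Simpson's index of diversity (probability two random individuals
#'   differ).
#' @export
simpson <- function(counts) {
  counts <- check_abundance_vector(counts)
  unname(vegan::diversity(counts, index = "simpson"))
}

check_abundance_vector <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0 || anyNA(counts) ||
      any(counts < 0)) {
    abort("`counts` must be a non-negative numeric vector.")
  }
  if (sum(counts) == 0) abort("`counts` sums to zero; indices are undefined.")
  counts
}

#' Per-sample alpha diversity table
#'
#' @param cm OTU x sample count matrix (usually rarefied first).
#' @return A tibble with one row per sample: `sample_id`, `richness`,
#'   `chao1`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(cm) {
  cm <- as_count_matrix(cm)
  cs <- colSums(cm)
  if (any(cs == 0)) {
    abort(sprintf("Sample(s) with zero total count: %s",
                  paste(colnames(cm)[cs == 0], collapse = ", ")))
  }
  tibble::tibble(
    sample_id = colnames(cm),
    richness = unname(apply(cm, 2, function(x) sum(x > 0))),
    chao1 = unname(apply(cm, 2, chao1)),
    shannon = unname(apply(cm, 2, shannon)),
    simpson = unname(apply(cm, 2, simpson))
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(a,b) = 1 - 2 \sum_i \min(x_{ia}, x_{ib}) /
#' (\sum_i x_{ia} + \sum_i x_{ib})}, the abundance dissimilarity underlying
#' the Raup-Crick null model.
#'
#' @param cm OTU x sample count matrix with at least two samples.
#' @return A symmetric sample x sample matrix with zero diagonal, values in
#'   \eqn{[0, 1]}.
#' @export
bray_curtis <- function(cm) {
  cm <- as_count_matrix(cm)
  if (ncol(cm) < 2) abort("Bray-Curtis needs at least two samples.")
  cs <- colSums(cm)
  if (any(cs == 0)) {
    abort(sprintf("Sample(s) with zero total count: %s",
                  paste(colnames(cm)[cs == 0], collapse = ", ")))
  }
  as.matrix(vegan::vegdist(t(cm), method = "bray"))
}
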