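#' Assembly process labels
#'
#' @return Character vector of the five process labels.
#' @export
process_levels <- function() {
  c("heterogeneous_selection", "homogeneous_selection",
    "dispersal_limitation", "homogenizing_dispersal", "undominated")
}

#' Patristic (cophenetic) distances between OTUs
#'
#' Sum of branch lengths along the path between each pair of tips.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param otu_ids Optional identifiers that must all be tips; the matrix is
#'   restricted (and ordered) to them.
#' @return A symmetric OTU x OTU distance matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree, otu_ids = NULL) {
  validate_tree(tree)
  if (!is.null(otu_ids)) {
    missing <- setdiff(otu_ids, tree$tip.label)
    if (length(missing) > 0) {
      abort(sprintf("OTU(s) not found as tips in the tree: %s",
                    paste(utils::head(missing, 10), collapse = ", ")))
    }
  }
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(otu_ids)) d <- d[otu_ids, otu_ids, drop = FALSE]
  d
}

#' Beta mean nearest taxon distance between two communities
#'
#' For every taxon in one community, the phylogenetic distance to its closest
#' relative in the other community, averaged with relative-abundance weights
#' and symmetrized:
#' \deqn{\beta MNTD = \tfrac12 \Big[ \sum_{i \in a} f_{ia} \min_{j \in b} d_{ij}
#'   + \sum_{k \in b} f_{kb} \min_{j \in a} d_{kj} \Big]}
#' A taxon present in both communities has nearest-taxon distance zero.
#'
#' @param comm_a,comm_b Abundance vectors over the same OTU universe as `d`
#'   (named, or in the row order of `d`); each must have positive total.
#' @param d OTU x OTU phylogenetic distance matrix
#'   (see [cophenetic_distances()]).
#' @param abundance_weighted Weight taxa by relative abundance (default
#'   `TRUE`); otherwise presence/absence with uniform weights.
#' @return A non-negative scalar.
#' @export
beta_mntd <- function(comm_a, comm_b, d, abundance_weighted = TRUE) {
  w <- align_communities(cbind(comm_a, comm_b), d, abundance_weighted)
  .bmntd_all_pairs_cpp(d, w, seq_len(nrow(d)) - 1L)[1, 2]
}

# Align an OTU x sample abundance matrix with a distance matrix and convert
# to per-sample weights (relative abundance, or uniform over present taxa).
align_communities <- function(cm, d, abundance_weighted) {
  if (nrow(d) != ncol(d)) abort("`d` must be square.")
  if (!is.null(rownames(cm)) && !is.null(rownames(d))) {
    missing <- setdiff(rownames(cm), rownames(d))
    if (length(missing) > 0) {
      abort(sprintf("OTU(s) absent from the distance matrix: %s",
                    paste(utils::head(missing, 10), collapse = ", ")))
    }
    full <- matrix(0, nrow(d), ncol(cm),
                   dimnames = list(rownames(d), colnames(cm)))
    full[rownames(cm), ] <- cm
    cm <- full
  } else if (nrow(cm) != nrow(d)) {
    abort("`cm` rows and `d` must cover the same OTUs.")
  }
  cs <- colSums(cm)
  if (any(cs == 0)) abort("Empty community: every sample needs at least one individual.")
  if (!abundance_weighted) cm <- (cm > 0) * 1
  sweep(cm, 2, colSums(cm), "/")
}

#' Pairwise beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of the observed betaMNTD against a null
#' distribution obtained by shuffling taxa across the tips of the phylogeny
#' (rows/columns of the distance matrix are permuted jointly; abundances stay
#' fixed):
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD_{null}}) /
#'   sd(\beta MNTD_{null})}
#' Values above +2 indicate more phylogenetic turnover than expected
#' (heterogeneous selection), below −2 less than expected (homogeneous
#' selection); in between, turnover is stochastic.
#'
#' @param cm OTU x sample count matrix; all OTUs must be tips of `tree`.
#' @param tree Phylogeny ([ape::phylo]); pruned to the OTUs of `cm`.
#' @param n_null Null randomizations (default 999, minimum 99).
#' @param seed Integer seed; the same seed reproduces the null draws.
#' @param abundance_weighted Weight betaMNTD by relative abundance
#'   (default `TRUE`).
#' @param min_otus Refuse tables with fewer OTUs than this (default 6).
#' @return A tibble with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `beta_mntd_obs`, `null_mean`, `null_sd`, `beta_nti`.
#'   Pairs with a degenerate null (`null_sd` = 0, e.g. a star phylogeny) get
#'   `beta_nti = NA` with a warning and are excluded from downstream
#'   partitioning.
#' @export
beta_nti <- function(cm, tree, n_null = 999, seed = NULL,
                     abundance_weighted = TRUE, min_otus = 6) {
  cm <- as_count_matrix(cm)
  cm <- cm[rowSums(cm) > 0, , drop = FALSE]
  if (!check_min_otus(cm, min_otus)) {
    abort(sprintf("Only %d OTUs with positive abundance; need at least %d.",
                  nrow(cm), min_otus))
  }
  check_scalar_number(n_null, "n_null", lower = 99)
  if (ncol(cm) < 2) abort("Need at least two samples.")
  d <- cophenetic_distances(tree, rownames(cm))
  w <- align_communities(cm, d, abundance_weighted)
  S <- nrow(d)
  id0 <- seq_len(S) - 1L

  obs <- .bmntd_all_pairs_cpp(d, w, id0)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(r) {
      .bmntd_all_pairs_cpp(d, w, sample.int(S) - 1L)
    }, matrix(0, ncol(cm), ncol(cm)))
  })

  pairs <- which(upper.tri(obs), arr.ind = TRUE)
  obs_v <- obs[pairs]
  mean_v <- apply(nulls, c(1, 2), mean)[pairs]
  sd_v <- apply(nulls, c(1, 2), sd)[pairs]
  out <- tibble::tibble(
    sample_a = colnames(cm)[pairs[, 1]],
    sample_b = colnames(cm)[pairs[, 2]],
    beta_mntd_obs = obs_v,
    null_mean = mean_v,
    null_sd = sd_v,
    beta_nti = ifelse(sd_v > 0, (obs_v - mean_v) / sd_v, NA_real_)
  )
  if (anyNA(out$beta_nti)) {
    warn(sprintf("%d pair(s) have a degenerate null (sd = 0); betaNTI set to NA.",
                 sum(is.na(out$beta_nti))))
  }
  out
}

bray_pair <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# One null community: observed richness and total abundance are preserved;
# taxa are drawn without replacement with probability proportional to their
# occurrence frequency, then get one individual each, and the remaining
# individuals are assigned with probability proportional to regional
# relative abundance.
rc_null_community <- function(richness, total, occ_prob, abund_prob) {
  S <- length(occ_prob)
  chosen <- sample.int(S, richness, prob = occ_prob)
  x <- numeric(S)
  x[chosen] <- 1
  rest <- total - richness
  if (rest > 0) {
    x[chosen] <- x[chosen] + rmultinom(1, rest, abund_prob[chosen])[, 1]
  }
  x
}

#' Pairwise Bray-Curtis Raup-Crick metric (RCbray)
#'
#' Locates the observed Bray-Curtis dissimilarity of each sample pair within
#' a null distribution of dissimilarities between probabilistically
#' reassembled communities. Each null community preserves the sample's
#' observed richness and total abundance; taxa enter with probability
#' proportional to their occurrence frequency across the analysed samples
#' and receive individuals with probability proportional to their regional
#' relative abundance. With ties given half weight,
#' \deqn{RC = \big(\#\{null < obs\} + \tfrac12 \#\{null = obs\}\big)/n_{null}}
#' rescaled to \eqn{[-1, 1]} as \eqn{2 RC - 1}. Values above +0.95 indicate
#' dispersal limitation, below −0.95 homogenizing dispersal.
#'
#' @param cm OTU x sample integer count matrix (>= 2 samples).
#' @param n_null Null replicates per pair (default 999).
#' @param seed Master seed; per-pair substreams are derived from it so
#'   results do not depend on pair evaluation order.
#' @return A tibble with one row per unordered pair: `sample_a`, `sample_b`,
#'   `bray_obs`, `rc_bray` (in \eqn{[-1, 1]}).
#' @export
rc_bray <- function(cm, n_null = 999, seed = NULL) {
  cm <- as_count_matrix(cm)
  if (ncol(cm) < 2) abort("Need at least two samples.")
  check_scalar_number(n_null, "n_null", lower = 2)
  cs <- colSums(cm)
  if (any(cs == 0)) {
    abort(sprintf("Sample(s) with zero richness: %s",
                  paste(colnames(cm)[cs == 0], collapse = ", ")))
  }
  cm <- cm[rowSums(cm) > 0, , drop = FALSE]
  occ_prob <- rowMeans(cm > 0)
  abund_prob <- rowSums(cm) / sum(cm)
  richness <- colSums(cm > 0)

  pairs <- which(upper.tri(matrix(0, ncol(cm), ncol(cm))), arr.ind = TRUE)
  pair_seeds <- derive_seeds(seed, nrow(pairs))

  rc <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    obs <- bray_pair(cm[, a], cm[, b])
    with_seed(pair_seeds[k], {
      null <- vapply(seq_len(n_null), function(r) {
        xa <- rc_null_community(richness[a], cs[a], occ_prob, abund_prob)
        xb <- rc_null_community(richness[b], cs[b], occ_prob, abund_prob)
        bray_pair(xa, xb)
      }, numeric(1))
      eps <- 1e-12
      2 * (sum(null < obs - eps) + 0.5 * sum(abs(null - obs) <= eps)) / n_null - 1
    })
  }, numeric(1))

  tibble::tibble(
    sample_a = colnames(cm)[pairs[, 1]],
    sample_b = colnames(cm)[pairs[, 2]],
    bray_obs = vapply(seq_len(nrow(pairs)),
                      function(k) bray_pair(cm[, pairs[k, 1]], cm[, pairs[k, 2]]),
                      numeric(1)),
    rc_bray = rc
  )
}

#' Assign an assembly process to a pairwise comparison
#'
#' The two-tier decision rule: selection first, then dispersal.
#' \eqn{\beta NTI > 2} gives heterogeneous selection and
#' \eqn{\beta NTI < -2} homogeneous selection; only pairs with
#' \eqn{|\beta NTI| < 2} (stochastic phylogenetic turnover) are partitioned
#' by RCbray — above +0.95 dispersal limitation, below −0.95 homogenizing
#' dispersal, otherwise undominated.
#'
#' @param beta_nti,rc Numeric vectors (recycled to common length).
#' @return A factor over [process_levels()]; `NA` where either input is `NA`.
#' @examples
#' partition_processes(c(2.5, 1.0, -1.0, -2.01), c(0.1, 0.97, 0.0, 0.99))
#' @export
partition_processes <- function(beta_nti, rc) {
  n <- max(length(beta_nti), length(rc))
  beta_nti <- rep_len(beta_nti, n)
  rc <- rep_len(rc, n)
  lab <- dplyr::case_when(
    is.na(beta_nti) | (abs(beta_nti) <= 2 & is.na(rc)) ~ NA_character_,
    beta_nti > 2 ~ "heterogeneous_selection",
    beta_nti < -2 ~ "homogeneous_selection",
    rc > 0.95 ~ "dispersal_limitation",
    rc < -0.95 ~ "homogenizing_dispersal",
    .default = "undominated"
  )
  factor(lab, levels = process_levels())
}

#' Run both null models and label every sample pair
#'
#' Convenience wrapper: [beta_nti()] and [rc_bray()] on the same table, joined
#' per pair, with the process label from [partition_processes()].
#'
#' @inheritParams beta_nti
#' @param n_null Null replicates for both null models.
#' @return A tibble with one row per pair: the betaNTI columns, `rc_bray`
#'   and `process`.
#' @export
assembly_processes <- function(cm, tree, n_null = 999, seed = NULL,
                               abundance_weighted = TRUE, min_otus = 6) {
  seeds <- derive_seeds(seed, 2)
  bn <- beta_nti(cm, tree, n_null = n_null, seed = seeds[1],
                 abundance_weighted = abundance_weighted, min_otus = min_otus)
  rc <- rc_bray(cm, n_null = n_null, seed = seeds[2])
  out <- dplyr::left_join(bn, rc, by = c("sample_a", "sample_b"))
  dplyr::mutate(out, process = partition_processes(.data$beta_nti, .data$rc_bray))
}

#' Aggregate pairwise process labels into fractions
#'
#' @param pairs Tibble with a `process` column (e.g. from
#'   [assembly_processes()]), optionally carrying grouping columns.
#' @param group_vars Character vector of columns in `pairs` to aggregate
#'   within (default none: one overall row).
#' @return A tibble with, per group, one column per process label holding its
#'   fraction of valid pairs, plus `n_pairs` (valid pairs),
#'   `deterministic_total` (both selection fractions) and `stochastic_total`
#'   (the remainder). A group with zero valid pairs is reported with `NA`
#'   fractions.
#' @export
aggregate_partition <- function(pairs, group_vars = character()) {
  if (!"process" %in% names(pairs)) abort("`pairs` must have a `process` column.")
  grouped <- dplyr::group_by(pairs, dplyr::across(dplyr::all_of(group_vars)))
  out <- dplyr::summarise(
    grouped,
    n_pairs = sum(!is.na(.data$process)),
    fractions = list(partition_fractions(.data$process)),
    .groups = "drop"
  )
  out <- tidyr::unnest_wider(out, "fractions")
  dplyr::mutate(
    out,
    deterministic_total = .data$heterogeneous_selection + .data$homogeneous_selection,
    stochastic_total = .data$dispersal_limitation + .data$homogenizing_dispersal +
      .data$undominated
  )
}

partition_fractions <- function(process) {
  valid <- sum(!is.na(process))
  counts <- table(factor(process, levels = process_levels()))
  fr <- if (valid == 0) {
    setNames(rep(NA_real_, length(process_levels())), process_levels())
  } else {
    setNames(as.numeric(counts) / valid, names(counts))
  }
  tibble::as_tibble_row(as.list(fr))
}
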