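scenario_descriptions <- c(
  "1" = "disturbance imposes selection",
  "2" = "disturbance relaxes selection, selection returns after removal",
  "3" = "absence of selection throughout",
  "4" = "selection emerges only after disturbance removal"
)

#' Map deterministic-process fractions onto the four disturbance scenarios
#'
#' Places a community on the stochastic-deterministic continuum across the
#' three disturbance states — resistant (undisturbed), impacted (disturbed),
#' resilient (recovering) — and assigns one of four conceptual scenarios. A
#' state counts as selection-dominated (`S`) when its deterministic fraction
#' (heterogeneous + homogeneous selection) reaches `tau`. Rules, checked in
#' the order 2, 1, 4, 3:
#'
#' 1. **Scenario 2** (disturbance relaxes selection): `S` resistant, not `S`
#'    impacted, `S` resilient.
#' 2. **Scenario 1** (disturbance imposes selection): not `S` resistant, `S`
#'    impacted, and the resilient fraction has relaxed below the impacted one.
#' 3. **Scenario 4** (selection emerges after disturbance removal): neither
#'    resistant nor impacted is `S`, and the resilient fraction exceeds both
#'    others and zero.
#' 4. **Scenario 3** (no selection): no state is `S`.
#'
#' Anything else is unassigned. The rules are an explicit operationalisation
#' of a qualitative conceptual model; `tau` is a tunable part of it.
#'
#' @param det_fractions Numeric length-3 vector of deterministic-process
#'   fractions in \[0, 1\], ordered (resistant, impacted, resilient).
#' @param tau Selection-dominance threshold (default 0.4; see the methods
#'   vignette for the rationale).
#' @return A one-row tibble: `det_resistant`, `det_impacted`,
#'   `det_resilient`, `tau`, `scenario` (integer, `NA` when unassigned or
#'   when a fraction is missing) and `description`.
#' @examples
#' assign_scenario(c(0.07, 0.47, 0.20)) # selection appears under disturbance
#' @export
assign_scenario <- function(det_fractions, tau = 0.4) {
  if (length(det_fractions) != 3 || !is.numeric(det_fractions)) {
    abort("`det_fractions` must be a numeric triple (resistant, impacted, resilient).")
  }
  check_scalar_number(tau, "tau", lower = 0, upper = 1)
  ok <- !anyNA(det_fractions)
  if (ok && (any(det_fractions < 0) || any(det_fractions > 1))) {
    abort("Deterministic fractions must lie in [0, 1].")
  }
  scenario <- NA_integer_
  if (ok) {
    d <- det_fractions
    s <- d >= tau
    scenario <- if (s[1] && !s[2] && s[3]) {
      2L
    } else if (!s[1] && s[2] && d[3] < d[2]) {
      1L
    } else if (!s[1] && !s[2] && d[3] > d[1] && d[3] > d[2] && d[3] > 0) {
      4L
    } else if (!s[1] && !s[2] && !s[3]) {
      3L
    } else {
      NA_integer_
    }
  }
  tibble::tibble(
    det_resistant = det_fractions[1],
    det_impacted = det_fractions[2],
    det_resilient = det_fractions[3],
    tau = tau,
    scenario = scenario,
    description = if (is.na(scenario)) "unassigned" else
      unname(scenario_descriptions[as.character(scenario)])
  )
}

#' Run the full community-assembly analysis
#'
#' Orchestrates the whole inference chain on one marker's data: classify
#' OTUs into abundance categories (all samples combined), then per condition
#' group fit the neutral community model on all taxa, and for each requested
#' category run the betaNTI and RCbray null models and partition sample
#' pairs into the five assembly processes. Categories with fewer than
#' `min_otus` OTUs present in a group are reported as `NA` with the reason.
#' When the groups are the three disturbance states, each category's
#' deterministic-fraction trajectory is mapped onto the four conceptual
#' scenarios.
#'
#' @param cm OTU x sample integer count matrix (rarefied to even depth).
#' @param tree Phylogeny over all OTUs ([ape::phylo]); pruned per category.
#' @param metadata Data frame with columns `sample_id` and `group` covering
#'   every sample of `cm`.
#' @param categories Abundance categories to analyse besides `"all"`
#'   (default: all, dominant, conditionally_rare, always_rare; moderate
#'   categories rarely pass the OTU gate).
#' @param n_null Null-model replicates (default 999).
#' @param seed Master seed; every stage derives its substream from it.
#' @param N Community size for the neutral fit (default: minimum column sum).
#' @param min_otus Minimum OTUs per group x category for the null models
#'   (default 6).
#' @param tau Scenario threshold (see [assign_scenario()]).
#' @param condition_order The (resistant, impacted, resilient) group labels,
#'   in that order; default: order of first appearance in `metadata`.
#'   Scenarios are only assigned when exactly three groups are present.
#' @return An object of class `assembly_analysis`: a list with
#'   `classification` (per-OTU categories), `ncm` (named list of `ncm_fit`
#'   per group), `pairs` (per-pair null-model results with `group` and
#'   `category`), `partitions` (per group x category process fractions, with
#'   `note` for skipped cells) and `scenarios` (per-category scenario
#'   assignment, or `NULL`). Use [tidy()] / [glance()] and [autoplot()].
#' @export
run_full_analysis <- function(cm, tree, metadata,
                              categories = c("all", "dominant",
                                             "conditionally_rare",
                                             "always_rare"),
                              n_null = 999, seed = NULL, N = NULL,
                              min_otus = 6, tau = 0.4,
                              condition_order = NULL) {
  cm <- as_count_matrix(cm)
  metadata <- tibble::as_tibble(metadata)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort("`metadata` needs columns `sample_id` and `group`.")
  }
  missing <- setdiff(colnames(cm), metadata$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("Sample(s) missing from metadata: %s",
                  paste(utils::head(missing, 10), collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) {
    abort("`metadata` has duplicated sample_id entries.")
  }
  validate_tree(tree)
  absent <- setdiff(rownames(cm), tree$tip.label)
  if (length(absent) > 0) {
    abort(sprintf("OTU(s) of `cm` missing from the tree: %s",
                  paste(utils::head(absent, 10), collapse = ", ")))
  }
  bad_cat <- setdiff(categories, c("all", abundance_categories()))
  if (length(bad_cat) > 0) {
    abort(sprintf("Unknown categor%s: %s",
                  if (length(bad_cat) > 1) "ies" else "y",
                  paste(bad_cat, collapse = ", ")))
  }

  meta_sub <- metadata[match(colnames(cm), metadata$sample_id), ]
  groups <- unique(condition_order %||% meta_sub$group)
  if (!setequal(groups, unique(meta_sub$group))) {
    abort("`condition_order` does not match the groups in `metadata`.")
  }

  classification <- classify_otus(to_relative(cm))
  group_seeds <- derive_seeds(seed, length(groups) * length(categories))

  pairs_list <- list()
  partition_list <- list()
  ncm_fits <- list()
  k <- 0L
  for (g in groups) {
    g_samples <- meta_sub$sample_id[meta_sub$group == g]
    cm_g_all <- cm[, g_samples, drop = FALSE]
    ncm_fits[[g]] <- fit_ncm(cm_g_all, N = N)
    for (cat in categories) {
      k <- k + 1L
      cm_cat <- subset_by_category(cm, classification, cat)
      cm_gc <- cm_cat[, g_samples, drop = FALSE]
      cm_gc <- cm_gc[rowSums(cm_gc) > 0, , drop = FALSE]
      if (!check_min_otus(cm_gc, min_otus)) {
        partition_list[[k]] <- tibble::tibble(
          group = g, category = cat, n_pairs = 0L,
          note = sprintf("fewer than %d OTUs (%d present)", min_otus, nrow(cm_gc))
        )
        next
      }
      pr <- assembly_processes(cm_gc, tree, n_null = n_null,
                               seed = group_seeds[k], min_otus = min_otus)
      pr <- dplyr::mutate(pr, group = g, category = cat, .before = 1)
      pairs_list[[k]] <- pr
      part <- aggregate_partition(pr)
      partition_list[[k]] <- dplyr::mutate(part, group = g, category = cat,
                                           note = NA_character_, .before = 1)
    }
  }

  partitions <- dplyr::bind_rows(partition_list)
  pairs <- dplyr::bind_rows(pairs_list)

  scenarios <- NULL
  if (length(groups) == 3) {
    scenarios <- purrr::map_dfr(categories, function(cat) {
      det <- vapply(groups, function(g) {
        row <- partitions[partitions$group == g & partitions$category == cat, ]
        if (nrow(row) == 0 || !"deterministic_total" %in% names(row) ||
            is.na(row$deterministic_total[1])) NA_real_ else row$deterministic_total[1]
      }, numeric(1))
      dplyr::mutate(assign_scenario(det, tau = tau), category = cat, .before = 1)
    })
  }

  structure(
    list(classification = classification, ncm = ncm_fits, pairs = pairs,
         partitions = partitions, scenarios = scenarios,
         groups = groups, categories = categories,
         params = list(n_null = n_null, seed = seed, min_otus = min_otus,
                       tau = tau)),
    class = "assembly_analysis"
  )
}

#' @export
print.assembly_analysis <- function(x, ...) {
  cat("Community assembly analysis\n")
  cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  cat(sprintf("  categories: %s\n", paste(x$categories, collapse = ", ")))
  m <- vapply(x$ncm, function(f) f$m, numeric(1))
  r2 <- vapply(x$ncm, function(f) f$r_squared, numeric(1))
  cat("  neutral model fits (all taxa):\n")
  for (g in names(x$ncm)) {
    cat(sprintf("    %s: m = %.3g, R2 = %.3f\n", g, m[[g]], r2[[g]]))
  }
  cat("  process partitions:\n")
  print(as.data.frame(x$partitions), row.names = FALSE, digits = 3)
  if (!is.null(x$scenarios)) {
    cat("  scenario assignments:\n")
    print(as.data.frame(x$scenarios), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write every result table of an analysis to a directory
#'
#' Emits `classification.tsv`, `ncm.tsv`, `pairs.tsv`, `partitions.tsv` and
#' (when present) `scenarios.tsv`.
#'
#' @param x An `assembly_analysis` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(x, dir) {
  if (!inherits(x, "assembly_analysis")) abort("`x` must be an assembly_analysis.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results(x$classification, file.path(dir, "classification.tsv"))
  ncm_tab <- purrr::imap_dfr(x$ncm, function(f, g) {
    dplyr::mutate(glance(f), group = g, .before = 1)
  })
  write_results(ncm_tab, file.path(dir, "ncm.tsv"))
  write_results(x$pairs, file.path(dir, "pairs.tsv"))
  write_results(x$partitions, file.path(dir, "partitions.tsv"))
  if (!is.null(x$scenarios)) {
    write_results(x$scenarios, file.path(dir, "scenarios.tsv"))
  }
  invisible(dir)
}
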