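#' Tidy a neutral community model fit
#'
#' @param x An `ncm_fit` from [fit_ncm()].
#' @param ... Unused.
#' @return One row per OTU: `otu_id`, `p` (mean relative abundance), `freq`
#'   (observed occurrence frequency), `predicted`, the Wilson band
#'   (`ci_lower`, `ci_upper`) and the `band` flag (above/within/below).
#' @export
tidy.ncm_fit <- function(x, ...) {
  x$table
}

#' @rdname tidy.ncm_fit
#' @return For `glance()`: a one-row tibble with `m`, `N`, `r_squared`,
#'   `ss_err`, `n_otus_used`, `n_samples`, `detection_threshold`, `log_lik`,
#'   `aic`, `bic`.
#' @export
glance.ncm_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, N = x$N, r_squared = x$r_squared, ss_err = x$ss_err,
    n_otus_used = x$n_otus_used, n_samples = x$n_samples,
    detection_threshold = x$detection_threshold,
    log_lik = x$log_lik, aic = x$aic, bic = x$bic
  )
}

#' Tidy a neutral/binomial/Poisson model comparison
#'
#' @param x An `ncm_comparison` from [compare_models()].
#' @param ... Unused.
#' @return One row per model: bootstrap-mean AIC/BIC and full-data AIC, BIC
#'   and R-squared, sorted by mean BIC.
#' @export
tidy.ncm_comparison <- function(x, ...) {
  x$summary
}

#' @rdname tidy.ncm_comparison
#' @return For `glance()`: a one-row tibble with `best_model`, `n_boot` and
#'   the fitted migration rate.
#' @export
glance.ncm_comparison <- function(x, ...) {
  tibble::tibble(best_model = x$best_model, n_boot = x$n_boot, m = x$fit$m)
}

#' Tidy a full assembly analysis
#'
#' @param x An `assembly_analysis` from [run_full_analysis()].
#' @param what Which table: `"partitions"` (default), `"pairs"`,
#'   `"classification"`, `"ncm"` (per-group fit summaries) or
#'   `"scenarios"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.assembly_analysis <- function(x, what = c("partitions", "pairs",
                                               "classification", "ncm",
                                               "scenarios"), ...) {
  what <- match.arg(what)
  switch(what,
    partitions = x$partitions,
    pairs = x$pairs,
    classification = x$classification,
    ncm = purrr::imap_dfr(x$ncm, function(f, g) {
      dplyr::mutate(glance(f), group = g, .before = 1)
    }),
    scenarios = x$scenarios %||%
      abort("No scenarios: the analysis does not have exactly three groups.")
  )
}

#' @rdname tidy.assembly_analysis
#' @return For `glance()`: one row per group with the neutral fit summary
#'   and the all-taxa deterministic and stochastic totals.
#' @export
glance.assembly_analysis <- function(x, ...) {
  ncm <- purrr::imap_dfr(x$ncm, function(f, g) {
    dplyr::mutate(glance(f)[, c("m", "r_squared")], group = g, .before = 1)
  })
  all_part <- x$partitions[x$partitions$category == "all",
                           intersect(c("group", "deterministic_total",
                                       "stochastic_total", "n_pairs"),
                                     names(x$partitions))]
  dplyr::left_join(ncm, all_part, by = "group")
}
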