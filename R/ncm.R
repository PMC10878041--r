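#' Expected occurrence frequency under the neutral community model
#'
#' Sloan's neutral prediction for the probability that a taxon with mean
#' metacommunity relative abundance `p` is detected (at least one individual
#' among `N`) in a local community, for migration rate `m`:
#' \deqn{Freq = 1 - I_{1/N}(N m p,\; N m (1 - p))}
#' where \eqn{I_x(\alpha,\beta)} is the regularized incomplete beta function
#' (the beta CDF) evaluated at the detection threshold \eqn{1/N}.
#'
#' @param p Mean relative abundance(s) in the metacommunity, each in (0, 1).
#' @param N Individuals per local community (>= 2); usually the rarefaction
#'   depth.
#' @param m Migration rate in (0, 1]: the probability that a death is
#'   replaced by an immigrant rather than a local birth.
#' @return Expected occurrence frequency in \[0, 1\], vectorised over `p`.
#' @examples
#' ncm_predict(0.5, N = 100, m = 0.02) # alpha = beta = 1: 1 - 1/100
#' @export
ncm_predict <- function(p, N, m) {
  if (!is.numeric(p) || length(p) == 0 || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  check_scalar_number(N, "N", lower = 2)
  check_scalar_number(m, "m", lower = .Machine$double.eps, upper = 1)
  1 - pbeta(1 / N, N * m * p, N * m * (1 - p))
}

#' Occurrence frequency vs mean relative abundance
#'
#' The observed (p_i, Freq_i) pairs the neutral model is fitted to: for each
#' OTU, its mean relative abundance across samples and the fraction of
#' samples where it is detected (count >= 1). OTUs absent everywhere are
#' dropped.
#'
#' @param cm OTU x sample count matrix with >= 2 samples.
#' @return A tibble with columns `otu_id`, `p`, `freq`.
#' @export
occurrence_frequency_table <- function(cm) {
  cm <- as_count_matrix(cm)
  if (ncol(cm) < 2) abort("Need at least two samples.")
  cm <- cm[rowSums(cm) > 0, , drop = FALSE]
  ra <- to_relative(cm)
  tibble::tibble(
    otu_id = rownames(cm),
    p = unname(rowMeans(ra)),
    freq = unname(rowMeans(cm >= 1))
  )
}

#' Wilson score interval for a proportion
#'
#' @param freq_hat Observed proportion(s) in \[0, 1\].
#' @param n Number of trials (samples), >= 1.
#' @param confidence Confidence level (default 0.95).
#' @return A tibble with columns `lower` and `upper`.
#' @examples
#' wilson_interval(0.5, 100)
#' @export
wilson_interval <- function(freq_hat, n, confidence = 0.95) {
  if (!is.numeric(freq_hat) || anyNA(freq_hat) ||
      any(freq_hat < 0) || any(freq_hat > 1)) {
    abort("`freq_hat` must lie in [0, 1].")
  }
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(confidence, "confidence", lower = 0, upper = 1)
  z <- qnorm(1 - (1 - confidence) / 2)
  denom <- 1 + z^2 / n
  centre <- (freq_hat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(freq_hat * (1 - freq_hat) / n + z^2 / (4 * n^2))
  tibble::tibble(lower = pmax(0, centre - half),
                 upper = pmin(1, centre + half))
}

# Sum of squared residuals of the neutral curve at migration rate m.
ncm_ss <- function(m, p, freq, N) {
  sum((freq - (1 - pbeta(1 / N, N * m * p, N * m * (1 - p))))^2)
}

# Deterministic 1-parameter least squares: multi-start over a log-spaced
# m grid, refined with stats::optimize() in the bracketing interval; ties on
# the grid broken towards the smallest m.
fit_m <- function(p, freq, N, m_grid = 10^seq(-4, 0, length.out = 81)) {
  ss <- vapply(m_grid, ncm_ss, numeric(1), p = p, freq = freq, N = N)
  if (all(!is.finite(ss))) abort("Neutral fit failed: no finite residual on the m grid.")
  i <- which.min(ss) # which.min takes the first (smallest m) on ties
  lo <- m_grid[max(1L, i - 1L)]
  hi <- m_grid[min(length(m_grid), i + 1L)]
  opt <- optimize(ncm_ss, interval = c(lo, hi), p = p, freq = freq, N = N,
                  tol = 1e-10)
  if (opt$objective <= ss[i]) {
    list(m = opt$minimum, ss = opt$objective)
  } else {
    list(m = m_grid[i], ss = ss[i])
  }
}

# Profiled-Gaussian log likelihood of residuals (variance at its MLE).
gaussian_loglik <- function(ss, n) {
  sigma2 <- max(ss / n, .Machine$double.xmin)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

#' Fit Sloan's neutral community model
#'
#' Estimates the migration rate `m` by nonlinear least squares on the
#' occurrence-frequency vs mean-abundance relationship, with `N` fixed to the
#' community size (rarefaction depth). The fit is deterministic: a multi-start
#' log-spaced grid over `m` followed by 1-D refinement. Goodness of fit is the
#' generalized R-squared \eqn{1 - SS_{err}/SS_{total}}, with
#' \eqn{SS_{total}} taken about the mean observed frequency. A 95% Wilson
#' score band around the predicted frequencies flags OTUs occurring more or
#' less often than neutral expectation.
#'
#' @param cm OTU x sample count matrix (>= 2 samples).
#' @param N Individuals per community; defaults to the minimum column sum
#'   (the rarefaction depth for an evenly rarefied table).
#' @param confidence Confidence level of the Wilson band (default 0.95).
#' @return An object of class `ncm_fit`: access the per-OTU table with
#'   [tidy()], the scalar summary (`m`, `r_squared`, `aic`, `bic`, ...) with
#'   [glance()], and plot with [autoplot()].
#' @seealso [compare_models()] for the neutral vs binomial vs Poisson
#'   competition.
#' @export
fit_ncm <- function(cm, N = NULL, confidence = 0.95) {
  cm <- as_count_matrix(cm)
  tab <- occurrence_frequency_table(cm)
  if (is.null(N)) {
    cs <- colSums(cm)
    N <- min(cs)
    if (length(unique(cs)) > 1) {
      warn(sprintf("Unequal sample depths; using N = %d (minimum). Rarefy first or pass N.", N))
    }
  }
  check_scalar_number(N, "N", lower = 2)
  n_informative <- sum(tab$freq > 0 & tab$freq < 1)
  if (n_informative < 10) {
    warn(sprintf("Only %d OTUs with 0 < Freq < 1; the fit may be unstable.",
                 n_informative))
  }
  fit <- fit_m(tab$p, tab$freq, N)
  pred <- ncm_predict(tab$p, N, fit$m)
  band <- wilson_interval(pred, n = ncol(cm), confidence = confidence)
  tab <- dplyr::mutate(
    tab,
    predicted = pred,
    ci_lower = band$lower,
    ci_upper = band$upper,
    band = dplyr::case_when(
      .data$freq > .data$ci_upper ~ "above",
      .data$freq < .data$ci_lower ~ "below",
      .default = "within"
    )
  )
  ss_total <- sum((tab$freq - mean(tab$freq))^2)
  r2 <- if (ss_total > 0) 1 - fit$ss / ss_total else as.numeric(fit$ss == 0)
  n <- nrow(tab)
  ll <- gaussian_loglik(fit$ss, n)
  k <- 2 # m and the residual sd
  structure(
    list(
      m = fit$m, N = as.integer(N), r_squared = r2, ss_err = fit$ss,
      ss_total = ss_total, n_otus_used = n, n_samples = ncol(cm),
      detection_threshold = 1 / N, log_lik = ll,
      aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
      confidence = confidence, table = tab
    ),
    class = "ncm_fit"
  )
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4g, N = %d (detection threshold 1/N = %.3g)\n",
              x$m, x$N, x$detection_threshold))
  cat(sprintf("  generalized R-squared = %.4f over %d OTUs, %d samples\n",
              x$r_squared, x$n_otus_used, x$n_samples))
  cat(sprintf("  AIC = %.2f, BIC = %.2f\n", x$aic, x$bic))
  bands <- table(x$table$band)
  cat(sprintf("  OTUs above/within/below the %g%% Wilson band: %d/%d/%d\n",
              100 * x$confidence,
              bands["above"] %||% 0L, bands["within"] %||% 0L,
              bands["below"] %||% 0L))
  invisible(x)
}

# Model-specific predicted frequencies and parameter counts (sampling-only
# competitors have no free shape parameter; k counts the residual sd).
sampling_model_pred <- function(model, p, N, m = NULL) {
  switch(model,
    neutral = ncm_predict(p, N, m),
    binomial = 1 - pbinom(0, size = N, prob = p),
    poisson = 1 - exp(-N * p),
    abort(sprintf("Unknown model '%s'.", model))
  )
}

#' Compare the neutral model with binomial and Poisson sampling models
#'
#' Asks whether the occurrence-frequency relationship requires immigration
#' dynamics (the neutral model's `m`) or is explained by random sampling of
#' the metacommunity alone: the binomial model predicts detection of at least
#' one individual among `N` binomial draws at abundance `p`
#' (\eqn{1 - (1-p)^N}), the Poisson model its small-`p` limit
#' (\eqn{1 - e^{-Np}}). AIC and BIC are computed from the profiled Gaussian
#' residual likelihood (one free parameter for the neutral model, none for
#' the samplers, plus the residual sd each) over bootstrap resamples of OTUs.
#'
#' @param cm OTU x sample count matrix.
#' @param N Individuals per community (default as in [fit_ncm()]).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `ncm_comparison` with elements `summary` (a
#'   tibble: model, mean AIC/BIC over replicates, full-data AIC/BIC and R2),
#'   `bootstrap` (per-replicate tibble), `best_model`, and the full-data
#'   `fit`.
#' @export
compare_models <- function(cm, N = NULL, n_boot = 1000, seed = NULL) {
  check_scalar_number(n_boot, "n_boot", lower = 2)
  fit <- fit_ncm(cm, N = N)
  tab <- fit$table
  N <- fit$N
  n <- nrow(tab)
  models <- c("neutral", "binomial", "poisson")
  k <- c(neutral = 2, binomial = 1, poisson = 1)

  ic <- function(p, freq, model, m = NULL) {
    if (model == "neutral") {
      m <- fit_m(p, freq, N)$m
    }
    ss <- sum((freq - sampling_model_pred(model, p, N, m))^2)
    ll <- gaussian_loglik(ss, length(p))
    c(aic = 2 * k[[model]] - 2 * ll,
      bic = k[[model]] * log(length(p)) - 2 * ll,
      ss = ss)
  }

  boot <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      purrr::map_dfr(models, function(mod) {
        v <- ic(tab$p[idx], tab$freq[idx], mod)
        tibble::tibble(replicate = r, model = mod,
                       aic = v[["aic"]], bic = v[["bic"]])
      })
    })
  })

  full <- purrr::map_dfr(models, function(mod) {
    v <- ic(tab$p, tab$freq, mod)
    ss_total <- sum((tab$freq - mean(tab$freq))^2)
    tibble::tibble(model = mod, aic = v[["aic"]], bic = v[["bic"]],
                   r_squared = if (ss_total > 0) 1 - v[["ss"]] / ss_total else NA_real_)
  })

  summary <- boot |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(aic_mean = mean(.data$aic), bic_mean = mean(.data$bic),
                     .groups = "drop") |>
    dplyr::left_join(full, by = "model") |>
    dplyr::arrange(.data$bic_mean, .data$aic_mean)

  structure(
    list(summary = summary, bootstrap = boot,
         best_model = summary$model[1], fit = fit, n_boot = n_boot),
    class = "ncm_comparison"
  )
}

#' @export
print.ncm_comparison <- function(x, ...) {
  cat(sprintf("Occurrence-frequency model comparison (%d bootstrap replicates)\n",
              x$n_boot))
  cat(sprintf("  best model by mean BIC: %s\n", x$best_model))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}
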