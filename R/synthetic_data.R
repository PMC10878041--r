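#' Simulate a metacommunity relative-abundance vector
#'
#' Draws per-OTU regional abundances from a heavy-tailed species abundance
#' distribution. The log-series (default, shape = Fisher's `x`) produces the
#' many-taxa-below-0.01% tail that populates the always-rare category;
#' the lognormal (shape = `sdlog`) is available as a milder alternative.
#'
#' @param n_otus Metacommunity richness (>= 10).
#' @param distribution `"logseries"` or `"lognormal"`.
#' @param shape Fisher's `x` in (0, 1) for the log-series (default 0.98), or
#'   `sdlog` > 0 for the lognormal (default 2).
#' @param seed Integer seed.
#' @return A named numeric vector of proportions summing to 1, names
#'   `OTU_1..OTU_n`.
#' @export
simulate_metacommunity <- function(n_otus,
                                   distribution = c("logseries", "lognormal"),
                                   shape = NULL, seed = NULL) {
  distribution <- match.arg(distribution)
  check_scalar_number(n_otus, "n_otus", lower = 10)
  n_otus <- as.integer(n_otus)
  ab <- with_seed(seed, {
    if (distribution == "logseries") {
      x <- shape %||% 0.98
      if (x <= 0 || x >= 1) abort("log-series shape `x` must be in (0, 1).")
      k_max <- 5000L
      pmf <- x^seq_len(k_max) / seq_len(k_max)
      sample.int(k_max, n_otus, replace = TRUE, prob = pmf)
    } else {
      sdlog <- shape %||% 2
      if (sdlog <= 0) abort("lognormal shape `sdlog` must be positive.")
      stats::rlnorm(n_otus, meanlog = 0, sdlog = sdlog)
    }
  })
  p <- ab / sum(ab)
  setNames(p, paste0("OTU_", seq_len(n_otus)))
}

#' Simulate neutral local communities
#'
#' Individual-based Moran dynamics: at each step one random individual dies
#' and is replaced, with probability `m`, by an immigrant drawn from the
#' metacommunity, otherwise by the offspring of a random local individual.
#' Replicate communities are independent. The default burn-in of `10 * N`
#' steps brings each community to quasi-stationarity from a metacommunity
#' draw.
#'
#' The `m` argument is by default the migration rate on the scale the
#' neutral community model estimates (effective immigration
#' \eqn{\theta = N m}). For the Moran scheme the effective immigration of a
#' per-death immigrant probability \eqn{\mu} is
#' \eqn{\theta = \mu (N - 1)/(1 - \mu)}, so the simulator uses
#' \eqn{\mu = N m / (N m + N - 1)} internally; this is what lets
#' [fit_ncm()] recover the simulator's `m` (up to the estimator's own
#' bias, see the methods vignette). Set `migration_scale = "replacement"`
#' to make `m` the literal per-death immigrant probability instead.
#'
#' Communities are initialised at the model's stationary distribution
#' (a Dirichlet-multinomial draw with concentration \eqn{\theta p}); the
#' burn-in then only has to erase the difference between that continuous
#' approximation and the exact discrete stationary state, which `10 * N`
#' steps do at any `m` (the relaxation time from an arbitrary start grows
#' like \eqn{N/\mu} and would be out of reach at small `m`).
#'
#' @param meta Metacommunity proportions (named).
#' @param n_samples Number of replicate local communities.
#' @param N Individuals per community (>= 10).
#' @param m Migration rate in (0, 1]; see Details for its scale.
#' @param generations Death-replacement steps per community
#'   (default `10 * N`).
#' @param seed Integer seed.
#' @param migration_scale `"sloan"` (default): `m` is the neutral-model
#'   migration rate; `"replacement"`: `m` is the per-death immigrant
#'   probability.
#' @param init Optional OTU x sample integer matrix of starting communities
#'   (column sums `N`); overrides the stationary initialisation.
#' @return OTU x sample count matrix with column sums `N`.
#' @export
simulate_neutral_local <- function(meta, n_samples, N = 1000, m,
                                   generations = NULL, seed = NULL,
                                   migration_scale = c("sloan", "replacement"),
                                   init = NULL) {
  migration_scale <- match.arg(migration_scale)
  check_scalar_number(N, "N", lower = 10)
  check_scalar_number(m, "m", lower = 0, upper = 1)
  check_scalar_number(n_samples, "n_samples", lower = 1)
  N <- as.integer(N)
  mu <- if (migration_scale == "sloan") N * m / (N * m + N - 1) else m
  theta <- if (mu < 1) mu * (N - 1) / (1 - mu) else Inf
  generations <- as.integer(generations %||% (10 * N))
  if (generations < 10 * N) {
    warn(sprintf("generations = %d is below the 10*N = %d burn-in; communities may not be stationary.",
                 generations, 10 * N))
  }
  if (!is.null(init)) {
    init <- as_count_matrix(init)
    if (ncol(init) != n_samples || nrow(init) != length(meta) ||
        any(colSums(init) != N)) {
      abort("`init` must be a length(meta) x n_samples matrix with column sums N.")
    }
  }
  counts <- with_seed(seed, {
    if (is.null(init)) {
      init <- vapply(seq_len(n_samples), function(s) {
        x <- if (is.finite(theta) && theta > 0) {
          g <- stats::rgamma(length(meta), shape = theta * meta)
          if (sum(g) > 0) g / sum(g) else meta
        } else {
          meta
        }
        rmultinom(1, N, x)[, 1]
      }, integer(length(meta)))
    }
    .neutral_local_cpp(unname(meta), as.integer(n_samples), N, mu,
                       generations, init)
  })
  dimnames(counts) <- list(names(meta) %||% paste0("OTU_", seq_along(meta)),
                           paste0("S", seq_len(n_samples)))
  counts
}

#' Simulate a phylogeny and Brownian traits for its tips
#'
#' `simulate_tree()` draws a pure-birth (Yule) tree; `evolve_trait()` evolves
#' a continuous trait along it by Brownian motion, so closely related tips
#' carry similar values (strong phylogenetic signal by construction).
#'
#' @param n_tips Number of tips (>= 6).
#' @param seed Integer seed.
#' @param tip_labels Optional tip names (default `OTU_1..OTU_n`).
#' @return `simulate_tree()`: an [ape::phylo]; `evolve_trait()`: a named
#'   numeric vector of tip traits.
#' @export
simulate_tree <- function(n_tips, seed = NULL, tip_labels = NULL) {
  check_scalar_number(n_tips, "n_tips", lower = 6)
  tree <- with_seed(seed, ape::rphylo(as.integer(n_tips), birth = 1, death = 0))
  tree$tip.label <- tip_labels %||% paste0("OTU_", seq_len(as.integer(n_tips)))
  tree
}

#' @rdname simulate_tree
#' @param tree Phylogeny over the taxa.
#' @param rate Brownian rate: trait variance accrued per unit branch length
#'   (default 1).
#' @export
evolve_trait <- function(tree, rate = 1, seed = NULL) {
  validate_tree(tree)
  check_scalar_number(rate, "rate", lower = 0)
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate)))
}

#' Simulate communities under trait-environment selection
#'
#' Each sample draws `N` individuals with weights
#' \eqn{w_i \propto meta_i \exp(-(trait_i - env)^2 / (2\sigma_{sel}^2))}:
#' a Gaussian environmental filter on a phylogenetically conserved trait.
#' Contrasting `env_values` under a strong filter (small `sigma_sel`)
#' generate heterogeneous selection between samples; identical `env_values`
#' generate a homogeneous-selection-like signal. `sigma_sel = 0` disables
#' the filter (neutral multinomial sampling of the metacommunity).
#'
#' @param meta Metacommunity proportions, names matching `names(traits)`.
#' @param traits Named trait vector (see [evolve_trait()]).
#' @param env_values Environment value per sample.
#' @param sigma_sel Filter width (same units as the trait); smaller is
#'   stronger selection; 0 turns selection off.
#' @param N Individuals per sample.
#' @param seed Integer seed.
#' @return OTU x sample count matrix with column sums `N`.
#' @export
simulate_selected_communities <- function(meta, traits, env_values,
                                          sigma_sel, N = 1000, seed = NULL) {
  check_scalar_number(sigma_sel, "sigma_sel", lower = 0)
  check_scalar_number(N, "N", lower = 1)
  if (is.null(names(meta)) || is.null(names(traits)) ||
      !setequal(names(meta), names(traits))) {
    abort("`meta` and `traits` must be named over the same OTUs.")
  }
  traits <- traits[names(meta)]
  counts <- with_seed(seed, {
    vapply(env_values, function(env) {
      w <- if (sigma_sel > 0) {
        meta * exp(-(traits - env)^2 / (2 * sigma_sel^2))
      } else {
        meta
      }
      if (sum(w) <= 0) abort("Selection filter left no viable taxa.")
      rmultinom(1, as.integer(N), w)[, 1]
    }, numeric(length(meta)))
  })
  dimnames(counts) <- list(names(meta), paste0("S", seq_along(env_values)))
  counts
}

#' Simulate dispersal-limited communities
#'
#' Samples are distributed over `n_patches` isolated patches. Each patch is
#' founded by its own small subset of the metacommunity (richness capped at
#' `founder_richness`; founder sets are disjoint across patches) and each
#' sample then drifts from a multinomial draw over its patch's founders with
#' negligible immigration. Between-patch sample pairs share no taxa while the
#' pooled occupancy structure would predict substantial overlap, which is
#' the dispersal-limitation signature (high Bray-Curtis with RCbray > 0.95)
#' at |betaNTI| < 2, since founders are random with respect to the
#' phylogeny. Within-patch pairs, sharing their founders, show the opposite
#' (homogenizing-dispersal-like) signal.
#'
#' @param meta Metacommunity proportions (named).
#' @param n_samples Number of samples (>= 4).
#' @param N Individuals per sample.
#' @param founder_richness Taxa per patch founder set (>= 2).
#' @param n_patches Number of isolated patches (default 3); samples are
#'   assigned to patches round-robin. `n_patches = n_samples` gives fully
#'   disjoint samples.
#' @param m Residual migration during drift (default 0: founders only).
#' @param generations Drift steps after founding (default `N`).
#' @param seed Integer seed.
#' @return OTU x sample count matrix with column sums `N`, with the patch
#'   assignment attached as attribute `"patch"`.
#' @export
simulate_dispersal_limited <- function(meta, n_samples, N = 1000,
                                       founder_richness = 10, n_patches = 3,
                                       m = 0, generations = NULL,
                                       seed = NULL) {
  check_scalar_number(n_samples, "n_samples", lower = 4)
  check_scalar_number(founder_richness, "founder_richness", lower = 2)
  check_scalar_number(n_patches, "n_patches", lower = 1)
  check_scalar_number(N, "N", lower = 10)
  N <- as.integer(N)
  n_patches <- as.integer(n_patches)
  generations <- as.integer(generations %||% N)
  S <- length(meta)
  if (n_patches * founder_richness > S) {
    abort("`n_patches * founder_richness` exceeds metacommunity richness.")
  }
  patch <- rep_len(seq_len(n_patches), n_samples)
  with_seed(seed, {
    pool <- sample.int(S, n_patches * founder_richness, prob = meta)
    founder_sets <- split(pool, rep(seq_len(n_patches),
                                    each = founder_richness))
    init <- vapply(seq_len(n_samples), function(s) {
      founders <- founder_sets[[patch[s]]]
      x <- integer(S)
      x[founders] <- rmultinom(1, N, meta[founders])[, 1]
      x
    }, integer(S))
    counts <- .neutral_local_cpp(unname(meta), as.integer(n_samples), N, m,
                                 generations, init)
    dimnames(counts) <- list(names(meta) %||% paste0("OTU_", seq_len(S)),
                             paste0("S", seq_len(n_samples)))
    attr(counts, "patch") <- patch
    counts
  })
}

#' Generate a study-like synthetic dataset with known assembly processes
#'
#' Builds one marker's worth of data shaped like the cave-survey design —
#' three rock-surface condition groups (`resistant`, `impacted`,
#' `resilient`) x `n_replicates` swabs x `n_dates` sampling dates — with the
#' generating process of each group known:
#'
#' * **resistant** — neutral assembly with high migration (`m_neutral`);
#' * **impacted** — trait-environment selection with two contrasting
#'   micro-environments across swabs (heterogeneous selection);
#' * **resilient** — dispersal-limited founder communities, plus a small set
#'   of *rare specialist* taxa (two phylogenetically distant clades, one read
#'   per sample each) that are environmentally sorted only in this group.
#'   The rare specialists stay below 0.01% everywhere, so they form an
#'   always-rare category that is selection-structured in the resilient
#'   state and stochastic elsewhere.
#'
#' The two dates are independent draws from the same group process. All
#' column sums equal `N`.
#'
#' @param seed Integer master seed (all randomness derives from it).
#' @param n_otus_meta Metacommunity richness (default 800).
#' @param n_replicates Swabs per group and date (default 6).
#' @param n_dates Sampling dates (default 2).
#' @param N Reads per sample (default 12105, a typical 16S rarefaction
#'   depth; large enough that single reads sit below the 0.01% rarity cut).
#' @param m_neutral Migration rate of the resistant group (default 0.5).
#' @param sigma_sel Selection filter width for the impacted group
#'   (default 0.4, traits standardised to unit sd).
#' @param founder_richness Founder taxa per resilient patch (default 60).
#' @param n_patches Isolated patches in the resilient group (default 6, i.e.
#'   two samples per patch at the default design; many patch pairs keep the
#'   group's between-patch phylogenetic turnover at its null expectation).
#' @param n_rare_specialists Rare specialist taxa reserved for the
#'   always-rare overlay (default 30, split into two trait-extreme clades).
#' @param rare_reads_per_sample Singleton reads of rare specialists added to
#'   every sample (default 8).
#' @return A list of class `synthetic_dataset`: `counts` (OTU x sample),
#'   `tree` ([ape::phylo] over all OTUs), `metadata` (tibble: `sample_id`,
#'   `group`, `date`, `env`), and `truth` (generating process and parameters
#'   per group).
#' @export
make_study_like_dataset <- function(seed = 1, n_otus_meta = 800,
                                    n_replicates = 6, n_dates = 2,
                                    N = 12105, m_neutral = 0.5,
                                    sigma_sel = 0.4, founder_richness = 60,
                                    n_patches = 6,
                                    n_rare_specialists = 30,
                                    rare_reads_per_sample = 8) {
  seeds <- derive_seeds(seed, 10)
  n_per_group <- n_replicates * n_dates
  S <- as.integer(n_otus_meta)

  meta <- simulate_metacommunity(S, "logseries", seed = seeds[1])
  tree <- simulate_tree(S, seed = seeds[2], tip_labels = names(meta))
  traits <- evolve_trait(tree, rate = 1, seed = seeds[3])
  traits <- (traits - mean(traits)) / sd(traits)

  # Reserve trait-extreme, regionally scarce taxa as rare specialists: one
  # clade-like set at each trait extreme. They are removed from the regional
  # pool so base communities never pick them up.
  scarce <- names(sort(meta))[seq_len(min(4 * n_rare_specialists, S))]
  by_trait <- scarce[order(traits[scarce])]
  half <- floor(n_rare_specialists / 2)
  rare_low <- by_trait[seq_len(half)]
  rare_high <- rev(by_trait)[seq_len(half)]
  specialists <- c(rare_low, rare_high)
  pool <- meta
  pool[specialists] <- 0
  pool <- pool / sum(pool)

  n_base <- as.integer(N - rare_reads_per_sample)
  env_pattern <- rep_len(c(-1.5, 1.5), n_per_group)

  resistant <- simulate_neutral_local(pool, n_per_group, N = n_base,
                                      m = m_neutral, seed = seeds[4])
  impacted <- simulate_selected_communities(pool, traits, env_pattern,
                                            sigma_sel = sigma_sel,
                                            N = n_base, seed = seeds[5])
  resilient <- simulate_dispersal_limited(pool, n_per_group, N = n_base,
                                          founder_richness = founder_richness,
                                          n_patches = n_patches,
                                          seed = seeds[6])

  # Always-rare overlay: singletons only, so every specialist stays below
  # one read per sample (< 0.01% at this depth). Resistant and impacted
  # samples draw specialists at random; resilient samples draw from the
  # clade matching their micro-environment.
  overlay <- function(counts, choose_for_sample, overlay_seed) {
    with_seed(overlay_seed, {
      for (s in seq_len(ncol(counts))) {
        picked <- choose_for_sample(s)
        counts[picked, s] <- counts[picked, s] + 1L
      }
      counts
    })
  }
  random_rare <- function(s) sample(specialists, rare_reads_per_sample)
  sorted_rare <- function(s) {
    clade <- if (env_pattern[s] < 0) rare_low else rare_high
    sample(clade, rare_reads_per_sample)
  }
  resistant <- overlay(resistant, random_rare, seeds[7])
  impacted <- overlay(impacted, random_rare, seeds[8])
  resilient <- overlay(resilient, sorted_rare, seeds[9])

  groups <- c("resistant", "impacted", "resilient")
  counts <- cbind(resistant, impacted, resilient)
  sample_ids <- paste0(rep(groups, each = n_per_group), "_",
                       rep(seq_len(n_per_group), times = 3))
  colnames(counts) <- sample_ids
  storage.mode(counts) <- "integer"

  metadata <- tibble::tibble(
    sample_id = sample_ids,
    group = rep(groups, each = n_per_group),
    date = rep(rep(paste0("date_", seq_len(n_dates)), each = n_replicates), 3),
    env = c(rep(0, n_per_group), env_pattern, env_pattern)
  )

  truth <- list(
    resistant = list(process = "neutral", m = m_neutral),
    impacted = list(process = "heterogeneous_selection", sigma_sel = sigma_sel,
                    env = env_pattern),
    resilient = list(process = "dispersal_limitation",
                     founder_richness = founder_richness,
                     always_rare_selected = TRUE),
    rare_specialists = list(low = rare_low, high = rare_high)
  )

  structure(list(counts = counts, tree = tree, metadata = metadata,
                 truth = truth, N = as.integer(N)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic community dataset: %d OTUs x %d samples (column sums %d)\n",
              nrow(x$counts), ncol(x$counts), x$N))
  print(dplyr::count(x$metadata, .data$group, .data$date))
  invisible(x)
}
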