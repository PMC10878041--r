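test_that("metacommunity draws are normalised, heavy-tailed and reproducible", {
  meta <- simulate_metacommunity(1000, "logseries", seed = 1)
  expect_equal(sum(meta), 1)
  expect_gte(sum(meta < 1e-4), 100) # the rare tail that feeds always_rare
  expect_identical(meta, simulate_metacommunity(1000, "logseries", seed = 1))

  ln <- simulate_metacommunity(500, "lognormal", seed = 2)
  expect_equal(sum(ln), 1)
  expect_true(all(ln > 0))
  expect_error(simulate_metacommunity(5), "n_otus")
  expect_error(simulate_metacommunity(100, "logseries", shape = 1.2), "shape")
})

test_that("full-replacement dynamics reduce to multinomial sampling of the pool", {
  withr::with_seed(30, meta <- {
    x <- stats::rgamma(20, 2); x / sum(x)
  })
  names(meta) <- paste0("OTU_", 1:20)
  # m = 1 on the replacement scale: every death is an immigrant draw
  rejections <- vapply(1:20, function(s) {
    cm <- simulate_neutral_local(meta, 1, N = 2000, m = 1,
                                 migration_scale = "replacement", seed = s)
    p <- suppressWarnings(stats::chisq.test(cm[, 1], p = meta)$p.value)
    p < 0.01
  }, logical(1))
  expect_lte(sum(rejections), 2)
})

test_that("drift without immigration tends to monodominance", {
  withr::with_seed(31, meta <- {
    x <- stats::rgamma(30, 1); x / sum(x)
  })
  names(meta) <- paste0("OTU_", 1:30)
  top_share <- vapply(1:10, function(s) {
    cm <- suppressWarnings(
      simulate_neutral_local(meta, 1, N = 50, m = 0,
                             migration_scale = "replacement",
                             generations = 20000, seed = s))
    max(cm[, 1]) / sum(cm[, 1])
  }, numeric(1))
  expect_gte(mean(top_share > 0.9), 0.7)
})

test_that("neutral simulation output is a valid reproducible count table", {
  meta <- simulate_metacommunity(100, seed = 3)
  cm <- simulate_neutral_local(meta, 5, N = 500, m = 0.2, seed = 4)
  expect_true(all(colSums(cm) == 500))
  expect_identical(rownames(cm), names(meta))
  expect_identical(cm, simulate_neutral_local(meta, 5, N = 500, m = 0.2, seed = 4))
  expect_error(simulate_neutral_local(meta, 5, N = 5, m = 0.2), "N")
})

test_that("migration rate is recovered from neutral simulations at low m", {
  meta <- simulate_metacommunity(200, seed = 5)
  ms <- vapply(1:5, function(s) {
    cm <- simulate_neutral_local(meta, 30, N = 1000, m = 0.05, seed = s)
    fit_ncm(cm, N = 1000)$m
  }, numeric(1))
  expect_lt(abs(median(ms) / 0.05 - 1), 0.3)
})

test_that("trees and Brownian traits are seeded and carry phylogenetic signal", {
  t1 <- simulate_tree(30, seed = 6)
  t2 <- simulate_tree(30, seed = 6)
  expect_equal(cophenetic_distances(t1), cophenetic_distances(t2))
  expect_identical(ape::Ntip(t1), 30L)

  tr1 <- evolve_trait(t1, rate = 1, seed = 7)
  expect_identical(tr1, evolve_trait(t1, rate = 1, seed = 7))
  # closely related tips have more similar traits: trait distance correlates
  # with cophenetic distance across many replicates
  d <- cophenetic_distances(t1)
  ut <- upper.tri(d)
  cors <- vapply(1:30, function(s) {
    tr <- evolve_trait(t1, rate = 1, seed = 100 + s)
    td <- abs(outer(tr, tr, "-"))[names(tr), names(tr)]
    stats::cor(td[ut], d[names(tr), names(tr)][ut], method = "spearman")
  }, numeric(1))
  expect_gt(mean(cors), 0.2)

  # trait variance scales with Brownian rate x depth
  depth <- mean(ape::node.depth.edgelength(t1)[seq_len(30)])
  vars <- vapply(1:200, function(s) stats::var(evolve_trait(t1, 2, seed = s)),
                 numeric(1))
  expect_equal(mean(vars), 2 * depth, tolerance = 0.35 * 2 * depth)
})

test_that("the environmental filter shapes selected communities as intended", {
  meta <- simulate_metacommunity(100, seed = 8)
  tree <- simulate_tree(100, seed = 9)
  traits <- evolve_trait(tree, seed = 10)
  traits <- (traits - mean(traits)) / stats::sd(traits)

  # sigma_sel = 0 disables the filter: identical to neutral sampling
  a <- simulate_selected_communities(meta, traits, c(0, 0), sigma_sel = 0,
                                     N = 400, seed = 11)
  b <- with(list(), {
    withr::with_seed(11, vapply(1:2, function(i) stats::rmultinom(1, 400, meta)[, 1],
                                numeric(100)))
  })
  expect_equal(unname(a), unname(b))

  # a strong filter at contrasting environments separates communities
  sel <- simulate_selected_communities(meta, traits, c(-1.5, -1.5, 1.5, 1.5),
                                       sigma_sel = 0.3, N = 400, seed = 12)
  bc <- bray_curtis(sel)
  expect_gt(mean(bc[1:2, 3:4]), mean(c(bc[1, 2], bc[3, 4])))

  # stronger filters raise between-environment phylogenetic turnover
  mean_between_bnti <- function(sigma) {
    cmx <- simulate_selected_communities(meta, traits, rep(c(-1.5, 1.5), 4),
                                         sigma_sel = sigma, N = 400, seed = 13)
    bn <- suppressWarnings(beta_nti(cmx, tree, n_null = 99, seed = 14))
    env <- rep(c(-1.5, 1.5), 4)
    between <- env[match(bn$sample_a, colnames(cmx))] !=
      env[match(bn$sample_b, colnames(cmx))]
    mean(bn$beta_nti[between], na.rm = TRUE)
  }
  vals <- vapply(c(2, 0.6, 0.3), mean_between_bnti, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("dispersal-limited patches are dissimilar between and cohesive within", {
  meta <- simulate_metacommunity(150, seed = 15)
  # one patch per sample: founder sets disjoint, Bray-Curtis near 1
  cm <- simulate_dispersal_limited(meta, 6, N = 500, founder_richness = 8,
                                   n_patches = 6, seed = 16)
  bc <- bray_curtis(cm)
  expect_gt(min(bc[upper.tri(bc)]), 0.95)
  expect_identical(cm, simulate_dispersal_limited(meta, 6, N = 500,
                                                  founder_richness = 8,
                                                  n_patches = 6, seed = 16))
  # patched design: within-patch pairs far more similar than between
  cm2 <- simulate_dispersal_limited(meta, 8, N = 500, founder_richness = 10,
                                    n_patches = 4, seed = 17)
  patch <- attr(cm2, "patch")
  bc2 <- bray_curtis(cm2)
  same <- outer(patch, patch, "==")[upper.tri(bc2)]
  expect_lt(mean(bc2[upper.tri(bc2)][same]), mean(bc2[upper.tri(bc2)][!same]))
  expect_error(simulate_dispersal_limited(meta, 8, founder_richness = 1), "founder")
})

test_that("the study-like dataset satisfies its declared structure", {
  ds <- make_study_like_dataset(seed = 3, N = 6000, n_otus_meta = 400, founder_richness = 40)
  expect_true(all(colSums(ds$counts) == 6000))
  expect_true(all(rownames(ds$counts) %in% ds$tree$tip.label))
  expect_identical(ncol(ds$counts), 36L)
  expect_identical(nrow(ds$metadata), 36L)
  expect_equal(sort(unique(ds$metadata$group)),
               c("impacted", "resilient", "resistant"))
  counts_per <- table(ds$metadata$group, ds$metadata$date)
  expect_true(all(counts_per == 6))

  # reproducible
  ds2 <- make_study_like_dataset(seed = 3, N = 6000, n_otus_meta = 400, founder_richness = 40)
  expect_identical(ds$counts, ds2$counts)

  # rare specialists stay below one read per sample everywhere
  sp <- unlist(ds$truth$rare_specialists)
  expect_true(all(ds$counts[sp, ] <= 1))
})
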