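test_that("patristic distances sum branch lengths along paths", {
  d <- cophenetic_distances(small_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(cophenetic_distances(ape::read.tree(text = "(A:0.5,B:0.5);"))["A", "B"], 1)
  st <- star_tree(5, len = 2)
  ds <- cophenetic_distances(st)
  expect_true(all(ds[upper.tri(ds)] == 4))
  expect_error(cophenetic_distances(small_tree(), c("A", "Z")), "Z")
})

test_that("betaMNTD matches hand evaluation, picante, and its invariances", {
  d <- matrix(c(0, 6, 2,
                6, 0, 4,
                2, 4, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # a = {A, B} equal weights, b = {C}: 0.5 * ((2 + 4)/2 + 2) = 2.5
  expect_equal(beta_mntd(c(A = 1, B = 1, C = 0), c(A = 0, B = 0, C = 1), d), 2.5)
  # identical communities share every taxon -> 0
  expect_equal(beta_mntd(c(A = 2, B = 1, C = 0), c(A = 2, B = 1, C = 0), d), 0)
  # uniform abundances: weighted equals unweighted
  expect_equal(beta_mntd(c(A = 3, B = 3, C = 0), c(A = 0, B = 0, C = 3), d,
                         abundance_weighted = TRUE),
               beta_mntd(c(A = 1, B = 1, C = 0), c(A = 0, B = 0, C = 1), d,
                         abundance_weighted = FALSE))
  expect_error(beta_mntd(c(A = 0, B = 0, C = 0), c(A = 1, B = 0, C = 0), d),
               "Empty community")

  # independent implementation: picante::comdistnt on random data
  tree <- simulate_tree(20, seed = 51)
  cm <- random_counts(20, 5, seed = 52)
  rownames(cm) <- tree$tip.label[seq_len(nrow(cm))]
  dd <- cophenetic_distances(tree, rownames(cm))
  pic <- as.matrix(picante::comdistnt(t(cm), dd, abundance.weighted = TRUE))
  for (a in 1:4) for (b in (a + 1):5) {
    expect_equal(beta_mntd(cm[, a], cm[, b], dd), pic[a, b], tolerance = 1e-10)
  }
})

test_that("betaNTI agrees with exhaustive tip-permutation enumeration", {
  tree <- ape::read.tree(text = "((t1:1,t2:2):1.5,(t3:0.5,t4:3):1);")
  cm <- matrix(c(5L, 3L, 0L, 1L,
                 0L, 2L, 6L, 2L), ncol = 2,
               dimnames = list(paste0("t", 1:4), c("S1", "S2")))
  exact <- exact_beta_nti_pair(cm, tree)
  mc <- beta_nti(cm, tree, n_null = 2000, seed = 1, min_otus = 4)
  expect_lt(abs(mc$beta_nti - exact), 0.1)
  # observed bMNTD is permutation-independent bookkeeping
  d <- cophenetic_distances(tree, rownames(cm))
  expect_equal(mc$beta_mntd_obs, beta_mntd(cm[, 1], cm[, 2], d))
})

test_that("betaNTI handles identical communities, degenerate nulls, and rescaling", {
  tree <- simulate_tree(10, seed = 61)
  # identical membership: observed bMNTD is 0 and every shuffle keeps it 0
  # (shared taxa keep nearest-taxon distance 0), so the null degenerates
  cm_same <- matrix(rep(c(3L, 2L, 0L, 1L, 4L, 0L, 2L, 1L, 0L, 5L), 2), ncol = 2,
                    dimnames = list(tree$tip.label, c("S1", "S2")))
  expect_warning(bn <- beta_nti(cm_same, tree, n_null = 199, seed = 2),
                 "degenerate")
  expect_equal(bn$beta_mntd_obs, 0)
  expect_true(is.na(bn$beta_nti))

  # one unshared taxon breaks the degeneracy
  cm_near <- cm_same
  cm_near[3, 2] <- 2L # taxon unique to S2
  bn2 <- beta_nti(cm_near, tree, n_null = 199, seed = 2)
  expect_true(is.finite(bn2$beta_nti))

  # star phylogeny: every shuffle leaves bMNTD unchanged -> sd 0 -> NA + warning
  st <- star_tree(8)
  cm_star <- random_counts(8, 3, seed = 62)
  rownames(cm_star) <- st$tip.label
  expect_warning(bs <- beta_nti(cm_star, st, n_null = 99, seed = 3),
                 "degenerate")
  expect_true(all(is.na(bs$beta_nti)))

  # uniform branch-length rescaling cancels in the standardized effect size
  # (sparse communities so pairs have unshared taxa and finite betaNTI)
  cm <- random_counts(10, 4, seed = 63)
  cm[cm < 4] <- 0L
  cm <- cm[, colSums(cm) > 0, drop = FALSE]
  rownames(cm) <- tree$tip.label
  tree3 <- tree; tree3$edge.length <- tree3$edge.length * 3
  b1 <- beta_nti(cm, tree, n_null = 199, seed = 4)
  b3 <- beta_nti(cm, tree3, n_null = 199, seed = 4)
  expect_true(any(is.finite(b1$beta_nti)))
  expect_equal(b1$beta_nti, b3$beta_nti, tolerance = 1e-9)

  expect_error(beta_nti(random_counts(5, 3, seed = 64), tree, n_null = 99),
               "at least 6")
  expect_error(beta_nti(cm, tree, n_null = 50), "n_null")
})

test_that("Raup-Crick locates observed dissimilarity within its null", {
  # identical communities sit at the bottom of the null distribution
  cm_same <- matrix(rep(c(10L, 5L, 3L, 2L), 3), ncol = 3,
                    dimnames = list(paste0("o", 1:4), paste0("S", 1:3)))
  rc <- rc_bray(cm_same, n_null = 199, seed = 5)
  expect_true(all(rc$rc_bray <= -0.95))

  # disjoint equal-size communities from a shared pool push toward +1
  withr::with_seed(6, {
    S <- 60
    cm <- matrix(0L, S, 2, dimnames = list(paste0("o", 1:S), c("a", "b")))
    cm[1:20, 1] <- stats::rmultinom(1, 500, rep(1, 20))[, 1]
    cm[21:40, 2] <- stats::rmultinom(1, 500, rep(1, 20))[, 1]
  })
  rc2 <- rc_bray(cm, n_null = 199, seed = 7)
  expect_gt(rc2$rc_bray, 0.95)
  expect_equal(rc2$bray_obs, 1)

  # bounded, deterministic under the master seed, order-independent substreams
  cm3 <- random_counts(25, 5, seed = 8)
  r1 <- rc_bray(cm3, n_null = 99, seed = 9)
  r2 <- rc_bray(cm3, n_null = 99, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$rc_bray >= -1 & r1$rc_bray <= 1))
})

test_that("the two-tier process rule reproduces the stated thresholds", {
  got <- partition_processes(c(2.5, 1.0, -1.0, -2.01),
                             c(0.1, 0.97, 0.0, 0.99))
  expect_equal(as.character(got),
               c("heterogeneous_selection", "dispersal_limitation",
                 "undominated", "homogeneous_selection"))
  # boundaries: betaNTI exactly 2 is stochastic; RC exactly 0.95 undominated
  expect_equal(as.character(partition_processes(2, 0.95)), "undominated")
  expect_equal(as.character(partition_processes(-2, -0.95)), "undominated")
  expect_true(is.na(partition_processes(NA, 0.5)))
  expect_true(is.na(partition_processes(1, NA)))
  expect_false(is.na(partition_processes(3, NA))) # selection needs no RC
})

test_that("process fractions aggregate to unity over valid pairs", {
  pairs <- tibble::tibble(
    group = rep(c("g1", "g2"), c(10, 4)),
    process = factor(c(rep("undominated", 10),
                       rep(c("heterogeneous_selection", "dispersal_limitation"),
                           c(1, 3))), levels = process_levels())
  )
  agg <- aggregate_partition(pairs, "group")
  expect_equal(agg$undominated[agg$group == "g1"], 1)
  g2 <- agg[agg$group == "g2", ]
  expect_equal(g2$heterogeneous_selection, 0.25)
  expect_equal(g2$dispersal_limitation, 0.75)
  expect_equal(agg$deterministic_total + agg$stochastic_total, c(1, 1))

  # a group with only undefined pairs reports NA
  na_pairs <- tibble::tibble(group = "g3",
                             process = factor(NA, levels = process_levels()))
  agg3 <- aggregate_partition(na_pairs, "group")
  expect_true(is.na(agg3$undominated))
  expect_identical(agg3$n_pairs, 0L)
})

test_that("assembly_processes joins both null models per pair", {
  tree <- simulate_tree(15, seed = 71)
  cm <- random_counts(15, 5, seed = 72)
  cm[cm < 4] <- 0L # unshared taxa so the null is informative
  cm <- cm[, colSums(cm) > 0, drop = FALSE]
  rownames(cm) <- tree$tip.label[seq_len(nrow(cm))]
  pr <- assembly_processes(cm, tree, n_null = 99, seed = 73)
  expect_identical(nrow(pr), as.integer(choose(ncol(cm), 2)))
  expect_true(all(c("beta_nti", "rc_bray", "process") %in% names(pr)))
  expect_true(any(!is.na(pr$process)))
  pr2 <- assembly_processes(cm, tree, n_null = 99, seed = 73)
  expect_identical(pr, pr2)
})
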