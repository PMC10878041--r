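# Small fixtures built in code.

counts_3x2 <- function() {
  matrix(c(5L, 1L, 0L, 0L, 2L, 7L), nrow = 3,
         dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("S1", "S2")))
}

write_tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# ((A:1,B:1):1,C:2); -> d(A,B)=2, d(A,C)=d(B,C)=4
small_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

star_tree <- function(n = 6, len = 1) {
  tree <- ape::stree(n, type = "star", tip.label = paste0("t", seq_len(n)))
  tree$edge.length <- rep(len, nrow(tree$edge))
  tree
}

random_counts <- function(n_otus, n_samples, seed, lambda = 4) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_otus * n_samples, lambda), n_otus, n_samples,
                dimnames = list(paste0("OTU_", seq_len(n_otus)),
                                paste0("S", seq_len(n_samples))))
    m[, colSums(m) > 0, drop = FALSE]
  })
}

# Exact betaNTI for one sample pair by enumerating every tip permutation.
exact_beta_nti_pair <- function(cm, tree) {
  d <- cophenetic_distances(tree, rownames(cm))
  obs <- beta_mntd(cm[, 1], cm[, 2], d)
  perms <- gtools_permutations(nrow(d))
  nulls <- apply(perms, 1, function(p) {
    dp <- d[p, p, drop = FALSE]
    dimnames(dp) <- dimnames(d)
    beta_mntd(cm[, 1], cm[, 2], dp)
  })
  (obs - mean(nulls)) / sd(nulls)
}

# All permutations of 1..n (n small), base R.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}
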