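test_that("pair counts tally transitions and transversions by hand", {
  pc <- pair_counts("ACGTACGT", "ACGTACAT")  # single G<->A transition
  expect_equal(pc, list(P = 1 / 8, Q = 0, n = 8))
  expect_equal(pair_counts("ACGTACGT", "ACGTACGT"),
               list(P = 0, Q = 0, n = 8))
  expect_equal(pair_counts("ACGT", "TGCA"),  # all four are transversions
               list(P = 0, Q = 1, n = 4))
  # pairwise deletion: only the gapped/ambiguous third column drops
  expect_equal(pair_counts("AC-GT", "ACNGA")$n, 4)
  expect_error(pair_counts("----", "AAAA"), "comparable")
  expect_error(pair_counts("ACG", "ACGT"), "length")
})

test_that("K2P formula matches hand evaluation and flags saturation", {
  expect_equal(k2p_distance(list(P = 0.125, Q = 0)), -0.5 * log(0.75))
  expect_equal(k2p_distance(list(P = 0, Q = 0)), 0)
  expect_equal(k2p_distance(list(P = 0.25, Q = 0.25)),
               -0.5 * log(0.25 * sqrt(0.5)))
  expect_true(is.na(k2p_distance(list(P = 0.5, Q = 0.1))))
  expect_true(is.na(k2p_distance(list(P = 0, Q = 0.5))))
})

test_that("distance matrices are symmetric and match composed oracles", {
  fx <- make_ds(c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT"),
                species = rep("A_a", 3))
  dm <- distance_matrix(fx$ds, "p")
  expect_equal(dm$distances["s1", "s2"], 0.25)
  expect_equal(dm$distances["s1", "s3"], 0.5)
  expect_equal(dm$distances["s2", "s3"], 0.25)
  expect_equal(dm$distances, t(dm$distances))
  expect_equal(diag(dm$distances), setNames(rep(0, 3), dm$ids))
  k <- distance_matrix(fx$ds, "k2p")
  for (i in 1:2) for (j in (i + 1):3) {
    pc <- pair_counts(fx$ds$records$sequence[i], fx$ds$records$sequence[j])
    expect_equal(k$distances[i, j], k2p_distance(pc))
  }
})

test_that("kernel agrees with a brute-force per-site tally on random pairs", {
  set.seed(21)
  for (r in 1:40) {
    a <- random_seq(50); b <- random_seq(50)
    pc <- pair_counts(a, b)
    or <- oracle_pair(a, b)
    expect_equal(pc, or)
    dk <- k2p_distance(pc); dp <- p_distance(pc)
    if (!is.na(dk)) expect_gte(dk, dp)  # Jensen-type inequality
  }
})

test_that("K2P converges to p-distance in the low-divergence limit", {
  for (p in c(1e-4, 5e-5, 1e-5)) {
    d <- k2p_distance(list(P = p / 2, Q = p / 2))
    expect_lt(abs(d - p), 1e-6)
  }
})

test_that("kernel cross-checks against ape::dist.dna", {
  set.seed(5)
  # moderately diverged sequences so K2P stays out of the saturated domain
  base <- strsplit(random_seq(200), "")[[1]]
  seqs <- vapply(1:6, function(i) {
    x <- base
    at <- sample(200, 15)
    x[at] <- sample(c("A", "C", "G", "T"), 15, replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:6)
  fx <- make_ds(seqs, species = rep("A_a", 6))
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  for (mod in c("p", "k2p")) {
    dm <- distance_matrix(fx$ds, mod)
    ref <- as.matrix(ape::dist.dna(bin, model = if (mod == "p") "raw" else "K80",
                                   pairwise.deletion = TRUE))
    expect_equal(unname(dm$distances), unname(ref[dm$ids, dm$ids]),
                 tolerance = 1e-10)
  }
})

test_that("site bootstrap is seeded, degenerate-safe and matches binomial SE", {
  fx <- make_ds(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC"),
                species = rep("A_a", 2))
  bs <- bootstrap_se(fx$ds, "p", replicates = 20, seed = 9)
  expect_equal(unname(bs$se["s1", "s2"]), 0)  # no column variance
  fx2 <- make_ds(c(s1 = random_seq(40), s2 = random_seq(40)),
                 species = rep("A_a", 2))
  b1 <- bootstrap_se(fx2$ds, "k2p", replicates = 50, seed = 4)
  b2 <- bootstrap_se(fx2$ds, "k2p", replicates = 50, seed = 4)
  expect_identical(b1, b2)
  # closed form: p-distance bootstrap SE for 2 sequences is sqrt(p(1-p)/L)
  L <- 20
  a <- paste(rep("A", L), collapse = "")
  b <- paste(c(rep("T", 5), rep("A", L - 5)), collapse = "")
  fx3 <- make_ds(c(s1 = a, s2 = b), species = rep("A_a", 2))
  bs3 <- bootstrap_se(fx3$ds, "p", replicates = 4000, seed = 2)
  expect_equal(unname(bs3$se["s1", "s2"]), sqrt(0.25 * 0.75 / L),
               tolerance = 0.05)
})
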