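test_that("ABGD splits two well-separated clusters at any sensible prior", {
  # points on a line: cluster at ~0 (intra <= .01), cluster at ~.3
  x <- c(0, 0.005, 0.01, 0.30, 0.304, 0.31)
  dm <- dm_from_points(x)
  parts <- abgd_partition(dm, abgd_config(p_min = 0.05, p_max = 0.05,
                                          steps = 1))
  expect_equal(parts[[1]]$n_motus, 2L)
  # brute-force connected components at any threshold inside (0.01, 0.29)
  thr <- 0.1
  comp <- barcodeval:::link_components(dm$distances, thr)
  expect_equal(unname(parts[[1]]$assignment), comp)
})

test_that("ABGD returns one MOTU with no distances or no qualifying gap", {
  dm0 <- make_dm(matrix(0, 4, 4))
  for (p in abgd_partition(dm0)) expect_equal(p$n_motus, 1L)
  # uniform ladder: every interval is below X times the running mean
  dml <- dm_from_points(c(0, 0.05, 0.10, 0.15))
  part <- abgd_partition(dml, abgd_config(p_min = 0.01, p_max = 0.01,
                                          steps = 1))[[1]]
  dsort <- sort(dml$distances[upper.tri(dml$distances)])
  widths <- diff(dsort)
  runmean <- (cumsum(dsort) / seq_along(dsort))[-length(dsort)]
  expect_true(all(widths <= 1.5 * runmean))
  expect_equal(part$n_motus, 1L)
})

test_that("increasing the ABGD prior never increases MOTU counts", {
  set.seed(13)
  for (r in 1:10) {
    dm <- dm_from_points(runif(8, 0, 0.3))
    counts <- vapply(abgd_partition(dm), `[[`, integer(1), "n_motus")
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("partitions cover every sample exactly once with contiguous MOTU ids", {
  set.seed(17)
  dm <- dm_from_points(runif(9, 0, 0.4))
  for (p in c(abgd_partition(dm), asap_partition(dm))) {
    expect_setequal(names(p$assignment), dm$ids)
    expect_equal(sort(unique(unname(p$assignment))), seq_len(p$n_motus))
  }
})

test_that("ASAP ranks the true grouping first on separable clusters", {
  x <- c(0, 0.004, 0.008, 0.30, 0.306, 0.60, 0.609)
  dm <- dm_from_points(x)
  cands <- asap_partition(dm)
  expect_equal(cands[[1]]$n_motus, 3L)
  expect_true(all(diff(vapply(cands, `[[`, numeric(1), "score")) <= 0))
  # 2 samples: exactly one nontrivial candidate
  dm2 <- dm_from_points(c(0, 0.1))
  c2 <- asap_partition(dm2)
  expect_length(c2, 1L)
  expect_equal(c2[[1]]$n_motus, 2L)
  # degenerate all-zero matrix: single flagged candidate
  c0 <- asap_partition(make_dm(matrix(0, 3, 3)))
  expect_length(c0, 1L)
  expect_true(isTRUE(c0[[1]]$degenerate))
})

test_that("ABGD and ASAP agree on the clearly separable two-cluster toy", {
  x <- c(0, 0.005, 0.01, 0.30, 0.304, 0.31)
  dm <- dm_from_points(x)
  ab <- choose_abgd_partition(abgd_partition(dm))
  as1 <- asap_partition(dm)[[1]]
  expect_equal(ab$n_motus, 2L)
  expect_equal(as1$n_motus, 2L)
  expect_true(all(ab$assignment[1:3] == ab$assignment[1]))
  expect_true(all(as1$assignment[4:6] == as1$assignment[4]))
})

test_that("taxonomy concordance uses the exact bidirectional match rule", {
  tax <- data.frame(sample_id = paste0("s", 1:6),
                    species = rep(c("A_a", "A_b", "A_c"), each = 2),
                    genus = "A", family = "F", stringsAsFactors = FALSE)
  perfect <- barcodeval:::new_partition(
    setNames(rep(1:3, each = 2), tax$sample_id), "abgd", 0.01)
  expect_equal(match_partition(perfect, tax)$rate, 100)
  lump <- barcodeval:::new_partition(
    setNames(rep(1L, 6), tax$sample_id), "abgd", 0.01)
  expect_equal(match_partition(lump, tax)$rate, 0)
  split1 <- barcodeval:::new_partition(
    setNames(c(1L, 4L, 2L, 2L, 3L, 3L), tax$sample_id), "abgd", 0.01)
  expect_equal(match_partition(split1, tax)$rate, 66.67)
  # invariant under MOTU relabeling
  relab <- perfect
  relab$assignment <- setNames(c(3L, 3L, 1L, 1L, 2L, 2L), tax$sample_id)
  relab <- barcodeval:::new_partition(relab$assignment, "abgd", 0.01)
  expect_equal(match_partition(relab, tax)$rate, 100)
})

test_that("the modal ABGD partition is chosen with ties toward fewer MOTUs", {
  fake <- function(k, n = 6) barcodeval:::new_partition(
    setNames(rep_len(seq_len(k), n), paste0("s", 1:n)), "abgd", 0.01)
  expect_equal(choose_abgd_partition(list(fake(2), fake(2), fake(2),
                                          fake(5)))$n_motus, 2L)
  expect_equal(choose_abgd_partition(list(fake(2), fake(3)))$n_motus, 2L)
  expect_equal(choose_abgd_partition(list(fake(4)))$n_motus, 4L)
})

test_that("both methods recover the species count on gap-enforced data", {
  hits_ab <- 0; hits_as <- 0; disc <- numeric(0)
  for (s in 1:12) {
    sim <- simulate_sequences(gap_config(seed = 100 + s))
    dm <- distance_matrix(sim$markers$ITS, "p")
    ab <- choose_abgd_partition(abgd_partition(dm))
    as1 <- asap_partition(dm)[[1]]
    hits_ab <- hits_ab + (ab$n_motus == 5L)
    hits_as <- hits_as + (as1$n_motus == 5L)
    disc <- c(disc, match_partition(ab, sim$taxonomy)$rate)
  }
  expect_gte(hits_ab, 11)
  expect_gte(hits_as, 11)
  expect_true(all(disc[vapply(disc, is.finite, TRUE)] >= 0))
})
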