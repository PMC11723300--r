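two_species_fixture <- function() {
  make_ds(c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAT",
            b1 = "TTTTTAAAAA", b2 = "TTTTTAAAAT"),
          species = c("A_a", "A_a", "A_b", "A_b"))
}

test_that("pools partition every applicable pair", {
  fx <- two_species_fixture()
  dm <- distance_matrix(fx$ds, "p")
  pools <- pool_distances(dm, fx$taxonomy, "toy")
  expect_equal(nrow(pools$intra), 2L)  # C(2,2) within each species
  expect_equal(nrow(pools$inter), 4L)  # 2x2 across
  n <- length(dm$ids)
  expect_equal(nrow(pools$intra) + nrow(pools$inter) + pools$n_inapplicable,
               n * (n - 1) / 2)
  # all conspecific -> empty inter pool; singletons give no intra
  fx2 <- make_ds(c(s1 = "AAAA", s2 = "AAAT"), species = rep("A_a", 2))
  p2 <- pool_distances(distance_matrix(fx2$ds, "p"), fx2$taxonomy)
  expect_equal(nrow(p2$inter), 0L)
  fx3 <- make_ds(c(s1 = "AAAA", s2 = "AAAT"), species = c("A_a", "A_b"))
  p3 <- pool_distances(distance_matrix(fx3$ds, "p"), fx3$taxonomy)
  expect_equal(nrow(p3$intra), 0L)
})

test_that("pool summaries report min/max/mean with empty pools flagged", {
  fx <- two_species_fixture()
  pools <- pool_distances(distance_matrix(fx$ds, "p"), fx$taxonomy)
  s <- summarize_pools(pools)
  expect_equal(s$intra_mean, mean(pools$intra$distance))
  expect_equal(s$inter_min, min(pools$inter$distance))
  fx3 <- make_ds(c(s1 = "AAAA", s2 = "AAAT"), species = c("A_a", "A_b"))
  s3 <- summarize_pools(pool_distances(distance_matrix(fx3$ds, "p"),
                                       fx3$taxonomy))
  expect_true(is.na(s3$intra_mean))
  expect_equal(s3$inter_min, s3$inter_max)
  expect_equal(s3$inter_min, s3$inter_mean)
})

test_that("the barcoding gap uses a strict per-species inequality", {
  fx <- two_species_fixture()
  pools <- pool_distances(distance_matrix(fx$ds, "p"), fx$taxonomy)
  gr <- barcode_gap(pools)
  expect_true(all(gr$per_species$gap_present))  # 0.1 intra vs 0.4 inter
  expect_equal(gr$overlap_fraction, 0)
  # boundary: max_intra == min_inter is NOT a gap
  fx2 <- make_ds(c(a1 = "AAAAAAAAAA", a2 = "TAAAAAAAAA",
                   b1 = "ATAAAAAAAA"),
                 species = c("A_a", "A_a", "A_b"))
  gr2 <- barcode_gap(pool_distances(distance_matrix(fx2$ds, "p"),
                                    fx2$taxonomy))
  a_row <- gr2$per_species[gr2$per_species$species == "A_a", ]
  expect_equal(a_row$max_intra, a_row$min_inter)
  expect_false(a_row$gap_present)
  # singleton species flagged, judged on min_inter alone
  b_row <- gr2$per_species[gr2$per_species$species == "A_b", ]
  expect_true(b_row$singleton)
  expect_equal(b_row$max_intra, 0)
  # one species only is an error
  fx4 <- make_ds(c(s1 = "AAAA", s2 = "AAAT"), species = rep("A_a", 2))
  expect_error(barcode_gap(pool_distances(distance_matrix(fx4$ds, "p"),
                                          fx4$taxonomy)), "2 species")
})

test_that("gap verdicts are invariant under species renaming", {
  fx <- two_species_fixture()
  pools <- pool_distances(distance_matrix(fx$ds, "p"), fx$taxonomy)
  gr <- barcode_gap(pools)
  tax2 <- fx$taxonomy
  tax2$species <- chartr("ab", "qz", tax2$species)
  gr2 <- barcode_gap(pool_distances(distance_matrix(fx$ds, "p"), tax2))
  expect_equal(sort(gr2$per_species$gap_present),
               sort(gr$per_species$gap_present))
  expect_equal(gr2$overlap_fraction, gr$overlap_fraction)
})

test_that("histograms bin left-closed right-open and conserve counts", {
  fx <- two_species_fixture()
  pools <- pool_distances(distance_matrix(fx$ds, "p"), fx$taxonomy)
  h <- gap_histogram(pools, bin_width = 0.01)
  expect_equal(sum(h$intra), nrow(pools$intra))
  expect_equal(sum(h$inter), nrow(pools$inter))
  # hand binning: intra {0.005, 0.015} with width 0.01
  p <- pools
  p$intra <- data.frame(species = "A_a", id_a = "x", id_b = "y",
                        distance = c(0.005, 0.015))
  p$inter <- p$inter[0, ]
  h2 <- gap_histogram(p, 0.01)
  expect_equal(h2$intra[1:2], c(1L, 1L))
  p$intra <- p$intra[0, ]
  expect_equal(nrow(gap_histogram(p, 0.01)), 0L)
})

test_that("marker concatenation joins shared samples and recomputes distances", {
  fx1 <- make_ds(c(s1 = "AAAA", s2 = "AATT", s3 = "ATTT"),
                 species = c("A_a", "A_a", "A_b"), marker = "ITS")
  fx2 <- make_ds(c(s2 = "GGGGGG", s3 = "GGGGCC", s4 = "GGCCCC"),
                 species = c("A_a", "A_b", "A_b"), marker = "matK")
  combo <- concatenate_markers(list(fx1$ds, fx2$ds))
  expect_equal(combo$marker, "ITS+matK")
  expect_setequal(combo$records$sample_id, c("s2", "s3"))
  expect_equal(nchar(combo$records$sequence[1]), 10L)
  # distance equals brute-force on the pasted alignment
  dm <- distance_matrix(combo, "p")
  s2 <- combo$records$sequence[combo$records$sample_id == "s2"]
  s3 <- combo$records$sequence[combo$records$sample_id == "s3"]
  expect_equal(unname(dm$distances["s2", "s3"]),
               p_distance(oracle_pair(s2, s3)))
  # disjoint sample sets are an error
  fx5 <- make_ds(c(z9 = "AAAA"), species = "A_z", marker = "rbcL")
  expect_error(concatenate_markers(list(fx1$ds, fx5$ds)), "shared")
})
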