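test_that("judgment matrices are validated as Saaty reciprocal matrices", {
  expect_s3_class(judgment_matrix(matrix(1, 3, 3)), "judgment_matrix")
  expect_error(judgment_matrix(matrix(1, 2, 3)), "square")
  expect_error(judgment_matrix(diag(3)), "positive")  # off-diagonal zeros
  bad <- diag(2); bad[1, 2] <- 3; bad[2, 1] <- 0.5
  expect_error(judgment_matrix(bad), "reciprocal")
  off <- diag(2); off[1, 2] <- 12; off[2, 1] <- 1 / 12
  expect_error(judgment_matrix(off), "Saaty")
})

test_that("consistent matrices recover their generating weights with CR 0", {
  w <- c(0.6, 0.3, 0.1)
  res <- derive_weights(consistent_judgment(w))
  expect_equal(res$weights, w, tolerance = 1e-8)
  expect_equal(res$CR, 0, tolerance = 1e-8)
  expect_equal(res$lambda_max, 3, tolerance = 1e-8)
  ones <- derive_weights(judgment_matrix(matrix(1, 4, 4) + diag(4) * 0))
  expect_equal(ones$weights, rep(0.25, 4), tolerance = 1e-10)
  # scale invariance of the generating weights
  res2 <- derive_weights(consistent_judgment(w * 7))
  expect_equal(res2$weights, w, tolerance = 1e-8)
  # recovery across sizes 3..9
  set.seed(31)
  for (n in 3:9) {
    v <- runif(n, 0.5, 2); v <- v / sum(v)
    r <- derive_weights(consistent_judgment(v))
    expect_lt(max(abs(r$weights - v)), 1e-8)
    expect_lt(r$CR, 1e-8)
  }
})

test_that("eigenvector and geometric-mean weights agree as cross-checks", {
  set.seed(41)
  for (r in 1:20) {
    m <- random_reciprocal(4)
    we <- derive_weights(m)$weights
    wg <- derive_weights(m, "geometric")$weights
    expect_lt(max(abs(we - wg)), 0.02)
  }
})

test_that("composite scores follow the weighted normalized-points sum", {
  sch <- default_criterion_scheme()
  ids <- sch$criteria$id
  expect_length(ids, 13L)
  expect_equal(sum(sch$criteria$weight), 1.0001, tolerance = 1e-9)
  s_max <- composite_score(setNames(sch$p_max, ids), sch)
  expect_equal(s_max, sum(sch$criteria$weight))
  s_min <- composite_score(setNames(rep(1, 13), ids), sch)
  expect_equal(s_min, sum(sch$criteria$weight / sch$p_max))
  expect_equal(s_min, 0.1701, tolerance = 1e-3)
  # single-criterion scheme: w = 1, levels 1..5, p = 3 -> 0.6
  one <- criterion_scheme(
    data.frame(id = "X", label = "only", weight = 1),
    data.frame(criterion = "X", label = paste0("l", 1:5), points = 1:5))
  expect_equal(composite_score(c(X = 3), one), 0.6)
  expect_error(composite_score(setNames(rep(1, 12), ids[-1]), sch), "D1")
  expect_error(composite_score(c(X = 2.5), one), "declared level")
})

test_that("raising any single criterion's points never decreases the score", {
  sch <- default_criterion_scheme()
  ids <- sch$criteria$id
  base <- setNames(rep(1, 13), ids)
  s0 <- composite_score(base, sch)
  for (id in ids) {
    pts <- sort(sch$levels$points[sch$levels$criterion == id])
    for (p in pts[-1]) {
      up <- base; up[id] <- p
      expect_gte(composite_score(up, sch), s0)
    }
  }
})

test_that("class boundaries put 0.60 in class 1 and 0.39 in class 3", {
  expect_equal(classify_score(c(0.65, 0.60, 0.599, 0.40, 0.399, 0.39, 0.28)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 3L))
})

test_that("ranking orders by score with alphabetical ties and tallies classes", {
  cards <- data.frame(species = c("b", "a", "c"),
                      family = c("F1", "F1", "F2"),
                      score = c(0.5, 0.5, 0.7), stringsAsFactors = FALSE)
  rk <- rank_species(cards)
  expect_equal(rk$ranked$species, c("c", "a", "b"))
  expect_equal(unname(rk$class_tally), c(1L, 2L, 0L))
  single <- rank_species(data.frame(species = "x", score = 0.3))
  expect_equal(single$ranked$rank, 1L)
  expect_equal(unname(single$class_tally), c(0L, 0L, 1L))
})

test_that("the published class-1 table reproduces its tallies", {
  t3 <- tianshan_class1()
  expect_equal(nrow(t3), 23L)
  rk <- rank_species(data.frame(species = t3$species, family = t3$family,
                                score = t3$ahp_value))
  expect_true(all(rk$ranked$class == 1L))
  expect_equal(unname(rk$class1_families["Asteraceae"]), 4L)
  expect_equal(max(rk$ranked$score), 0.69)
})
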