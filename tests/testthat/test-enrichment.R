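test_that("two-class tissue degenerates to an undefined score, not infinity", {
  ct <- random_cell_table(21, n = 80, k = 2)
  p <- net_score_pair(ct, "A", "B", radius = 10, permutations = 50, seed = 1)
  expect_true(is.na(p$score))
  expect_identical(p$undefined_reason, "sigma_zero")
  expect_equal(p$null$sigma, 0)
  fit <- net_enrichment(ct, radius = 10, permutations = 50, seed = 1)
  expect_true(all(is.na(fit$scores)))
  expect_true(all(fit$undefined_reason[row(fit$scores) != col(fit$scores)] == "sigma_zero"))
})

test_that("exhaustive enumeration on the 7-cell toy has the hand-checked null", {
  enum <- toy_enumeration(d = 2)
  # 3 of 6 pool positions lie within d of the focal cell: hypergeometric
  expect_equal(enum$mu, 1.5)
  expect_equal(enum$sigma^2, 0.45)
  expect_equal(sort(unique(enum$values)), 0:3)
})

test_that("Monte-Carlo null converges to the exhaustive enumeration", {
  enum <- toy_enumeration(d = 2)
  p <- net_score_pair(toy_table(), "A", "B", radius = 2,
                      permutations = 3000, seed = 5)
  expect_equal(p$observed, 2)  # two of the three B cells within d
  expect_lt(abs(p$null$mu - enum$mu), 0.05)
  expect_lt(abs(p$null$sigma - enum$sigma) / enum$sigma, 0.08)
})

test_that("score reproduces exactly from the stored null summary", {
  ct <- random_cell_table(31, n = 150, k = 3)
  fit <- net_enrichment(ct, radius = 15, permutations = 200, seed = 7,
                        keep_replicates = TRUE)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    reps <- fit$replicates[[i, j]]
    expect_identical(fit$null_mean[i, j], mean(reps))
    expect_identical(fit$null_sd[i, j], sd(reps))
    expect_identical(fit$scores[i, j],
                     (fit$observed[i, j] - mean(reps)) / sd(reps))
  }
})

test_that("results are seed-deterministic and order-invariant", {
  ct <- random_cell_table(41, n = 200, k = 3)
  f1 <- net_enrichment(ct, radius = 12, permutations = 100, seed = 3)
  f2 <- net_enrichment(ct, radius = 12, permutations = 100, seed = 3)
  expect_identical(f1$scores, f2$scores)
  f3 <- net_enrichment(ct, radius = 12, permutations = 100, seed = 4)
  expect_false(identical(f1$scores, f3$scores))
  # shuffled record order: same entries, matched by class name
  set.seed(1)
  shuf <- cell_table(as.data.frame(ct)[sample(nrow(ct)), ])
  f4 <- net_enrichment(shuf, radius = 12, permutations = 100, seed = 3)
  expect_identical(f1$scores[c("A", "B", "C"), c("A", "B", "C")],
                   f4$scores[c("A", "B", "C"), c("A", "B", "C")])
})

test_that("pair-level scores agree with the matrix entries", {
  ct <- random_cell_table(43, n = 150, k = 3)
  fit <- net_enrichment(ct, radius = 10, permutations = 150, seed = 11)
  p <- net_score_pair(ct, "B", "C", radius = 10, permutations = 150, seed = 11)
  expect_identical(p$score, fit$scores["B", "C"])
})

test_that("a pair's stream survives removing an unrelated class", {
  ct3 <- random_cell_table(47, n = 200, k = 3)
  # drop class C: the (A, B) pool changes, but the sub-seed keyed by names
  # must still give the same draws for the same pool
  sub1 <- derive_subseed(9L, "A", "B")
  sub2 <- derive_subseed(9L, "A", "B")
  expect_identical(sub1, sub2)
  expect_false(identical(derive_subseed(9L, "A", "B"), derive_subseed(9L, "B", "A")))
})

test_that("Monte-Carlo scatter shrinks as permutations grow", {
  ct <- random_cell_table(53, n = 120, k = 3)
  scatter <- vapply(c(100, 1000, 10000), function(R) {
    s <- vapply(1:5, function(s)
      net_score_pair(ct, "A", "B", radius = 12, permutations = R,
                     seed = s)$score, 0)
    sd(s)
  }, 0)
  expect_true(scatter[3] < scatter[1])
})

test_that("full shuffle is symmetric, defined on the diagonal, and works at R = 2", {
  ct <- random_cell_table(61, n = 180, k = 3)
  fit <- net_enrichment(ct, radius = 15, permutations = 100, seed = 2,
                        method = "full_shuffle")
  for (p in list(c("A", "B"), c("A", "C"), c("B", "C")))
    expect_equal(fit$scores[p[1], p[2]], fit$scores[p[2], p[1]], tolerance = 1e-10)
  expect_true(all(is.finite(diag(fit$scores))))
  tiny <- net_enrichment(ct, radius = 15, permutations = 2, seed = 8,
                         method = "full_shuffle")
  expect_true(all(is.finite(tiny$null_mean)))
})

test_that("conditional diagonal follows the chosen policy", {
  ct <- generate_tissue(list(place_clustered("A", 120, parents = 6, sd = 10),
                             place_uniform("B", 120)),
                        window = c(500, 500), seed = 3)
  omit <- net_enrichment(ct, radius = 25, permutations = 100, seed = 5)
  expect_true(all(is.na(diag(omit$scores))))
  expect_true(all(diag(omit$undefined_reason) == "diagonal_omitted"))
  full <- net_enrichment(ct, radius = 25, permutations = 200, seed = 5,
                         diagonal = "full_shuffle")
  # clustered class is enriched around itself under a full-shuffle null
  expect_gt(full$scores["A", "A"], 2)
  expect_identical(full$diagonal, "full_shuffle")
})

test_that("population sd divisor rescales the score as expected", {
  ct <- random_cell_table(71, n = 150, k = 3)
  s1 <- net_score_pair(ct, "A", "B", radius = 12, permutations = 100, seed = 1)
  s2 <- net_score_pair(ct, "A", "B", radius = 12, permutations = 100, seed = 1,
                       sd_divisor = "population")
  expect_equal(s2$null$sigma, s1$null$sigma * sqrt(99 / 100))
  expect_equal(s2$score, s1$score / sqrt(99 / 100))
})

test_that("invalid requests are rejected up front", {
  ct <- random_cell_table(1, n = 60, k = 2)
  expect_error(net_score_pair(ct, "A", "A", radius = 5, permutations = 10),
               class = "netenrich_validation_error")
  expect_error(net_score_pair(ct, "A", "Z", radius = 5, permutations = 10),
               class = "netenrich_validation_error")
  expect_error(net_score_pair(ct, "A", "B", radius = 5, permutations = 1),
               class = "netenrich_validation_error")
  expect_error(net_enrichment(ct, radius = 0, permutations = 10),
               class = "netenrich_validation_error")
  one <- cell_table(data.frame(id = c("u", "v"), x = 0:1, y = 0:1,
                               class = c("A", "A")))
  expect_error(net_enrichment(one, radius = 5, permutations = 10),
               class = "netenrich_validation_error")
})
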