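test_that("generators are pure functions of their seed", {
  a <- generate_tissue(list(place_uniform("A", 100)), c(100, 100), seed = 5)
  b <- generate_tissue(list(place_uniform("A", 100)), c(100, 100), seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_tissue(list(place_uniform("A", 100)), c(100, 100), seed = 6)
  expect_false(identical(a$x, c2$x))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_csr_tissue(seed = 2, n_per_class = 10))
  expect_identical(runif(1), before)
})

test_that("placements honor their constraints", {
  ct <- generate_tissue(
    list(place_uniform("A", 80),
         place_attracted("B", 60, to = "A", sd = 0),
         place_inhibited("C", 40, from = "A", radius = 15),
         place_region("D", 30, xmin = 10, xmax = 20, ymin = 30, ymax = 60),
         place_clustered("E", 50, parents = 4, sd = 3)),
    window = c(400, 400), seed = 9)
  expect_identical(unname(c(table(ct$class)[c("A", "B", "C", "D", "E")])),
                   c(80L, 60L, 40L, 30L, 50L))
  A <- ct[ct$class == "A", ]; B <- ct[ct$class == "B", ]
  C <- ct[ct$class == "C", ]; D <- ct[ct$class == "D", ]
  # sd = 0 attraction: every B coincides with some A
  for (i in seq_len(nrow(B)))
    expect_true(min((A$x - B$x[i])^2 + (A$y - B$y[i])^2) == 0)
  # inhibition: brute-force min distance over all A-C pairs
  mind <- Inf
  for (i in seq_len(nrow(C)))
    mind <- min(mind, sqrt((A$x - C$x[i])^2 + (A$y - C$y[i])^2))
  expect_gte(mind, 15)
  expect_true(all(D$x >= 10 & D$x <= 20 & D$y >= 30 & D$y <= 60))
  expect_true(all(ct$x >= 0 & ct$x <= 400 & ct$y >= 0 & ct$y <= 400))
})

test_that("impossible exclusion fails with advice instead of hanging", {
  expect_error(
    generate_tissue(list(place_uniform("A", 40),
                         place_inhibited("B", 5, from = "A", radius = 500)),
                    window = c(100, 100), seed = 1),
    class = "netenrich_generation_error", regexp = "window")
})

test_that("forward references and duplicate labels are rejected", {
  expect_error(
    generate_tissue(list(place_attracted("B", 10, to = "A", sd = 1),
                         place_uniform("A", 10)), c(100, 100), seed = 1),
    class = "netenrich_validation_error")
  expect_error(
    generate_tissue(list(place_uniform("A", 10), place_uniform("A", 10)),
                    c(100, 100), seed = 1),
    class = "netenrich_validation_error")
})

test_that("regular placement respects disc constraints exactly", {
  discs <- data.frame(x = 50, y = 50, r = 20)
  out <- generate_tissue(list(place_regular("T", 60, exclude = discs)),
                         c(100, 100), seed = 3)
  expect_true(all((out$x - 50)^2 + (out$y - 50)^2 > 400))
  inside <- generate_tissue(list(place_regular("T", 40, exclude = discs,
                                               inside = TRUE)),
                            c(100, 100), seed = 3)
  expect_true(all((inside$x - 50)^2 + (inside$y - 50)^2 <= 400))
})

test_that("the structured-tissue scenario has its documented geometry", {
  ct <- generate_asymmetry_scenario(seed = 4)
  expect_identical(class_set(ct), c("Glioma", "TAMM", "Other"))
  expect_identical(unname(c(table(ct$class)[c("Glioma", "TAMM", "Other")])),
                   c(300L, 152L, 600L))
  tamm <- ct[ct$class == "TAMM", ]
  expect_true(all(tamm$x > 500))   # restricted to the right half-window
  # every TAMM inside a vessel disc; no Glioma or Other inside any disc
  vx <- c(640, 860, 640, 860); vy <- c(200, 420, 640, 840)
  in_vessel <- function(x, y)
    Reduce(`|`, lapply(1:4, function(k) (x - vx[k])^2 + (y - vy[k])^2 <= 6400))
  expect_true(all(in_vessel(tamm$x, tamm$y)))
  rest <- ct[ct$class != "TAMM", ]
  expect_false(any(in_vessel(rest$x, rest$y)))
})

test_that("two-core feature tables carry the documented shift", {
  tab <- generate_two_core_features(n_cells = 300, n_features = 3,
                                    shift = c(2, 100), seed = 8)
  expect_identical(nrow(tab), 600L)
  expect_identical(names(tab), c("id", "sample", paste0("feature_", 1:3)))
  expect_identical(unname(c(table(tab$sample))), c(300L, 300L))
  # shifted core lives on a disjoint scale before normalization
  expect_gt(min(tab$feature_1[tab$sample == "core2"]),
            max(tab$feature_1[tab$sample == "core1"]))
  # identity shift with no noise: same distribution family, overlapping range
  same <- generate_two_core_features(n_cells = 300, n_features = 2,
                                     shift = c(1, 0), noise_sd = 0, seed = 8)
  ks <- suppressWarnings(ks.test(same$feature_1[same$sample == "core1"],
                                 same$feature_1[same$sample == "core2"])$statistic)
  expect_lt(ks, 0.2)
  expect_error(generate_two_core_features(shift = c(-1, 0), seed = 1),
               class = "netenrich_validation_error")
})
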