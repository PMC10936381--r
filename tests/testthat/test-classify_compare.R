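test_that("confusion matrix matches hand counts on the 3-cell toy", {
  p <- data.frame(id = c("1", "2", "3"),
                  expected = c("A", "A", "B"), predicted = c("A", "B", "B"))
  cm <- confusion_matrix(p)
  expect_identical(cm$expected_classes, c("A", "B"))
  expect_identical(cm$predicted_classes, c("A", "B"))
  expect_identical(as.vector(cm$counts), c(1L, 0L, 1L, 1L))
  expect_identical(cm$total, 3L)
  ag <- agreement_summary(cm)
  expect_equal(ag$agreement, 2 / 3)
  expect_equal(ag$per_class$recall[ag$per_class$class == "A"], 0.5)
  expect_equal(ag$per_class$precision[ag$per_class$class == "B"], 0.5)
})

test_that("perfect agreement gives a diagonal matrix and unit metrics", {
  set.seed(3)
  lab <- sample(LETTERS[1:4], 100, replace = TRUE)
  p <- data.frame(id = as.character(1:100), expected = lab, predicted = lab)
  cm <- confusion_matrix(p)
  expect_true(all(cm$counts[row(cm$counts) != col(cm$counts)] == 0))
  expect_identical(diag(cm$counts)[cm$expected_classes],
                   c(table(lab)[cm$expected_classes]))
  ag <- agreement_summary(cm)
  expect_equal(ag$agreement, 1)
  expect_true(all(ag$per_class$recall == 1) && all(ag$per_class$precision == 1))
})

test_that("random labels match an independent tally and marginals", {
  p <- make_pairs(7, n = 1000, k = 4, agree = 0.5)
  cm <- confusion_matrix(p)
  oracle <- brute_confusion_tally(p$expected, p$predicted)
  for (r in seq_len(nrow(oracle)))
    expect_identical(cm$counts[oracle$expected[r], oracle$predicted[r]],
                     oracle$n[r])
  expect_identical(sum(cm$counts), 1000L)
  # marginals equal per-class tallies of each labeling independently
  expect_identical(rowSums(cm$counts)[cm$expected_classes],
                   c(table(p$expected)[cm$expected_classes]) + 0)
  expect_identical(colSums(cm$counts)[cm$predicted_classes],
                   c(table(p$predicted)[cm$predicted_classes]) + 0)
})

test_that("element selections partition the cells", {
  p <- make_pairs(11, n = 400, k = 3, agree = 0.6)
  cm <- confusion_matrix(p)
  seen <- character(0)
  for (e in cm$expected_classes) for (q in cm$predicted_classes) {
    sel <- select_cells(p, e, q)
    expect_identical(nrow(sel), unname(cm$counts[e, q] + 0L))
    expect_length(intersect(seen, sel$id), 0L)
    seen <- c(seen, sel$id)
  }
  expect_setequal(seen, p$id)
  # selections preserve input order and carry coordinates
  sel <- select_cells(p, cm$expected_classes[1], cm$predicted_classes[1])
  expect_identical(sel$id, p$id[p$expected == cm$expected_classes[1] &
                                p$predicted == cm$predicted_classes[1]])
  expect_true(all(c("x", "y") %in% names(sel)))
})

test_that("zero elements and unknown classes behave as specified", {
  p <- data.frame(id = c("1", "2"), expected = c("A", "B"),
                  predicted = c("A", "B"))
  expect_identical(nrow(select_cells(p, "A", "B")), 0L)
  expect_error(select_cells(p, "C", "A"), class = "netenrich_validation_error")
})

test_that("one-sided classes yield NA metrics, not zero", {
  p <- data.frame(id = as.character(1:4), expected = c("A", "A", "B", "B"),
                  predicted = c("A", "C", "B", "C"))
  ag <- agreement_summary(confusion_matrix(p))
  pc <- ag$per_class
  expect_true(is.na(pc$recall[pc$class == "C"]))     # C never expected
  expect_true(is.na(pc$precision[pc$class == "C"]))  # no shared diagonal
  expect_equal(ag$agreement, 2 / 4)
})

test_that("degenerate paired inputs are rejected", {
  expect_error(confusion_matrix(data.frame(id = character(),
                                           expected = character(),
                                           predicted = character())),
               class = "netenrich_validation_error")
  dup <- data.frame(id = c("1", "1"), expected = c("A", "B"),
                    predicted = c("A", "B"))
  expect_error(confusion_matrix(dup), class = "netenrich_validation_error")
})
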