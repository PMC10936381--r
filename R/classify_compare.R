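# Confusion-matrix comparison of two classifications over the same cells.
# Matching is by cell id, never by coordinates: both classifications must
# come from the same segmentation so the cells line up one-to-one.

validate_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0L)
    stop_validation("paired classification is empty")
  need <- c("id", "expected", "predicted")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0)
    stop_format("missing required column(s): %s", paste(miss, collapse = ", "))
  pairs$id <- as.character(pairs$id)
  pairs$expected <- trim_ws(as.character(pairs$expected))
  pairs$predicted <- trim_ws(as.character(pairs$predicted))
  if (any(pairs$expected == "") || any(pairs$predicted == ""))
    stop_validation("empty class label in paired classification")
  if (anyDuplicated(pairs$id))
    stop_validation("duplicate cell_id: %s",
                    paste(utils::head(unique(pairs$id[duplicated(pairs$id)]), 10),
                          collapse = ", "))
  if (!"x" %in% names(pairs)) pairs$x <- NA_real_
  if (!"y" %in% names(pairs)) pairs$y <- NA_real_
  pairs
}

#' Confusion matrix between two classifications of the same cells
#'
#' Cross-tabulates an expected labeling (rows) against a predicted labeling
#' (columns) over cells matched by id. Each axis keeps its own label set in
#' first-appearance order, since one method may emit a class the other
#' never uses.
#'
#' @param pairs A data frame with columns `id`, `expected`, `predicted` and
#'   optionally `x`, `y` (see [read_paired_classification()]).
#' @return An object of class `confusion` with `counts` (integer matrix),
#'   `expected_classes`, `predicted_classes` and `total`.
#' @examples
#' p <- data.frame(id = c("1", "2", "3"),
#'                 expected = c("A", "A", "B"), predicted = c("A", "B", "B"))
#' confusion_matrix(p)$counts
#' @export
confusion_matrix <- function(pairs) {
  pairs <- validate_pairs(pairs)
  er <- unique(pairs$expected)
  pr <- unique(pairs$predicted)
  counts <- table(factor(pairs$expected, levels = er),
                  factor(pairs$predicted, levels = pr))
  counts <- matrix(as.integer(counts), nrow = length(er),
                   dimnames = list(expected = er, predicted = pr))
  structure(list(counts = counts, expected_classes = er, predicted_classes = pr,
                 total = nrow(pairs)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix over %d paired cells (rows expected, columns predicted)\n",
              x$total))
  print(x$counts)
  ag <- agreement_summary(x)
  if (!is.na(ag$agreement))
    cat(sprintf("overall agreement: %.3f\n", ag$agreement))
  invisible(x)
}

#' Cells behind one element of the confusion matrix
#'
#' Returns exactly the cells tallied in `counts[expected, predicted]`, in
#' input order, with their coordinates, for display or export to a spatial
#' viewer.
#'
#' @inheritParams confusion_matrix
#' @param expected,predicted Class labels on the respective axes.
#' @return A data frame with columns `id`, `x`, `y`.
#' @export
select_cells <- function(pairs, expected, predicted) {
  pairs <- validate_pairs(pairs)
  if (!expected %in% pairs$expected)
    stop_validation("unknown expected class: '%s'", expected)
  if (!predicted %in% pairs$predicted)
    stop_validation("unknown predicted class: '%s'", predicted)
  sel <- pairs$expected == expected & pairs$predicted == predicted
  out <- pairs[sel, c("id", "x", "y")]
  rownames(out) <- NULL
  out
}

#' Agreement and per-class recall/precision from a confusion matrix
#'
#' Overall agreement is the trace over the shared label set divided by the
#' total cell count. Per-class recall is the diagonal count over the row
#' sum, precision over the column sum. Labels absent from one axis, and
#' zero denominators, yield `NA` rather than 0, so averages are never
#' silently deflated or inflated.
#'
#' @param cm A `confusion` object from [confusion_matrix()].
#' @return A list with `agreement` and `per_class` (data frame of `class`,
#'   `recall`, `precision`).
#' @export
agreement_summary <- function(cm) {
  if (!inherits(cm, "confusion")) stop_validation("not a confusion object")
  shared <- intersect(cm$expected_classes, cm$predicted_classes)
  all_cls <- unique(c(cm$expected_classes, cm$predicted_classes))
  diag_of <- function(cl) if (cl %in% shared) cm$counts[cl, cl] else NA_integer_
  per <- data.frame(class = all_cls, recall = NA_real_, precision = NA_real_)
  for (k in seq_along(all_cls)) {
    cl <- all_cls[k]
    dg <- diag_of(cl)
    if (cl %in% cm$expected_classes) {
      rs <- sum(cm$counts[cl, ])
      per$recall[k] <- if (!is.na(dg) && rs > 0) dg / rs else NA_real_
    }
    if (cl %in% cm$predicted_classes) {
      cs <- sum(cm$counts[, cl])
      per$precision[k] <- if (!is.na(dg) && cs > 0) dg / cs else NA_real_
    }
  }
  agreement <- if (length(shared) > 0)
    sum(vapply(shared, diag_of, 0L)) / cm$total else NA_real_
  list(agreement = agreement, per_class = per)
}
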