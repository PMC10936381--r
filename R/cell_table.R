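#' Cell tables: positions and class labels of cells in one tissue sample
#'
#' A `cell_table` is a validated data frame with columns `id` (unique,
#' character), `x`, `y` (finite planar coordinates in the user's length
#' units), `class` (non-empty cell-type label, whitespace-trimmed,
#' case-sensitive) and optionally `sample`. The attribute `class_set` holds
#' the distinct class labels in first-appearance order; all spatial
#' statistics in the package run over this object.
#'
#' @param df A data frame with at least columns `id`, `x`, `y`, `class`
#'   (an optional `sample` column is kept).
#' @return An object of class `cell_table` (also a `data.frame`).
#' @examples
#' ct <- cell_table(data.frame(
#'   id = c("c1", "c2"), x = c(0, 1), y = c(0, 0),
#'   class = c("Glioma", "TAMM")))
#' class_set(ct)
#' @export
cell_table <- function(df) {
  if (!is.data.frame(df)) stop_validation("cell_table() expects a data.frame")
  need <- c("id", "x", "y", "class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_format("missing required column(s): %s", paste(miss, collapse = ", "))
  keep <- intersect(c("id", "x", "y", "class", "sample"), names(df))
  df <- as.data.frame(df)[keep]
  df$id <- as.character(df$id)
  df$class <- trim_ws(as.character(df$class))
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop_format("columns 'x' and 'y' must be numeric")
  if (nrow(df) > 0 && (anyNA(df$x) || anyNA(df$y) ||
      !all(is.finite(df$x)) || !all(is.finite(df$y))))
    stop_format("non-finite coordinate at row %d",
                which(!is.finite(df$x) | !is.finite(df$y))[1])
  if (nrow(df) > 0 && any(df$class == ""))
    stop_validation("empty class label at row %d (use read_cell_table() to drop such rows)",
                    which(df$class == "")[1])
  if (anyDuplicated(df$id))
    stop_validation("duplicate cell_id: %s",
                    paste(utils::head(unique(df$id[duplicated(df$id)]), 10), collapse = ", "))
  rownames(df) <- NULL
  structure(df,
            class_set = unique(df$class),
            class = c("cell_table", "data.frame"))
}

#' @rdname cell_table
#' @param ct A `cell_table`.
#' @export
class_set <- function(ct) {
  if (!inherits(ct, "cell_table")) stop_validation("not a cell_table")
  attr(ct, "class_set")
}

#' Rows dropped while reading a cell table
#'
#' [read_cell_table()] drops rows whose class label is empty after trimming.
#' This accessor returns the report: a data frame of dropped row numbers and
#' the reason.
#' @param ct A `cell_table` produced by [read_cell_table()].
#' @return A data frame with columns `row` and `reason` (zero rows if
#'   nothing was dropped).
#' @export
dropped_rows <- function(ct) {
  attr(ct, "dropped") %||% data.frame(row = integer(), reason = character())
}

#' @export
print.cell_table <- function(x, ...) {
  cs <- attr(x, "class_set")
  cat(sprintf("cell_table: %d cells, %d class%s\n", nrow(x), length(cs),
              if (length(cs) == 1) "" else "es"))
  if (nrow(x) > 0) {
    tab <- table(factor(x$class, levels = cs))
    cat("  ", paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "), "\n")
    cat(sprintf("  window occupied: x [%.6g, %.6g], y [%.6g, %.6g]\n",
                min(x$x), max(x$x), min(x$y), max(x$y)))
  }
  nd <- nrow(dropped_rows(x))
  if (nd > 0) cat(sprintf("  %d input row%s dropped (see dropped_rows())\n",
                          nd, if (nd == 1) "" else "s"))
  invisible(x)
}
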