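# Plain-CSV readers and writers for every tabular artifact: comma
# separated, UTF-8, header row required, RFC 4180 quoting, "." as the only
# decimal separator. Default column names are "id", "x", "y", "class",
# "sample"; cell-profiler exports with other headers are handled through
# the `columns` override. Class labels are whitespace-trimmed but
# case-sensitive - silent case folding could merge distinct cell types.

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = character(0))
}

# locale-independent numeric parsing: "." decimal separator only
parse_numeric <- function(v, col, allow_na = FALSE) {
  v <- trim_ws(v)
  out <- suppressWarnings(as.numeric(v))
  blank <- v == "" | toupper(v) == "NA"
  if (allow_na) out[blank] <- NA_real_
  bad <- is.na(out) & !(allow_na & blank)
  if (any(bad))
    stop_format("non-numeric value '%s' in column '%s' at data row %d",
                v[which(bad)[1]], col, which(bad)[1])
  out
}

#' Read a cell table from CSV
#'
#' Expects a header row and (by default) columns `id`, `x`, `y`, `class`,
#' optionally `sample`; other layouts are mapped with `columns`. Rows whose
#' class label is empty after whitespace trimming are dropped and counted
#' (see [dropped_rows()]).
#'
#' @param path CSV file path.
#' @param columns Named character vector overriding default column names,
#'   e.g. `c(x = "Centroid X", y = "Centroid Y", class = "Class")`.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, columns = character(0)) {
  map <- c(id = "id", x = "x", y = "y", class = "class", sample = "sample")
  map[names(columns)] <- columns
  df <- read_csv_strict(path)
  for (col in c("id", "x", "y", "class"))
    if (!map[[col]] %in% names(df))
      stop_format("missing required column '%s'", map[[col]])
  out <- data.frame(id = df[[map[["id"]]]],
                    x = parse_numeric(df[[map[["x"]]]], map[["x"]]),
                    y = parse_numeric(df[[map[["y"]]]], map[["y"]]),
                    class = trim_ws(df[[map[["class"]]]]))
  if (map[["sample"]] %in% names(df)) out$sample <- df[[map[["sample"]]]]
  drop <- which(out$class == "")
  if (length(drop) > 0) out <- out[-drop, , drop = FALSE]
  ct <- cell_table(out)
  attr(ct, "dropped") <- data.frame(row = drop,
                                    reason = rep("empty class label", length(drop)))
  ct
}

#' @rdname read_cell_table
#' @param ct A [cell_table()].
#' @export
write_cell_table <- function(ct, path) {
  if (!inherits(ct, "cell_table")) stop_validation("not a cell_table")
  write_csv_atomic(as.data.frame(ct), path)
}

#' Read a per-cell feature table from CSV
#'
#' Expects an id column, a sample/core column and at least one numeric
#' feature column. Empty fields and `NA` become missing values.
#'
#' @param path CSV file path.
#' @param id_col,sample_col Column names (defaults `"id"`, `"sample"`).
#' @return A data frame: `id`, `sample`, then numeric feature columns.
#' @export
read_feature_table <- function(path, id_col = "id", sample_col = "sample") {
  df <- read_csv_strict(path)
  for (col in c(id_col, sample_col))
    if (!col %in% names(df)) stop_format("missing required column '%s'", col)
  fc <- setdiff(names(df), c(id_col, sample_col))
  if (length(fc) == 0L) stop_format("no feature columns found")
  out <- data.frame(id = df[[id_col]], sample = df[[sample_col]])
  for (f in fc) out[[f]] <- parse_numeric(df[[f]], f, allow_na = TRUE)
  out
}

#' @rdname read_feature_table
#' @param features A feature table data frame.
#' @export
write_feature_table <- function(features, path) write_csv_atomic(features, path)

#' Read a paired classification from one or two CSV files
#'
#' One file: columns `id`, `expected`, `predicted` (plus optional `x`,
#' `y`). Two files: each with `id` and a class column (default `class`),
#' joined on `id`; the id sets must match exactly, because the comparison
#' only makes sense over one shared segmentation.
#'
#' @param path CSV with both label columns, or the expected-class CSV.
#' @param path2 Optional predicted-class CSV.
#' @param expected_col,predicted_col Label column names in the one-file
#'   layout.
#' @param class_col Label column name in the two-file layout.
#' @return A data frame with columns `id`, `x`, `y`, `expected`,
#'   `predicted`.
#' @export
read_paired_classification <- function(path, path2 = NULL,
                                       expected_col = "expected",
                                       predicted_col = "predicted",
                                       class_col = "class") {
  df <- read_csv_strict(path)
  if (is.null(path2)) {
    for (col in c("id", expected_col, predicted_col))
      if (!col %in% names(df)) stop_format("missing required column '%s'", col)
    out <- data.frame(id = df$id, expected = df[[expected_col]],
                      predicted = df[[predicted_col]])
    if (all(c("x", "y") %in% names(df))) {
      out$x <- parse_numeric(df$x, "x"); out$y <- parse_numeric(df$y, "y")
    }
    return(validate_pairs(out))
  }
  df2 <- read_csv_strict(path2)
  for (d in list(df, df2))
    for (col in c("id", class_col))
      if (!col %in% names(d)) stop_format("missing required column '%s'", col)
  only1 <- setdiff(df$id, df2$id); only2 <- setdiff(df2$id, df$id)
  if (length(only1) + length(only2) > 0)
    stop_validation("cell ids do not match between the two files (matched segmentation required); offending ids: %s",
                    paste(utils::head(c(only1, only2), 10), collapse = ", "))
  out <- data.frame(id = df$id, expected = df[[class_col]],
                    predicted = df2[[class_col]][match(df$id, df2$id)])
  if (all(c("x", "y") %in% names(df))) {
    out$x <- parse_numeric(df$x, "x"); out$y <- parse_numeric(df$y, "y")
  }
  validate_pairs(out)
}

## ---- square named-matrix dialect ----------------------------------------

# 17 significant digits: doubles round-trip exactly through text
fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

csv_quote <- function(s) {
  need <- grepl('[",\n\r]', s)
  s[need] <- paste0('"', gsub('"', '""', s[need]), '"')
  s
}

write_square_csv <- function(mat, class_rows, class_cols, path, meta = NULL,
                             fmt = fmt_num) {
  lines <- character(0)
  if (!is.null(meta))
    lines <- sprintf("# %s: %s", names(meta), vapply(meta, as.character, ""))
  lines <- c(lines, paste(c("", csv_quote(class_cols)), collapse = ","))
  for (i in seq_along(class_rows))
    lines <- c(lines, paste(c(csv_quote(class_rows[i]), fmt(mat[i, ])), collapse = ","))
  write_lines_atomic(lines, path)
}

#' Write / read an enrichment matrix as CSV
#'
#' The square named-matrix dialect consumed by interaction viewers: comment
#' lines prefixed `#` carrying the provenance (radius, permutations, seed,
#' method), then a header row whose first cell is empty and whose remaining
#' cells are the class names (columns = the re-drawn query type), then one
#' row per focal type beginning with its name. Undefined scores are empty
#' fields. Scores are printed with 17 significant digits, so a read-back
#' reproduces them bit for bit.
#'
#' @param fit A `net_enrichment` object (or the score-carrying object
#'   returned by `read_enrichment_csv()`).
#' @param path Output CSV path.
#' @return `write_enrichment_csv()` returns `path` invisibly;
#'   `read_enrichment_csv()` returns a `net_enrichment`-classed object
#'   carrying `scores`, `classes` and the metadata (but no observed/null
#'   summaries, which the CSV does not store).
#' @export
write_enrichment_csv <- function(fit, path) {
  if (!inherits(fit, "net_enrichment")) stop_validation("not a net_enrichment object")
  meta <- list(radius = fmt_num(fit$radius), permutations = fit$permutations,
               seed = fit$seed, method = fit$method)
  write_square_csv(fit$scores, fit$classes, fit$classes, path, meta = meta)
  invisible(path)
}

#' @rdname write_enrichment_csv
#' @export
read_enrichment_csv <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trim_ws(m[2])]] <- trim_ws(m[3])
  }
  body <- lines[!is_meta]
  if (length(body) < 2L) stop_format("no matrix body in %s", path)
  df <- utils::read.csv(text = body, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  classes <- names(df)[-1]
  if (length(classes) < 1L || nrow(df) != length(classes))
    stop_format("enrichment matrix in %s is not square", path)
  if (!identical(df[[1]], classes))
    stop_format("row names do not match column names in %s", path)
  scores <- matrix(NA_real_, length(classes), length(classes),
                   dimnames = list(focal = classes, query = classes))
  for (j in seq_along(classes))
    scores[, j] <- parse_numeric(df[[j + 1]], classes[j], allow_na = TRUE)
  structure(list(scores = scores, classes = classes,
                 radius = if (!is.null(meta$radius)) as.numeric(meta$radius) else NA_real_,
                 permutations = if (!is.null(meta$permutations)) as.integer(meta$permutations) else NA_integer_,
                 seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_,
                 method = meta$method %||% NA_character_,
                 observed = NULL, null_mean = NULL, null_sd = NULL,
                 n_cells = NA_integer_),
            class = "net_enrichment")
}

#' Write a confusion matrix as CSV
#'
#' Same square layout as [write_enrichment_csv()]: empty first header cell,
#' predicted classes as columns, one row per expected class.
#' @param cm A `confusion` object.
#' @param path Output CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  if (!inherits(cm, "confusion")) stop_validation("not a confusion object")
  write_square_csv(cm$counts, cm$expected_classes, cm$predicted_classes, path,
                   meta = list(total = cm$total),
                   fmt = function(x) as.character(x))
  invisible(path)
}

## ---- atomic writes -------------------------------------------------------

# write to a temp file in the target directory, then rename: a failing run
# never leaves a partial output behind
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: %s", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- tryCatch({
    con <- file(tmp, open = "wb", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    stop_io("cannot write %s", path)
  }
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: %s", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- tryCatch({
    utils::write.csv(df, tmp, row.names = FALSE, quote = which(!vapply(df, is.numeric, TRUE)),
                     na = "", fileEncoding = "UTF-8", eol = "\n")
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    stop_io("cannot write %s", path)
  }
  invisible(path)
}
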