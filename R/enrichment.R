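# The neighborhood enrichment test (NET).
#
# For an ordered pair of cell types (A, B) the observed statistic is the
# average number of B cells within distance d of an A cell. The conditional
# null keeps every A cell where it is and re-draws the n_B positions of B
# uniformly, without replacement, from the positions of ALL non-A cells
# (the original B positions are part of that pool). Re-drawing over real
# cell positions, rather than over the whole window, makes the null share
# the tissue's architecture - dense regions stay dense, empty regions stay
# empty - which is what lets the score ignore structure that both types
# merely inhabit. The score is the z-value
#
#     score = (observed - mu) / sigma
#
# with mu and sigma the mean and standard deviation of the statistic over
# the R randomizations. Positive = attraction, negative = repulsion,
# near zero = mutual randomness. The matrix of all ordered pairs is NOT
# symmetric: each row conditions on a different fixed type.
#
# The full-shuffle null (one label permutation over all positions per
# replicate, reused for every pair) is the conventional alternative; it is
# symmetric by construction and blind to structure-driven asymmetry.

# Conditional null for one ordered pair over raw geometry.
# cc: neighbor count of A around every pool position (computed once per
# focal class); b_in_pool: logical, which pool entries are the B cells.
cond_pair_stats <- function(cc, n_a, b_in_pool, permutations, seed, sd_divisor) {
  n_b <- sum(b_in_pool)
  n_pool <- length(cc)
  if (n_b < 1L) stop_validation("query class has no cells")
  if (n_pool < n_b) stop_validation("randomization pool (%d) smaller than n_B (%d)", n_pool, n_b)
  observed <- sum(cc[b_in_pool]) / n_a
  reps <- with_seed(seed,
    vapply(seq_len(permutations),
           function(r) sum(cc[sample.int(n_pool, n_b)]),
           numeric(1))) / n_a
  summarize_null(observed, reps, seed, sd_divisor)
}

summarize_null <- function(observed, reps, seed, sd_divisor) {
  mu <- mean(reps)
  sigma <- stats::sd(reps)
  if (identical(sd_divisor, "population"))
    sigma <- sigma * sqrt((length(reps) - 1) / length(reps))
  score <- if (is.na(sigma) || sigma == 0) NA_real_ else (observed - mu) / sigma
  list(score = score, observed = observed,
       null = list(replicates = reps, mu = mu, sigma = sigma,
                   permutations = length(reps), seed = seed),
       undefined_reason = if (is.na(score)) "sigma_zero" else NA_character_)
}

#' Neighborhood enrichment score for one ordered pair of cell types
#'
#' Computes the NET z-score for `focal` versus `query` under the
#' conditional permutation null: `focal` cells stay fixed and the `query`
#' positions are re-drawn without replacement from the positions of all
#' non-focal cells. See [net_enrichment()] for the all-pairs matrix.
#'
#' @inheritParams mean_neighbor_count
#' @param permutations Number of randomizations R (default 1000).
#' @param seed Integer seed; if `NULL` one is drawn and recorded.
#' @param sd_divisor `"sample"` (divisor R - 1, default) or `"population"`
#'   (divisor R) for the null standard deviation.
#' @return A list of class `net_pair`: `score` (`NA` when the null is
#'   degenerate, never infinite), `observed`, and `null` with the replicate
#'   values, `mu`, `sigma`, `permutations` and `seed`.
#' @examples
#' ct <- generate_csr_tissue(seed = 1, n_per_class = 50, window = c(300, 300))
#' net_score_pair(ct, "A", "B", radius = 30, permutations = 200, seed = 9)$score
#' @export
net_score_pair <- function(cells, focal, query, radius, permutations = 1000,
                           seed = NULL, sd_divisor = c("sample", "population")) {
  if (!inherits(cells, "cell_table")) stop_validation("'cells' must be a cell_table")
  d <- check_radius(radius)
  sd_divisor <- match.arg(sd_divisor)
  if (!is_count(permutations, min = 2))
    stop_validation("'permutations' must be an integer >= 2")
  if (identical(focal, query))
    stop_validation("focal and query class must differ (the conditional null is undefined for a type against itself)")
  cs <- class_set(cells)
  for (lab in c(focal, query)) if (!lab %in% cs)
    stop_validation("unknown class label: '%s'", lab)
  seed <- check_seed(seed) %||% draw_seed()

  cells <- canonical_order(cells)
  a <- cells$class == focal
  pool <- !a
  n_a <- sum(a)
  if (n_a == 0L) stop_validation("no cells of focal class '%s'", focal)
  cc <- neighbor_counts(cells$x[a], cells$y[a], cells$x[pool], cells$y[pool], d)
  # same name-keyed sub-seed as net_enrichment(), so the pair-level score
  # equals the corresponding matrix entry for the same master seed
  res <- cond_pair_stats(cc, n_a, cells$class[pool] == query,
                         as.integer(permutations),
                         derive_subseed(seed, focal, query), sd_divisor)
  structure(c(list(focal = focal, query = query, radius = d,
                   method = "conditional", seed = seed), res),
            class = "net_pair")
}

#' @export
print.net_pair <- function(x, ...) {
  cat(sprintf("NET score %s -> %s (radius %g, R = %d, conditional null)\n",
              x$focal, x$query, x$radius, x$null$permutations))
  if (is.na(x$score))
    cat(sprintf("  score: undefined (%s)\n", x$undefined_reason))
  else
    cat(sprintf("  score: %.3f  (observed %.4f, null mu %.4f, sigma %.4f)\n",
                x$score, x$observed, x$null$mu, x$null$sigma))
  invisible(x)
}

# Scores are independent of input row order: all permutation streams run
# over cells sorted by id (radix order, locale-independent), and sub-seeds
# are keyed by class names.
canonical_order <- function(cells) {
  ord <- order(cells$id, method = "radix")
  list(id = cells$id[ord], x = cells$x[ord], y = cells$y[ord],
       class = cells$class[ord])
}

# Sparse symmetric 0/1 adjacency of all cells within distance d, diagonal 0.
radius_adjacency <- function(x, y, d, block = 512L) {
  n <- length(x)
  d2 <- d * d
  ii <- list(); jj <- list(); k <- 0L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dd <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    w <- which(dd <= d2, arr.ind = TRUE)
    gi <- idx[w[, 1L]]
    keep <- gi < w[, 2L]          # strict upper triangle: drops self, dedups
    if (any(keep)) {
      k <- k + 1L
      ii[[k]] <- gi[keep]; jj[[k]] <- w[keep, 2L]
    }
  }
  i <- unlist(ii) %||% integer(0); j <- unlist(jj) %||% integer(0)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
}

#' Neighborhood enrichment matrix over all ordered cell-type pairs
#'
#' The central fitting function of the package. For every ordered pair
#' (A, B) of cell types it computes the neighborhood enrichment z-score
#' `(observed - mu) / sigma`, where `observed` is the mean number of B
#' cells within `radius` of an A cell and `mu`, `sigma` summarize the
#' statistic over `permutations` randomizations of the null.
#'
#' Two nulls are available. `method = "conditional"` (the NET proper) keeps
#' the focal type A fixed and re-draws the B positions from the positions
#' of all other cell types; each ordered pair gets its own reproducible
#' sub-seed derived from `seed` and the pair's class indices. The resulting
#' matrix is deliberately not symmetric. `method = "full_shuffle"` permutes
#' all class labels over all positions simultaneously, one permutation per
#' replicate shared by every pair; its z-scores are symmetric for distinct
#' types.
#'
#' Under the conditional null the diagonal (a type against itself) is
#' contradictory - the type cannot be both fixed and re-drawn - so by
#' default it is left undefined. `diagonal = "full_shuffle"` instead fills
#' it by re-drawing the type's positions over all cell positions, and the
#' choice is recorded in the fitted object. Degenerate pairs (null standard
#' deviation zero, e.g. a two-class table under the conditional null) are
#' reported as undefined with a reason, never as infinite, and never abort
#' the rest of the matrix.
#'
#' @inheritParams net_score_pair
#' @param method `"conditional"` (default) or `"full_shuffle"`.
#' @param diagonal Diagonal policy for the conditional method: `"omit"`
#'   (default) or `"full_shuffle"`.
#' @param keep_replicates Keep the per-pair replicate values (list matrix in
#'   `$replicates`) so empirical p-values can be formed; default `FALSE`.
#' @return An object of class `net_enrichment` with components `scores`,
#'   `observed`, `null_mean`, `null_sd` (K x K named matrices; rows = focal
#'   type held fixed, columns = query type re-drawn), `classes`, `radius`,
#'   `permutations`, `seed`, `method`, `diagonal`, `undefined_reason`, and
#'   optionally `replicates`. Methods: `print`, `summary`, `plot`,
#'   `as.matrix`.
#' @examples
#' ct <- generate_csr_tissue(seed = 4, n_per_class = 60, window = c(400, 400))
#' fit <- net_enrichment(ct, radius = 40, permutations = 200, seed = 11)
#' round(as.matrix(fit), 2)
#' @export
net_enrichment <- function(cells, radius, permutations = 1000, seed = NULL,
                           method = c("conditional", "full_shuffle"),
                           diagonal = c("omit", "full_shuffle"),
                           sd_divisor = c("sample", "population"),
                           keep_replicates = FALSE) {
  if (!inherits(cells, "cell_table")) stop_validation("'cells' must be a cell_table")
  d <- check_radius(radius)
  method <- match.arg(method)
  diagonal <- match.arg(diagonal)
  sd_divisor <- match.arg(sd_divisor)
  if (!is_count(permutations, min = 2))
    stop_validation("'permutations' must be an integer >= 2")
  permutations <- as.integer(permutations)
  seed <- check_seed(seed) %||% draw_seed()
  classes <- class_set(cells)
  K <- length(classes)
  if (K < 2L) stop_validation("need at least 2 cell classes, found %d", K)

  empty <- matrix(NA_real_, K, K, dimnames = list(focal = classes, query = classes))
  out <- list(scores = empty, observed = empty, null_mean = empty, null_sd = empty,
              classes = classes, radius = d, permutations = permutations,
              seed = seed, method = method,
              diagonal = if (method == "conditional") diagonal else "computed",
              sd_divisor = sd_divisor,
              undefined_reason = matrix(NA_character_, K, K,
                                        dimnames = list(focal = classes, query = classes)),
              n_cells = nrow(cells),
              class_counts = as.integer(table(factor(cells$class, levels = classes))),
              replicates = if (keep_replicates) empty_rep_list(classes) else NULL,
              call = match.call())

  cells <- canonical_order(cells)
  if (method == "conditional") {
    out <- fit_conditional(out, cells, keep_replicates)
  } else {
    out <- fit_full_shuffle(out, cells, keep_replicates)
  }
  class(out) <- "net_enrichment"
  out
}

empty_rep_list <- function(classes) {
  K <- length(classes)
  m <- vector("list", K * K)
  dim(m) <- c(K, K)
  dimnames(m) <- list(focal = classes, query = classes)
  m
}

fit_conditional <- function(out, cells, keep_replicates) {
  classes <- out$classes
  K <- length(classes)
  need_adj <- identical(out$diagonal, "full_shuffle")
  adj <- if (need_adj) radius_adjacency(cells$x, cells$y, out$radius) else NULL
  n <- length(cells$id)

  for (i in seq_len(K)) {
    a <- cells$class == classes[i]
    n_a <- sum(a)
    pool <- !a
    cc <- neighbor_counts(cells$x[a], cells$y[a], cells$x[pool], cells$y[pool], out$radius)
    pool_class <- cells$class[pool]
    for (j in seq_len(K)) {
      if (i == j) next
      sub <- derive_subseed(out$seed, classes[i], classes[j])
      res <- tryCatch(
        cond_pair_stats(cc, n_a, pool_class == classes[j],
                        out$permutations, sub, out$sd_divisor),
        netenrich_error = function(e) e)
      out <- store_pair(out, i, j, res, keep_replicates)
    }
    # diagonal: undefined by default; optional full-shuffle null for (A, A)
    if (need_adj) {
      sub <- derive_subseed(out$seed, classes[i], classes[i])
      obs <- (sum(cc_self <- neighbor_counts(cells$x[a], cells$y[a],
                                             cells$x[a], cells$y[a], out$radius)) - n_a) / n_a
      reps <- with_seed(sub, vapply(seq_len(out$permutations), function(r) {
        idx <- sample.int(n, n_a)
        sum(adj[idx, idx])
      }, numeric(1))) / n_a
      res <- summarize_null(obs, reps, sub, out$sd_divisor)
      out <- store_pair(out, i, i, res, keep_replicates)
    } else {
      out$undefined_reason[i, i] <- "diagonal_omitted"
    }
  }
  out
}

store_pair <- function(out, i, j, res, keep_replicates) {
  if (inherits(res, "condition")) {
    out$undefined_reason[i, j] <- conditionMessage(res)
    return(out)
  }
  out$scores[i, j] <- res$score
  out$observed[i, j] <- res$observed
  out$null_mean[i, j] <- res$null$mu
  out$null_sd[i, j] <- res$null$sigma
  out$undefined_reason[i, j] <- res$undefined_reason
  if (keep_replicates) out$replicates[[i, j]] <- res$null$replicates
  out
}

fit_full_shuffle <- function(out, cells, keep_replicates) {
  classes <- out$classes
  K <- length(classes)
  n <- length(cells$id)
  adj <- radius_adjacency(cells$x, cells$y, out$radius)
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(cells$class, classes),
                            x = 1, dims = c(n, K))
  n_a <- out$class_counts
  obs_counts <- as.matrix(Matrix::t(Z) %*% adj %*% Z)
  R <- out$permutations
  rep_counts <- with_seed(out$seed, {
    m <- matrix(NA_real_, R, K * K)
    for (r in seq_len(R)) {
      Zp <- Z[sample.int(n), , drop = FALSE]  # one permutation, all pairs
      m[r, ] <- as.vector(as.matrix(Matrix::t(Zp) %*% adj %*% Zp))
    }
    m
  })
  for (i in seq_len(K)) for (j in seq_len(K)) {
    col <- (j - 1L) * K + i
    res <- summarize_null(obs_counts[i, j] / n_a[i], rep_counts[, col] / n_a[i],
                          out$seed, out$sd_divisor)
    out <- store_pair(out, i, j, res, keep_replicates)
  }
  out
}

#' @export
print.net_enrichment <- function(x, digits = 3, ...) {
  cat(sprintf("Neighborhood enrichment (%s null)\n", x$method))
  cat(sprintf("  %d cells, %d classes; radius %g, %d permutations, seed %d\n",
              x$n_cells, length(x$classes), x$radius, x$permutations, x$seed))
  if (identical(x$method, "conditional"))
    cat(sprintf("  diagonal policy: %s\n", x$diagonal))
  cat("  z-scores (rows = focal type kept fixed, columns = type re-drawn):\n")
  print(round(x$scores, digits))
  invisible(x)
}

#' @export
as.matrix.net_enrichment <- function(x, ...) x$scores

#' @export
summary.net_enrichment <- function(object, ...) {
  s <- object$scores
  off <- s[row(s) != col(s)]
  pairs <- which(!is.na(s), arr.ind = TRUE)
  tab <- data.frame(
    focal = object$classes[pairs[, 1]],
    query = object$classes[pairs[, 2]],
    observed = object$observed[pairs],
    null_mean = object$null_mean[pairs],
    null_sd = object$null_sd[pairs],
    score = s[pairs])
  tab <- tab[order(-abs(tab$score)), ]
  rownames(tab) <- NULL
  structure(list(fit = object, pairs = tab,
                 n_undefined = sum(is.na(off)),
                 n_pairs = length(off)),
            class = "summary.net_enrichment")
}

#' @export
print.summary.net_enrichment <- function(x, digits = 3, ...) {
  print(x$fit)
  cat(sprintf("\n%d of %d off-diagonal pairs defined; pairs by |score|:\n",
              x$n_pairs - x$n_undefined, x$n_pairs))
  print(format(x$pairs, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Heatmap of a fitted enrichment matrix
#'
#' Diverging base-graphics heatmap of the z-scores: blue repulsion, red
#' attraction, grey undefined entries.
#' @param x A `net_enrichment` object.
#' @param zlim Symmetric color range; defaults to the largest finite |score|.
#' @param ... Passed to [graphics::image()].
#' @export
plot.net_enrichment <- function(x, zlim = NULL, ...) {
  s <- x$scores
  K <- length(x$classes)
  zmax <- max(abs(s), na.rm = TRUE)
  if (!is.finite(zmax) || zmax == 0) zmax <- 1
  zlim <- zlim %||% c(-zmax, zmax)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(51)
  op <- graphics::par(mar = c(5, 5, 3, 2))
  on.exit(graphics::par(op))
  graphics::image(seq_len(K), seq_len(K), t(s[K:1, , drop = FALSE]),
                  col = pal, zlim = zlim, axes = FALSE, xlab = "query type (re-drawn)",
                  ylab = "focal type (fixed)",
                  main = sprintf("NET z-scores (%s null, d = %g)", x$method, x$radius), ...)
  graphics::axis(1, at = seq_len(K), labels = x$classes, las = 2)
  graphics::axis(2, at = seq_len(K), labels = rev(x$classes), las = 1)
  na_at <- which(is.na(t(s[K:1, , drop = FALSE])), arr.ind = TRUE)
  if (nrow(na_at) > 0)
    graphics::rect(na_at[, 1] - 0.5, na_at[, 2] - 0.5, na_at[, 1] + 0.5,
                   na_at[, 2] + 0.5, col = "grey85", border = NA)
  graphics::box()
  invisible(x)
}
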