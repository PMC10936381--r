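# Radius neighborhoods. The neighborhood of a cell is every other cell at
# Euclidean distance <= d (boundary inclusive). The focal cell never counts
# itself, by identity rather than by coordinates: distinct cells that share
# a position do count each other. No edge correction is applied; the
# permutation null inherits the same window geometry, which is what
# compensates for border losses.

# For each point in (px, py), the number of points in (ax, ay) at squared
# distance <= d^2. Blocked so memory stays O(block * n_a); the arithmetic
# per pair is the same expression a plain double loop evaluates, so results
# are identical to brute force bit for bit.
neighbor_counts <- function(ax, ay, px, py, d, block = 512L) {
  np <- length(px)
  out <- numeric(np)
  if (np == 0L || length(ax) == 0L) return(out)
  d2 <- d * d
  for (start in seq(1L, np, by = block)) {
    idx <- start:min(start + block - 1L, np)
    dd <- outer(px[idx], ax, "-")^2 + outer(py[idx], ay, "-")^2
    out[idx] <- rowSums(dd <= d2)
  }
  out
}

check_radius <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop_validation("'radius' must be a single positive finite number (in the units of x and y)")
  as.numeric(d)
}

#' Mean neighbor count between two cell types
#'
#' The observed statistic of the neighborhood enrichment test: the average
#' number of cells of the query type within distance `radius` of a cell of
#' the focal type. Distances are 2-D Euclidean and the boundary is
#' inclusive (`<= radius`). When focal and query are the same type, a cell
#' never counts itself.
#'
#' @param cells A [cell_table()].
#' @param focal,query Class labels present in `cells`.
#' @param radius Neighborhood radius, in the same length units as the
#'   coordinates. There is no default: the radius is unit-bound and must be
#'   chosen by the user.
#' @return A single number: (1 / n_focal) * total number of (focal, query)
#'   pairs within `radius`.
#' @examples
#' ct <- cell_table(data.frame(id = c("a", "b"), x = c(0, 0), y = c(0, 1),
#'                             class = c("A", "B")))
#' mean_neighbor_count(ct, "A", "B", radius = 1)  # 1: boundary inclusive
#' @export
mean_neighbor_count <- function(cells, focal, query, radius) {
  if (!inherits(cells, "cell_table")) stop_validation("'cells' must be a cell_table")
  d <- check_radius(radius)
  cs <- class_set(cells)
  for (lab in c(focal, query)) if (!lab %in% cs)
    stop_validation("unknown class label: '%s'", lab)
  a <- cells$class == focal
  b <- cells$class == query
  n_a <- sum(a)
  if (n_a == 0L) stop_validation("no cells of focal class '%s'", focal)
  cnt <- sum(neighbor_counts(cells$x[a], cells$y[a], cells$x[b], cells$y[b], d))
  if (identical(focal, query)) cnt <- cnt - n_a  # remove self-matches
  cnt / n_a
}

#' Mean neighbor count over raw coordinate sets
#'
#' The kernel the permutation loop calls with relabeled positions: same
#' statistic as [mean_neighbor_count()] but over plain coordinate vectors.
#' With `same_set = TRUE` the two sets are taken to be the identical,
#' identically ordered set of cells and each point's match with itself is
#' excluded; distinct points at coincident coordinates still count.
#'
#' @param ax,ay Coordinates of the focal points (non-empty).
#' @param bx,by Coordinates of the query points (may be empty).
#' @param radius Neighborhood radius.
#' @param same_set Logical; are the two sets the same cells?
#' @return (1 / length(ax)) * number of cross pairs within `radius`.
#' @export
mean_neighbor_count_at_positions <- function(ax, ay, bx, by, radius, same_set = FALSE) {
  d <- check_radius(radius)
  if (length(ax) == 0L) stop_validation("focal position set is empty")
  if (length(ax) != length(ay) || length(bx) != length(by))
    stop_validation("coordinate vectors must have matching lengths")
  if (!all(is.finite(ax)) || !all(is.finite(ay)) ||
      (length(bx) > 0 && (!all(is.finite(bx)) || !all(is.finite(by)))))
    stop_validation("positions must be finite")
  cnt <- sum(neighbor_counts(ax, ay, bx, by, d))
  if (isTRUE(same_set)) {
    if (length(bx) != length(ax)) stop_validation("same_set = TRUE requires identical sets")
    cnt <- cnt - length(ax)
  }
  cnt / length(ax)
}
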