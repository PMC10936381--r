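# Seeded generators for synthetic tissue maps and two-core feature tables.
# Every generator is a pure function of its arguments including the seed,
# so each analysis stage can be tested end to end without image data.

## ---- placement specifications -------------------------------------------

place_spec <- function(type, label, n, ...) {
  if (!is.character(label) || length(label) != 1L || trim_ws(label) == "")
    stop_validation("placement label must be a non-empty string")
  if (!is_count(n)) stop_validation("n_cells must be a positive integer")
  structure(list(type = type, label = label, n = as.integer(n), ...),
            class = "place_spec")
}

#' Placement specifications for synthetic tissue
#'
#' Building blocks for [generate_tissue()]. Each describes how one cell
#' class is laid out on the window:
#' * `place_uniform()`: homogeneous (complete spatial randomness).
#' * `place_clustered()`: Thomas-style parent/offspring clustering: parents
#'   uniform, each cell an isotropic-normal displacement (`sd`) from a
#'   uniformly chosen parent; displacements falling outside the window are
#'   re-drawn (keeping the parent) so isotropy is preserved near edges.
#' * `place_attracted()`: each cell displaced (isotropic normal, `sd`) from
#'   a uniformly chosen cell of an earlier-placed class.
#' * `place_inhibited()`: uniform rejection sampling until farther than
#'   `radius` from every cell of an earlier-placed class; generation fails
#'   with advice if the exclusion leaves too little room.
#' * `place_region()`: uniform on a sub-rectangle of the window.
#' * `place_regular()`: stratified (jittered-grid) placement with
#'   near-constant density, emulating the packing regularity of real
#'   tissue; optionally excluded from circular structures given as a data
#'   frame `exclude` with columns `x`, `y`, `r` (or confined inside them
#'   with `inside = TRUE`).
#'
#' @param label Class label.
#' @param n Number of cells (exact).
#' @param parents Number of cluster parents.
#' @param sd Isotropic normal displacement standard deviation.
#' @param to,from Label of an earlier-placed class.
#' @param radius Exclusion radius around every `from` cell.
#' @param xmin,xmax,ymin,ymax Sub-rectangle bounds.
#' @param exclude `NULL` or a data frame of discs (`x`, `y`, `r`).
#' @param inside Place inside the discs instead of outside.
#' @return A placement specification for [generate_tissue()].
#' @name placements
NULL

#' @rdname placements
#' @export
place_uniform <- function(label, n) place_spec("uniform", label, n)

#' @rdname placements
#' @export
place_clustered <- function(label, n, parents, sd) {
  if (!is_count(parents)) stop_validation("'parents' must be a positive integer")
  if (!is.numeric(sd) || sd < 0) stop_validation("'sd' must be non-negative")
  place_spec("clustered", label, n, parents = as.integer(parents), sd = sd)
}

#' @rdname placements
#' @export
place_attracted <- function(label, n, to, sd) {
  if (!is.numeric(sd) || sd < 0) stop_validation("'sd' must be non-negative")
  place_spec("attracted", label, n, to = to, sd = sd)
}

#' @rdname placements
#' @export
place_inhibited <- function(label, n, from, radius) {
  if (!is.numeric(radius) || radius <= 0) stop_validation("'radius' must be positive")
  place_spec("inhibited", label, n, from = from, radius = radius)
}

#' @rdname placements
#' @export
place_region <- function(label, n, xmin, xmax, ymin, ymax) {
  if (!(xmin < xmax && ymin < ymax)) stop_validation("degenerate sub-rectangle")
  place_spec("region", label, n, xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
}

#' @rdname placements
#' @export
place_regular <- function(label, n, exclude = NULL, inside = FALSE) {
  if (!is.null(exclude) && !all(c("x", "y", "r") %in% names(exclude)))
    stop_validation("'exclude' needs columns x, y, r")
  place_spec("regular", label, n, exclude = exclude, inside = inside)
}

## ---- samplers ------------------------------------------------------------

MAX_TRIES <- 10000L

in_window <- function(x, y, w) x >= 0 & x <= w[1] & y >= 0 & y <= w[2]

in_discs <- function(x, y, discs) {
  hit <- rep(FALSE, length(x))
  for (k in seq_len(nrow(discs)))
    hit <- hit | ((x - discs$x[k])^2 + (y - discs$y[k])^2 <= discs$r[k]^2)
  hit
}

sample_uniform <- function(n, w) list(x = stats::runif(n, 0, w[1]), y = stats::runif(n, 0, w[2]))

# redraw the normal displacement (keeping the anchor) until inside the window
displaced <- function(anchor_x, anchor_y, sd, w, what) {
  x <- stats::rnorm(length(anchor_x), anchor_x, sd)
  y <- stats::rnorm(length(anchor_y), anchor_y, sd)
  bad <- !in_window(x, y, w)
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > MAX_TRIES)
      stop_generation("%s: could not place cells inside the window after %d rounds",
                      what, MAX_TRIES)
    x[bad] <- stats::rnorm(sum(bad), anchor_x[bad], sd)
    y[bad] <- stats::rnorm(sum(bad), anchor_y[bad], sd)
    bad <- !in_window(x, y, w)
  }
  list(x = x, y = y)
}

sample_clustered <- function(n, parents, sd, w) {
  px <- stats::runif(parents, 0, w[1]); py <- stats::runif(parents, 0, w[2])
  k <- sample.int(parents, n, replace = TRUE)
  displaced(px[k], py[k], sd, w, "place_clustered")
}

sample_attracted <- function(n, ax, ay, sd, w) {
  k <- sample.int(length(ax), n, replace = TRUE)
  displaced(ax[k], ay[k], sd, w, "place_attracted")
}

sample_inhibited <- function(n, fx, fy, radius, w) {
  got_x <- numeric(0); got_y <- numeric(0)
  tries <- 0L
  while (length(got_x) < n) {
    tries <- tries + 1L
    if (tries > MAX_TRIES)
      stop_generation(paste("place_inhibited: rejection sampling exceeded %d rounds;",
                            "use a larger window or a smaller exclusion radius"), MAX_TRIES)
    m <- max(2L * (n - length(got_x)), 64L)
    cx <- stats::runif(m, 0, w[1]); cy <- stats::runif(m, 0, w[2])
    ok <- neighbor_counts(fx, fy, cx, cy, radius) == 0
    got_x <- c(got_x, cx[ok]); got_y <- c(got_y, cy[ok])
  }
  list(x = got_x[seq_len(n)], y = got_y[seq_len(n)])
}

# Stratified jittered grid over the window (or a bounding box), keeping
# points that satisfy the disc constraint, then a uniform subsample to n.
# `alpha` scales the jitter around each cell center: 1 is uniform within
# the cell, smaller values emulate the hard-core regularity of packed
# cells. If the constraint leaves too few points the grid is redrawn
# denser (still seed-deterministic); an unsatisfiable constraint errors.
sample_regular <- function(n, w, exclude = NULL, inside = FALSE, bbox = NULL,
                           over = NULL, alpha = 1) {
  bb <- bbox %||% (if (inside && !is.null(exclude))
    c(min(exclude$x - exclude$r), max(exclude$x + exclude$r),
      min(exclude$y - exclude$r), max(exclude$y + exclude$r))
    else c(0, w[1], 0, w[2]))
  over <- over %||% (if (inside) 2.2 else 1.4)
  for (attempt in 1:8) {
    m <- ceiling(sqrt(over * n))
    cw <- (bb[2] - bb[1]) / m; ch <- (bb[4] - bb[3]) / m
    cx <- bb[1] + (rep(seq_len(m) - 1L, m) + 0.5) * cw
    cy <- bb[3] + (rep(seq_len(m) - 1L, each = m) + 0.5) * ch
    x <- cx + alpha * (stats::runif(m * m) - 0.5) * cw
    y <- cy + alpha * (stats::runif(m * m) - 0.5) * ch
    ok <- in_window(x, y, w)
    if (!is.null(exclude)) {
      hit <- in_discs(x, y, exclude)
      ok <- ok & (if (inside) hit else !hit)
    }
    keep <- which(ok)
    if (length(keep) >= n) {
      sel <- sort(sample(keep, n))
      return(list(x = x[sel], y = y[sel]))
    }
    over <- over * 1.5
  }
  stop_generation("place_regular: constraint leaves %d of %d points needed",
                  length(keep), n)
}

# Deterministic sunflower (Fibonacci) layout filling a disc with n points,
# plus a random global rotation and a small positional jitter re-drawn
# until inside the disc: a dense, regularly packed cell infiltrate.
sample_sunflower_disc <- function(n, cx, cy, r, jitter_sd = 3, margin = 0.96) {
  i <- seq_len(n)
  rad <- r * margin * sqrt((i - 0.5) / n)
  th <- i * 2.399963229728653 + stats::runif(1, 0, 2 * pi)
  x0 <- cx + rad * cos(th); y0 <- cy + rad * sin(th)
  x <- x0 + stats::rnorm(n, 0, jitter_sd)
  y <- y0 + stats::rnorm(n, 0, jitter_sd)
  bad <- (x - cx)^2 + (y - cy)^2 > r^2
  while (any(bad)) {
    x[bad] <- x0[bad] + stats::rnorm(sum(bad), 0, jitter_sd)
    y[bad] <- y0[bad] + stats::rnorm(sum(bad), 0, jitter_sd)
    bad <- (x - cx)^2 + (y - cy)^2 > r^2
  }
  list(x = x, y = y)
}

## ---- tissue generation ---------------------------------------------------

#' Generate a synthetic tissue cell map
#'
#' Places each class in order according to its placement specification (see
#' [placements]) on a rectangular window `[0, width] x [0, height]`.
#' Placements may reference only earlier-placed classes. Exact cell counts
#' are honored and the result is fully determined by `seed`.
#'
#' @param classes A list of placement specifications.
#' @param window `c(width, height)` in length units.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [cell_table()] with ids `<label>_<k>`.
#' @examples
#' ct <- generate_tissue(list(place_uniform("A", 100),
#'                            place_attracted("B", 50, to = "A", sd = 5)),
#'                       window = c(500, 500), seed = 1)
#' table(ct$class)
#' @export
generate_tissue <- function(classes, window = c(1000, 1000), seed = NULL) {
  if (!is.list(classes) || length(classes) == 0L ||
      !all(vapply(classes, inherits, TRUE, "place_spec")))
    stop_validation("'classes' must be a non-empty list of placement specifications")
  w <- as.numeric(window)
  if (length(w) != 2L || any(!is.finite(w)) || any(w <= 0))
    stop_validation("'window' must be c(width, height), both positive")
  labels <- vapply(classes, `[[`, "", "label")
  if (anyDuplicated(labels)) stop_validation("duplicate class labels in scenario")
  seed <- check_seed(seed)

  with_seed(seed, {
    placed <- list()
    rows <- vector("list", length(classes))
    for (k in seq_along(classes)) {
      sp <- classes[[k]]
      pts <- switch(sp$type,
        uniform = sample_uniform(sp$n, w),
        clustered = sample_clustered(sp$n, sp$parents, sp$sd, w),
        attracted = {
          if (!sp$to %in% names(placed))
            stop_validation("place_attracted('%s'): class '%s' not placed yet", sp$label, sp$to)
          ref <- placed[[sp$to]]
          sample_attracted(sp$n, ref$x, ref$y, sp$sd, w)
        },
        inhibited = {
          if (!sp$from %in% names(placed))
            stop_validation("place_inhibited('%s'): class '%s' not placed yet", sp$label, sp$from)
          ref <- placed[[sp$from]]
          sample_inhibited(sp$n, ref$x, ref$y, sp$radius, w)
        },
        region = {
          if (sp$xmin < 0 || sp$xmax > w[1] || sp$ymin < 0 || sp$ymax > w[2])
            stop_validation("place_region('%s'): sub-rectangle outside the window", sp$label)
          list(x = stats::runif(sp$n, sp$xmin, sp$xmax),
               y = stats::runif(sp$n, sp$ymin, sp$ymax))
        },
        regular = sample_regular(sp$n, w, sp$exclude, sp$inside),
        stop_validation("unknown placement type '%s'", sp$type))
      placed[[sp$label]] <- pts
      rows[[k]] <- data.frame(id = sprintf("%s_%d", sp$label, seq_len(sp$n)),
                              x = pts$x, y = pts$y, class = sp$label)
    }
    cell_table(do.call(rbind, rows))
  })
}

#' Canned complete-spatial-randomness tissue
#'
#' All classes uniform and independent on the window: the calibration
#' baseline under which enrichment scores should center on zero.
#'
#' @param seed Integer seed.
#' @param n_per_class Cells per class (default 200).
#' @param classes Class labels (default `A`, `B`, `C`).
#' @param window `c(width, height)`, default 1000 x 1000.
#' @return A [cell_table()].
#' @export
generate_csr_tissue <- function(seed = NULL, n_per_class = 200,
                                classes = c("A", "B", "C"),
                                window = c(1000, 1000)) {
  generate_tissue(lapply(classes, place_uniform, n = n_per_class),
                  window = window, seed = seed)
}

# Frozen geometry of the structured-tissue scenario: four vessel-like discs
# in the right half of a 1000 x 1000 window.
asymmetry_vessels <- function() {
  data.frame(x = c(640, 860, 640, 860), y = c(200, 420, 640, 840), r = 80)
}

#' Canned structured-tissue scenario with one-way repulsion
#'
#' A three-class tissue built to show why the conditional null matters.
#' Four fixed vessel-like discs (radius 80) sit in the right half of a
#' 1000 x 1000 window. "TAMM" (152 cells, 38 per vessel) pack each disc as
#' a dense regular infiltrate (sunflower layout with a small positional
#' jitter). The extravascular tissue is a jittered lattice of 900 cells
#' with hard-core-like packing, finely interleaved between "Glioma" (300,
#' every third lattice cell) and "Other" (600): the local composition of
#' the tissue outside the vessels is everywhere one third tumor, two
#' thirds other cells, so - seen from a TAMM cell - Glioma occupy exactly
#' a typical share of the surrounding non-TAMM cells, while TAMM sit where
#' Glioma cannot be.
#'
#' With a neighborhood radius comparable to the vessel size (the package's
#' analyses of this scenario use d = 100) the conditionally randomized
#' matrix shows `score[Glioma, TAMM]` strongly negative (re-drawing TAMM
#' over non-Glioma positions spreads them through Glioma-rich tissue, so
#' the observed neighborhood count falls far below the null) while
#' `score[TAMM, Glioma]` stays near zero. The full-shuffle null, symmetric
#' by construction, cannot express this asymmetry.
#'
#' @param seed Integer seed.
#' @return A [cell_table()] with class set `Glioma`, `TAMM`, `Other`; all
#'   TAMM cells lie in the right half-window (x > 500).
#' @export
generate_asymmetry_scenario <- function(seed = NULL) {
  vessels <- asymmetry_vessels()
  seed <- check_seed(seed)
  with_seed(seed, {
    tx <- ty <- numeric(0)
    for (v in seq_len(nrow(vessels))) {
      pts <- sample_sunflower_disc(38L, vessels$x[v], vessels$y[v], vessels$r[v])
      tx <- c(tx, pts$x); ty <- c(ty, pts$y)
    }
    tissue <- sample_regular(900L, c(1000, 1000), exclude = vessels,
                             over = 1.05, alpha = 0.5)
    is_g <- seq_len(900L) %% 3L == 1L   # every third lattice cell is tumor
    cell_table(rbind(
      data.frame(id = sprintf("Glioma_%d", 1:300),
                 x = tissue$x[is_g], y = tissue$y[is_g], class = "Glioma"),
      data.frame(id = sprintf("TAMM_%d", seq_along(tx)),
                 x = tx, y = ty, class = "TAMM"),
      data.frame(id = sprintf("Other_%d", 1:600),
                 x = tissue$x[!is_g], y = tissue$y[!is_g], class = "Other")))
  })
}

#' Canned attraction and repulsion scenarios
#'
#' `generate_attraction_scenario()`: "B" cells displaced from uniformly
#' chosen "A" cells by an isotropic normal with sd = `radius / 5`, plus an
#' unrelated uniform class "C" (the randomization pool filler); the
#' conditional score A -> B is strongly positive.
#' `generate_repulsion_scenario()`: "B" cells kept at least `2 * radius`
#' from every "A" cell by rejection sampling (A is sparse enough to leave
#' room), plus uniform "C"; the observed A -> B neighborhood count is
#' exactly zero and the score strongly negative.
#'
#' @param seed Integer seed.
#' @param radius The analysis radius d the scenario is built around
#'   (default 50; the generator only uses it to scale the displacement or
#'   exclusion distance).
#' @return A [cell_table()] on a 1000 x 1000 window.
#' @export
generate_attraction_scenario <- function(seed = NULL, radius = 50) {
  generate_tissue(list(place_uniform("A", 200),
                       place_attracted("B", 150, to = "A", sd = radius / 5),
                       place_uniform("C", 200)),
                  window = c(1000, 1000), seed = seed)
}

#' @rdname generate_attraction_scenario
#' @export
generate_repulsion_scenario <- function(seed = NULL, radius = 50) {
  generate_tissue(list(place_uniform("A", 80),
                       place_inhibited("B", 120, from = "A", radius = 2 * radius),
                       place_uniform("C", 200)),
                  window = c(1000, 1000), seed = seed)
}

#' Two-core feature table with an affine intensity shift
#'
#' Emulates per-cell intensity features extracted from two tissue cores
#' whose staining differs strongly. Each feature of core 1 is drawn from a
#' two-component normal mixture (a dim and a bright cell population; the
#' component means rise slowly with the feature index). Core 2 values are
#' fresh draws from the same mixture transformed by `a * x + b` plus
#' independent Gaussian noise - the affine shift that per-sample
#' Winsorization removes.
#'
#' @param n_cells Cells per core (default 1000).
#' @param n_features Number of feature columns (default 4).
#' @param shift `c(a, b)` with `a > 0`: the affine map applied to core 2.
#' @param noise_sd Standard deviation of the independent noise added to
#'   core 2 (on the shifted scale; default 0.05).
#' @param seed Integer seed.
#' @return A data frame with columns `id`, `sample` (`core1` / `core2`)
#'   and `feature_1 ... feature_n`; `2 * n_cells` rows.
#' @export
generate_two_core_features <- function(n_cells = 1000, n_features = 4,
                                       shift = c(2, 100), noise_sd = 0.05,
                                       seed = NULL) {
  if (!is_count(n_cells) || !is_count(n_features))
    stop_validation("'n_cells' and 'n_features' must be positive integers")
  if (length(shift) != 2L || !is.numeric(shift) || shift[1] <= 0)
    stop_validation("'shift' must be c(a, b) with a > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_validation("'noise_sd' must be >= 0")
  seed <- check_seed(seed)
  with_seed(seed, {
    draw_core <- function(n) {
      vapply(seq_len(n_features), function(f) {
        bright <- stats::runif(n) < 0.45
        m <- ifelse(bright, 0.6 + 0.05 * (f - 1), 0.15 + 0.02 * (f - 1))
        s <- ifelse(bright, 0.12, 0.05)
        stats::rnorm(n, m, s)
      }, numeric(n))
    }
    c1 <- draw_core(n_cells)
    c2 <- shift[1] * draw_core(n_cells) + shift[2] +
      matrix(stats::rnorm(n_cells * n_features, 0, noise_sd), n_cells, n_features)
    out <- data.frame(
      id = c(sprintf("core1_%d", seq_len(n_cells)), sprintf("core2_%d", seq_len(n_cells))),
      sample = rep(c("core1", "core2"), each = n_cells))
    feats <- rbind(c1, c2)
    colnames(feats) <- sprintf("feature_%d", seq_len(n_features))
    cbind(out, as.data.frame(feats))
  })
}
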