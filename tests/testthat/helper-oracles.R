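# Independent oracles kept deliberately naive: plain loops and
# enumeration, no reuse of package internals.

# O(n^2) brute force: loop over focal cells, self-exclusion by identity
brute_mean_neighbor_count <- function(cells, focal, query, d) {
  a <- which(cells$class == focal)
  b <- which(cells$class == query)
  total <- 0
  for (i in a) {
    dx <- cells$x[b] - cells$x[i]
    dy <- cells$y[b] - cells$y[i]
    total <- total + sum(dx * dx + dy * dy <= d * d & b != i)
  }
  total / length(a)
}

brute_count_positions <- function(ax, ay, bx, by, d, same_set = FALSE) {
  total <- 0
  for (i in seq_along(ax)) {
    dx <- bx - ax[i]
    dy <- by - ay[i]
    hit <- dx * dx + dy * dy <= d * d
    if (same_set) hit[i] <- FALSE
    total <- total + sum(hit)
  }
  total / length(ax)
}

random_cell_table <- function(seed, n = 200, k = 3, window = 100) {
  set.seed(seed)
  cell_table(data.frame(
    id = sprintf("c%04d", seq_len(n)),
    x = runif(n, 0, window), y = runif(n, 0, window),
    class = sample(LETTERS[seq_len(k)], n, replace = TRUE)))
}

# The 7-cell toy for the conditional null: one focal A at the origin and
# six non-A cells (3 B, 3 C), three of them within d = 2 of A. The exact
# null distribution enumerates all choose(6, 3) = 20 position subsets.
toy_table <- function() {
  cell_table(data.frame(
    id = sprintf("t%d", 1:7),
    x = c(0, 1, 0, 5, -1, 4, 6),
    y = c(0, 0, 1, 5, 0, 4, 6),
    class = c("A", "B", "B", "B", "C", "C", "C")))
}

# exhaustive null for the toy: mean neighbor count of each 3-subset of the
# six non-A positions around the single A, population mean and sd
toy_enumeration <- function(d = 2) {
  ct <- toy_table()
  pool <- which(ct$class != "A")
  ax <- ct$x[ct$class == "A"]; ay <- ct$y[ct$class == "A"]
  subsets <- utils::combn(pool, 3)
  vals <- apply(subsets, 2, function(idx) {
    sum((ct$x[idx] - ax)^2 + (ct$y[idx] - ay)^2 <= d * d)
  })
  list(values = vals, mu = mean(vals),
       sigma = sqrt(mean((vals - mean(vals))^2)))
}

# independent confusion tally by string pasting and sorting
brute_confusion_tally <- function(expected, predicted) {
  key <- paste(expected, predicted, sep = "\r")
  tab <- table(key)
  out <- data.frame(do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE)))
  names(out) <- c("expected", "predicted")
  out$n <- as.integer(tab)
  out[order(out$expected, out$predicted), ]
}

make_pairs <- function(seed, n = 100, k = 3, agree = 0.7) {
  set.seed(seed)
  expected <- sample(LETTERS[seq_len(k)], n, replace = TRUE)
  predicted <- ifelse(runif(n) < agree, expected,
                      sample(LETTERS[seq_len(k)], n, replace = TRUE))
  data.frame(id = sprintf("p%05d", seq_len(n)),
             x = runif(n, 0, 100), y = runif(n, 0, 100),
             expected = expected, predicted = predicted)
}
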