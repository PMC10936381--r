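`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' package functions never clobber the global random stream. A `NULL` seed
#' evaluates `code` against the current stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Content-addressed sub-seed for the ordered class pair (focal, query)
# under a master seed: keyed by the class NAMES, not their positions, so a
# pair's random stream survives re-ordered input rows and added or removed
# other classes. Kept below 2^31 - 1.
str_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  h
}

derive_subseed <- function(seed, focal, query = "") {
  m <- 2147483647
  s <- as.double(seed) %% m
  h <- str_hash(paste(focal, query, sep = "\x1f"))
  as.integer((s * 69069 + h) %% (m - 1)) + 1L
}

# seed must be a single finite integer-valued number
check_seed <- function(seed) {
  if (is.null(seed)) return(NULL)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop_validation("'seed' must be a single integer")
  as.integer(seed %% 2147483647)
}

# Draw a reportable master seed when the user supplied none.
draw_seed <- function() sample.int(2147483646L, 1L)

trim_ws <- function(x) gsub("^[ \t\r\n]+|[ \t\r\n]+$", "", x)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
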