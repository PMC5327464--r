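#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so generators are
#' reproducible without disturbing the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Centered moving average
#'
#' Rolling mean with a centered window, edge windows shrink symmetrically.
#' Implemented with cumulative sums so it is O(n) on 10 kHz traces.
#'
#' @param x Numeric vector.
#' @param width Window length in samples (coerced to an odd integer).
#' @return Numeric vector, same length as `x`.
#' @keywords internal
rolling_mean <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || n < 2L) return(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Analytic signal via the frequency-domain construction; used for
# band-power envelopes (no Hilbert transform in the imported packages).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' @param x Numeric vector.
#' @return The G1 skewness estimate (`e1071` type 2).
#' @export
sample_skewness <- function(x) {
  e1071::skewness(x, type = 2)
}

# Runs of TRUE in a logical vector as (start, end) sample indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Local maxima with a minimum separation (in samples) and a minimum
# prominence relative to the lower of the two flanking troughs.
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  core <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(core)) return(integer(0))
  # enforce separation greedily, highest peaks first
  ord <- core[order(x[core], decreasing = TRUE)]
  taken <- integer(0)
  for (p in ord) {
    if (!length(taken) || all(abs(taken - p) >= min_distance)) {
      taken <- c(taken, p)
    }
  }
  taken <- sort(taken)
  if (min_prominence > 0 && length(taken)) {
    keep <- logical(length(taken))
    bounds <- c(1L, taken, n)
    for (k in seq_along(taken)) {
      left <- min(x[bounds[k]:taken[k]])
      right <- min(x[taken[k]:bounds[k + 2L]])
      keep[k] <- (x[taken[k]] - max(left, right)) >= min_prominence
    }
    taken <- taken[keep]
  }
  taken
}

# Down-sample a full-rate vector to frame times by block averaging;
# labels (factors/characters) are down-sampled by block majority.
block_downsample <- function(x, n_blocks) {
  n <- length(x)
  idx <- ceiling(seq_len(n) / (n / n_blocks))
  idx[idx > n_blocks] <- n_blocks
  if (is.numeric(x)) {
    as.numeric(tapply(x, idx, mean))
  } else {
    xx <- as.character(x)
    as.character(tapply(xx, idx, function(v) names(which.max(table(v)))))
  }
}
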