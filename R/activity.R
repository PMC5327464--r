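#' Adaptive skewness-zero activity threshold
#'
#' Iteratively withdraws the highest data point and recomputes the
#' sample skewness (adjusted Fisher-Pearson); the loop stops at the
#' first iteration where skewness is null (<= 0). The threshold is the
#' standard deviation of the surviving data, which estimates the noise
#' sigma of a positively contaminated sample. Values above the
#' threshold are labelled "on". If skewness never crosses zero before
#' half the points are removed, the routine falls back to
#' median + 2 MAD with a warning.
#'
#' @param values Numeric vector (>= 50 samples).
#' @return List: `threshold`, `on` (logical per value), `n_removed`,
#'   `fallback` (TRUE when the MAD fallback was used).
#' @export
adaptive_threshold <- function(values) {
  x <- values[is.finite(values)]
  n0 <- length(x)
  if (n0 < 50L) stop("need at least 50 samples")
  xs <- sort(x)                     # remove from the top, O(1) updates
  s1 <- sum(xs); s2 <- sum(xs^2); s3 <- sum(xs^3)
  n <- n0
  skew_g1 <- function(n, s1, s2, s3) {
    m <- s1 / n
    m2 <- s2 / n - m^2
    m3 <- s3 / n - 3 * m * s2 / n + 2 * m^3
    if (m2 <= 0) return(0)
    g1 <- m3 / m2^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  removed <- 0L
  repeat {
    if (skew_g1(n, s1, s2, s3) <= 0) break
    if (removed >= n0 %/% 2L) {
      warning("skewness never crossed zero; falling back to median + 2 MAD")
      thr <- stats::median(x) + 2 * stats::mad(x)
      return(list(threshold = thr, on = values > thr,
                  n_removed = removed, fallback = TRUE))
    }
    top <- xs[n]
    s1 <- s1 - top; s2 <- s2 - top^2; s3 <- s3 - top^3
    n <- n - 1L
    removed <- removed + 1L
  }
  kept <- xs[seq_len(n)]
  thr <- stats::sd(kept)
  list(threshold = thr, on = values > thr,
       n_removed = removed, fallback = FALSE)
}

#' Detect calcium transients in a delta-F/F trace
#'
#' Candidate onsets are rising crossings of the first derivative above
#' its mean + 2 SD (computed on a lightly smoothed trace). Each
#' candidate event runs from its onset to the return below half of the
#' peak amplitude. Events are accepted only on traces whose overall
#' skewness exceeds 1 (a positively skewed trace is the signature of
#' genuine transients; symmetric signals and pure noise are rejected),
#' and each event's peak must exceed the trace median + 2 robust SDs
#' (1.4826 MAD).
#'
#' @param trace Numeric delta-F/F trace.
#' @param frame_rate Frames per second.
#' @param smooth_frames Moving-average width applied before
#'   differentiation. Default 3.
#' @param deriv_sd Derivative threshold in SDs. Default 2.
#' @param trace_skew_min Minimum trace skewness. Default 1.
#' @param min_len Minimum event length, frames. Default 2.
#' @return A `transient_set` list: `onset_times` (s), `peak_times`,
#'   `amplitudes` (delta-F/F at peak minus event baseline),
#'   `rise_times_ms`, `rate_hz`, `n`, `threshold` (the derivative
#'   threshold used), `trace_skewness`.
#' @export
detect_transients <- function(trace, frame_rate, smooth_frames = 3,
                              deriv_sd = 2, trace_skew_min = 1,
                              min_len = 2L) {
  n <- length(trace)
  if (n < 10 * frame_rate) stop("need at least 10 s of trace")
  empty <- function(thr, sk) {
    structure(list(onset_times = numeric(0), peak_times = numeric(0),
                   amplitudes = numeric(0), rise_times_ms = numeric(0),
                   rate_hz = 0, n = 0L, threshold = thr,
                   trace_skewness = sk), class = "transient_set")
  }
  if (stats::sd(trace) == 0) return(empty(NA_real_, NA_real_))
  sm <- rolling_mean(trace, smooth_frames)
  d <- diff(sm)
  thr_d <- mean(d) + deriv_sd * stats::sd(d)
  sk <- sample_skewness(trace)
  if (is.na(sk) || sk <= trace_skew_min) return(empty(thr_d, sk))
  amp_floor <- stats::median(trace) + 2 * 1.4826 * stats::mad(trace, constant = 1)
  onsets <- which(diff(c(FALSE, d > thr_d)) == 1L)
  # raw-derivative run starts locate the rise foot without the
  # one-frame spread the detection smoothing introduces
  d_raw <- diff(trace)
  thr_raw <- mean(d_raw) + deriv_sd * stats::sd(d_raw)
  raw_starts <- which(diff(c(FALSE, d_raw > thr_raw)) == 1L)
  keep_on <- numeric(0); keep_pk <- numeric(0)
  keep_amp <- numeric(0); keep_rise <- numeric(0)
  last_end <- 0L
  for (o in onsets) {
    if (o <= last_end) next
    horizon <- min(n, o + round(2 * frame_rate))
    pk <- o - 1L + which.max(sm[o:horizon])
    if (sm[pk] < amp_floor) next
    base <- min(sm[o:pk])
    half <- base + 0.5 * (sm[pk] - base)
    after <- which(sm[pk:horizon] < half)
    e <- if (length(after)) pk + after[1L] - 1L else horizon
    last_end <- e
    # kinetics measured on the raw trace: peak near the smoothed peak,
    # onset = the last derivative threshold crossing at or before the
    # peak (the first crossing may fire on noise shortly before the
    # true rise, whose derivative is far larger)
    pk_raw <- o - 1L + which.max(trace[o:min(horizon, pk + 2L)])
    prior <- raw_starts[raw_starts < pk_raw & raw_starts >= o - 2L]
    foot <- if (length(prior)) prior[length(prior)] else o
    base_raw <- min(trace[foot:pk_raw])
    if (e - foot + 1L < min_len) next
    keep_on <- c(keep_on, foot)
    keep_pk <- c(keep_pk, pk_raw)
    keep_amp <- c(keep_amp, trace[pk_raw] - base_raw)
    keep_rise <- c(keep_rise, (pk_raw - foot) / frame_rate * 1000)
  }
  structure(list(onset_times = keep_on / frame_rate,
                 peak_times = keep_pk / frame_rate,
                 amplitudes = keep_amp,
                 rise_times_ms = keep_rise,
                 rate_hz = length(keep_on) / (n / frame_rate),
                 n = length(keep_on),
                 threshold = thr_d,
                 trace_skewness = sk),
            class = "transient_set")
}

#' Population sparseness
#'
#' Per 500 ms bin, the fraction of cells that are "off": a cell's
#' binned response is the mean of its trace within the bin, and the
#' cell is "on" when that response exceeds its own adaptive threshold
#' (computed on the raw trace by [adaptive_threshold()]). Averaging
#' within the bin is what makes noise read "off": the bin mean of
#' noise shrinks as 1/sqrt(bin size) below the frame-level noise SD,
#' while a GCaMP6f transient (decay ~0.4 s) still lifts its bin well
#' above threshold. Higher sparseness means lower coactivation.
#'
#' @param traces Numeric matrix, frames x cells (delta-F/F).
#' @param frame_rate Frames per second.
#' @param bin_s Bin width, s. Default 0.5.
#' @param thresholds Optional per-cell thresholds; default computed
#'   with [adaptive_threshold()] on each raw trace.
#' @return A `sparseness_series` list: `fraction_off` (per bin),
#'   `bin_s`, `thresholds`, `on_matrix` (bins x cells).
#' @export
population_sparseness <- function(traces, frame_rate, bin_s = 0.5,
                                  thresholds = NULL) {
  stopifnot(is.matrix(traces), ncol(traces) >= 2L)
  if (is.null(thresholds)) {
    thresholds <- apply(traces, 2L, function(x) {
      suppressWarnings(adaptive_threshold(x)$threshold)
    })
  }
  n <- nrow(traces)
  per_bin <- max(1L, round(bin_s * frame_rate))
  bins <- ceiling(seq_len(n) / per_bin)
  nb <- max(bins)
  binned <- matrix(0, nb, ncol(traces))
  for (c0 in seq_len(ncol(traces))) {
    binned[, c0] <- tapply(traces[, c0], bins, mean)
  }
  on <- sweep(binned, 2L, thresholds, ">")
  structure(list(fraction_off = rowMeans(!on),
                 bin_s = bin_s,
                 thresholds = thresholds,
                 on_matrix = on),
            class = "sparseness_series")
}

#' Zero-lag pairwise correlations between cell traces
#'
#' Zero-lag cross-covariance normalized by the two SDs (the Pearson
#' correlation of the mean-removed traces) for every cell pair.
#' Zero-variance traces are excluded with a warning.
#'
#' @param traces Numeric matrix, frames x cells.
#' @return List: `matrix` (cells x cells), `values` (upper triangle),
#'   `q75` (75th percentile of the pairwise values), `excluded`
#'   (indices of zero-variance cells).
#' @export
pairwise_correlations <- function(traces) {
  stopifnot(is.matrix(traces), ncol(traces) >= 2L)
  sds <- apply(traces, 2L, stats::sd)
  excluded <- which(sds == 0)
  if (length(excluded)) {
    warning("zero-variance traces excluded: ",
            paste(excluded, collapse = ", "))
  }
  keep <- setdiff(seq_len(ncol(traces)), excluded)
  m <- matrix(NA_real_, ncol(traces), ncol(traces))
  if (length(keep) >= 2L) {
    m[keep, keep] <- stats::cor(traces[, keep, drop = FALSE])
  }
  vals <- m[upper.tri(m)]
  vals <- vals[!is.na(vals)]
  list(matrix = m, values = vals,
       q75 = if (length(vals)) stats::quantile(vals, 0.75, names = FALSE)
             else NA_real_,
       excluded = excluded)
}

#' Speed-calcium cross-covariance with a circular-shift null
#'
#' Normalized circular cross-covariance between a cell trace and the
#' animal speed over +/- `window_s` lags. The null distribution comes
#' from circular time shifts of the trace (preserving autocorrelation,
#' destroying alignment): because a circular shift simply translates
#' the circular covariance function, the full surrogate set is read
#' off the base covariance at random offsets. Significance uses the
#' max-over-window statistic against its surrogate 99th percentile
#' (controlling for the multiple lags in the window); the pointwise
#' 99th-percentile band is also returned for plotting.
#'
#' @param trace Numeric cell trace.
#' @param speed Numeric speed trace, same sampling.
#' @param rate Common sampling rate, Hz.
#' @param labels Optional per-sample behaviour labels (for the
#'   locomotion-related trace values).
#' @param window_s Lag window half-width, s. Default 10.
#' @param n_surrogates Number of circular shifts. Default 5000.
#' @param alpha_pct Surrogate percentile. Default 0.99.
#' @param seed Seed for the shifts.
#' @return A `covariance_result` list: `lags_s`, `covariance`
#'   (normalized, in \[-1, 1\]), `band` (pointwise percentile),
#'   `max_stat`, `max_null_pct` (surrogate percentile of the max
#'   statistic), `significant`, `locomotion_dff` (trace values during
#'   locomotion, or NULL).
#' @export
speed_covariance <- function(trace, speed, rate, labels = NULL,
                             window_s = 10, n_surrogates = 5000,
                             alpha_pct = 0.99, seed = NULL) {
  stopifnot(length(trace) == length(speed))
  n <- length(trace)
  L <- round(window_s * rate)
  if (n < 6 * L) stop("recording shorter than 3 windows")
  x <- trace - mean(trace)
  y <- speed - mean(speed)
  rms_x <- sqrt(mean(x^2)); rms_y <- sqrt(mean(y^2))
  if (rms_x == 0 || rms_y == 0) stop("constant trace or speed")
  # circular cross-covariance for all lags via FFT;
  # cc[l + 1] = (1/n) sum_t x_t y_{t-l}, normalized so |cc| <= 1
  cc <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(y)), inverse = TRUE)) /
    n^2 / (rms_x * rms_y)
  # lag l means trace shifted l samples after speed
  lag_index <- function(l) ((l) %% n) + 1L
  lags <- -L:L
  window_cc <- cc[lag_index(lags)]
  obs_max <- max(abs(window_cc))
  with_seed(seed, {
    # shifts keep the surrogate window clear of the true alignment
    shifts <- sample(seq(2L * L + 1L, n - 2L * L - 1L), n_surrogates,
                     replace = TRUE)
    null_max <- vapply(shifts, function(s0) {
      max(abs(cc[lag_index(lags + s0)]))
    }, 0)
    null_point <- cc[lag_index(shifts)]
  })
  structure(list(lags_s = lags / rate,
                 covariance = window_cc,
                 band = stats::quantile(abs(null_point), alpha_pct,
                                        names = FALSE),
                 max_stat = obs_max,
                 max_null_pct = stats::quantile(null_max, alpha_pct,
                                                names = FALSE),
                 significant = obs_max > stats::quantile(null_max, alpha_pct,
                                                         names = FALSE),
                 locomotion_dff = if (!is.null(labels))
                   trace[labels == "locomotion"] else NULL),
            class = "covariance_result")
}
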