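# Integer-pixel shift of frame `fr` relative to `ref` maximizing the
# circular cross-correlation; positive dx means `fr` content sits dx
# pixels to the right of `ref`. The search is limited to |shift| <=
# max_shift per axis so circularly wrapped content cannot win.
xcorr_shift <- function(ref, fr, max_shift = NULL) {
  ny <- nrow(ref); nx <- ncol(ref)
  if (is.null(max_shift)) max_shift <- floor(min(ny, nx) / 4)
  a <- ref - mean(ref)
  b <- fr - mean(fr)
  if (stats::sd(b) == 0 || stats::sd(a) == 0) {
    return(list(dx = 0L, dy = 0L, flat = TRUE))
  }
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  lag <- function(n) { k <- seq_len(n) - 1L; ifelse(k > n / 2, k - n, k) }
  ok <- outer(abs(lag(ny)) <= max_shift, abs(lag(nx)) <= max_shift, "&")
  cc[!ok] <- -Inf
  pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  list(dx = lag(nx)[pk[2L]], dy = lag(ny)[pk[1L]], flat = FALSE)
}

# Translate a matrix by integer (dx, dy), zero-filling the exposed edge.
translate_frame <- function(fr, dx, dy, fill = 0) {
  ny <- nrow(fr); nx <- ncol(fr)
  out <- matrix(fill, ny, nx)
  src_x <- seq_len(nx) - dx
  src_y <- seq_len(ny) - dy
  ok_x <- src_x >= 1 & src_x <= nx
  ok_y <- src_y >= 1 & src_y <= ny
  out[which(ok_y), which(ok_x)] <- fr[src_y[ok_y], src_x[ok_x]]
  out
}

#' Rigid motion correction by cross-correlation with a reference
#'
#' Finds, for every frame, the integer-pixel shift maximizing the
#' cross-correlation with a reference image and translates the frame
#' back. The reference defaults to a two-pass choice: a median
#' projection of immobility frames gives provisional shifts, then the
#' mean of the 10 lowest-motion immobility frames (a period free of
#' motion and activity) is used for the final pass. Featureless (flat)
#' frames get zero shift and a low-confidence flag.
#'
#' @param frames Array ny x nx x T, or a list with `frames`,
#'   `pixel_size`, `frame_rate` (as from [synthesize_movie()]).
#' @param labels Optional per-frame behaviour labels (used for
#'   reference selection).
#' @param pixel_size Microns per pixel (taken from `frames` if it is a
#'   movie list). Default 1.
#' @param reference Optional explicit reference matrix; skips the
#'   two-pass selection.
#' @param max_shift Largest shift searched per axis, px; default a
#'   quarter of the smaller frame dimension. Frames whose estimate
#'   sits on this bound are flagged `saturated` (their true motion
#'   likely exceeded the searchable range).
#' @return A `motion_corrected` list: `frames` (aligned array),
#'   `shifts_px` (T x 2, dx dy), `shifts_um`, `vector_length_um`,
#'   `low_confidence` (logical per frame), `saturated` (logical per
#'   frame), `reference`, `pixel_size`.
#' @export
motion_correct <- function(frames, labels = NULL, pixel_size = 1,
                           reference = NULL, max_shift = NULL) {
  if (is.list(frames) && !is.null(frames$frames)) {
    pixel_size <- frames$pixel_size
    frames <- frames$frames
  }
  nt <- dim(frames)[3]
  if (nt < 10L) stop("need at least 10 frames")
  if (is.null(max_shift)) max_shift <- floor(min(dim(frames)[1:2]) / 4)
  pass <- function(ref) {
    out <- matrix(0L, nt, 2L)
    flat <- logical(nt)
    for (f in seq_len(nt)) {
      s <- xcorr_shift(ref, frames[, , f], max_shift)
      out[f, ] <- c(s$dx, s$dy)
      flat[f] <- s$flat
    }
    list(shifts = out, flat = flat)
  }
  if (is.null(reference)) {
    base_idx <- if (!is.null(labels) && any(labels == "immobility")) {
      which(labels == "immobility")
    } else seq_len(nt)
    ref0 <- apply(frames[, , base_idx, drop = FALSE], c(1, 2), stats::median)
    p1 <- pass(ref0)
    len1 <- sqrt(rowSums(p1$shifts^2))
    quiet <- base_idx[order(len1[base_idx])][seq_len(min(10L, length(base_idx)))]
    reference <- apply(frames[, , quiet, drop = FALSE], c(1, 2), mean)
  }
  p <- pass(reference)
  aligned <- frames
  for (f in seq_len(nt)) {
    if (any(p$shifts[f, ] != 0L)) {
      aligned[, , f] <- translate_frame(frames[, , f],
                                        -p$shifts[f, 1L], -p$shifts[f, 2L])
    }
  }
  shifts_um <- p$shifts * pixel_size
  structure(list(frames = aligned,
                 shifts_px = p$shifts,
                 shifts_um = shifts_um,
                 vector_length_um = sqrt(rowSums(shifts_um^2)),
                 low_confidence = p$flat,
                 saturated = apply(abs(p$shifts) >= max_shift, 1L, any),
                 reference = reference,
                 pixel_size = pixel_size),
            class = "motion_corrected")
}

#' Select the "more stable" immobility frames
#'
#' Behavioural immobility does not guarantee brain immobility: the
#' more-stable template is the subset of immobility frames whose
#' per-axis |shift| stays below the recording's mean motion-vector
#' length.
#'
#' @param mc A `motion_corrected` object.
#' @param labels Per-frame behaviour labels.
#' @return Integer vector of frame indices.
#' @export
more_stable_template <- function(mc, labels) {
  stopifnot(length(labels) == nrow(mc$shifts_um))
  avg_len <- mean(mc$vector_length_um)
  idx <- which(labels == "immobility" &
                 abs(mc$shifts_um[, 1L]) < avg_len &
                 abs(mc$shifts_um[, 2L]) < avg_len)
  if (!length(idx)) {
    stop("no more-stable frames found; record a longer immobility period")
  }
  idx
}

#' Motion magnitude by behavioural state
#'
#' Median motion-vector length in the more-stable and locomotion frame
#' groups, their fold change, and the onset-triggered displacement
#' profile (median and interquartile range in an 8 s window around
#' locomotion onsets).
#'
#' @param mc A `motion_corrected` object.
#' @param labels Per-frame behaviour labels.
#' @param frame_rate Frames per second.
#' @param stable_idx More-stable frame indices (default:
#'   [more_stable_template()]).
#' @param window_s Onset window total width, s. Default 8.
#' @return List: `median_stable_um`, `median_locomotion_um`,
#'   `fold_change`, `onset_profile` (data.frame: `t`, `median`, `q25`,
#'   `q75`), `n_onsets`. Absent states give `NA` entries.
#' @export
motion_by_state <- function(mc, labels, frame_rate,
                            stable_idx = NULL, window_s = 8) {
  len <- mc$vector_length_um
  loco <- which(labels == "locomotion")
  if (is.null(stable_idx)) {
    stable_idx <- tryCatch(more_stable_template(mc, labels),
                           error = function(e) integer(0))
  }
  med_stable <- if (length(stable_idx)) stats::median(len[stable_idx]) else NA_real_
  med_loco <- if (length(loco)) stats::median(len[loco]) else NA_real_
  fold <- if (!is.na(med_stable) && med_stable > 0) med_loco / med_stable else NA_real_
  onsets <- which(diff(c(FALSE, labels == "locomotion")) == 1L)
  half <- round(window_s / 2 * frame_rate)
  prof <- NULL
  if (length(onsets)) {
    rows <- lapply(onsets, function(o) {
      idx <- (o - half):(o + half)
      v <- rep(NA_real_, length(idx))
      ok <- idx >= 1 & idx <= length(len)
      v[ok] <- len[idx[ok]]
      v
    })
    m <- do.call(rbind, rows)
    prof <- data.frame(
      t = (seq_len(ncol(m)) - half - 1L) / frame_rate,
      median = apply(m, 2L, stats::median, na.rm = TRUE),
      q25 = apply(m, 2L, stats::quantile, 0.25, na.rm = TRUE),
      q75 = apply(m, 2L, stats::quantile, 0.75, na.rm = TRUE))
  }
  list(median_stable_um = med_stable,
       median_locomotion_um = med_loco,
       fold_change = fold,
       onset_profile = prof,
       n_onsets = length(onsets))
}

# Largest connected component (4-connectivity) of `mask` containing
# pixel `seed` (row, col); flood fill.
connected_component <- function(mask, seed) {
  ny <- nrow(mask); nx <- ncol(mask)
  comp <- matrix(FALSE, ny, nx)
  if (!mask[seed[1L], seed[2L]]) return(comp)
  queue <- list(seed)
  comp[seed[1L], seed[2L]] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      q <- p + d
      if (q[1L] >= 1L && q[1L] <= ny && q[2L] >= 1L && q[2L] <= nx &&
          mask[q[1L], q[2L]] && !comp[q[1L], q[2L]]) {
        comp[q[1L], q[2L]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  comp
}

#' Axial-stability probability map with spatial-reshuffling surrogates
#'
#' For each frame of the selected template, the ROI is binarized at
#' that frame's own 90th intensity percentile (so the map is invariant
#' to global intensity rescaling); the stability map is the per-pixel
#' fraction of frames above threshold. Chance is estimated by randomly
#' permuting the pixels within each frame, `n_surrogates` times; the
#' per-pixel 95th percentile of the surrogate maps is the statistical
#' threshold. The supra-chance region is the connected component above
#' threshold containing the map's peak, reported with its
#' equivalent-circle diameter.
#'
#' @param frames Array ny x nx x F (an ROI crop over a frame template).
#' @param pixel_size Microns per pixel.
#' @param n_surrogates Number of spatial reshuffles. Default 1000.
#' @param threshold_pct Per-frame binarization percentile. Default 0.9.
#' @param surrogate_pct Surrogate-map percentile used as the chance
#'   threshold. Default 0.95.
#' @param peak_at Optional `(row, col)` of the structure of interest;
#'   the supra-chance component and peak are then taken at the local
#'   maximum nearest that pixel (within 3 px) instead of the map's
#'   global maximum, so a specific terminal can be quantified in a
#'   crop containing several.
#' @param seed Seed for the reshuffles.
#' @return A `stability_map` list: `probability` (matrix in \[0, 1\]),
#'   `chance_map` (per-pixel surrogate threshold), `surrogate_mean`
#'   (mean surrogate map, ~0.1 everywhere), `supra_mask`,
#'   `supra_area_px`, `diameter_um`, `peak_probability`,
#'   `peak_percent` (of frames), `peak_over_chance` (peak divided by
#'   the chance level at the peak), `n_frames`, `n_surrogates`.
#' @export
stability_map <- function(frames, pixel_size = 1, n_surrogates = 1000,
                          threshold_pct = 0.9, surrogate_pct = 0.95,
                          peak_at = NULL, seed = NULL) {
  nf <- dim(frames)[3]
  if (is.na(nf) || nf < 20L) stop("need at least 20 frames for stable percentiles")
  ny <- dim(frames)[1]; nx <- dim(frames)[2]
  npx <- ny * nx
  masks <- matrix(FALSE, npx, nf)
  for (f in seq_len(nf)) {
    fr <- frames[, , f]
    masks[, f] <- as.vector(fr > stats::quantile(fr, threshold_pct))
  }
  prob <- matrix(rowMeans(masks), ny, nx)
  k_per_frame <- colSums(masks)
  with_seed(seed, {
    surr <- matrix(0, npx, n_surrogates)
    for (s in seq_len(n_surrogates)) {
      counts <- integer(npx)
      for (f in seq_len(nf)) {
        idx <- sample.int(npx, k_per_frame[f])
        counts[idx] <- counts[idx] + 1L
      }
      surr[, s] <- counts / nf
    }
    chance <- matrix(apply(surr, 1L, stats::quantile, surrogate_pct), ny, nx)
    surrogate_mean <- matrix(rowMeans(surr), ny, nx)
  })
  if (is.null(peak_at)) {
    peak <- which(prob == max(prob), arr.ind = TRUE)[1L, ]
  } else {
    rr <- max(1L, peak_at[1L] - 3L):min(ny, peak_at[1L] + 3L)
    cc <- max(1L, peak_at[2L] - 3L):min(nx, peak_at[2L] + 3L)
    local <- which(prob[rr, cc] == max(prob[rr, cc]), arr.ind = TRUE)[1L, ]
    peak <- c(rr[local[1L]], cc[local[2L]])
  }
  peak_p <- prob[peak[1L], peak[2L]]
  supra <- prob > chance
  comp <- connected_component(supra, as.integer(peak))
  area <- sum(comp)
  structure(list(probability = prob,
                 chance_map = chance,
                 surrogate_mean = surrogate_mean,
                 supra_mask = comp,
                 supra_area_px = area,
                 supra_total_px = sum(supra),
                 diameter_um = 2 * sqrt(area / pi) * pixel_size,
                 peak_probability = peak_p,
                 peak_percent = 100 * peak_p,
                 peak_over_chance = peak_p / chance[peak[1L], peak[2L]],
                 n_frames = nf,
                 n_surrogates = n_surrogates),
            class = "stability_map")
}

#' Delta-F/F with a mode-of-low-percentiles baseline
#'
#' `(F - F0) / F0` where the baseline F0 is the main mode of the
#' trace's value distribution restricted to the 5th-10th percentile
#' interval (a 50-bin histogram of that interval), so transients do
#' not contaminate the baseline.
#'
#' @param f Numeric fluorescence trace (raw ROI mean).
#' @param probs Percentile interval for the baseline. Default
#'   `c(0.05, 0.10)`.
#' @param bins Histogram bins for the mode. Default 50.
#' @return List: `dff` (same length as `f`), `f0`.
#' @export
dff <- function(f, probs = c(0.05, 0.10), bins = 50) {
  q <- stats::quantile(f, probs)
  vals <- f[f >= q[1L] & f <= q[2L]]
  f0 <- if (length(unique(vals)) <= 1L) {
    if (length(vals)) vals[1L] else unname(q[1L])
  } else {
    h <- graphics::hist(vals, breaks = bins, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  if (f0 <= 0) stop("baseline F0 <= 0; delta-F/F undefined")
  list(dff = (f - f0) / f0, f0 = f0)
}
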