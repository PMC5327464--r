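#' Segment behaviour into locomotion, flickering and immobility
#'
#' Applies the speed-threshold rules: locomotion epochs are contiguous
#' runs with |speed| above `loco_speed` (2 cm/s) covering at least
#' `loco_distance` (2 cm); flickering is movement above
#' `immobility_speed` (0.25 cm/s) that does not qualify as locomotion
#' (including fast but sub-distance runs); immobility is no wheel
#' rotation. Runs above the locomotion threshold separated by gaps
#' shorter than `bridge_s` are merged before the distance criterion, so
#' an epoch does not fragment at each step's speed trough.
#'
#' @param trace A `speed_trace`, or a list with `speed`, `position`,
#'   `sample_rate`.
#' @param loco_speed Locomotion speed threshold, cm/s. Default 2.
#' @param loco_distance Minimum locomotion distance, cm. Default 2.
#' @param immobility_speed Immobility threshold, cm/s. Default 0.25.
#' @param bridge_s Maximum sub-threshold gap bridged inside a
#'   locomotion epoch, seconds. Default 0.5.
#' @return A `behaviour_segmentation` list: `labels` (character per
#'   sample), `epochs` (data.frame: `state`, `start`, `end` in s,
#'   `distance` cm), logic vectors `is_locomotion`, `is_flickering`,
#'   `is_immobility`, and `sample_rate`.
#' @export
segment_behaviour <- function(trace,
                              loco_speed = 2,
                              loco_distance = 2,
                              immobility_speed = 0.25,
                              bridge_s = 0.5) {
  fs <- trace$sample_rate
  sp <- abs(trace$speed)
  pos <- trace$position
  n <- length(sp)
  labels <- rep("immobility", n)
  labels[sp > immobility_speed] <- "flickering"
  fast <- sp > loco_speed
  runs <- logical_runs(fast)
  if (nrow(runs) > 1L) {
    gap <- (runs$start[-1L] - runs$end[-nrow(runs)] - 1L) / fs
    merged <- list()
    cur <- c(runs$start[1L], runs$end[1L])
    for (k in seq_along(gap)) {
      if (gap[k] < bridge_s) {
        cur[2L] <- runs$end[k + 1L]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(runs$start[k + 1L], runs$end[k + 1L])
      }
    }
    merged[[length(merged) + 1L]] <- cur
    runs <- data.frame(start = vapply(merged, `[`, 0, 1L),
                       end = vapply(merged, `[`, 0, 2L))
  }
  if (nrow(runs)) {
    dist <- vapply(seq_len(nrow(runs)), function(k) {
      sum(abs(diff(pos[runs$start[k]:runs$end[k]])))
    }, 0)
    for (k in which(dist >= loco_distance)) {
      labels[runs$start[k]:runs$end[k]] <- "locomotion"
    }
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epochs <- data.frame(
    state = r$values,
    start = (starts - 1L) / fs,
    end = ends / fs,
    distance = vapply(seq_along(starts), function(k) {
      sum(abs(diff(pos[starts[k]:ends[k]])))
    }, 0)
  )
  structure(list(labels = labels,
                 epochs = epochs,
                 is_locomotion = labels == "locomotion",
                 is_flickering = labels == "flickering",
                 is_immobility = labels == "immobility",
                 sample_rate = fs),
            class = "behaviour_segmentation")
}

#' Detect walking steps from the speed oscillation
#'
#' Within locomotion epochs, peaks of the smoothed speed signal are
#' step events: the limbs are anti-phase, so the speed oscillates twice
#' per limb cycle and the distance between consecutive speed peaks is
#' half a limb step. Peaks need a prominence of at least
#' `prominence_frac` of the epoch's median speed and a separation of at
#' least `min_separation_s`.
#'
#' @param trace A `speed_trace`.
#' @param seg A `behaviour_segmentation` for the same trace.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   epoch median speed. Default 0.25.
#' @param min_separation_s Minimum peak separation, s. Default 0.1.
#' @return A `step_series` list: `step_times` (s),
#'   `step_lengths_speed` (cm between consecutive speed peaks),
#'   `step_lengths_limb` (= 2 x speed-signal lengths), `step_rate`
#'   (Hz, peaks per locomotion second), `n_steps`.
#' @export
detect_steps <- function(trace, seg,
                         prominence_frac = 0.25,
                         min_separation_s = 0.1) {
  fs <- trace$sample_rate
  ep <- seg$epochs[seg$epochs$state == "locomotion", , drop = FALSE]
  times <- numeric(0)
  lens <- numeric(0)
  loco_s <- 0
  for (k in seq_len(nrow(ep))) {
    i0 <- round(ep$start[k] * fs) + 1L
    i1 <- round(ep$end[k] * fs)
    sp <- abs(trace$speed[i0:i1])
    loco_s <- loco_s + (i1 - i0 + 1L) / fs
    pk <- find_peaks(sp,
                     min_distance = round(min_separation_s * fs),
                     min_prominence = prominence_frac * stats::median(sp))
    if (length(pk) >= 1L) {
      times <- c(times, (i0 - 1L + pk) / fs)
      if (length(pk) >= 2L) {
        lens <- c(lens, abs(diff(trace$position[i0 - 1L + pk])))
      }
    }
  }
  structure(list(step_times = times,
                 step_lengths_speed = lens,
                 step_lengths_limb = 2 * lens,
                 step_rate = if (loco_s > 0) length(times) / loco_s else NA_real_,
                 n_steps = length(times)),
            class = "step_series")
}

#' Stereotypy of a distribution
#'
#' Dimensionless dispersion, `iqr(D) / median(D)`: near zero for a
#' stereotyped (narrow) distribution, above one for a broad one. Scale
#' invariant and outlier robust, so sessions with different units and
#' distribution shapes can be compared.
#'
#' @param d Numeric sample (at least 4 values, positive median).
#' @return List with `phi`, `iqr`, `center` (the median).
#' @export
stereotypy <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 4L) stop("need at least 4 values")
  m <- stats::median(d)
  if (m <= 0) stop("stereotypy undefined for non-positive median")
  iqr <- stats::IQR(d)
  list(phi = iqr / m, iqr = iqr, center = m)
}

#' Intra- vs inter-individual variability of locomotion probability
#'
#' Mean within-unit interquartile range of locomotion probabilities.
#' For the intra-individual condition the units are the animals and the
#' spread is taken across days (how variable each mouse is over days);
#' for the inter-individual condition the units are the days and the
#' spread is across animals.
#'
#' @param prob Matrix of locomotion probabilities, rows = mice,
#'   columns = days. `NA`s are dropped with a warning.
#' @param condition `"intra"` or `"inter"`.
#' @return List with `V`, `condition`, `unit_iqr` (per-unit spreads).
#' @export
variability <- function(prob, condition = c("intra", "inter")) {
  condition <- match.arg(condition)
  stopifnot(is.matrix(prob))
  if (anyNA(prob)) warning("missing sessions; computed on available data")
  spread <- function(x) stats::IQR(x, na.rm = TRUE)
  unit_iqr <- if (condition == "intra") {
    apply(prob, 1L, spread)  # each mouse across days
  } else {
    apply(prob, 2L, spread)  # each day across mice
  }
  list(V = mean(unit_iqr), condition = condition, unit_iqr = unit_iqr)
}

#' Per-day habituation metrics
#'
#' State-time fractions, median locomotion speed and speed stereotypy
#' for each recording day, in the form consumed by
#' [bootstrap_slope_test()].
#'
#' @param days List of per-day lists, each with elements `trace`
#'   (a `speed_trace`) and `seg` (its `behaviour_segmentation`).
#' @return data.frame with one row per day: `day`, `frac_locomotion`,
#'   `frac_flickering`, `frac_immobility`, `median_speed` (cm/s over
#'   locomotion samples), `stereotypy` (of the locomotion speed
#'   distribution; `NA` if undefined).
#' @export
habituation_metrics <- function(days) {
  if (length(days) < 2L) stop("need at least 2 days")
  rows <- lapply(seq_along(days), function(k) {
    d <- days[[k]]
    lab <- d$seg$labels
    n <- length(lab)
    if (n == 0L) {
      warning(sprintf("day %d empty; excluded", k))
      return(NULL)
    }
    sp <- abs(d$trace$speed)[d$seg$is_locomotion]
    phi <- tryCatch(stereotypy(sp)$phi, error = function(e) NA_real_)
    data.frame(day = k,
               frac_locomotion = mean(lab == "locomotion"),
               frac_flickering = mean(lab == "flickering"),
               frac_immobility = mean(lab == "immobility"),
               median_speed = if (length(sp)) stats::median(sp) else NA_real_,
               stereotypy = phi)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
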