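#' Two-photon movie generator specification
#'
#' Describes a synthetic calcium movie: Gaussian-profile structures
#' (somata, dendrites, boutons) on a dim background, GCaMP6f-like
#' transients, lateral brain motion coupled to the behavioural state,
#' per-frame axial (in/out of focus) draws, and photon + read noise.
#'
#' @param frame_shape `c(ny, nx)` pixels. Default `c(64, 64)`.
#' @param pixel_size Microns per pixel (0.3-2). Default 0.3.
#' @param frame_rate Frames per second (8-39). Default 30.
#' @param structures data.frame with columns `x`, `y` (pixel centers,
#'   1-based), `diameter_um`, `kind` (`"soma"`, `"dendrite"`,
#'   `"bouton"`), `amplitude` (baseline fluorescence), `in_focus_prob`
#'   (per-frame probability of being in the focal plane),
#'   `activity` (`"none"`, `"spontaneous"`, `"speed"`), `rate_hz`
#'   (spontaneous transient rate).
#' @param transient_rise_s,transient_decay_s GCaMP6f-like kinetics, s.
#'   Defaults 0.03 and 0.4.
#' @param transient_amp Peak transient amplitude as a fraction of the
#'   structure baseline (delta-F/F). Default 1.
#' @param speed_coupling Delta-F/F per cm/s for `"speed"` structures.
#'   Default 0.1.
#' @param motion_sigma_um Named per-axis motion SD (microns) per
#'   behavioural state. Defaults give a ~0.32 um median motion vector
#'   in immobility and ~1.8 um during locomotion (a ~5.6-fold state
#'   ratio, typical of a well-damped wheel).
#' @param onset_boost Multiplier on the motion SD during the first
#'   second of each locomotion epoch (motion spikes at onsets).
#'   Default 1.5.
#' @param background Baseline background intensity. Default 10.
#' @param photon_scale Photons per intensity unit for Poisson shot
#'   noise; 0 disables. Default 0 (noise applied only when requested).
#' @param read_noise_sd Additive Gaussian read noise SD. Default 0.
#' @param seed Integer seed.
#' @return An object of class `movie_gen_spec`.
#' @export
movie_gen_spec <- function(frame_shape = c(64, 64),
                           pixel_size = 0.3,
                           frame_rate = 30,
                           structures = default_structures(),
                           transient_rise_s = 0.03,
                           transient_decay_s = 0.4,
                           transient_amp = 1,
                           speed_coupling = 0.1,
                           motion_sigma_um = c(immobility = 0.27,
                                               flickering = 0.27,
                                               locomotion = 1.53),
                           onset_boost = 1.5,
                           background = 10,
                           photon_scale = 0,
                           read_noise_sd = 0,
                           seed = NULL) {
  if (frame_rate < 8 || frame_rate > 39) stop("frame_rate must be 8-39 Hz")
  if (pixel_size < 0.3 || pixel_size > 2) stop("pixel_size must be 0.3-2 um")
  r_px <- structures$diameter_um / pixel_size / 2
  if (any(structures$x - r_px < 1 | structures$x + r_px > frame_shape[2] |
          structures$y - r_px < 1 | structures$y + r_px > frame_shape[1])) {
    stop("structure outside frame")
  }
  structure(as.list(environment()), class = "movie_gen_spec")
}

#' Default synthetic field of view
#'
#' A static dendrite crossing the field diagonally with irregular
#' varicosity brightness (real dendrites are not periodic, and a
#' non-repeating scene keeps rigid registration unambiguous) plus one
#' bright bouton (1 um, inside the 0.8-1.3 um interquartile range
#' typical of VIP boutons).
#'
#' @param ny,nx Frame shape used to place the dendrite. Default 64.
#' @return data.frame usable as `structures` in [movie_gen_spec()].
#' @export
default_structures <- function(ny = 64, nx = 64) {
  xs <- seq(8, nx - 7, by = 2)
  ys <- round(ny * 0.2 + 0.35 * (xs - xs[1]))
  amp <- 30 + 15 * (1 + sin(2.4 * seq_along(xs))) / 2  # irregular varicosities
  nd <- length(xs)
  data.frame(
    x = c(xs, round(nx * 0.65)),
    y = c(ys, round(ny * 0.75)),
    diameter_um = c(rep(0.9, nd), 1.0),
    kind = c(rep("dendrite", nd), "bouton"),
    amplitude = c(amp, 60),
    in_focus_prob = rep(1, nd + 1L),
    activity = c(rep("none", nd), "spontaneous"),
    rate_hz = c(rep(0, nd), 0.05)
  )
}

# Difference-of-exponentials transient kernel, peak-normalized.
# `rise_s` is the time-to-peak (how a rise time is read off a trace);
# the corresponding rise constant is solved from the decay constant.
transient_kernel <- function(fs, rise_s, decay_s, len_s = 3) {
  tau_r <- tryCatch(
    stats::uniroot(function(tr) log(decay_s / tr) / (1 / tr - 1 / decay_s) -
                     rise_s,
                   interval = c(1e-5, decay_s * 0.999))$root,
    error = function(e) rise_s / 3)
  tt <- seq(0, len_s, by = 1 / fs)
  k <- exp(-tt / decay_s) - exp(-tt / tau_r)
  k / max(k)
}

# Render one 2-D Gaussian blob on an (ny, nx) grid (FWHM = diameter).
render_blob <- function(ny, nx, cx, cy, diameter_px, amplitude) {
  sig <- diameter_px / 2.355
  gx <- exp(-((seq_len(nx) - cx)^2) / (2 * sig^2))
  gy <- exp(-((seq_len(ny) - cy)^2) / (2 * sig^2))
  amplitude * outer(gy, gx)
}

#' Synthesize a calcium movie with ground truth
#'
#' Renders each structure as a 2-D Gaussian whose amplitude is
#' modulated by (i) calcium transients following difference-of-
#' exponentials kinetics, and (ii) a per-frame axial in-focus Bernoulli
#' draw. Lateral shifts are drawn from the state-coupled motion model
#' (boosted within 1 s of locomotion onsets), rounded to the pixel
#' grid, and applied by shifting the structure centers, so integer
#' ground-truth shifts are rendered exactly.
#'
#' @param labels Character behaviour labels at the frame rate.
#' @param speed Speed (cm/s) at the frame rate.
#' @param spec A [movie_gen_spec()].
#' @param shifts_px Optional integer matrix (frames x 2, columns dx,
#'   dy) overriding the motion model.
#' @return List: `frames` (array ny x nx x T), `pixel_size`,
#'   `frame_rate`, and `ground_truth` with `shifts_px`, `shifts_um`,
#'   `in_focus` (structures x frames), `dff` (frames x structures),
#'   `transients` (list of event-time vectors), `roi_masks` (list of
#'   logical ny x nx masks at half maximum).
#' @export
synthesize_movie <- function(labels, speed, spec = movie_gen_spec(),
                             shifts_px = NULL) {
  stopifnot(length(labels) == length(speed))
  nt <- length(labels)
  ny <- spec$frame_shape[1]; nx <- spec$frame_shape[2]
  st <- spec$structures
  ns <- nrow(st)
  fs <- spec$frame_rate
  with_seed(spec$seed, {
    # --- motion ---
    if (is.null(shifts_px)) {
      sig <- spec$motion_sigma_um[labels]
      sig[is.na(sig)] <- spec$motion_sigma_um[["immobility"]]
      onset <- which(diff(c(FALSE, labels == "locomotion")) == 1L)
      for (o in onset) {
        idx <- o:min(nt, o + round(fs) - 1L)
        sig[idx] <- sig[idx] * spec$onset_boost
      }
      shifts_um_cont <- cbind(stats::rnorm(nt, 0, sig),
                              stats::rnorm(nt, 0, sig))
      shifts_px <- round(shifts_um_cont / spec$pixel_size)
    } else {
      shifts_px <- as.matrix(shifts_px)
      stopifnot(nrow(shifts_px) == nt, ncol(shifts_px) == 2L)
    }
    shifts_um <- shifts_px * spec$pixel_size

    # --- activity traces (delta-F/F per structure) ---
    kern <- transient_kernel(fs, spec$transient_rise_s, spec$transient_decay_s)
    dff <- matrix(0, nrow = nt, ncol = ns)
    transients <- vector("list", ns)
    for (s in seq_len(ns)) {
      transients[[s]] <- numeric(0)
      if (st$activity[s] == "spontaneous" && st$rate_hz[s] > 0) {
        n_ev <- stats::rpois(1L, st$rate_hz[s] * nt / fs)
        ev <- sort(sample.int(nt, min(n_ev, nt)))
        tr <- numeric(nt)
        for (e in ev) {
          idx <- e:min(nt, e + length(kern) - 1L)
          tr[idx] <- tr[idx] + spec$transient_amp * kern[seq_along(idx)]
        }
        dff[, s] <- tr
        transients[[s]] <- ev / fs
      } else if (st$activity[s] == "speed") {
        dff[, s] <- spec$speed_coupling * speed
      }
    }

    # --- axial focus draws ---
    in_focus <- matrix(TRUE, nrow = ns, ncol = nt)
    for (s in seq_len(ns)) {
      if (st$in_focus_prob[s] < 1) {
        in_focus[s, ] <- stats::runif(nt) < st$in_focus_prob[s]
      }
    }

    # --- render ---
    frames <- array(spec$background, dim = c(ny, nx, nt))
    d_px <- st$diameter_um / spec$pixel_size
    for (f in seq_len(nt)) {
      fr <- frames[, , f]
      for (s in seq_len(ns)) {
        if (!in_focus[s, f]) next
        fr <- fr + render_blob(ny, nx,
                               st$x[s] + shifts_px[f, 1],
                               st$y[s] + shifts_px[f, 2],
                               d_px[s],
                               st$amplitude[s] * (1 + dff[f, s]))
      }
      if (spec$photon_scale > 0) {
        fr <- stats::rpois(length(fr), fr * spec$photon_scale) /
          spec$photon_scale
      }
      if (spec$read_noise_sd > 0) {
        fr <- fr + stats::rnorm(length(fr), 0, spec$read_noise_sd)
      }
      frames[, , f] <- fr
    }

    roi_masks <- lapply(seq_len(ns), function(s) {
      blob <- render_blob(ny, nx, st$x[s], st$y[s], d_px[s], 1)
      blob >= 0.5
    })

    list(frames = frames,
         pixel_size = spec$pixel_size,
         frame_rate = fs,
         ground_truth = list(shifts_px = shifts_px,
                             shifts_um = shifts_um,
                             in_focus = in_focus,
                             dff = dff,
                             transients = transients,
                             roi_masks = roi_masks))
  })
}
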