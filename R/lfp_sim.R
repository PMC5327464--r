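#' LFP generator specification
#'
#' Parameters for the synthetic hippocampal LFP: pink (1/f) background,
#' ripple bursts injected during immobility as a Poisson process, and a
#' speed-modulated theta oscillation during locomotion. Event-rate and
#' slope defaults follow typical CA1 values in head-fixed mice (ripples
#' at 0.11 Hz with a 143 +/- 14 Hz carrier lasting ~37.7 ms; theta
#' frequency and power growing with speed at 0.01 Hz and 0.023 dB per
#' cm/s).
#'
#' @param noise_exponent Spectral slope of the 1/f background. Default 1.
#' @param noise_sd Background standard deviation (arbitrary LFP units).
#' @param ripple_rate Ripple occurrence during immobility, Hz. Default 0.11.
#' @param ripple_freq_mean,ripple_freq_sd Carrier frequency distribution,
#'   Hz; drawn per event from a normal truncated to 100-250 Hz.
#'   Defaults 143 and 14.
#' @param ripple_duration_ms Burst duration (4-sigma width of the
#'   Gaussian envelope), ms. Default 37.7.
#' @param ripple_amplitude Peak burst amplitude as a multiple of the
#'   background's 100-250 Hz band SD. Default 5 (ripples stand well
#'   above the band noise, as in vivo).
#' @param theta_base_freq Theta frequency at zero speed, Hz. Default 7.
#' @param theta_freq_slope Hz per cm/s. Default 0.01.
#' @param theta_power_slope dB per cm/s. Default 0.023.
#' @param theta_amplitude Theta amplitude at the base speed as a multiple
#'   of the background's 5-15 Hz band SD. Default 4 (theta dominates the
#'   band during locomotion).
#' @param seed Integer seed.
#' @return An object of class `lfp_gen_spec`.
#' @export
lfp_gen_spec <- function(noise_exponent = 1,
                         noise_sd = 1,
                         ripple_rate = 0.11,
                         ripple_freq_mean = 143,
                         ripple_freq_sd = 14,
                         ripple_duration_ms = 37.7,
                         ripple_amplitude = 5,
                         theta_base_freq = 7,
                         theta_freq_slope = 0.01,
                         theta_power_slope = 0.023,
                         theta_amplitude = 4,
                         seed = NULL) {
  if (ripple_freq_mean < 100 || ripple_freq_mean > 250) {
    stop("ripple_freq_mean must lie in the 100-250 Hz band")
  }
  if (theta_base_freq < 5 || theta_base_freq > 15) {
    stop("theta_base_freq must lie in the 5-15 Hz band")
  }
  if (ripple_rate < 0 || ripple_amplitude < 0 || theta_amplitude < 0) {
    stop("rates and amplitudes must be >= 0")
  }
  structure(as.list(environment()), class = "lfp_gen_spec")
}

# 1/f^alpha Gaussian noise of length n, unit SD before rescaling.
pink_noise <- function(n, alpha) {
  white <- stats::rnorm(n)
  if (alpha == 0) return(white)
  X <- stats::fft(white)
  k <- c(1, seq_len(n - 1))                 # DC handled separately
  f <- pmin(k, n - k + 1)                   # symmetric frequency index
  shape <- f^(-alpha / 2)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Synthesize an LFP trace with ground-truth events
#'
#' Builds a 1/f background and injects (i) Gaussian-windowed ripple
#' bursts during immobility, as a Poisson process at `ripple_rate`, and
#' (ii) a theta sinusoid during locomotion whose instantaneous
#' frequency is `theta_base_freq + theta_freq_slope * speed` and whose
#' amplitude grows with speed at `theta_power_slope` dB per cm/s.
#' Ripples keep at least 4 carrier cycles by construction, so they pass
#' the downstream detector's cycle criterion.
#'
#' @param labels Character vector of per-sample behaviour states.
#' @param speed Numeric vector, cm/s, same length as `labels`.
#' @param spec An [lfp_gen_spec()].
#' @param sample_rate Hz. Default 10000.
#' @return List: `lfp` (numeric), `sample_rate`, and `ground_truth`
#'   with `ripples` (data.frame: `time`, `freq`, `duration_ms`),
#'   `theta_freq` (per-sample Hz, `NA` outside locomotion),
#'   `immobility_s` (total immobility time).
#' @export
synthesize_lfp <- function(labels, speed, spec = lfp_gen_spec(),
                           sample_rate = 10000) {
  stopifnot(length(labels) == length(speed))
  n <- length(labels)
  fs <- sample_rate
  with_seed(spec$seed, {
    lfp <- pink_noise(n, spec$noise_exponent) * spec$noise_sd
    band_sd_ripple <- stats::sd(bandpass(lfp, fs, 100, 250))
    band_sd_theta <- stats::sd(bandpass(lfp, fs, 5, 15))

    # --- ripples in immobility ---
    ripples <- list()
    if (spec$ripple_rate > 0) {
      runs <- logical_runs(labels == "immobility")
      half <- round(0.1 * fs)                 # event margin from run edges
      for (k in seq_len(nrow(runs))) {
        dur <- (runs$end[k] - runs$start[k] + 1L) / fs
        n_ev <- stats::rpois(1L, spec$ripple_rate * dur)
        if (n_ev == 0L) next
        centers <- runs$start[k] + round(stats::runif(n_ev, 0.05, dur - 0.05) * fs)
        centers <- centers[centers - half > 1 & centers + half < n]
        for (c0 in sort(centers)) {
          f_c <- Inf
          while (f_c < 100 || f_c > 250) {
            f_c <- stats::rnorm(1, spec$ripple_freq_mean, spec$ripple_freq_sd)
          }
          # nominal duration maps to the envelope so that the
          # detector's boundary-measured extent matches the nominal
          # scale, and every event carries >= 4 carrier cycles by
          # construction (slow-carrier draws are widened)
          dur_s <- max(spec$ripple_duration_ms / 1000, 4.5 / f_c)
          sigma <- dur_s / 3
          half_ev <- round(2.5 * sigma * fs)
          idx <- max(1L, c0 - half_ev):min(n, c0 + half_ev)
          tt <- (idx - c0) / fs
          burst <- exp(-tt^2 / (2 * sigma^2)) *
            cos(2 * pi * f_c * tt + stats::runif(1, 0, 2 * pi))
          lfp[idx] <- lfp[idx] + spec$ripple_amplitude * band_sd_ripple * burst
          ripples[[length(ripples) + 1L]] <-
            data.frame(time = c0 / fs, freq = f_c,
                       duration_ms = dur_s * 1000)
        }
      }
    }
    ripples <- if (length(ripples)) do.call(rbind, ripples) else
      data.frame(time = numeric(0), freq = numeric(0),
                 duration_ms = numeric(0))

    # --- theta during locomotion ---
    theta_freq <- rep(NA_real_, n)
    if (spec$theta_amplitude > 0) {
      loco <- labels == "locomotion"
      f_inst <- spec$theta_base_freq + spec$theta_freq_slope * speed
      phase <- cumsum(2 * pi * f_inst / fs)
      amp <- spec$theta_amplitude * band_sd_theta *
        10^(spec$theta_power_slope * speed / 20)
      gate <- rolling_mean(as.numeric(loco), round(0.05 * fs))  # 50 ms ramp
      lfp <- lfp + amp * gate * sin(phase)
      theta_freq[loco] <- f_inst[loco]
    }

    list(lfp = lfp,
         sample_rate = fs,
         ground_truth = list(
           ripples = ripples,
           theta_freq = theta_freq,
           immobility_s = sum(labels == "immobility") / fs))
  })
}
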