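#' Wheel and optical-encoder specification
#'
#' The wheel circumference and encoder resolution used throughout.
#' Defaults match the physical wheel: one turn is 24.19 cm and channels
#' A/B emit 500 square fringes per turn, phase-offset by a quarter
#' pitch so the lead/lag of A vs B encodes rotation direction. Channel
#' I emits one index pulse per full turn.
#'
#' @param circumference Wheel circumference, cm. Default 24.19.
#' @param fringes_per_turn Full A/B square cycles per turn. Default 500.
#' @param index_pulse_volts Channel-I pulse amplitude, V. Default 5.
#' @param channel_volts A/B square amplitude, V. Default 5.
#' @param sample_rate Digitizer rate, Hz. Default 10000 (the minimal
#'   rate at which the full 0-120 cm/s range stays below one quadrature
#'   quarter-step per sample).
#' @return An object of class `wheel_spec`.
#' @export
wheel_spec <- function(circumference = 24.19,
                       fringes_per_turn = 500L,
                       index_pulse_volts = 5,
                       channel_volts = 5,
                       sample_rate = 10000) {
  stopifnot(circumference > 0, fringes_per_turn >= 1, sample_rate > 0)
  structure(list(circumference = circumference,
                 fringes_per_turn = as.integer(fringes_per_turn),
                 index_pulse_volts = index_pulse_volts,
                 channel_volts = channel_volts,
                 sample_rate = sample_rate,
                 pitch = circumference / fringes_per_turn),
            class = "wheel_spec")
}

#' Synthesize quadrature encoder waveforms from a position trace
#'
#' Renders the three digitized encoder channels for a continuous wheel
#' position trace. One fringe (one full A/B square cycle) corresponds
#' to `circumference / fringes_per_turn` cm of travel; channel B lags A
#' by a quarter cycle for forward motion and leads for backward motion.
#' Channel I goes high for 2 ms whenever the index mark (a multiple of
#' the circumference) passes, and at the first sample if the recording
#' starts on the mark. Toggles are edge-exact at the sampling grid: a
#' fringe boundary falling between samples toggles at the next sample.
#'
#' @param position Numeric vector, wheel position in cm (signed,
#'   cumulative), sampled at `spec$sample_rate`.
#' @param spec A [wheel_spec()].
#' @return An `encoder_recording` list: `channel_I`, `channel_A`,
#'   `channel_B` (V), `sample_rate`, `wheel`.
#' @export
synthesize_encoder <- function(position, spec = wheel_spec()) {
  stopifnot(inherits(spec, "wheel_spec"), is.numeric(position))
  pitch <- spec$pitch
  dp <- diff(position)
  if (length(dp) && max(abs(dp)) >= pitch) {
    stop("aliasing: speed implies >= 1 fringe per sample; raise sample_rate")
  }
  # quarter-cycle index within one fringe; gray-coded so exactly one
  # channel toggles per quarter step
  q <- floor(4 * position / pitch) %% 4
  a <- as.numeric(q == 1 | q == 2) * spec$channel_volts
  b <- as.numeric(q == 2 | q == 3) * spec$channel_volts
  # index pulses: 2 ms high at every crossing of a circumference multiple
  turn <- floor(position / spec$circumference)
  cross <- which(diff(turn) != 0) + 1L
  if (abs(position[1]) %% spec$circumference < pitch) cross <- c(1L, cross)
  i <- numeric(length(position))
  w <- max(1L, round(0.002 * spec$sample_rate))
  for (cix in cross) i[cix:min(cix + w - 1L, length(i))] <- spec$index_pulse_volts
  structure(list(channel_I = i, channel_A = a, channel_B = b,
                 sample_rate = spec$sample_rate, wheel = spec),
            class = "encoder_recording")
}
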