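#' Gait / behaviour profile for the synthetic session generator
#'
#' Describes a head-fixed session as an ordered plan of behavioural
#' epochs. Locomotion epochs carry a base speed; the gait model turns
#' that into a speed trace oscillating at twice the limb frequency
#' (the two forelimbs are anti-phase, so the wheel is pulled twice per
#' full limb cycle).
#'
#' @param epoch_plan data.frame with columns `state` (one of
#'   `"immobility"`, `"flickering"`, `"locomotion"`) and `duration`
#'   (seconds). Optionally a `speed` column giving the base speed of
#'   each locomotion epoch (cm/s); rows for other states ignore it.
#' @param base_speed Default base locomotion speed in cm/s, used where
#'   the plan has no `speed` column. Default 7.5 cm/s, a typical median
#'   locomotion speed for habituated head-fixed mice.
#' @param step_length_limb Distance the wheel travels per limb step
#'   cycle, cm. Default 5.0.
#' @param limb_frequency Limb step frequency in Hz, or `NULL` (default)
#'   to derive it per epoch as `speed / step_length_limb`.
#' @param oscillation_depth Fraction of the base speed modulated by the
#'   rectified-sinusoid gait oscillation (0 = constant speed). Default 0.6.
#' @param sample_rate Sampling rate, Hz. Default 10000.
#' @param seed Integer seed for the (small) stochastic components.
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(epoch_plan,
                         base_speed = 7.5,
                         step_length_limb = 5.0,
                         limb_frequency = NULL,
                         oscillation_depth = 0.6,
                         sample_rate = 10000,
                         seed = NULL) {
  stopifnot(is.data.frame(epoch_plan),
            all(c("state", "duration") %in% names(epoch_plan)))
  states <- as.character(epoch_plan$state)
  if (!all(states %in% c("immobility", "flickering", "locomotion"))) {
    stop("epoch_plan$state must be immobility/flickering/locomotion")
  }
  if (any(epoch_plan$duration <= 0)) stop("epoch durations must be positive")
  if (base_speed < 0) stop("base_speed must be >= 0")
  if (step_length_limb <= 0) stop("step_length_limb must be > 0")
  if (oscillation_depth < 0 || oscillation_depth >= 1) {
    stop("oscillation_depth must be in [0, 1)")
  }
  structure(list(
    epoch_plan = data.frame(state = states,
                            duration = epoch_plan$duration,
                            speed = if ("speed" %in% names(epoch_plan))
                              epoch_plan$speed else rep(base_speed, length(states))),
    duration = sum(epoch_plan$duration),
    base_speed = base_speed,
    step_length_limb = step_length_limb,
    limb_frequency = limb_frequency,
    oscillation_depth = oscillation_depth,
    sample_rate = sample_rate,
    seed = seed
  ), class = "gait_profile")
}

#' Simulate wheel speed, position and gait ground truth
#'
#' Generates the per-sample speed and position of the wheel together
#' with ground-truth behaviour labels, limb contact signals and step
#' times. During locomotion the speed is a smoothed baseline plus a
#' rectified-sinusoid oscillation at twice the limb frequency; during
#' flickering the speed wanders inside (0.25, 2) cm/s; immobility is
#' exactly zero.
#'
#' @param profile A [gait_profile()].
#' @return List with elements `time` (s), `speed` (cm/s), `position`
#'   (cm, cumulative), `labels` (character per sample), `steps`
#'   (data.frame: `time`, `limb`, `length_limb`), `limb_left`,
#'   `limb_right` (contact signals in \[0, 1\]), and `sample_rate`.
#' @export
simulate_gait <- function(profile) {
  stopifnot(inherits(profile, "gait_profile"))
  fs <- profile$sample_rate
  plan <- profile$epoch_plan
  with_seed(profile$seed, {
    speed <- numeric(0)
    labels <- character(0)
    limb_l <- numeric(0)
    limb_r <- numeric(0)
    steps <- list()
    t0 <- 0
    for (k in seq_len(nrow(plan))) {
      n <- round(plan$duration[k] * fs)
      tt <- seq_len(n) / fs
      st <- plan$state[k]
      if (st == "immobility") {
        v <- numeric(n)
        ll <- numeric(n); lr <- numeric(n)
      } else if (st == "flickering") {
        # slow sub-threshold wobble, kept strictly inside (0.25, 2) cm/s
        ph <- stats::runif(1, 0, 2 * pi)
        v <- 1.1 + 0.7 * sin(2 * pi * 0.4 * tt + ph)
        ll <- numeric(n); lr <- numeric(n)
      } else {
        vb <- plan$speed[k]
        if (vb <= 0) stop("locomotion epoch with non-positive speed")
        f_limb <- if (is.null(profile$limb_frequency))
          vb / profile$step_length_limb else profile$limb_frequency
        f_osc <- 2 * f_limb  # anti-phase limbs: two pulls per limb cycle
        d <- profile$oscillation_depth
        osc <- abs(sin(pi * f_osc * tt))  # period 1/f_osc, mean 2/pi
        v <- vb * ((1 - d) + d * (pi / 2) * osc)
        ll <- sin(pi * f_limb * tt)^2      # contact bumps, period 1/f_limb
        lr <- cos(pi * f_limb * tt)^2      # anti-phase
        # limb contact times: one step per limb per limb cycle
        t_l <- seq(0.5 / (2 * f_limb), plan$duration[k], by = 1 / f_limb)
        t_r <- seq(0.5 / (2 * f_limb) + 0.5 / f_limb, plan$duration[k],
                   by = 1 / f_limb)
        if (length(t_l) || length(t_r)) {
          steps[[length(steps) + 1L]] <- data.frame(
            time = t0 + c(t_l, t_r),
            limb = rep(c("left", "right"), c(length(t_l), length(t_r))),
            length_limb = vb / f_limb
          )
        }
      }
      speed <- c(speed, v)
      labels <- c(labels, rep(st, n))
      limb_l <- c(limb_l, ll)
      limb_r <- c(limb_r, lr)
      t0 <- t0 + plan$duration[k]
    }
    steps <- if (length(steps)) {
      out <- do.call(rbind, steps)
      out[order(out$time), , drop = FALSE]
    } else {
      data.frame(time = numeric(0), limb = character(0),
                 length_limb = numeric(0))
    }
    n <- length(speed)
    list(time = seq_len(n) / fs,
         speed = speed,
         position = cumsum(speed) / fs,
         labels = labels,
         steps = steps,
         limb_left = limb_l,
         limb_right = limb_r,
         sample_rate = fs)
  })
}
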