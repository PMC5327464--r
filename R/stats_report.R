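#' Permutation (bootstrap) test for a trend across days
#'
#' Compares the least-squares slope of value against day with the
#' slopes of `n_surrogates` full reshuffles of the values across days
#' (random permutation of the whole dataset, preserving the value
#' multiset and destroying temporal order). The trend is significantly
#' positive when the observed slope exceeds the 95th percentile of the
#' surrogate slopes, negative when it is below the 5th.
#'
#' @param values Numeric vector of observations.
#' @param days Numeric day index per observation (>= 3 distinct days).
#' @param n_surrogates Number of reshuffles. Default 10000.
#' @param lower_pct,upper_pct Surrogate percentiles. Defaults 0.05, 0.95.
#' @param seed Seed for the permutations.
#' @return A `bootstrap_slope` list: `slope`, `surrogate_q` (the two
#'   percentiles), `direction` (`"positive"`, `"negative"`, `"none"`),
#'   `n_surrogates`, `seed`.
#' @export
bootstrap_slope_test <- function(values, days, n_surrogates = 10000,
                                 lower_pct = 0.05, upper_pct = 0.95,
                                 seed = NULL) {
  stopifnot(length(values) == length(days))
  if (length(unique(days)) < 3L) stop("need at least 3 days")
  w <- days - mean(days)
  ssx <- sum(w^2)
  if (ssx == 0) stop("degenerate day index")
  slope <- sum(w * values) / ssx
  if (stats::sd(values) == 0) {
    return(structure(list(slope = 0, surrogate_q = c(0, 0),
                          direction = "none", n_surrogates = n_surrogates,
                          seed = seed), class = "bootstrap_slope"))
  }
  with_seed(seed, {
    surr <- vapply(seq_len(n_surrogates), function(i) {
      sum(w * values[sample.int(length(values))]) / ssx
    }, 0)
  })
  q <- stats::quantile(surr, c(lower_pct, upper_pct), names = FALSE)
  direction <- if (slope > q[2L]) "positive" else
    if (slope < q[1L]) "negative" else "none"
  structure(list(slope = slope, surrogate_q = q, direction = direction,
                 n_surrogates = n_surrogates, seed = seed),
            class = "bootstrap_slope")
}

#' Default configuration for a synthetic session
#'
#' The study conditions for one simulated head-fixed session: a
#' 5-minute recording alternating immobility, flickering and
#' locomotion, the default wheel, LFP and movie generators, and a
#' single top-level seed expanded per stage.
#'
#' @param seed Top-level integer seed.
#' @param duration_s Nominal session length (the epoch plan is built to
#'   roughly this length). Default 300.
#' @param movie_s Length of the imaged sub-session, s. Default 60.
#' @return Config list accepted by [run_session()].
#' @export
session_config <- function(seed = 1, duration_s = 300, movie_s = 60) {
  block <- data.frame(
    state = c("immobility", "flickering", "locomotion",
              "immobility", "locomotion", "flickering",
              "immobility", "locomotion"),
    duration = c(20, 8, 14, 18, 10, 6, 16, 8),
    speed = c(NA, NA, 7.5, NA, 10, NA, NA, 5))
  reps <- max(1L, round(duration_s / sum(block$duration)))
  plan <- do.call(rbind, replicate(reps, block, simplify = FALSE))
  list(seed = seed,
       epoch_plan = plan,
       wheel = wheel_spec(),
       lfp = lfp_gen_spec(seed = seed + 1L),
       movie_s = movie_s,
       movie = movie_gen_spec(seed = seed + 2L,
                              photon_scale = 2, read_noise_sd = 1))
}

#' Load a session configuration from a YAML file
#'
#' Reads `seed`, `duration_s` and `movie_s` (all optional) plus any
#' generator overrides under `lfp` and `movie` (passed to
#' [lfp_gen_spec()] / [movie_gen_spec()]) and returns the
#' corresponding [session_config()].
#'
#' @param path Path to a YAML file.
#' @return Config list accepted by [run_session()].
#' @export
load_session_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  y <- yaml::read_yaml(path)
  pick <- function(name, default) {
    if (!is.null(y[[name]])) y[[name]] else default
  }
  cfg <- session_config(seed = pick("seed", 1),
                        duration_s = pick("duration_s", 300),
                        movie_s = pick("movie_s", 60))
  if (!is.null(y[["lfp"]])) {
    cfg$lfp <- do.call(lfp_gen_spec,
                       c(y[["lfp"]], list(seed = cfg$seed + 1L)))
  }
  if (!is.null(y[["movie"]])) {
    cfg$movie <- do.call(movie_gen_spec,
                         c(y[["movie"]], list(seed = cfg$seed + 2L)))
  }
  cfg
}

#' Run the full synthetic-session pipeline
#'
#' Simulates gait, synthesizes and decodes the encoder, segments
#' behaviour, counts steps, synthesizes and analyses the LFP (ripples,
#' theta), renders a calcium movie, corrects motion, computes the
#' bouton stability map and delta-F/F, detects transients and returns
#' a session report. Stages with missing inputs are skipped with a
#' notice in the report.
#'
#' @param config A [session_config()] list.
#' @param out_dir Optional directory: writes `report.json` plus CSV
#'   tables of the main traces.
#' @return A `session_report` list.
#' @export
run_session <- function(config = session_config(), out_dir = NULL) {
  notices <- character(0)
  prof <- gait_profile(config$epoch_plan, seed = config$seed)
  gait <- simulate_gait(prof)
  rec <- synthesize_encoder(gait$position, config$wheel)
  trace <- decode_quadrature(rec)
  seg <- segment_behaviour(trace)
  steps <- detect_steps(trace, seg)
  behaviour <- list(
    frac_locomotion = mean(seg$labels == "locomotion"),
    frac_flickering = mean(seg$labels == "flickering"),
    frac_immobility = mean(seg$labels == "immobility"),
    median_speed = stats::median(abs(trace$speed)[seg$is_locomotion]),
    total_distance = sum(abs(diff(trace$position))),
    n_steps = steps$n_steps,
    median_step_length_limb = stats::median(steps$step_lengths_limb),
    n_invalid_transitions = trace$n_invalid)

  lfp_block <- NULL
  if (!is.null(config[["lfp"]])) {
    lf <- synthesize_lfp(gait$labels, gait$speed, config$lfp,
                         sample_rate = gait$sample_rate)
    rip <- detect_ripples(lf$lfp, lf$sample_rate, labels = gait$labels)
    th <- theta_profile(lf$lfp, lf$sample_rate, abs(trace$speed))
    lfp_block <- list(ripple_stats = rip$stats,
                      theta_freq_slope = th$freq_fit$slope,
                      theta_power_slope = th$power_fit$slope,
                      theta_freq_r = th$freq_fit$r)
  } else notices <- c(notices, "lfp stage skipped: no lfp config")

  imaging_block <- NULL
  if (!is.null(config[["movie"]])) {
    n_frames <- round(config$movie_s * config$movie$frame_rate)
    lab_f <- block_downsample(gait$labels[seq_len(config$movie_s *
                                                    gait$sample_rate)],
                              n_frames)
    sp_f <- block_downsample(gait$speed[seq_len(config$movie_s *
                                                  gait$sample_rate)],
                             n_frames)
    mv <- synthesize_movie(lab_f, sp_f, config$movie)
    mc <- motion_correct(mv, labels = lab_f)
    ms <- motion_by_state(mc, lab_f, mv$frame_rate)
    bouton <- which(config$movie$structures$kind == "bouton")[1L]
    tr_raw <- vapply(seq_len(dim(mc$frames)[3]), function(f) {
      mean(mc$frames[, , f][mv$ground_truth$roi_masks[[bouton]]])
    }, 0)
    dd <- dff(tr_raw)
    ts <- detect_transients(dd$dff, mv$frame_rate)
    imaging_block <- list(median_motion_stable_um = ms$median_stable_um,
                          median_motion_locomotion_um = ms$median_locomotion_um,
                          motion_fold_change = ms$fold_change,
                          f0 = dd$f0,
                          n_transients = ts$n,
                          transient_rate_hz = ts$rate_hz)
  } else notices <- c(notices, "imaging stage skipped: no movie config")

  report <- structure(list(behaviour = behaviour,
                           lfp = lfp_block,
                           imaging = imaging_block,
                           notices = notices,
                           seed = config$seed),
                      class = "session_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(seg$epochs, file.path(out_dir, "epochs.csv"),
                     row.names = FALSE)
  }
  report
}
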