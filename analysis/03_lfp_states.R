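#!/usr/bin/env Rscript
# Hippocampal state detection on a synthetic session: ripple events
# during immobility (frequency, duration, occurrence), the theta
# frequency/power vs running-speed profile, and the overlap between
# theta epochs and locomotion.

suppressMessages(library(wheelphys))

out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 20260921L
fs <- 10000

set.seed(seed)
plan <- do.call(rbind, lapply(1:20, function(k) {
  data.frame(state = c("locomotion", "immobility"),
             duration = c(10, 14),
             speed = c(stats::runif(1, 3, 25), NA))
}))
g <- simulate_gait(gait_profile(plan, seed = seed))
lf <- synthesize_lfp(g$labels, g$speed, lfp_gen_spec(seed = seed + 1L),
                     sample_rate = fs)

rip <- detect_ripples(lf$lfp, fs, labels = g$labels)
truth <- lf$ground_truth$ripples
message(sprintf(
  "ripples: %d detected / %d injected; occurrence %.3f Hz (true %.3f)",
  rip$stats$n, nrow(truth), rip$stats$occurrence_hz,
  nrow(truth) / lf$ground_truth$immobility_s))
message(sprintf("  median frequency %.1f Hz (injected %.1f), duration %.1f ms",
                rip$stats$median_freq, median(truth$freq),
                rip$stats$median_duration_ms))
utils::write.csv(rip$events, file.path(out, "ripple_events.csv"),
                 row.names = FALSE)

th <- theta_profile(lf$lfp, fs, g$speed)
message(sprintf(
  "theta: frequency slope %.4f Hz/(cm/s) (generator 0.0100), r = %.2f, p = %.2g",
  th$freq_fit$slope, th$freq_fit$r, th$freq_fit$p))
message(sprintf("       power slope %.4f dB/(cm/s), r = %.2f",
                th$power_fit$slope, th$power_fit$r))
utils::write.csv(th$bins, file.path(out, "theta_speed_bins.csv"),
                 row.names = FALSE)

seg <- segment_behaviour(decode_quadrature(synthesize_encoder(g$position)))
ov <- state_overlap(lf$lfp, fs, seg)
message(sprintf(
  "overlap: %.0f%% of locomotion episodes contain theta; %.0f%% of theta time is in locomotion",
  100 * ov$frac_loco_episodes_with_theta, 100 * ov$frac_theta_in_locomotion))

jsonlite::write_json(list(
  ripple_stats = rip$stats,
  theta_freq_fit = th$freq_fit, theta_power_fit = th$power_fit,
  overlap = ov[c("frac_loco_episodes_with_theta",
                 "frac_theta_in_locomotion")]),
  file.path(out, "lfp_summary.json"), auto_unbox = TRUE, digits = NA)
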