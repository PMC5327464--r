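#!/usr/bin/env Rscript
# Decode the encoder, segment behaviour, count steps, and quantify
# habituation across seven simulated days: per-day state fractions,
# median locomotion speed and speed stereotypy, with the permutation
# slope test for day trends and the intra/inter-individual
# variability comparison.

suppressMessages(library(wheelphys))

out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 20260921L

day_plan <- function(day) {
  # habituation: flickering shrinks and locomotion speeds up over days
  flick <- max(2, 10 - day)
  v <- 5 + 0.6 * min(day, 4)
  do.call(rbind, replicate(3, data.frame(
    state = c("immobility", "flickering", "locomotion"),
    duration = c(15, flick, 20),
    speed = c(NA, NA, v)), simplify = FALSE))
}

days <- lapply(1:7, function(d) {
  g <- simulate_gait(gait_profile(day_plan(d), seed = seed + d))
  tr <- decode_quadrature(synthesize_encoder(g$position))
  seg <- segment_behaviour(tr)
  st <- detect_steps(tr, seg)
  list(trace = tr, seg = seg, steps = st)
})

hm <- habituation_metrics(days)
utils::write.csv(hm, file.path(out, "habituation.csv"), row.names = FALSE)
message("per-day metrics:")
print(hm, digits = 3)

flick_trend <- bootstrap_slope_test(hm$frac_flickering, hm$day,
                                    seed = seed)
speed_trend <- bootstrap_slope_test(hm$median_speed, hm$day, seed = seed + 1L)
message(sprintf("flickering fraction trend: slope %.4f/day, %s",
                flick_trend$slope, flick_trend$direction))
message(sprintf("median speed trend:        slope %.3f cm/s/day, %s",
                speed_trend$slope, speed_trend$direction))

st_all <- days[[7]]$steps
message(sprintf("day 7: %d steps, median limb step %.2f cm, rate %.2f Hz",
                st_all$n_steps, median(st_all$step_lengths_limb),
                st_all$step_rate))

# intra- vs inter-individual variability on a 5-mouse x 7-day grid of
# locomotion probabilities (each mouse gets its own habituation curve)
set.seed(seed)
prob <- sapply(1:7, function(d) {
  base <- c(0.30, 0.40, 0.50, 0.60, 0.70)          # mouse identities
  pmin(0.95, pmax(0.05, base + 0.01 * d + stats::rnorm(5, 0, 0.03)))
})
v_intra <- variability(prob, "intra")
v_inter <- variability(prob, "inter")
message(sprintf("variability: intra %.3f, inter %.3f (inter > intra: %s)",
                v_intra$V, v_inter$V, v_inter$V > v_intra$V))
jsonlite::write_json(list(
  flickering_trend = flick_trend[c("slope", "direction")],
  speed_trend = speed_trend[c("slope", "direction")],
  variability_intra = v_intra$V, variability_inter = v_inter$V),
  file.path(out, "behaviour_summary.json"), auto_unbox = TRUE, digits = NA)
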