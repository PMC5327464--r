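#!/usr/bin/env Rscript
# Simulate one head-fixed session: gait-driven wheel position, the
# three digitized encoder channels, a CA1-like LFP with ripples and
# speed-modulated theta, and a two-photon bouton movie. Writes the
# traces (decimated where bulky) and the ground truth under
# results/session/.

suppressMessages(library(wheelphys))

out <- "results/session"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

plan <- do.call(rbind, replicate(3, data.frame(
  state = c("immobility", "flickering", "locomotion",
            "immobility", "locomotion"),
  duration = c(15, 8, 20, 12, 15),
  speed = c(NA, NA, 7.5, NA, 12)), simplify = FALSE))

g <- simulate_gait(gait_profile(plan, seed = seed))
rec <- synthesize_encoder(g$position)
lf <- synthesize_lfp(g$labels, g$speed, lfp_gen_spec(seed = seed + 1L),
                     sample_rate = g$sample_rate)

message(sprintf("session: %.0f s at %d Hz, %d ground-truth steps, %d ripples",
                max(g$time), g$sample_rate, nrow(g$steps),
                nrow(lf$ground_truth$ripples)))

# encoder + LFP traces, decimated 10x for the archive (analysis uses
# the full-rate objects in later scripts, regenerated from the seed)
dec <- seq(1, length(g$time), by = 10)
utils::write.csv(data.frame(time_s = g$time[dec],
                            channel_I = rec$channel_I[dec],
                            channel_A = rec$channel_A[dec],
                            channel_B = rec$channel_B[dec],
                            lfp = lf$lfp[dec],
                            speed_true = g$speed[dec],
                            state_true = g$labels[dec]),
                 file.path(out, "traces_1khz.csv"), row.names = FALSE)
utils::write.csv(g$steps, file.path(out, "steps_truth.csv"),
                 row.names = FALSE)
utils::write.csv(lf$ground_truth$ripples,
                 file.path(out, "ripples_truth.csv"), row.names = FALSE)

# 60 s calcium movie at 30 Hz, multi-page TIFF if the tiff package is
# available (the later scripts regenerate it from the seed)
fr <- 30
nf <- 60 * fr
lab_f <- wheelphys:::block_downsample(g$labels[seq_len(60 * g$sample_rate)], nf)
sp_f <- wheelphys:::block_downsample(g$speed[seq_len(60 * g$sample_rate)], nf)
mv <- synthesize_movie(lab_f, sp_f,
                       movie_gen_spec(seed = seed + 2L, photon_scale = 2,
                                      read_noise_sd = 1))
if (requireNamespace("tiff", quietly = TRUE)) {
  pages <- lapply(seq_len(nf), function(f) {
    m <- mv$frames[, , f]
    pmin(pmax(m / max(m), 0), 1)
  })
  tiff::writeTIFF(pages, file.path(out, "movie.tif"))
  message("wrote ", nf, "-frame movie.tif")
}
jsonlite::write_json(list(seed = seed, plan = plan,
                          movie_frames = nf, frame_rate = fr),
                     file.path(out, "session_meta.json"),
                     auto_unbox = TRUE, digits = NA)
message("session written to ", out)
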