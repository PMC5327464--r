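# Shared fixtures: small synthetic sessions built in code.

fs_enc <- 10000

# A mixed-behaviour plan used across modules.
mixed_plan <- function() {
  data.frame(state = c("immobility", "locomotion", "flickering",
                       "locomotion", "immobility"),
             duration = c(10, 20, 8, 15, 10),
             speed = c(NA, 10, NA, 7.5, NA))
}

# Frame-rate behaviour labels/speed for movie tests.
frame_session <- function(frame_rate = 30, block_s = 40, loco_s = 20,
                          reps = 2, speed_cms = 10) {
  labels <- rep(rep(c("immobility", "locomotion"),
                    times = c(round((block_s - loco_s) * frame_rate),
                              round(loco_s * frame_rate))), reps)
  list(labels = labels,
       speed = ifelse(labels == "locomotion", speed_cms, 0),
       frame_rate = frame_rate)
}

# GCaMP6f-like trace with injected transients at known times.
transient_trace <- function(n_s = 300, frame_rate = 30, amp = 1,
                            noise_sd = 0.05, n_events = 15, seed = 2) {
  set.seed(seed)
  n <- n_s * frame_rate
  kern <- wheelphys:::transient_kernel(frame_rate, 0.03, 0.4)
  tr <- stats::rnorm(n, 0, noise_sd)
  ev <- sort(sample(100:(n - length(kern) - 10), n_events))
  for (e in ev) {
    idx <- e:(e + length(kern) - 1L)
    tr[idx] <- tr[idx] + amp * kern[seq_along(idx)]
  }
  list(trace = tr, events = ev, frame_rate = frame_rate)
}
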