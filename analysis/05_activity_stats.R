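#!/usr/bin/env Rscript
# Population activity statistics on synthetic traces: adaptive
# skewness-zero thresholds, per-500-ms population sparseness, pairwise
# correlations, and the speed-calcium covariance significance of a
# locomotion-locked interneuron-like trace.

suppressMessages(library(wheelphys))

out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 20260921L
fr <- 30
n_s <- 300
n_cells <- 25

set.seed(seed)
kern <- wheelphys:::transient_kernel(fr, 0.03, 0.4)
n <- n_s * fr
traces <- sapply(seq_len(n_cells), function(c0) {
  tr <- stats::rnorm(n, 0, 0.05)
  n_ev <- stats::rpois(1, 0.05 * n_s)            # sparse pyramidal firing
  for (e in sample(seq_len(n - length(kern)), n_ev)) {
    idx <- e:(e + length(kern) - 1L)
    tr[idx] <- tr[idx] + stats::rlnorm(1, log(0.8), 0.4) * kern[seq_along(idx)]
  }
  tr
})

sp <- population_sparseness(traces, fr)
message(sprintf("sparseness: median %.2f (IQR %.2f-%.2f) across %d bins",
                median(sp$fraction_off),
                quantile(sp$fraction_off, 0.25),
                quantile(sp$fraction_off, 0.75), length(sp$fraction_off)))
utils::write.csv(data.frame(bin = seq_along(sp$fraction_off),
                            fraction_off = sp$fraction_off),
                 file.path(out, "sparseness.csv"), row.names = FALSE)

pc <- pairwise_correlations(traces)
message(sprintf("pairwise correlation: 75th percentile %.3f over %d pairs",
                pc$q75, length(pc$values)))

# per-cell transient statistics
ts_all <- lapply(seq_len(n_cells), function(c0)
  detect_transients(traces[, c0], fr))
rates <- vapply(ts_all, function(t) t$rate_hz, 0)
rises <- unlist(lapply(ts_all, function(t) t$rise_times_ms))
message(sprintf("transients: median rate %.3f Hz, median rise %.0f ms",
                median(rates), median(rises)))

# locomotion-locked interneuron-like trace vs speed
lab <- rep(rep(c("immobility", "locomotion"), times = c(20 * fr, 20 * fr)),
           length.out = n)
speed <- wheelphys:::rolling_mean(ifelse(lab == "locomotion", 10, 0), fr)
vip <- 0.08 * speed + stats::rnorm(n, 0, 0.05)
cv <- speed_covariance(vip, speed, fr, labels = lab, seed = seed + 1L)
message(sprintf(
  "speed covariance: peak %.2f (99%% max-stat threshold %.2f) -> %s",
  cv$max_stat, cv$max_null_pct,
  if (cv$significant) "significant" else "not significant"))

jsonlite::write_json(list(
  sparseness_median = median(sp$fraction_off),
  pairwise_q75 = pc$q75,
  transient_rate_median = median(rates),
  rise_time_median_ms = median(rises),
  speed_cov_significant = cv$significant),
  file.path(out, "activity_summary.json"), auto_unbox = TRUE, digits = NA)
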