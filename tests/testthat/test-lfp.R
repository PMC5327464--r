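test_that("band-pass keeps in-band tones and attenuates out-of-band ones", {
  fs <- 2000
  tt <- seq_len(4 * fs) / fs
  x150 <- sin(2 * pi * 150 * tt)
  y150 <- bandpass(x150, fs, 100, 250)
  mid <- (fs):(3 * fs)
  expect_equal(stats::sd(y150[mid]) / stats::sd(x150[mid]), 1, tolerance = 0.05)
  x50 <- sin(2 * pi * 50 * tt)
  y50 <- bandpass(x50, fs, 100, 250)
  atten_db <- 20 * log10(stats::sd(y50[mid]) / stats::sd(x50[mid]))
  expect_lt(atten_db, -20)
  expect_identical(bandpass(numeric(100), fs, 100, 250), numeric(100))
  expect_error(bandpass(x50, fs, 100, 1100), "band")
})

test_that("a constructed burst yields one ripple at its carrier frequency", {
  fs <- 10000
  set.seed(5)
  noise <- wheelphys:::pink_noise(30 * fs, 1)
  bsd <- stats::sd(bandpass(noise, fs, 100, 250))
  tt <- seq(-0.03, 0.03, by = 1 / fs)
  burst <- 10 * bsd * exp(-tt^2 / (2 * 0.0125^2)) * cos(2 * pi * 150 * tt)
  x <- noise
  c0 <- 15 * fs
  x[c0:(c0 + length(tt) - 1L)] <- x[c0:(c0 + length(tt) - 1L)] + burst
  rip <- detect_ripples(x, fs)
  expect_equal(rip$stats$n, 1L)
  expect_equal(rip$events$freq, 150, tolerance = 10)
  expect_equal(rip$events$peak_time, 15, tolerance = 0.05)
  # occurrence is N / D
  expect_equal(rip$stats$occurrence_hz, 1 / 30)
  # frequency is invariant to amplitude rescaling of the LFP
  rip2 <- detect_ripples(5 * x, fs)
  expect_equal(rip2$events$freq, rip$events$freq)
  expect_error(detect_ripples(x[1:100], fs), "100 ms")
})

test_that("ripple occurrence arithmetic and duration are reported", {
  fs <- 10000
  lab <- rep("immobility", 60 * fs)
  lf <- synthesize_lfp(lab, numeric(length(lab)),
                       lfp_gen_spec(seed = 21, ripple_rate = 0.1),
                       sample_rate = fs)
  rip <- detect_ripples(lf$lfp, fs, labels = lab)
  expect_equal(rip$stats$occurrence_hz, rip$stats$n / 60)
  if (rip$stats$n > 0) {
    expect_true(all(rip$events$n_cycles >= 4))
    expect_true(all(rip$events$freq >= 100 & rip$events$freq <= 250))
  }
})

test_that("theta weighted frequency reads pure tones and tracks chirps", {
  fs <- 2000
  tt <- seq_len(60 * fs) / fs
  th <- theta_profile(sin(2 * pi * 8 * tt), fs, rep(0, length(tt)))
  expect_equal(mean(th$freq), 8.0, tolerance = 0.1)
  expect_true(th$undefined)       # all-immobile: fit flagged
  # amplitude independence
  th5 <- theta_profile(5 * sin(2 * pi * 8 * tt), fs, rep(0, length(tt)))
  expect_equal(mean(th5$freq), mean(th$freq), tolerance = 1e-6)
  # linear chirp 5 -> 15 Hz: monotonically increasing estimate
  f_inst <- 5 + 10 * tt / max(tt)
  chirp <- sin(2 * pi * cumsum(f_inst) / fs)
  thc <- theta_profile(chirp, fs, rep(0, length(tt)))
  n <- length(thc$freq)
  core <- thc$freq[round(0.1 * n):round(0.9 * n)]
  sm <- wheelphys:::rolling_mean(core, 201)
  expect_gt(mean(diff(sm) > -1e-6), 0.95)
  expect_gt(utils::tail(sm, 1), utils::head(sm, 1) + 5)
})

test_that("state overlap fractions follow the masks", {
  fs <- 100
  labels <- rep(c("immobility", "locomotion"), each = 10 * fs)
  seg <- list(labels = labels,
              is_locomotion = labels == "locomotion",
              epochs = data.frame(state = c("immobility", "locomotion"),
                                  start = c(0, 10), end = c(10, 20)))
  # theta exactly equal to locomotion
  ov <- state_overlap(NULL, fs, seg, theta_mask = seg$is_locomotion)
  expect_equal(ov$frac_loco_episodes_with_theta, 1)
  expect_equal(ov$frac_theta_in_locomotion, 1)
  # theta never present: 0 and flagged undefined
  ov0 <- state_overlap(NULL, fs, seg,
                       theta_mask = rep(FALSE, length(labels)))
  expect_equal(ov0$frac_loco_episodes_with_theta, 0)
  expect_true(is.na(ov0$frac_theta_in_locomotion))
  # constructed half-overlap: theta covers half the locomotion time and
  # equal time in immobility
  half <- rep(FALSE, length(labels))
  half[(5 * fs):(15 * fs - 1)] <- TRUE
  ovh <- state_overlap(NULL, fs, seg, theta_mask = half)
  expect_equal(ovh$frac_theta_in_locomotion, 0.5, tolerance = 0.01)
})
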