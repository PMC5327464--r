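test_that("flat channels decode to zero displacement and speed", {
  rec <- list(channel_I = rep(0, 5000), channel_A = rep(0, 5000),
              channel_B = rep(0, 5000), sample_rate = fs_enc,
              wheel = wheel_spec())
  tr <- decode_quadrature(rec)
  expect_true(all(tr$position == 0))
  expect_true(all(tr$speed == 0))
})

test_that("one quadrature cycle with A leading B decodes to one fringe", {
  w <- wheel_spec()
  # hand-enumerated gray sequence: (A,B) 00 -> 10 -> 11 -> 01 -> 00
  a <- rep(c(0, 5, 5, 0, 0), each = 10)
  b <- rep(c(0, 0, 5, 5, 0), each = 10)
  rec <- list(channel_I = rep(0, 50), channel_A = a, channel_B = b,
              sample_rate = fs_enc, wheel = w)
  tr <- decode_quadrature(rec)
  expect_equal(tr$position[length(tr$position)], 24.19 / 500,
               tolerance = 1e-12)
  # reversing the sequence negates the displacement exactly
  rec_r <- rec
  rec_r$channel_A <- rev(a); rec_r$channel_B <- rev(b)
  tr_r <- decode_quadrature(rec_r)
  expect_equal(tr_r$position[length(tr_r$position)], -24.19 / 500,
               tolerance = 1e-12)
})

test_that("encoder round trip recovers position within a fringe and speed within 2%", {
  prof <- gait_profile(mixed_plan(), seed = 42)
  g <- simulate_gait(prof)
  tr <- decode_quadrature(synthesize_encoder(g$position))
  expect_lt(max(abs(tr$position - g$position)), wheel_spec()$pitch)
  # decoded speed is the 100 ms-smoothed derivative: compare against
  # the true speed smoothed identically; the per-sample error floor is
  # the quarter-fringe resolution over the window (0.12 cm/s), so the
  # relative check is on the median and the absolute one on the q99
  truth <- wheelphys:::rolling_mean(g$speed, 1001)
  fast <- truth >= 1
  rel <- abs(tr$speed[fast] - truth[fast]) / truth[fast]
  expect_lt(stats::median(rel), 0.02)
  expect_lt(stats::quantile(abs(tr$speed[fast] - truth[fast]), 0.99,
                            names = FALSE), 2 * 0.121)
  expect_equal(tr$n_invalid, 0L)
})

test_that("per-turn median speed is displacement over time", {
  w <- wheel_spec()
  v <- w$circumference / 2.0               # one turn in exactly 2 s
  n <- round(1.02 * 2.0 * fs_enc)
  pos <- v * seq_len(n) / fs_enc
  tr <- decode_quadrature(synthesize_encoder(pos, w))
  ts <- median_speed_per_turn(tr)
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$speed, 12.095, tolerance = 0.001)
  # stationary wheel: no turn peaks, empty with warning
  rec0 <- synthesize_encoder(rep(3.7, 2000), w)
  expect_warning(ts0 <- median_speed_per_turn(decode_quadrature(rec0)))
  expect_equal(nrow(ts0), 0L)
})

test_that("behaviour segmentation applies the speed and distance rules", {
  fs <- 1000
  mk <- function(speed_vec) {
    list(speed = speed_vec, position = cumsum(speed_vec) / fs,
         sample_rate = fs)
  }
  # 3 cm/s sustained over > 2 cm -> one locomotion epoch
  seg <- segment_behaviour(mk(rep(3, 2 * fs)))
  expect_true(all(seg$labels == "locomotion"))
  expect_equal(sum(seg$epochs$state == "locomotion"), 1L)
  # constant 1 cm/s -> all flickering
  expect_true(all(segment_behaviour(mk(rep(1, fs)))$labels == "flickering"))
  # zero speed -> all immobility
  expect_true(all(segment_behaviour(mk(rep(0, fs)))$labels == "immobility"))
  # fast but sub-distance run stays flickering
  burst <- c(rep(0, fs), rep(3, round(0.2 * fs)), rep(0, fs))
  seg_b <- segment_behaviour(mk(burst))
  expect_false(any(seg_b$labels == "locomotion"))
  # appending immobility padding does not change existing labels
  padded <- segment_behaviour(mk(c(rep(3, 2 * fs), rep(0, fs))))
  expect_identical(padded$labels[1:(2 * fs)], seg$labels)
})

test_that("step detection counts speed-oscillation peaks and obeys the twofold rule", {
  fs <- 1000
  # constant speed: no oscillation, no steps
  tr_const <- list(speed = rep(10, 10 * fs),
                   position = cumsum(rep(10, 10 * fs)) / fs,
                   sample_rate = fs)
  seg_c <- segment_behaviour(tr_const)
  expect_equal(detect_steps(tr_const, seg_c)$n_steps, 0L)
  # 4 Hz oscillation sustained 10 s -> 40 step events
  tt <- seq_len(10 * fs) / fs
  sp <- 10 * (0.4 + 0.6 * (pi / 2) * abs(sin(pi * 4 * tt)))
  tr_osc <- list(speed = sp, position = cumsum(sp) / fs, sample_rate = fs)
  st <- detect_steps(tr_osc, segment_behaviour(tr_osc))
  expect_equal(st$n_steps, 40, tolerance = 0.03)
  # synthetic gait with 5 cm limb steps: speed-signal step ~2.5, limb ~5
  g <- simulate_gait(gait_profile(mixed_plan(), seed = 42))
  tr <- decode_quadrature(synthesize_encoder(g$position))
  seg <- segment_behaviour(tr)
  sg <- detect_steps(tr, seg)
  expect_equal(stats::median(sg$step_lengths_speed), 2.5, tolerance = 0.1)
  expect_equal(stats::median(sg$step_lengths_limb), 5.0, tolerance = 0.2)
  expect_identical(sg$step_lengths_limb, 2 * sg$step_lengths_speed)
  # step count x mean limb step ~ locomotion distance
  loco_dist <- sum(seg$epochs$distance[seg$epochs$state == "locomotion"])
  est <- sg$n_steps * mean(sg$step_lengths_limb) / 2
  expect_equal(est, loco_dist, tolerance = 0.1)
})

test_that("stereotypy is iqr over median with its stated properties", {
  expect_equal(stereotypy(rep(7.5, 10))$phi, 0)
  u <- seq(0.001, 1, length.out = 100001)
  expect_equal(stereotypy(u)$phi, 1.0, tolerance = 0.01)
  d <- stats::rlnorm(500)
  expect_equal(stereotypy(d)$phi, stereotypy(3 * d)$phi)
  expect_error(stereotypy(c(1, 2, 3)), "4")
  expect_error(stereotypy(c(-2, -1, 0, 1)), "median")
})

test_that("variability separates intra- from inter-individual spread", {
  # 5 mice x 7 days, each mouse constant across days but mice differ
  prob <- matrix(rep(c(0.2, 0.4, 0.5, 0.7, 0.9), 7), nrow = 5)
  v_intra <- variability(prob, "intra")
  v_inter <- variability(prob, "inter")
  expect_equal(v_intra$V, 0)
  expect_gt(v_inter$V, 0)
  # identical everywhere: both zero
  expect_equal(variability(matrix(0.5, 5, 7), "inter")$V, 0)
  # permuting days within a mouse leaves intra unchanged
  prob2 <- matrix(stats::runif(35), nrow = 5)
  perm <- prob2[, sample(7)]
  expect_equal(variability(prob2, "intra")$V, variability(perm, "intra")$V)
  expect_warning(variability(cbind(prob2[, 1:6], NA), "intra"), "missing")
})

test_that("habituation metrics partition time and track per-day state fractions", {
  mk_day <- function(seed) {
    g <- simulate_gait(gait_profile(mixed_plan(), seed = seed))
    tr <- decode_quadrature(synthesize_encoder(g$position))
    list(trace = tr, seg = segment_behaviour(tr))
  }
  days <- list(mk_day(1), mk_day(2))
  hm <- habituation_metrics(days)
  expect_equal(nrow(hm), 2L)
  sums <- hm$frac_locomotion + hm$frac_flickering + hm$frac_immobility
  expect_equal(sums, rep(1, 2), tolerance = 1e-12)
  expect_true(all(hm$median_speed > 2))
  expect_error(habituation_metrics(days[1]), "2 days")
})
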