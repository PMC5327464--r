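test_that("degenerate all-immobility plan gives zero speed and no steps", {
  prof <- gait_profile(data.frame(state = "immobility", duration = 5), seed = 1)
  g <- simulate_gait(prof)
  expect_true(all(g$speed == 0))
  expect_equal(nrow(g$steps), 0L)
  expect_equal(g$position[length(g$position)], 0)
})

test_that("gait rates follow speed / step length and limbs are anti-phase", {
  prof <- gait_profile(data.frame(state = "locomotion", duration = 10,
                                  speed = 10), seed = 2)
  g <- simulate_gait(prof)
  # 10 cm/s with 5 cm limb steps: 2 contacts/s per limb, 4 speed peaks/s
  expect_equal(sum(g$steps$limb == "left"), 20, tolerance = 0.05)
  expect_equal(mean(g$steps$length_limb), 5.0)
  pk <- wheelphys:::find_peaks(g$speed, min_distance = 0.1 * g$sample_rate,
                               min_prominence = 1)
  expect_equal(length(pk), 40, tolerance = 0.05)
  # anti-phase contact signals
  expect_lt(stats::cor(g$limb_left, g$limb_right), -0.9)
})

test_that("gait generation is deterministic under a fixed seed and speed integrates to position", {
  prof <- gait_profile(mixed_plan(), seed = 42)
  g1 <- simulate_gait(prof)
  g2 <- simulate_gait(prof)
  expect_identical(g1$speed, g2$speed)
  expect_identical(g1$steps, g2$steps)
  expect_equal(g1$position[length(g1$position)],
               sum(g1$speed) / g1$sample_rate)
})

test_that("invalid gait plans are rejected", {
  expect_error(gait_profile(data.frame(state = "running", duration = 5)))
  expect_error(gait_profile(data.frame(state = "immobility", duration = -1)))
})

test_that("encoder channels are flat without motion and alias above the fringe limit", {
  rec <- synthesize_encoder(rep(0, 1000))
  expect_true(all(rec$channel_A == rec$channel_A[1]))
  expect_true(all(rec$channel_B == rec$channel_B[1]))
  # > 1 fringe per sample must error
  fast <- seq(0, 100, length.out = 100)   # ~1 cm per sample
  expect_error(synthesize_encoder(fast), "aliasing")
})

test_that("forward then equal backward travel reverses phase and preserves net index count", {
  w <- wheel_spec()
  v <- 10
  t_half <- seq_len(2 * fs_enc) / fs_enc
  pos <- c(v * t_half, v * 2 - v * t_half)
  rec <- synthesize_encoder(pos, w)
  tr <- decode_quadrature(rec)
  expect_lt(abs(tr$position[length(tr$position)]), w$pitch)
  # phase relation: decoded direction flips sign between halves
  n <- length(pos)
  expect_gt(mean(tr$speed[1000:(n / 2 - 1000)]), 9)
  expect_lt(mean(tr$speed[(n / 2 + 1000):(n - 1000)]), -9)
})

test_that("LFP generator honours rates and theta frequency law", {
  fs <- 2000
  lab <- rep("immobility", 60 * fs)
  lf0 <- synthesize_lfp(lab, numeric(length(lab)),
                        lfp_gen_spec(seed = 1, ripple_rate = 0,
                                     theta_amplitude = 0), sample_rate = fs)
  expect_equal(nrow(lf0$ground_truth$ripples), 0L)
  # Poisson expectation on a longer immobility stretch
  lab2 <- rep("immobility", 600 * fs)
  lf1 <- synthesize_lfp(lab2, numeric(length(lab2)),
                        lfp_gen_spec(seed = 2, ripple_rate = 0.1,
                                     theta_amplitude = 0), sample_rate = fs)
  expect_gt(nrow(lf1$ground_truth$ripples), 60 - 3 * sqrt(60))
  expect_lt(nrow(lf1$ground_truth$ripples), 60 + 3 * sqrt(60))
  # theta ground-truth frequency differs by slope * speed difference
  lab3 <- rep("locomotion", 10 * fs)
  sp10 <- rep(10, length(lab3)); sp20 <- rep(20, length(lab3))
  f10 <- synthesize_lfp(lab3, sp10, lfp_gen_spec(seed = 3),
                        sample_rate = fs)$ground_truth$theta_freq
  f20 <- synthesize_lfp(lab3, sp20, lfp_gen_spec(seed = 3),
                        sample_rate = fs)$ground_truth$theta_freq
  expect_equal(mean(f20 - f10, na.rm = TRUE), 10 * 0.01, tolerance = 1e-10)
  expect_error(lfp_gen_spec(ripple_rate = -1))
})

test_that("movie generator renders deterministic frames and honours focus fractions", {
  ses <- frame_session(reps = 1)
  st <- data.frame(x = 20, y = 20, diameter_um = 1, kind = "bouton",
                   amplitude = 60, in_focus_prob = 1, activity = "none",
                   rate_hz = 0)
  spec <- movie_gen_spec(frame_shape = c(32, 32), seed = 4, structures = st,
                         motion_sigma_um = c(immobility = 0, flickering = 0,
                                             locomotion = 0))
  mv <- synthesize_movie(ses$labels, ses$speed, spec)
  # no motion, no transients, no noise: all frames identical
  expect_equal(mv$frames[, , 1], mv$frames[, , dim(mv$frames)[3]])
  # in-focus fraction 0.6 visible in ~60% of frames
  st$in_focus_prob <- 0.6
  spec2 <- movie_gen_spec(frame_shape = c(32, 32), seed = 5, structures = st,
                          motion_sigma_um = c(immobility = 0, flickering = 0,
                                              locomotion = 0))
  mv2 <- synthesize_movie(ses$labels, ses$speed, spec2)
  frac <- mean(mv2$ground_truth$in_focus[1, ])
  expect_equal(frac, 0.6, tolerance = 0.1)
  # imposed integer shifts are returned exactly
  sh <- cbind(sample(-3:3, length(ses$labels), TRUE),
              sample(-3:3, length(ses$labels), TRUE))
  mv3 <- synthesize_movie(ses$labels, ses$speed, spec, shifts_px = sh)
  expect_identical(mv3$ground_truth$shifts_px, sh)
  # structure outside the frame is a validation error
  st_bad <- st; st_bad$x <- 32
  expect_error(movie_gen_spec(frame_shape = c(32, 32), structures = st_bad),
               "outside")
})
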