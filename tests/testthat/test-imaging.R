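test_that("motion correction recovers imposed integer shifts exactly", {
  ses <- frame_session(reps = 1, block_s = 4, loco_s = 2)
  spec <- movie_gen_spec(seed = 11,
                         motion_sigma_um = c(immobility = 0, flickering = 0,
                                             locomotion = 0))
  # identical frames: zero shifts everywhere
  mv0 <- synthesize_movie(ses$labels, ses$speed, spec)
  mc0 <- motion_correct(mv0, labels = ses$labels)
  expect_true(all(mc0$shifts_px == 0L))
  # noise-free imposed integer shift sequence (with a motion-free
  # immobility period for the reference): exact recovery
  set.seed(12)
  nt <- length(ses$labels)
  sh <- cbind(sample(-6:6, nt, TRUE), sample(-6:6, nt, TRUE))
  sh[ses$labels == "immobility", ] <- 0L
  storage.mode(sh) <- "integer"
  mv <- synthesize_movie(ses$labels, ses$speed, spec, shifts_px = sh)
  mc <- motion_correct(mv, labels = ses$labels)
  expect_identical(mc$shifts_px, sh)
  # corrected frames match the unshifted rendering away from edges
  expect_lt(max(abs(mc$frames[10:50, 10:50, ] - mv0$frames[10:50, 10:50, ])),
            1e-9)
})

test_that("flat featureless frames get zero shift and a low-confidence flag", {
  fr <- array(0, dim = c(16, 16, 12))
  mc <- motion_correct(fr, pixel_size = 1)
  expect_true(all(mc$shifts_px == 0L))
  expect_true(all(mc$low_confidence))
  expect_error(motion_correct(fr[, , 1:5]), "10 frames")
})

test_that("more-stable template selects quiet immobility frames only", {
  labels <- rep(c("immobility", "locomotion"), each = 20)
  sh <- matrix(0, 40, 2)
  sh[seq(2, 20, by = 2), 1] <- 5          # alternating 0 / 5 um immobility
  sh[21:40, ] <- 4
  mc <- list(shifts_um = sh, vector_length_um = sqrt(rowSums(sh^2)))
  idx <- more_stable_template(mc, labels)
  expect_true(all(labels[idx] == "immobility"))
  expect_true(all(mc$vector_length_um[idx] == 0))
  expect_error(more_stable_template(
    list(shifts_um = sh, vector_length_um = sqrt(rowSums(sh^2))),
    rep("locomotion", 40)), "more-stable")
})

test_that("motion by state recovers the generator's imposed fold change", {
  ses <- frame_session(reps = 2)
  spec <- movie_gen_spec(seed = 13, photon_scale = 2, read_noise_sd = 1)
  mv <- synthesize_movie(ses$labels, ses$speed, spec)
  mc <- motion_correct(mv, labels = ses$labels)
  ms <- motion_by_state(mc, ses$labels, ses$frame_rate)
  truth_len <- sqrt(rowSums(mv$ground_truth$shifts_um^2))
  stable_idx <- more_stable_template(mc, ses$labels)
  truth_fold <- stats::median(truth_len[ses$labels == "locomotion"]) /
    stats::median(truth_len[stable_idx])
  expect_equal(ms$fold_change, truth_fold, tolerance = 0.2)
  # onset-locked motion: profile peaks within 1 s after onset
  prof <- ms$onset_profile
  pk_t <- prof$t[which.max(prof$median)]
  expect_gte(pk_t, -0.2)
  expect_lte(pk_t, 1)
  # constant motion in both states gives fold change 1
  sh1 <- matrix(2, length(ses$labels), 2)
  mc1 <- list(shifts_um = sh1,
              vector_length_um = sqrt(rowSums(sh1^2)))
  ms1 <- motion_by_state(mc1, ses$labels, ses$frame_rate)
  expect_equal(ms1$fold_change, 1)
})

test_that("stability maps count frame-wise supra-threshold fractions", {
  set.seed(14)
  nf <- 60
  # static disk on noise: always in the top decile
  fr <- array(stats::rnorm(32 * 32 * nf), dim = c(32, 32, nf))
  disk <- matrix(0, 32, 32)
  disk[15:18, 15:18] <- 50
  for (f in seq_len(nf)) fr[, , f] <- fr[, , f] + disk
  sm <- stability_map(fr, pixel_size = 0.5, n_surrogates = 200, seed = 1)
  expect_equal(sm$peak_probability, 1.0)
  bg <- sm$probability[1:10, 1:10]
  expect_lt(abs(mean(bg) - 0.1), 0.03)
  # invariance to global intensity rescaling
  sm2 <- stability_map(fr * 7.3, pixel_size = 0.5, n_surrogates = 200,
                       seed = 1)
  expect_identical(sm2$probability, sm$probability)
  # mean surrogate maps are spatially flat at the 10% marking rate
  expect_lt(abs(mean(sm$surrogate_mean) - 0.1), 0.02)
  expect_lt(stats::sd(sm$surrogate_mean), 0.02)
  expect_lt(stats::sd(sm$chance_map), 0.05)
  expect_error(stability_map(fr[, , 1:10]), "20 frames")
})

test_that("delta-F/F uses the mode of the low-percentile interval as baseline", {
  # constant trace: dF/F identically zero
  d0 <- dff(rep(80, 1000))
  expect_true(all(d0$dff == 0))
  # baseline 100 with a brief peak at 200: peak dF/F = 100%
  set.seed(15)
  f <- stats::rnorm(2000, 100, 1)
  f[1000:1010] <- 200
  d1 <- dff(f)
  expect_equal(d1$f0, 100, tolerance = 2)
  expect_equal(max(d1$dff), 1.0, tolerance = 0.05)
  # adding transients moves F0 by less than 2%
  f2 <- f
  idx <- seq(100, 1900, by = 200)
  for (i in idx) f2[i:(i + 15)] <- f2[i:(i + 15)] + 120
  expect_equal(dff(f2)$f0, d1$f0, tolerance = 0.02)
  expect_error(dff(rep(-5, 100)), "F0")
})
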