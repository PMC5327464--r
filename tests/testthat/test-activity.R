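test_that("adaptive threshold exits immediately on symmetric data", {
  set.seed(21)
  x <- stats::rnorm(2000)
  at <- adaptive_threshold(x)
  expect_equal(at$threshold, stats::sd(x), tolerance = 0.05)
  expect_lt(at$n_removed, 20)
  # mirrored symmetric data: identical threshold magnitude
  at_m <- adaptive_threshold(-x)
  expect_equal(abs(at_m$threshold), abs(at$threshold), tolerance = 0.02)
  expect_error(adaptive_threshold(stats::rnorm(20)), "50")
})

test_that("adaptive threshold recovers noise sigma under positive contamination", {
  set.seed(22)
  for (frac in c(0.05, 0.1, 0.2)) {
    n <- 2000
    x <- c(stats::rnorm(n * (1 - frac)), stats::rnorm(n * frac, 10, 0.5))
    at <- adaptive_threshold(x)
    expect_equal(at$threshold, 1, tolerance = 0.15)
    expect_true(all(at$on[x > 5]))
  }
  # exponential data never reach zero skewness: MAD fallback with warning
  set.seed(23)
  expect_warning(af <- adaptive_threshold(stats::rexp(500)), "fallback|MAD")
  expect_true(af$fallback)
})

test_that("transient detection finds injected events, rejects symmetric signals", {
  fr <- 30
  # flat + white noise: ~0 events across seeds
  fp <- vapply(1:5, function(s) {
    set.seed(s)
    detect_transients(stats::rnorm(300 * fr, 0, 0.05), fr)$rate_hz
  }, 0)
  expect_true(all(fp < 0.02))
  expect_equal(detect_transients(rep(0.3, 20 * fr), fr)$n, 0L)
  # single 5-SD GCaMP-like transient in 10 s: one event, rise ~1 frame
  set.seed(4)
  kern <- wheelphys:::transient_kernel(fr, 0.03, 0.4)
  tr <- stats::rnorm(10 * fr, 0, 0.05)
  tr[150:(150 + length(kern) - 1)] <- tr[150:(150 + length(kern) - 1)] +
    0.25 * kern
  ts <- detect_transients(tr, fr)
  expect_equal(ts$n, 1L)
  expect_equal(ts$rise_times_ms, 30, tolerance = 0.5)
  expect_gt(ts$amplitudes, 0.15)
  # pure sinusoid: symmetric, rejected by the skewness gate
  tt <- seq_len(60 * fr) / fr
  expect_equal(detect_transients(sin(2 * pi * 0.5 * tt), fr)$n, 0L)
  expect_error(detect_transients(stats::rnorm(30), fr), "10 s")
})

test_that("transient rate recovery on generator-style traces within 20%", {
  fr <- 30
  rates <- vapply(1:4, function(s) {
    tt <- transient_trace(n_s = 400, amp = 0.6, noise_sd = 0.05,
                          n_events = 20, seed = 30 + s)
    detect_transients(tt$trace, fr)$n / 20
  }, 0)
  expect_true(all(abs(rates - 1) <= 0.2))
})

test_that("population sparseness counts off-cells per bin", {
  fr <- 30
  # all cells silent: sparseness 1 everywhere
  z <- matrix(0, 60, 5)
  sp0 <- population_sparseness(z, fr, thresholds = rep(0.5, 5))
  expect_true(all(sp0$fraction_off == 1))
  # 10 cells, exactly 2 on in the first bin: 0.8
  m <- matrix(0, 30, 10)
  m[1:15, 1:2] <- 1
  sp <- population_sparseness(m, fr, thresholds = rep(0.5, 10))
  expect_equal(sp$fraction_off[1], 0.8)
  # duplicating every cell leaves the series unchanged
  sp_dup <- population_sparseness(cbind(m, m), fr,
                                  thresholds = rep(0.5, 20))
  expect_identical(sp_dup$fraction_off, sp$fraction_off)
  # per-cell rescaling with adaptive thresholds leaves sparseness intact
  set.seed(24)
  traces <- matrix(stats::rnorm(3000 * 4, 0, 0.05), ncol = 4)
  for (c0 in 1:4) traces[sample(3000, 20), c0] <- 1
  scl <- sweep(traces, 2, c(1, 2, 5, 10), "*")
  s1 <- population_sparseness(traces, fr)
  s2 <- population_sparseness(scl, fr)
  expect_identical(s1$fraction_off, s2$fraction_off)
})

test_that("pairwise correlations are normalized zero-lag covariances", {
  set.seed(25)
  a <- stats::rnorm(500)
  pc <- pairwise_correlations(cbind(a, a))
  expect_equal(pc$values, 1)
  ph <- sin(seq_len(500) / 10)
  pc2 <- pairwise_correlations(cbind(ph, -ph))
  expect_equal(pc2$values, -1)
  # independent noise: |r| < 3 / sqrt(T)
  nn <- matrix(stats::rnorm(2000 * 6), ncol = 6)
  pcn <- pairwise_correlations(nn)
  expect_true(all(abs(pcn$values) < 3 / sqrt(2000)))
  expect_true(is.numeric(pcn$q75))
  expect_warning(pairwise_correlations(cbind(a, rep(1, 500))), "zero-variance")
})

test_that("speed covariance flags aligned traces and calibrates on noise", {
  rate <- 20
  n <- 400 * rate
  set.seed(26)
  speed <- wheelphys:::rolling_mean(abs(stats::rnorm(n)), 40)
  cv <- speed_covariance(2 * speed + 1e-3 * stats::rnorm(n), speed, rate,
                         n_surrogates = 1000, seed = 1)
  expect_equal(max(cv$covariance), cv$covariance[cv$lags_s == 0],
               tolerance = 1e-9)
  expect_gt(cv$max_stat, 0.99)
  expect_true(cv$significant)
  # independent traces: significant in at most a few % of seeds
  sig <- vapply(1:15, function(s) {
    set.seed(100 + s)
    tr <- stats::rnorm(n)
    speed_covariance(tr, speed, rate, n_surrogates = 500,
                     seed = 900 + s)$significant
  }, TRUE)
  expect_lte(mean(sig), 1 / 15 + 1e-9)
  expect_error(speed_covariance(stats::rnorm(100), stats::rnorm(100), 20),
               "3 windows")
})
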