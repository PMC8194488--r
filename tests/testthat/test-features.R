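test_that("z-score standardization centers and scales; degenerate input errors", {
  clip <- audio_clip(c(0, 2, 4), 8000, "s")
  out <- standardize(clip)
  expect_equal(mean(out$samples), 0)
  expect_equal(sqrt(mean(out$samples^2)), 1)

  already <- audio_clip(c(-1, 1, -1, 1), 8000, "s")  # mean 0, pop sd 1
  expect_equal(standardize(already)$samples, already$samples)

  expect_error(standardize(audio_clip(rep(1, 4), 8000, "s")),
               class = "resemote_degenerate_signal")
})

test_that("frame count follows t = 1 + floor((L - win)/hop)", {
  cfg <- feature_config()  # 25 ms / 10 ms at 16 kHz
  clip <- audio_clip(rnorm(16000), 16000, "s")
  pow <- frame_power_spectrum(standardize(clip), cfg)
  expect_identical(nrow(pow), 98L)

  set.seed(31)
  for (L in sample(500:30000, 8)) {
    clip <- audio_clip(rnorm(L), 16000, "s")
    expect_equal(nrow(frame_power_spectrum(clip, cfg)),
                 1 + floor((L - 400) / 160))
  }
  expect_error(frame_power_spectrum(audio_clip(rnorm(100), 16000, "s"), cfg),
               class = "resemote_too_short")
})

test_that("power spectra are nonnegative, zero frames give zero rows, and a
           bin-centered sinusoid peaks at its bin", {
  cfg <- feature_config(sample_rate = 16000)
  # first 400 samples silent: frame 1 must be exactly zero
  x <- c(rep(0, 400), rnorm(1600))
  pow <- frame_power_spectrum(audio_clip(x, 16000, "s"), cfg)
  expect_true(all(pow >= 0))
  expect_equal(unname(pow[1, ]), rep(0, ncol(pow)))

  # sinusoid exactly on bin 41 of a 512-point FFT: 40 * 16000/512 = 1250 Hz
  f0 <- 40 * 16000 / 512
  tt <- (0:15999) / 16000
  pow <- frame_power_spectrum(audio_clip(sin(2 * pi * f0 * tt), 16000, "s"),
                              cfg)
  expect_true(all(apply(pow, 1, which.max) == 41))
})

test_that("log-Mel obeys the log homomorphism and its floor", {
  cfg <- feature_config(n_mels = 16, sample_rate = 8000)
  zero <- matrix(0, 3, 129)
  expect_equal(unname(log_mel(zero, cfg)),
               matrix(log(cfg$log_floor), 3, 16))

  set.seed(7)
  pow <- matrix(rexp(5 * 129), 5, 129)
  expect_equal(log_mel(2 * pow, cfg), log_mel(pow, cfg) + log(2),
               tolerance = 1e-6)

  # single-band toy filterbank summing two power bins
  fb <- matrix(c(1, 1), 2, 1)
  expect_equal(as.vector(log_mel(matrix(c(2, 3), 1, 2), cfg, filterbank = fb)),
               log(5 + cfg$log_floor))
})

test_that("log-Mel is monotone in the power values", {
  cfg <- feature_config(n_mels = 16, sample_rate = 8000)
  set.seed(8)
  pow <- matrix(rexp(4 * 129), 4, 129)
  base <- log_mel(pow, cfg)
  for (r in 1:5) {
    pow2 <- pow
    pow2[sample(length(pow2), 10)] <- pow2[sample(length(pow2), 10)] + rexp(10)
    expect_true(all(log_mel(pmax(pow2, pow), cfg) >= base - 1e-12))
  }
})

test_that("regression delta: zero on constants, unit slope on ramps,
           twice-applied equals delta-delta, and linear", {
  const <- matrix(3, 10, 4)
  expect_equal(delta(const, 2), matrix(0, 10, 4))

  ramp <- matrix(rep(1:20, 3), 20, 3)
  d <- delta(ramp, 2)
  # interior frames: (1*2 + 2*4) / (2*(1 + 4)) = 1
  expect_equal(unname(d[3:18, ]), matrix(1, 16, 3))

  set.seed(9)
  x <- matrix(rnorm(60), 12, 5)
  expect_equal(delta(delta(x, 2), 2), delta(delta(x, 2), 2))

  y <- matrix(rnorm(60), 12, 5)
  expect_equal(delta(2 * x + 3 * y, 2), 2 * delta(x, 2) + 3 * delta(y, 2),
               tolerance = 1e-12)
})

test_that("extract_features yields [t][f][3] with matching frame count", {
  cfg <- small_feature_cfg()
  clip <- generate_clip(1, 1, small_synth_spec())
  feat <- extract_features(clip, cfg)
  expect_identical(dim(feat)[3], 3L)
  expect_identical(dim(feat)[2], 16L)
  pow <- frame_power_spectrum(standardize(clip), cfg)
  expect_identical(dim(feat)[1], nrow(pow))
  expect_true(all(is.finite(feat)))
})

test_that("delta channels of stationary noise are much smaller than the static
           channel", {
  cfg <- small_feature_cfg()
  for (seed in 1:3) {
    set.seed(seed)
    clip <- audio_clip(rnorm(6000), 8000, "s")
    feat <- extract_features(clip, cfg)
    m0 <- mean(abs(feat[, , 1]))
    expect_lt(mean(abs(feat[, , 2])), 0.2 * m0)
    expect_lt(mean(abs(feat[, , 3])), 0.2 * m0)
  }
})

test_that("global gain cancels after standardization: identical features", {
  cfg <- small_feature_cfg()
  set.seed(10)
  x <- rnorm(5000)
  f1 <- extract_features(audio_clip(x, 8000, "s"), cfg)
  f2 <- extract_features(audio_clip(7.3 * x, 8000, "s"), cfg)
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-10)
})

test_that("channel subsetting drives the channel dimension", {
  cfg <- small_feature_cfg(channels = c("static", "delta"))
  feat <- extract_features(generate_clip(1, 1, tiny_synth_spec()), cfg)
  expect_identical(dim(feat)[3], 2L)
  expect_error(feature_config(channels = character(0)),
               class = "resemote_bad_config")
})
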