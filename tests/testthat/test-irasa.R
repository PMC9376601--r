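cfg <- spectral_config()

test_that("segment_windows places 50%-overlapping 8-s blocks", {
  x <- rnorm(6000)                        # 60 s at 100 Hz
  w <- segment_windows(x, 100, cfg)
  expect_length(w, 14)                    # floor((60-8)/4)+1
  expect_equal(vapply(w, `[[`, numeric(1), "window_start"), seq(0, 52, by = 4))
  expect_true(all(lengths(lapply(w, `[[`, "samples")) == 800))

  w16 <- segment_windows(rnorm(1600), 100, cfg)
  expect_length(w16, 3)
  expect_equal(vapply(w16, `[[`, numeric(1), "window_start"), c(0, 4, 8))

  expect_tremor_error(segment_windows(rnorm(790), 100, cfg), "data")
})

test_that("mixed_spectrum locates a sinusoid and respects Parseval", {
  t <- (0:799) / 100
  m <- mixed_spectrum(sin(2 * pi * 6 * t), 100, cfg)
  expect_equal(m$freqs[which.max(m$values)], 6.0)
  expect_equal(m$freqs[2] - m$freqs[1], 0.125)
  expect_equal(max(m$freqs), 50)

  # constant block: linear detrend removes it entirely
  mc <- mixed_spectrum(rep(3.7, 800), 100, cfg)
  expect_true(all(abs(mc$values) < 1e-25))

  # Parseval: the PSD integral tracks the variance (window-averaged; a
  # single Hann-tapered 8-s window has ~8% statistical spread)
  set.seed(301)
  x <- rnorm(100 * 88)
  ratios <- vapply(segment_windows(x, 100, cfg), function(w) {
    m <- mixed_spectrum(w$samples, 100, cfg)
    sum(m$values) * 0.125 / var(w$samples)
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("fractal spectrum tracks pure 1/f noise and stays flat for white", {
  # beta = 1: the fractal estimate matches the mixed spectrum with no
  # systematic multiplicative offset (median bin-wise log ratio within
  # 0.15 of 0 over 20 windows) and no frequency-dependent distortion
  # (the null holds equally in the low and high half of the band)
  x <- fractal_noise(100 * 84, 100, beta = 1, seed = 501)
  ratios <- list(lo = c(), hi = c())
  for (w in segment_windows(x, 100, cfg)[1:20]) {
    m <- mixed_spectrum(w$samples, 100, cfg)
    f <- fractal_spectrum(w$samples, 100, cfg)
    r <- m$values / f$values
    ratios$lo <- c(ratios$lo, r[m$freqs >= 1 & m$freqs < 6.5])
    ratios$hi <- c(ratios$hi, r[m$freqs >= 6.5 & m$freqs <= 12])
  }
  expect_lt(abs(log(median(c(ratios$lo, ratios$hi)))), 0.15)
  expect_lt(abs(log(median(ratios$lo))), 0.15)
  expect_lt(abs(log(median(ratios$hi))), 0.15)

  # white noise: fractal estimate is flat (log-log slope within 0.2 of 0)
  xw <- fractal_noise(100 * 40, 100, beta = 0, seed = 502)
  slopes <- vapply(segment_windows(xw, 100, cfg)[1:8], function(w) {
    f <- fractal_spectrum(w$samples, 100, cfg)
    sel <- f$freqs >= 1 & f$freqs <= 12
    coef(lm(log10(f$values[sel]) ~ log10(f$freqs[sel])))[[2]]
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.2)
})

test_that("fractal spectrum suppresses a rhythmic peak", {
  # 6 Hz oscillation at SNR 2 on 1/f background: the fractal estimate at
  # 6 Hz must sit far below the mixed spectrum there
  supp <- vapply(1:6, function(i) {
    bg <- fractal_noise(800, 100, beta = 1, seed = 600 + i)
    osc <- tremor_component(800, 100, f0 = 6, rel_amp = 2, seed = 700 + i)
    m <- fractal_spectrum(bg + osc, 100, cfg)
    mm <- mixed_spectrum(bg + osc, 100, cfg)
    i6 <- which(mm$freqs == 6)
    mm$values[i6] / m$values[i6]
  }, numeric(1))
  expect_true(all(supp > 3))
})

test_that("oscillatory_ratio contracts: identity, proportionality, errors", {
  f <- seq(0, 50, by = 0.125)
  v <- 1 / (1 + f)
  m <- tremorsense:::new_spectrum(f, v, "mixed")
  fr <- tremorsense:::new_spectrum(f, v, "fractal")
  expect_equal(oscillatory_ratio(m, fr)$values, rep(1, length(f)))

  v2 <- v; v2[100] <- 2 * v[100]
  m2 <- tremorsense:::new_spectrum(f, v2, "mixed")
  r2 <- oscillatory_ratio(m2, fr)
  expect_equal(r2$values[100], 2)
  expect_equal(r2$values[-100], rep(1, length(f) - 1))

  bad <- tremorsense:::new_spectrum(f + 0.01, v, "fractal")
  expect_tremor_error(oscillatory_ratio(m2, bad), "parameter")
  expect_tremor_error(oscillatory_ratio(fr, fr), "parameter")
})

test_that("ratio peaks at the oscillation frequency on 1/f background", {
  hits <- vapply(1:6, function(i) {
    x <- fractal_noise(800, 100, 1, seed = 800 + i) +
      tremor_component(800, 100, 6, rel_amp = 2, seed = 900 + i)
    r <- oscillatory_ratio(mixed_spectrum(x, 100, cfg),
                           fractal_spectrum(x, 100, cfg))
    sel <- r$freqs >= 1 & r$freqs <= 12
    r$freqs[sel][which.max(r$values[sel])]
  }, numeric(1))
  expect_true(all(abs(hits - 6) <= 0.25))
})

test_that("mixed and fractal scale with gain^2, leaving the ratio invariant", {
  x <- fractal_noise(800, 100, 1, seed = 31) +
    tremor_component(800, 100, 5, 1.5, seed = 32)
  g <- 7.3
  m1 <- mixed_spectrum(x, 100, cfg);  m2 <- mixed_spectrum(g * x, 100, cfg)
  f1 <- fractal_spectrum(x, 100, cfg); f2 <- fractal_spectrum(g * x, 100, cfg)
  expect_equal(m2$values, g^2 * m1$values, tolerance = 1e-12)
  expect_equal(f2$values, g^2 * f1$values, tolerance = 1e-12)
  r1 <- oscillatory_ratio(m1, f1); r2 <- oscillatory_ratio(m2, f2)
  expect_equal(r2$values, r1$values, tolerance = 1e-9)
})

test_that("spectrogram covers all windows x channels on one frequency grid", {
  p <- subject_params("ET", seed = 21, tremor_rel_amp = 2, tremor_freq = 6)
  rec <- simulate_recording(p, sensor_model("phone"), duration = 60)
  sp <- spectrogram(rec, cfg)
  expect_length(sp, 84)                 # 14 windows x 6 channels
  expect_true(all(vapply(sp, function(s) s$kind == "ratio", logical(1))))
  grids <- unique(lapply(sp, `[[`, "freqs"))
  expect_length(grids, 1)               # one shared grid
  expect_equal(grids[[1]][2] - grids[[1]][1], 0.125)

  rec1 <- simulate_recording(p, sensor_model("phone"), duration = 60,
                             channels = "la_x")
  expect_length(spectrogram(rec1, cfg), 14)
})
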