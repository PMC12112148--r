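test_that("phase segmentation reproduces the canonical protocol arithmetic", {
  tr <- fmsf_trace(rep(100, 13500), sampling_rate = 25)
  seg <- segment_phases(tr, fmsf_protocol())
  expect_equal(seg$baseline, c(1L, 4501L))
  expect_equal(seg$occlusion, c(4501L, 9001L))
  expect_equal(seg$hyperemic, c(9001L, 9751L))
  expect_equal(seg$reperfusion, c(9751L, 13501L))

  seg20 <- segment_phases(tr, fmsf_protocol(hyperemic_window = 20))
  expect_equal(diff(seg20$hyperemic), 500L)
})

test_that("a trace shorter than the protocol is rejected naming the deficit", {
  tr <- fmsf_trace(rep(100, 2500), sampling_rate = 25)
  expect_error(segment_phases(tr, fmsf_protocol()), "truncated trace")
  expect_error(segment_phases(tr, fmsf_protocol()), "440\\.0 s")
})

test_that("phases partition the protocol span for arbitrary settings", {
  set.seed(4)
  for (i in 1:10) {
    fs <- sample(c(1, 5, 25), 1)
    p <- fmsf_protocol(baseline_duration = sample(60:240, 1),
                       occlusion_duration = sample(60:240, 1),
                       post_release_duration = sample(120:240, 1),
                       hyperemic_window = sample(10:40, 1))
    n <- round(total_duration <- (p$baseline_duration + p$occlusion_duration +
                                    p$post_release_duration) * fs)
    seg <- segment_phases(fmsf_trace(rnorm(n, 100), sampling_rate = fs), p)
    iv <- rbind(seg$baseline, seg$occlusion, seg$hyperemic, seg$reperfusion)
    expect_equal(iv[1, 1], 1L)
    expect_equal(iv[2:4, 1], iv[1:3, 2])      # contiguous, no gap/overlap
    expect_equal(iv[4, 2] - 1L, n)            # covers the protocol span
  }
})

test_that("baseline level is the mean over the baseline phase", {
  p <- fmsf_protocol()
  const <- fmsf_trace(rep(100, 13500), sampling_rate = 25)
  seg <- segment_phases(const, p)
  expect_equal(estimate_baseline(const, seg), 100)

  # sinusoid over an integer number of periods averages out
  t <- (0:13499) / 25
  y <- 100 + 2 * sin(2 * pi * 0.03 * t)  # 0.03 * 180 s = 5.4; use grid tone
  y2 <- 100 + 2 * sin(2 * pi * (6 / 180) * t)
  tr2 <- fmsf_trace(y2, sampling_rate = 25)
  expect_equal(estimate_baseline(tr2, seg), 100, tolerance = 1e-6)

  # linear ramp 90 -> 110 over the baseline averages to the midpoint
  ramp <- c(seq(90, 110, length.out = 4500), rep(100, 9000))
  tr3 <- fmsf_trace(ramp, sampling_rate = 25)
  expect_equal(estimate_baseline(tr3, seg), 100)
})

test_that("linear detrending annihilates trends, preserves oscillation, is idempotent", {
  fs <- 25
  expect_equal(detrend_window(rep(5, 1000), fs), rep(0, 1000))

  ramp <- seq(90, 110, length.out = 4500)
  r <- detrend_window(ramp, fs)
  expect_lt(mean(r^2), 1e-10 * mean(ramp^2))

  # ramp + sinusoid over integer periods: residual mean square = A^2 / 2
  t <- (0:14999) / fs                       # 600 s
  y <- seq(0, 50, length.out = 15000) + 2 * sin(2 * pi * 0.03 * t)
  r2 <- detrend_window(y, fs)
  expect_lt(abs(mean(r2)), 1e-9 * max(abs(y)))
  expect_equal(mean(r2^2), 2.0, tolerance = 1e-2)
  # idempotence
  expect_equal(detrend_window(r2, fs), r2, tolerance = 1e-9)
})

test_that("detrending rejects windows too short for the requested low cut", {
  expect_error(detrend_window(rnorm(100), 25, low_cut = 0.005),
               "window too short for low_cut")
  expect_silent(detrend_window(rnorm(25 * 400), 25, low_cut = 0.005))
})

test_that("band decomposition places single tones and superpositions correctly", {
  fs <- 1
  t <- (0:599)                               # 600 s at 1 Hz
  r <- detrend_window(2 * sin(2 * pi * 0.03 * t), fs)
  bp <- band_decompose(r, fs)
  expect_equal(bp$neuro, 2.0, tolerance = 0.01)
  expect_lt(bp$endo, 0.01 * bp$total_ms)
  expect_lt(bp$myo, 0.01 * bp$total_ms)

  # superposition; a 0.01 Hz sine runs 6 cycles here and linear detrending
  # absorbs a few percent of it, so the endothelial check is the looser one
  r2 <- detrend_window(sin(2 * pi * 0.01 * t) + sin(2 * pi * 0.10 * t), fs)
  bp2 <- band_decompose(r2, fs)
  expect_equal(bp2$endo, 0.5, tolerance = 0.04)
  expect_equal(bp2$myo, 0.5, tolerance = 0.01)
  expect_lt(bp2$neuro, 0.01 * bp2$total_ms)
  expect_equal(bp2$endo, dft_band_ms(r2, fs, 0.005, 0.021), tolerance = 1e-9)

  bp0 <- band_decompose(rep(0, 600), fs)
  expect_equal(c(bp0$endo, bp0$neuro, bp0$myo), c(0, 0, 0))
})

test_that("band decomposition matches the brute-force DFT oracle", {
  fs <- 1
  t <- 0:599
  set.seed(11)
  for (f in c(0.01, 0.03, 0.05, 0.07, 0.10, 0.14)) {
    r <- detrend_window(sin(2 * pi * f * t + runif(1, 0, 2 * pi)), fs)
    bp <- band_decompose(r, fs)
    b <- fmsf_bands()
    edges <- c(b$low_cut, b$endothelial_upper, b$neurogenic_upper,
               b$myogenic_upper)
    i <- findInterval(f, edges)
    got <- c(bp$endo, bp$neuro, bp$myo)[i]
    want <- dft_band_ms(r, fs, edges[i], edges[i + 1])
    expect_equal(got, want, tolerance = 1e-9)
    # >= 95% of total power in the band containing f
    expect_gt(got / bp$total_ms, 0.95)
  }
})

test_that("off-grid tones still concentrate >= 95% of power in their band", {
  fs <- 1
  t <- 0:569                                 # 570 s: tones off the bin grid
  set.seed(12)
  for (f in c(0.01, 0.03, 0.07, 0.10)) {
    r <- detrend_window(sin(2 * pi * f * t + runif(1, 0, 2 * pi)), fs)
    bp <- band_decompose(r, fs)
    b <- fmsf_bands()
    edges <- c(b$low_cut, b$endothelial_upper, b$neurogenic_upper,
               b$myogenic_upper)
    i <- findInterval(f, edges)
    expect_gt(c(bp$endo, bp$neuro, bp$myo)[i] / bp$total_ms, 0.95)
  }
})

test_that("Parseval consistency and amplitude scaling hold", {
  set.seed(21)
  fs <- 5
  for (i in 1:5) {
    r <- detrend_window(rnorm(3000), fs)
    bp <- band_decompose(r, fs)
    total <- bp$endo + bp$neuro + bp$myo + bp$below_cut + bp$above_myo
    expect_equal(total, mean(r^2), tolerance = 1e-6)

    bp3 <- band_decompose(3 * r, fs)
    expect_equal(c(bp3$endo, bp3$neuro, bp3$myo),
                 9 * c(bp$endo, bp$neuro, bp$myo), tolerance = 1e-9)
  }
})

test_that("band components are invariant to a constant offset before detrending", {
  fs <- 5
  t <- (0:2999) / fs
  y <- 2 * sin(2 * pi * 0.03 * t)
  bp1 <- band_decompose(detrend_window(y, fs), fs)
  bp2 <- band_decompose(detrend_window(y + 500, fs), fs)
  expect_equal(c(bp1$endo, bp1$neuro, bp1$myo),
               c(bp2$endo, bp2$neuro, bp2$myo), tolerance = 1e-9)
})

test_that("too-slow sampling cannot resolve the myogenic band", {
  expect_error(band_decompose(rnorm(100), 0.25), "sampling too slow")
})
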