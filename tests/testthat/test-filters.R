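test_that("phase-band design follows the +/- 1 Hz rule and rejects low centres", {
  b <- design_phase_band(10)
  expect_equal(c(b$lo_edge, b$hi_edge), c(9, 11))
  expect_equal(b$half_bw, 1)
  expect_equal(b$order, 4L)
  expect_equal(b$passes, 2L)
  b7 <- design_phase_band(7)
  expect_equal(c(b7$lo_edge, b7$hi_edge), c(6, 8))
  expect_error(design_phase_band(0.5), "invalid band")
  expect_error(design_phase_band(1.9), "lower edge|invalid band")
})

test_that("amplitude-band design scales with the centre frequency", {
  b <- design_amplitude_band(60)
  expect_equal(c(b$lo_edge, b$hi_edge), c(36, 84))
  expect_equal(b$half_bw, 24)
  # minimal sideband-covering band for fp = 13 at fa = 60
  bmin <- design_amplitude_band(60, scale = 13 / 60)
  expect_equal(c(bmin$lo_edge, bmin$hi_edge), c(47, 73))
  expect_equal(bmin$half_bw, 13)
  b100 <- design_amplitude_band(100)
  expect_equal(c(b100$lo_edge, b100$hi_edge), c(60, 140))
  expect_error(design_amplitude_band(-5), "positive")
  expect_error(design_amplitude_band(60, scale = 1.2), "between 0 and 1")
})

test_that("smallest admissible amplitude centre matches a brute-force scan", {
  expect_identical(min_amplitude_center(13, 0.4, 2), 34)
  expect_identical(min_amplitude_center(10, 0.5, 1), 20)
  # independent oracle: scan the grid upward
  scan_min <- function(max_phase, scale, step) {
    f <- step
    while (scale * f < max_phase) f <- f + step
    f
  }
  expect_identical(min_amplitude_center(13, 0.4, 1), scan_min(13, 0.4, 1))
  expect_identical(min_amplitude_center(13, 0.4, 1), 33)
  for (mp in c(7, 9.5, 13)) for (st in c(1, 2))
    expect_identical(min_amplitude_center(mp, 0.4, st), scan_min(mp, 0.4, st))
})

test_that("SOS zero-phase filtering matches the reference implementation", {
  x <- scan(test_path("fixtures", "filter_input.txt"), quiet = TRUE)
  cases <- list(
    list(file = "filtfilt_band_6_8.txt", edges = c(6, 8), type = "pass"),
    list(file = "filtfilt_band_9_11.txt", edges = c(9, 11), type = "pass"),
    list(file = "filtfilt_band_36_84.txt", edges = c(36, 84), type = "pass"),
    list(file = "filtfilt_low_40.txt", edges = 40, type = "low")
  )
  for (cs in cases) {
    expected <- scan(test_path("fixtures", cs$file), quiet = TRUE)
    sos <- phaseamp:::butter_sos(4, cs$edges, 1000, cs$type)
    got <- phaseamp:::sos_filtfilt(sos, x)
    expect_lt(max(abs(got - expected)), 1e-9 * max(abs(expected)))
  }
})

test_that("filters stay stable where transfer-function forms blow up", {
  # the 6-8 Hz band at fs 1000 has poles at radius > 1 in expanded form
  sos <- phaseamp:::butter_sos(4, c(6, 8), 1000, "pass")
  for (i in seq_len(nrow(sos))) {
    r <- Mod(polyroot(rev(sos[i, 4:6])))
    expect_true(all(r < 1))
  }
  y <- phaseamp:::sos_filtfilt(sos, rnorm(5000))
  expect_true(all(is.finite(y)))
})

test_that("two-pass filtering leaves a symmetric pulse peak in place", {
  x <- numeric(3001)
  x[1501] <- 1
  for (band in list(design_phase_band(10), design_amplitude_band(60))) {
    y <- band_filter(x, band, fs = 1000)
    expect_equal(which.max(abs(y)), 1501)
  }
})

test_that("analytic extraction recovers a pure cosine's flat envelope and phase rate", {
  ts <- cosine_trials(freq = 10, dur = 2.2)
  a <- extract_analytic(ts, design_phase_band(10))
  env <- a$amplitude[1, ]
  expect_lt(stats::sd(env) / mean(env), 0.01)
  # phase advances 2 pi per 100 ms
  d <- diff(a$phase[1, ])
  d[d < -pi] <- d[d < -pi] + 2 * pi
  expect_equal(mean(d) * 1000 / (2 * pi), 10, tolerance = 0.01)
})

test_that("trim bookkeeping is exact and outputs respect their ranges", {
  ts <- noise_trials(n_trials = 3, dur = 2.2, seed = 5)
  a <- extract_analytic(ts, design_amplitude_band(60), trim = 0.5)
  expect_identical(a$n_samples, 2200L - 2L * 500L)
  expect_true(all(a$amplitude >= 0))
  expect_true(all(a$phase >= -pi & a$phase < pi))
  expect_equal(a$t0, ts$t0 + 0.5)
  expect_error(extract_analytic(cosine_trials(dur = 0.8), design_phase_band(10),
                                trim = 0.5), "too short")
  expect_error(extract_analytic(ts, band_filter_spec(480, 40)), "invalid band")
})

test_that("a wide-enough amplitude band recovers the true modulator; a narrow one cannot", {
  set.seed(10)
  t <- (0:2199) / 1000
  modulator <- 1 + 0.8 * cos(2 * pi * 10 * t)
  x <- modulator * cos(2 * pi * 60 * t) + 0.3 * rnorm(2200)
  ts <- trial_series(matrix(x, 1), fs = 1000, t0 = -0.5, pad = 0.5)
  interior <- 501:1700
  # +/- 24 Hz covers the 10 Hz sidebands
  wide <- extract_analytic(ts, design_amplitude_band(60), trim = 0.5)
  expect_gt(cor(wide$amplitude[1, ], modulator[interior]), 0.95)
  # +/- 5 Hz misses them: the modulation vanishes from the envelope even
  # though the coupling is present in the signal
  narrow <- extract_analytic(ts, band_filter_spec(60, 5), trim = 0.5)
  expect_lt(abs(cor(narrow$amplitude[1, ], modulator[interior])), 0.3)
})

test_that("flat trials are flagged degenerate instead of failing", {
  X <- rbind(rnorm(2200), rep(0, 2200))
  ts <- trial_series(X, fs = 1000, t0 = -0.5, pad = 0.5)
  a <- extract_analytic(ts, design_phase_band(10))
  expect_identical(a$degenerate, c(FALSE, TRUE))
  expect_true(all(a$amplitude[2, ] == 0))
  expect_true(all(is.finite(a$phase[2, ])))
})
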