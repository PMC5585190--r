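test_that("mean-vector-length estimators match hand-computed toy values", {
  ph <- c(0, pi / 2, -pi, -pi / 2)  # quadrature phases
  amp <- c(2, 0, 0, 0)
  expect_equal(mvl_canolty(ph, amp)$value, 0.5)
  expect_equal(mvl_ozkurt(ph, amp)$value, 0.5)
  # symmetric vectors cancel
  n <- 400
  ph_u <- uniform_phases(n)
  expect_lt(mvl_canolty(ph_u, rep(1, n))$value, 1e-12)
  expect_lt(mvl_ozkurt(ph_u, rep(1, n))$value, 1e-12)
})

test_that("amplitude scaling is a confound for Canolty's MVL but cancels in Ozkurt's", {
  set.seed(2)
  ph <- runif(500, -pi, pi)
  amp <- abs(rnorm(500)) + 0.1
  for (c_scale in c(0.5, 3, 17)) {
    expect_equal(mvl_canolty(ph, c_scale * amp)$value,
                 c_scale * mvl_canolty(ph, amp)$value)
    expect_equal(mvl_ozkurt(ph, c_scale * amp)$value,
                 mvl_ozkurt(ph, amp)$value, tolerance = 1e-12)
    expect_equal(plv_cohen(ph, c_scale * amp)$value,
                 plv_cohen(ph, amp)$value, tolerance = 1e-12)
    expect_equal(kl_tort(ph, c_scale * amp)$value,
                 kl_tort(ph, amp)$value, tolerance = 1e-12)
  }
})

test_that("degenerate metric inputs raise named errors", {
  ph <- uniform_phases(100)
  expect_error(mvl_canolty(ph, rep(1, 99)), "equal length")
  expect_error(mvl_canolty(ph[1], 1), "at least 2")
  expect_error(mvl_ozkurt(ph, rep(0, 100)), "degenerate")
  expect_error(plv_cohen(ph, rep(3, 100)), "constant")
})

test_that("an envelope oscillating at the phase frequency gives PLV 1", {
  t <- (0:1999) / 1000
  phase_lo <- phaseamp:::wrap_phase(Arg(analytic_signal(cos(2 * pi * 10 * t))))
  amp <- 1 + cos(2 * pi * 10 * t)
  expect_equal(plv_cohen(phase_lo, amp)$value, 1, tolerance = 0.02)
  # a fixed lag preserves locking
  amp_lag <- 1 + cos(2 * pi * 10 * t + pi)
  expect_equal(plv_cohen(phase_lo, amp_lag)$value, 1, tolerance = 0.02)
})

test_that("PLV of incoherent phases shrinks like the random-resultant law", {
  # expected |mean of N random unit phasors| ~ sqrt(pi / (4 N))
  set.seed(11)
  for (n in c(200, 2000)) {
    vals <- replicate(40, {
      ph <- runif(n, -pi, pi)
      # feed a random envelope and compare its envelope phase to ph
      amp <- 1 + 0.5 * sin(2 * pi * seq_len(n) / 100 + runif(1, 0, 2 * pi))
      plv_cohen(ph, amp)$value
    })
    expect_equal(mean(vals), sqrt(pi / (4 * n)), tolerance = 0.3)
  }
})

test_that("phase-binned amplitude distribution matches an independent binning oracle", {
  n <- 3600
  ph <- uniform_phases(n)
  amp <- 1 + cos(ph)
  h <- phase_amplitude_histogram(ph, amp, n_bins = 18)
  expect_equal(sum(h$P), 1, tolerance = 1e-9)
  expect_true(all(h$P >= 0))
  # oracle: cut()-based binning, computed independently
  bins <- cut(ph, breaks = seq(-pi, pi, length.out = 19),
              include.lowest = TRUE, right = FALSE)
  oracle_means <- as.vector(tapply(amp, bins, mean))
  expect_equal(unname(h$P), oracle_means / sum(oracle_means),
               tolerance = 1e-12)
  # uniform amplitude -> flat distribution
  hu <- phase_amplitude_histogram(ph, rep(2.5, n))
  expect_equal(hu$P, rep(1 / 18, 18))
  # amplitude confined to one bin
  amp1 <- ifelse(ph >= -pi & ph < -pi + 2 * pi / 18, 1, 0)
  h1 <- phase_amplitude_histogram(ph, amp1)
  expect_equal(h1$P[1], 1)
  expect_equal(sum(h1$P[-1]), 0)
})

test_that("empty phase bins raise an error naming the bin", {
  ph <- runif(50, 0, pi / 2)  # covers only a quarter cycle
  expect_error(phase_amplitude_histogram(ph, rep(1, 50)), "empty phase bin")
})

test_that("Kullback-Leibler MI hits its analytic anchors and a brute-force oracle", {
  n <- 3600
  ph <- uniform_phases(n)
  expect_equal(kl_tort(ph, rep(1, n))$value, 0)
  amp1 <- ifelse(ph >= -pi & ph < -pi + 2 * pi / 18, 1, 0)
  expect_equal(kl_tort(ph, amp1)$value, 1)
  # brute-force evaluation of D(P,Q)/log(Nbins) for amp = 1 + cos(phase)
  amp <- 1 + cos(ph)
  bins <- cut(ph, breaks = seq(-pi, pi, length.out = 19),
              include.lowest = TRUE, right = FALSE)
  P <- tapply(amp, bins, mean)
  P <- P / sum(P)
  D <- sum(P * log(P / (1 / 18)))
  expect_equal(kl_tort(ph, amp)$value, unname(D / log(18)), tolerance = 1e-12)
})

test_that("KL-Tort is insensitive to the bin count on coupled data", {
  # sweep coupling depth; values across 9/18/36 bins must co-vary tightly
  couplings <- c(0, 0.25, 0.5, 0.75, 1)
  vals <- sapply(c(9, 18, 36), function(nb) {
    sapply(couplings, function(cp) {
      ts <- simulate_pac_trials(simulation_spec(n_trials = 8, coupling = cp,
                                                snr_db = 0, seed = 300 + cp * 4))
      ap <- extract_analytic(ts, design_phase_band(10))
      aa <- extract_analytic(ts, design_amplitude_band(60))
      mean(sapply(seq_len(8), function(i)
        kl_tort(ap$phase[i, ], aa$amplitude[i, ], n_bins = nb)$value))
    })
  })
  cm <- cor(vals)
  expect_true(all(cm[upper.tri(cm)] > 0.95))
})

test_that("bounded metrics stay in [0, 1] over toy, null, coupled and adversarial inputs", {
  corpus <- list()
  set.seed(33)
  corpus$toy <- list(phase = c(0, pi / 2, -pi, -pi / 2), amp = c(2, 0, 0, 0))
  corpus$null <- list(phase = runif(1000, -pi, pi), amp = abs(rnorm(1000)))
  ts <- simulate_pac_trials(simulation_spec(n_trials = 2, seed = 9))
  ap <- extract_analytic(ts, design_phase_band(10))
  aa <- extract_analytic(ts, design_amplitude_band(60))
  corpus$coupled <- list(phase = ap$phase[1, ], amp = aa$amplitude[1, ])
  corpus$spiky <- list(phase = runif(500, -pi, pi),
                       amp = c(rep(1e-12, 499), 1e12))
  saw <- sawtooth_wave(10, 2)
  corpus$sawtooth <- list(
    phase = phaseamp:::wrap_phase(Arg(analytic_signal(saw))),
    amp = abs(analytic_signal(rnorm(2000))))
  for (cs in corpus) {
    expect_lte(plv_cohen(cs$phase, cs$amp)$value, 1)
    expect_gte(plv_cohen(cs$phase, cs$amp)$value, 0)
    kl <- tryCatch(kl_tort(cs$phase, cs$amp)$value, error = function(e) NA)
    if (!is.na(kl)) {
      expect_lte(kl, 1)
      expect_gte(kl, 0)
    }
    expect_lte(mvl_ozkurt(cs$phase, cs$amp)$value, 1)
  }
})

test_that("uncoupled inputs fall below their own surrogate 95th percentile", {
  grid <- grid_spec(phase_centers = 10, amp_centers = 60)
  below <- sapply(1:10, function(s) {
    ts <- noise_trials(n_trials = 8, dur = 2.2, seed = 400 + s)
    cc <- phaseamp:::analytic_cache(ts, grid)
    obs <- compute_comodulogram(ts, grid, cache = cc)
    su <- generate_surrogates(ts, grid, n = 100, seed = s, cache = cc)
    sapply(phaseamp:::mi_methods, function(m)
      obs$mi[[m]][1, 1] < quantile(su$values[[m]][, 1, 1], 0.95))
  })
  # pooled over the 4 metrics x 10 runs, at least 90 % below the 95th
  # surrogate percentile (the per-run indicator is itself Bernoulli(0.95))
  expect_gte(sum(below), 0.9 * length(below))
})

test_that("the dispatcher and the reference estimators agree", {
  set.seed(77)
  ph <- runif(600, -pi, pi)
  amp <- abs(rnorm(600)) + 0.05
  expect_identical(modulation_index("mvl_canolty", ph, amp)$value,
                   mvl_canolty(ph, amp)$value)
  expect_identical(modulation_index("kl_tort", ph, amp)$value,
                   kl_tort(ph, amp)$value)
})
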