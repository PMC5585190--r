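test_that("the default grid has the full 7 x 34 sideband-admissible layout", {
  g <- grid_spec()
  expect_length(g$phase_centers, 7)
  expect_length(g$amp_centers, 34)
  expect_identical(g$amp_centers[1], 34)
  expect_true(all(g$admissible))
  # a lower amplitude bound would violate sideband coverage and be flagged
  g2 <- grid_spec(amp_centers = seq(28, 40, 2))
  expect_false(all(g2$admissible))
  expect_error(grid_spec(phase_centers = c(9, 8)), "strictly increasing")
})

test_that("a single trial's per-trial layer equals the averaged grid exactly", {
  ts <- simulate_pac_trials(simulation_spec(n_trials = 1, seed = 3))
  g <- grid_spec(phase_centers = 9:11, amp_centers = c(56, 60, 64))
  cm <- compute_comodulogram(ts, g, keep_trials = TRUE)
  for (m in names(cm$mi))
    expect_equal(cm$mi[[m]], matrix(cm$per_trial[[m]][1, , ], 3, 3,
                                    dimnames = dimnames(cm$mi[[m]])))
})

test_that("the sweep's fast path agrees with the reference estimators cell by cell", {
  ts <- simulate_pac_trials(simulation_spec(n_trials = 4, seed = 21))
  g <- grid_spec(phase_centers = c(8, 10), amp_centers = c(50, 60))
  cm <- compute_comodulogram(ts, g, keep_trials = TRUE)
  for (p in 1:2) for (q in 1:2) {
    ap <- extract_analytic(ts, design_phase_band(g$phase_centers[p]))
    aa <- extract_analytic(ts, design_amplitude_band(g$amp_centers[q]))
    for (i in 1:4) {
      expect_equal(cm$per_trial$mvl_canolty[i, p, q],
                   mvl_canolty(ap$phase[i, ], aa$amplitude[i, ])$value,
                   tolerance = 1e-12)
      expect_equal(cm$per_trial$mvl_ozkurt[i, p, q],
                   mvl_ozkurt(ap$phase[i, ], aa$amplitude[i, ])$value,
                   tolerance = 1e-12)
      expect_equal(cm$per_trial$plv_cohen[i, p, q],
                   plv_cohen(ap$phase[i, ], aa$amplitude[i, ])$value,
                   tolerance = 1e-12)
      expect_equal(cm$per_trial$kl_tort[i, p, q],
                   kl_tort(ap$phase[i, ], aa$amplitude[i, ])$value,
                   tolerance = 1e-12)
    }
  }
})

test_that("comodulograms are deterministic and surrogate draws reproducible", {
  ts <- simulate_pac_trials(simulation_spec(n_trials = 6, seed = 8))
  g <- grid_spec(phase_centers = 10, amp_centers = c(58, 60))
  cm1 <- compute_comodulogram(ts, g)
  cm2 <- compute_comodulogram(ts, g)
  expect_identical(cm1$mi, cm2$mi)
  s1 <- generate_surrogates(ts, g, n = 20, seed = 99)
  s2 <- generate_surrogates(ts, g, n = 20, seed = 99)
  expect_identical(s1$values, s2$values)
  s3 <- generate_surrogates(ts, g, n = 20, seed = 100)
  expect_false(identical(s1$values, s3$values))
  expect_identical(dim(s1$values$kl_tort), dim(s3$values$kl_tort))
})

test_that("shuffling identical trials is a no-op", {
  one <- simulate_pac_trials(simulation_spec(n_trials = 1, seed = 17))
  X <- one$data[rep(1, 5), ]
  ts <- trial_series(X, fs = one$fs, t0 = one$t0, pad = one$pad)
  g <- grid_spec(phase_centers = 10, amp_centers = 60)
  cc <- phaseamp:::analytic_cache(ts, g)
  obs <- compute_comodulogram(ts, g, cache = cc)
  su <- generate_surrogates(ts, g, n = 10, seed = 1, cache = cc)
  for (m in names(obs$mi)) {
    expect_equal(max(abs(su$values[[m]] - obs$mi[[m]][1, 1])), 0,
                 tolerance = 1e-10)
  }
})

test_that("surrogate normalization is an exact standardized score", {
  g <- grid_spec(phase_centers = 9:10, amp_centers = c(50, 60))
  dn <- list(g$phase_centers, g$amp_centers)
  mu <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = dn)
  sd_ <- matrix(c(0.5, 1, 2, 4), 2, 2, dimnames = dn)
  fake_obs <- structure(list(mi = list(kl_tort = mu), grid = g, n_trials = 5,
                             condition = "x", normalized = FALSE),
                        class = "comodulogram")
  fake_surr <- structure(list(mean = list(kl_tort = mu),
                              sd = list(kl_tort = sd_),
                              n_surrogates = 10, grid = g),
                         class = "surrogate_ensemble")
  z0 <- normalize_mi(fake_obs, fake_surr)
  expect_equal(unname(z0$mi$kl_tort), matrix(0, 2, 2))
  fake_obs$mi$kl_tort <- mu + sd_
  z1 <- normalize_mi(fake_obs, fake_surr)
  expect_equal(unname(z1$mi$kl_tort), matrix(1, 2, 2))
  expect_true(z1$normalized)
  # zero spread flags the cell
  fake_surr$sd$kl_tort[1, 1] <- 0
  expect_warning(zf <- normalize_mi(fake_obs, fake_surr), "zero surrogate spread")
  expect_true(is.na(zf$mi$kl_tort[1, 1]))
})

test_that("coupled data stand out from their trial-shuffled surrogates", {
  ts <- simulate_pac_trials(simulation_spec(n_trials = 16, seed = 7))
  g <- grid_spec(phase_centers = 10, amp_centers = 60)
  cc <- phaseamp:::analytic_cache(ts, g)
  obs <- compute_comodulogram(ts, g, cache = cc)
  su <- generate_surrogates(ts, g, n = 100, seed = 1, cache = cc)
  for (m in names(obs$mi)) {
    expect_gt(obs$mi[[m]][1, 1],
              su$mean[[m]][1, 1] + 2 * su$sd[[m]][1, 1])
  }
  # normalized peak location equals raw peak location on a small grid
  g2 <- grid_spec(phase_centers = 9:11, amp_centers = c(44, 60, 76))
  cc2 <- phaseamp:::analytic_cache(ts, g2)
  obs2 <- compute_comodulogram(ts, g2, cache = cc2)
  su2 <- generate_surrogates(ts, g2, n = 100, seed = 2, cache = cc2)
  nz <- normalize_mi(obs2, su2)
  for (m in c("mvl_ozkurt", "kl_tort")) {
    expect_identical(comodulogram_peak(nz, m)$amp, 60)
  }
})

test_that("white-noise comodulograms show no systematic surrogate exceedance", {
  # 10 null datasets x 15 cells; under exchangeability the observed value
  # tops all 100 surrogates with probability 1/101 per cell
  g <- grid_spec(phase_centers = 9:11, amp_centers = seq(40, 80, 10))
  exceed <- 0L
  for (s in 1:10) {
    ts <- noise_trials(n_trials = 8, dur = 2.2, seed = 500 + s)
    cc <- phaseamp:::analytic_cache(ts, g)
    obs <- compute_comodulogram(ts, g, cache = cc)
    su <- generate_surrogates(ts, g, n = 100, seed = s, cache = cc)
    top <- apply(su$values$mvl_ozkurt, c(2, 3), max)
    exceed <- exceed + sum(obs$mi$mvl_ozkurt > top)
  }
  expect_lte(exceed, qbinom(0.999, 150, 1 / 101))
})

test_that("surrogate generation refuses fewer than 2 trials", {
  ts <- simulate_pac_trials(simulation_spec(n_trials = 1, seed = 1))
  g <- grid_spec(phase_centers = 10, amp_centers = 60)
  expect_error(generate_surrogates(ts, g, n = 5), "fewer than 2 trials")
})
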