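test_that("time-domain SNR is peak over out-of-burst noise, with Inf flagged", {
  set.seed(10)
  fs <- 20e6
  x <- rnorm(2000, sd = 0.1)
  x[1] <- 1
  igm <- interferogram(x, fs, channel = "pa")
  res <- time_domain_snr(igm)
  t <- (seq_len(2000) - 1) / fs
  d <- pmin(t, 1e-4 - t)
  manual <- max(abs(x[d <= 2.4e-6])) / sd(x[d > 7.2e-6])
  expect_equal(res$value, manual)
  expect_equal(res$value, 10, tolerance = 0.5)       # peak 1 V over 0.1 V noise
  expect_false(res$infinite)
  expect_equal(res$averaging_time, 1e-4)

  clean <- interferogram(c(1, rep(0, 1999)), fs)
  expect_true(time_domain_snr(clean)$infinite)
  expect_equal(time_domain_snr(clean)$value, Inf)
  expect_error(time_domain_snr(igm, 1e-6, 1e-7), "exclusion")
})

test_that("a polymer scene at unit single-shot SNR reaches ~32 after 1024 averages", {
  nd <- calibrate_noise(pdms_demo(), target_snr = 1)
  scene <- pdms_demo(noise = nd, seed = 6)
  # at unit single-shot SNR the peak estimate is dominated by the noise
  # maximum inside the search window, so the anchor is checked after
  # averaging, where the peak is unambiguous: SNR(1024) = 32 * SNR(1)
  snr1024 <- mean(sapply(1:8, function(r) averaged_snr(scene, 1024, r)$value))
  expect_equal(snr1024, 32, tolerance = 0.1)
})

test_that("spectral SNR needs replicates and matches Rayleigh statistics on noise", {
  grid <- tibble::tibble(f_acoustic = 1:10, magnitude = 1)
  expect_error(spectral_snr(rep(list(grid), 5)), "8")
  identical_reps <- spectral_snr(rep(list(grid), 10))
  expect_true(all(identical_reps$infinite))

  # magnitudes of FFT bins of white noise are Rayleigh; per-bin mean/sd is
  # sqrt(pi/2) / sqrt(2 - pi/2) = 1.9131 (analytic moments oracle)
  reps <- lapply(1:100, function(r) {
    magnitude_spectrum(interferogram(
      with_seed_helper(r, rnorm(512)), 1e6))
  })
  ss <- spectral_snr(reps)
  expect_equal(mean(ss$snr), sqrt(pi / 2) / sqrt(2 - pi / 2), tolerance = 0.03)

  # strong fixed signal: per-bin SNR approaches s/sigma
  sig <- lapply(1:32, function(r) {
    m <- grid
    m$magnitude <- 50 + with_seed_helper(200 + r, rnorm(10))
    m
  })
  expect_equal(mean(spectral_snr(sig)$snr), 50, tolerance = 0.2)
})

test_that("sqrt-tau fits recover exact laws and flag coherent drift", {
  tau <- c(0.01, 0.1, 1, 10, 100)
  exact <- tibble::tibble(value = 3 * sqrt(tau), averaging_time = tau)
  fit <- fit_sqrt_tau(exact)
  expect_equal(fit$A, 3, tolerance = 1e-9)
  expect_equal(fit$exponent, 0.5, tolerance = 1e-9)
  expect_true(fit$white_noise_consistent)
  expect_equal(tidy(fit)$estimate[1], 3, tolerance = 1e-9)

  drift <- tibble::tibble(value = 2 * tau, averaging_time = tau)
  fit_d <- fit_sqrt_tau(drift)
  expect_equal(fit_d$exponent, 1, tolerance = 1e-9)
  expect_false(fit_d$white_noise_consistent)

  expect_error(fit_sqrt_tau(exact[1:3, ]), ">= 4")
  expect_error(fit_sqrt_tau(tibble::tibble(value = c(1, 2, 3, 4),
                                           averaging_time = c(1, 2, 3, 4))),
               "decade")
})

test_that("power fits recover linear SNR scaling and flag shot-noise curves", {
  p <- c(6, 12, 18, 24)
  lin <- tibble::tibble(value = 2 * p, power = p)
  fit <- fit_power_linear(lin)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$exponent, 1, tolerance = 1e-9)
  expect_true(fit$detector_noise_consistent)

  shot <- tibble::tibble(value = 4 * sqrt(p), power = p)
  fit_s <- fit_power_linear(shot)
  expect_equal(fit_s$exponent, 0.5, tolerance = 1e-9)
  expect_false(fit_s$detector_noise_consistent)

  expect_error(fit_power_linear(tibble::tibble(value = c(1, 2), power = c(1, 2))),
               ">= 3")
  expect_error(fit_power_linear(tibble::tibble(value = c(1, 2, 3),
                                               power = c(2, 2, 2))),
               "distinct")
})

test_that("the acquisition-time calculator reproduces the projection arithmetic", {
  base <- acquisition_time_scale()
  expect_equal(base$time_factor, 1)
  expect_equal(base$projected_time, 7200)

  rep_only <- acquisition_time_scale(f_rep_factor = 3000)
  expect_equal(rep_only$snr_factor, sqrt(3000))

  proj <- acquisition_time_scale(f_rep_factor = 3000, absorbance_factor = 10,
                                 baseline_time = 7200)
  expect_equal(1 / proj$time_factor, 300000)
  expect_equal(proj$projected_time, 0.024)

  # multiplicative composition of scenarios
  a <- acquisition_time_scale(f_rep_factor = 5, power_factor = 2)
  b <- acquisition_time_scale(absorbance_factor = 3, noise_factor = 2)
  ab <- acquisition_time_scale(f_rep_factor = 5, power_factor = 2,
                               absorbance_factor = 3, noise_factor = 2)
  expect_equal(ab$time_factor, a$time_factor * b$time_factor)
  expect_error(acquisition_time_scale(f_rep_factor = 0), "> 0")
})

test_that("noise calibration and the shots-to-threshold search are consistent", {
  nd <- calibrate_noise(pdms_demo(), target_snr = 8)
  scene <- pdms_demo(noise = nd, seed = 12)
  snr1 <- mean(sapply(1:8, function(r) averaged_snr(scene, 1, r)$value))
  expect_equal(snr1, 8, tolerance = 0.15)

  # single shot already above a low threshold
  expect_equal(shots_to_reach_snr(scene, threshold = 4, stream = 1), 1)
  # reaching 4x the single-shot SNR needs ~16 shots
  m16 <- shots_to_reach_snr(scene, threshold = 32, stream = 2)
  expect_gt(m16, 8)
  expect_lt(m16, 32)
  expect_error(shots_to_reach_snr(pdms_demo()), "no noise")
})
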