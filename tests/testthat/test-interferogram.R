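test_that("on-grid synthesis reproduces cosines, centerbursts and Parseval", {
  pair <- edge_pair(n_teeth = 8, delta_f = 1e4)
  b <- beat_notes(pair)

  one <- b[b$index == 3, ]
  one$amplitude <- 0.7
  igm <- synthesize(one, sample_rate = 2e6, delta_f_rep = 1e4)
  n <- length(igm$samples)
  t <- (seq_len(n) - 1) / igm$sample_rate
  expect_equal(igm$samples, 0.7 * cos(2 * pi * 3e4 * t), tolerance = 1e-12)
  expect_equal(max(igm$samples), 0.7)                # peak A at t = 0

  # constructive interference: N zero-phase notes of amplitude A peak at N*A
  many <- dplyr::mutate(b, amplitude = 0.25)
  igm_m <- synthesize(many, 2e6, 1e4)
  n_notes <- sum(b$index >= 1)                       # DC excluded
  expect_equal(igm_m$samples[1], n_notes * 0.25)
  expect_equal(mean(igm_m$samples), 0, tolerance = 1e-12)  # no DC term

  # Parseval: sum x^2 dt = sum A^2/2 * T for on-grid tones
  set.seed(1)
  rnd <- dplyr::mutate(b, amplitude = runif(nrow(b)), phase = runif(nrow(b), 0, 2 * pi))
  igm_r <- synthesize(rnd, 2e6, 1e4)
  lhs <- sum(igm_r$samples^2) / igm_r$sample_rate
  rhs <- sum(rnd$amplitude[rnd$index >= 1]^2) / 2 * (1 / 1e4)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # magnitude round trip recovers every amplitude on its bin
  spec <- magnitude_spectrum(igm_r)
  got <- spec$magnitude[rnd$index[rnd$index >= 1]]
  expect_equal(got, rnd$amplitude[rnd$index >= 1], tolerance = 1e-9)

  # aliasing guard
  expect_error(synthesize(b, sample_rate = 1e5, delta_f_rep = 1e4), "alias")
})

test_that("shots are reproducible and carry the acoustic delay", {
  scene <- pdms_demo()
  s0 <- simulate_shot(scene, 0)
  s1 <- simulate_shot(scene, 1)
  expect_identical(s0$pa$samples, s1$pa$samples)   # no noise, no jitter
  expect_identical(s0$reference$samples, s1$reference$samples)

  # PA centerburst delayed by t_acoustic = 14 us
  fs <- s0$pa$sample_rate
  expect_equal(which.max(abs(s0$pa$samples)) - 1, round(14e-6 * fs))
  expect_equal(s0$pa$t0, 14e-6)
  # reference centerburst at the origin
  expect_equal(which.max(abs(s0$reference$samples)), 1L)

  # noisy scenes: same seed identical, different shot index different
  sn <- pdms_demo(noise = 1e-7, seed = 5)
  expect_identical(simulate_shot(sn, 0)$pa$samples, simulate_shot(sn, 0)$pa$samples)
  expect_false(identical(simulate_shot(sn, 0)$pa$samples,
                         simulate_shot(sn, 1)$pa$samples))
})

test_that("strong and weak absorbers differ by the calibrated amplitude ratios", {
  peak <- function(name) {
    sc <- scene_from_config(make_fixture(name, noise_density = 0))
    max(abs(simulate_average(sc, 1)$pa$samples))
  }
  v <- peak("vacnt"); p <- peak("pdms"); f <- peak("paraffin")
  expect_equal(v / p, 100, tolerance = 0.05)
  expect_equal(v / f, 50, tolerance = 0.05)
  expect_equal(f / p, 2, tolerance = 0.05)
})

test_that("coherent averaging obeys the sqrt(M) law and validates inputs", {
  scene <- pdms_demo(noise = calibrate_noise(pdms_demo(), 10), seed = 2)

  # noiseless: the average of identical shots is any one of them
  clean <- pdms_demo()
  shots <- lapply(0:3, function(i) simulate_shot(clean, i)$pa)
  expect_equal(coherent_average(shots)$samples, shots[[1]]$samples)
  expect_equal(coherent_average(shots)$n_averaged, 4)

  # M = 4 shots with independent noise: time-domain SNR about x2
  snr1 <- mean(sapply(1:6, function(r) averaged_snr(scene, 1, r)$value))
  shots4 <- lapply(0:3, function(i) simulate_shot(scene, i)$pa)
  avg4 <- remove_acoustic_delay(coherent_average(shots4), scene$chain$t_acoustic)
  expect_equal(time_domain_snr(avg4)$value / snr1, 2, tolerance = 0.25)

  expect_error(coherent_average(list()), "empty")
  bad <- shots
  bad[[2]] <- interferogram(bad[[2]]$samples[-1], bad[[2]]$sample_rate, channel = "pa")
  expect_error(coherent_average(bad), "differ")
})

test_that("phase correction recovers jitter-attenuated averages", {
  jit <- demo_scene(sample = builtin_sample("pdms_like"),
                    phase_jitter_std = 0.5, seed = 9)
  shots <- lapply(0:63, function(i) simulate_shot(jit, i))
  refs <- lapply(shots, `[[`, "reference")
  pas <- lapply(shots, `[[`, "pa")
  base <- simulate_shot(pdms_demo(), 0)$pa

  uncorrected <- coherent_average(pas)
  corrected <- coherent_average(pas, correct_phase = TRUE, reference = refs)
  peak0 <- max(abs(base$samples))
  # phasor averaging: E[cos(phi)] = exp(-sigma^2/2) = 0.8825 for sigma = 0.5
  expect_equal(max(abs(uncorrected$samples)) / peak0, exp(-0.125),
               tolerance = 0.08)
  expect_gte(max(abs(corrected$samples)) / peak0, 0.95)
})

test_that("acoustic-delay removal is an exact circular inverse", {
  x <- rep(0, 1000); x[281] <- 1                    # spike 280 samples in
  igm <- interferogram(x, 20e6, t0 = 14e-6, channel = "pa")
  out <- remove_acoustic_delay(igm, 14e-6)          # 14 us at 20 MS/s = 280
  expect_equal(which.max(out$samples), 1L)
  expect_equal(out$t0, 0)
  expect_identical(remove_acoustic_delay(igm, 0)$samples, x)

  scene <- pdms_demo()
  pa <- simulate_average(scene, 1)$pa
  back <- remove_acoustic_delay(pa, scene$chain$t_acoustic)
  expect_equal(which.max(abs(back$samples)), 1L)
  expect_warning(remove_acoustic_delay(igm, 1), "wraps")
})

test_that("interferograms round-trip through CSV with sidecar metadata", {
  igm <- simulate_average(pdms_demo(), 3)$pa
  path <- withr::local_tempfile(fileext = ".csv")
  write_interferogram_csv(igm, path)
  back <- read_interferogram_csv(path)
  expect_equal(back$samples, igm$samples)
  expect_equal(back$sample_rate, igm$sample_rate)
  expect_equal(back$t0, igm$t0)
  expect_equal(back$channel, "pa")
  expect_equal(back$n_averaged, 3)
})
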