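test_that("apodization zeroes outside the window and preserves record length", {
  igm <- interferogram(rep(1, 2000), 20e6)          # 100 us record
  cfg <- processing_config(apodization_width = 4.8e-6)
  ap <- apodize(igm, cfg)
  expect_length(ap$samples, 2000)
  expect_equal(sum(ap$samples != 0), 96)            # 4.8 us at 20 MS/s
  t <- (seq_len(2000) - 1) / 20e6
  outside <- pmin(t, 1e-4 - t) > 2.4e-6
  expect_true(all(ap$samples[outside] == 0))        # energy outside = 0 exactly

  # window at least as long as the record: identity
  wide <- processing_config(apodization_width = 1)
  expect_identical(apodize(igm, wide)$samples, igm$samples)

  # hann tapers to the window edge and keeps the center untouched
  hn <- apodize(igm, processing_config(apodization_width = 4.8e-6,
                                       apodization_shape = "hann"))
  expect_equal(hn$samples[1], 1)
  expect_lt(max(abs(hn$samples[49:1952])), 0.01)
})

test_that("magnitude spectra are amplitude-calibrated on the bin grid", {
  n <- 2000
  t <- (seq_len(n) - 1) / 2e6
  igm <- interferogram(cos(2 * pi * 5e4 * t), 2e6)  # bin 50 of 1 kHz grid
  spec <- magnitude_spectrum(igm)
  expect_equal(spec$magnitude[50], 1, tolerance = 1e-12)
  expect_lt(max(spec$magnitude[-50]), 1e-9)
  expect_equal(spec$f_acoustic[50], 5e4)

  two <- interferogram(cos(2 * pi * 5e4 * t) + 0.5 * cos(2 * pi * 1.2e5 * t), 2e6)
  sp2 <- magnitude_spectrum(two)
  expect_equal(sp2$magnitude[50] / sp2$magnitude[120], 2, tolerance = 1e-9)

  expect_error(magnitude_spectrum(interferogram(numeric(0), 1e6)), "empty")
})

test_that("a rectangular window turns a tone into a sinc of width ~1.21/w", {
  # 4.8 us rectangular apodization: tone-response FWHM ~ 1.2067 / w = 251 kHz
  delta_f <- 1000
  fs <- 20e6
  t <- (seq_len(fs / delta_f) - 1) / fs
  igm <- interferogram(cos(2 * pi * 5e6 * t), fs)
  ap <- apodize(igm, processing_config(apodization_width = 4.8e-6))
  spec <- magnitude_spectrum(ap)
  fw <- estimate_fwhm(spec$f_acoustic, spec$magnitude)
  expect_equal(fw, 1.2067 / 4.8e-6, tolerance = 0.02)
})

test_that("optical mapping relabels bins without touching magnitudes", {
  pair <- canonical_pair()
  spec <- tibble::tibble(f_acoustic = seq(1e6, 10e6, by = 1e5),
                         magnitude = runif(91))
  mapped <- map_to_optical(spec, pair)
  expect_equal(mapped$magnitude, spec$magnitude)
  expect_equal(sum(mapped$magnitude), sum(spec$magnitude))
  expect_equal(mapped$nu_optical, pair$nu0 + pair$scale * spec$f_acoustic)
  # apodization-limited resolution after mapping: 1/w * scale ~ 500 GHz
  expect_equal((1 / 4.8e-6) * pair$scale, 5e11, tolerance = 0.01)
})

test_that("normalization cancels excitation and instrument response exactly", {
  scene <- demo_scene(sample = builtin_sample("vacnt_like"))
  no_apod <- processing_config(apodization_width = 1)
  rec <- recover_absorption(scene, 1, no_apod)
  s <- rec$spectra[!rec$spectra$masked, ]
  # flat absorber: normalized response constant = absorbed fraction (beta = 1)
  expect_lt(diff(range(s$pa_normalized)) / mean(s$pa_normalized), 1e-6)
  af <- absorbed_fraction(scene$sample, s$nu_optical[1])
  expect_equal(mean(s$pa_normalized), af, tolerance = 1e-9)
  expect_true(all(is.na(rec$spectra$pa_normalized[rec$spectra$masked])))

  # linear-regime bound: V_hat / (beta * mu_a * L) within mu_a*L/2 of 1
  pd <- demo_scene(sample = builtin_sample("pdms_like"))
  rec_p <- recover_absorption(pd, 1, no_apod)
  sp <- rec_p$spectra[!rec_p$spectra$masked, ]
  mul <- absorbed_fraction(pd$sample, sp$nu_optical, "linearized")
  ratio <- sp$pa_normalized / mul
  expect_true(all(abs(ratio - 1) <= mul / 2 + 1e-9))

  expect_error(
    normalize_pa(tibble::tibble(f_acoustic = 1:3, magnitude = 1),
                 tibble::tibble(f_acoustic = 1:4, magnitude = 1),
                 make_transducer()),
    "identical acoustic grid")
})

test_that("spectral SNR grows fourfold for a sixteenfold shot increase", {
  # signal-dominated regime (the sqrt(M) law for magnitude spectra breaks
  # down in the Rician low-SNR regime), measured at the strongest bins
  nd <- calibrate_noise(pdms_demo(), 8)
  scene <- pdms_demo(noise = nd, seed = 4)
  spec_at <- function(m, r) {
    scene_r <- scene; scene_r$seed <- 100 * m + r
    rec <- recover_absorption(scene_r, m)
    s <- rec$spectra[!rec$spectra$masked, ]
    tibble::tibble(f_acoustic = s$f_acoustic, magnitude = s$pa_raw)
  }
  snr_at_signal <- function(m) {
    reps <- lapply(1:32, function(r) spec_at(m, r))
    ss <- spectral_snr(reps)
    mean(ss$snr[order(ss$mean, decreasing = TRUE)[1:50]])
  }
  expect_equal(snr_at_signal(64) / snr_at_signal(4), 4, tolerance = 0.15)
})

test_that("spectral-averaging SNR gain follows sqrt(bins per element)", {
  expect_equal(apodization_snr_gain(3125), sqrt(3125))
  mc <- apodization_snr_gain(25, "montecarlo", n_bins = 2500, repeats = 100,
                             seed = 3)
  expect_equal(mc, 5, tolerance = 0.05)
})

test_that("peak finding and width estimation work on shaped spectra", {
  x <- seq(0, 100, by = 0.1)
  y <- 2 * exp(-4 * log(2) * ((x - 40) / 5)^2)
  expect_equal(estimate_fwhm(x, y), 5, tolerance = 1e-3)

  rec <- recover_absorption(scene_from_config(make_fixture("pdms", noise_density = 0)), 1)
  pk <- spectrum_peaks(rec)
  expect_equal(sort(pk$nu_optical), c(171.6e12, 176.0e12, 177.4e12),
               tolerance = 1e-3)
  expect_equal(pk$nu_optical[1], 171.6e12, tolerance = 1e-3)  # tallest first
})
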