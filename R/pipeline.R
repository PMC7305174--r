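#' Canned run configurations for the three canonical samples
#'
#' Returns a fully specified `run_config` reproducing the demonstration
#' regime: 160 MHz combs with `delta_f_rep` = 66.81 Hz, a 15 THz band
#' anchored so 7.5 MHz maps to 171.2 THz, a Gaussian 7.5 MHz / 7.5 MHz FWHM
#' transducer, 80 dB gain, 15 MHz low-pass, 14 us acoustic delay, and the
#' matching built-in sample. Detector noise defaults to the level at which
#' the paraffin fixture reaches a single-shot time-domain SNR of 1; pass
#' `noise_density = 0` for noiseless runs.
#'
#' @param name `"vacnt"`, `"pdms"` or `"paraffin"`.
#' @param m_shots Number of coherently averaged shots (default 16).
#' @param repeats Repeated noise realizations for spectral-SNR output
#'   (default 0 = skip).
#' @param seed Base seed (default 0).
#' @param noise_density Detector noise (V/sample before gain), or `NULL`
#'   (default) for the calibrated level.
#' @return A `run_config` list understood by [scene_from_config()] and
#'   [run_pipeline()].
#' @export
make_fixture <- function(name, m_shots = 16, repeats = 0, seed = 0,
                         noise_density = NULL) {
  valid <- c(vacnt = "vacnt_like", pdms = "pdms_like", paraffin = "paraffin_like")
  if (!is.character(name) || length(name) != 1L || !name %in% names(valid)) {
    abort(sprintf("unknown fixture; valid names: %s",
                  paste(names(valid), collapse = ", ")))
  }
  config <- list(
    comb = list(f_rep1_Hz = 160e6, delta_f_rep_Hz = 66.81,
                band_center_Hz = 171.2e12, band_width_Hz = 15e12,
                anchor_f_us_Hz = 7.5e6, anchor_nu_Hz = 171.2e12,
                envelope = list(type = "gaussian", total_power_W = 24e-3,
                                fwhm_Hz = 10e12)),
    sample = list(name = valid[[name]]),
    transducer = list(f_peak_Hz = 7.5e6, bandwidth_Hz = 7.5e6,
                      shape = "gaussian"),
    chain = list(gain_db = 80, lowpass_Hz = 15e6, lowpass_order = 4,
                 noise_density_V = noise_density, t_acoustic_s = 14e-6),
    processing = list(apodization_width_s = 4.8e-6,
                      apodization_shape = "rectangular",
                      mask_threshold = 0.05),
    simulation = list(sample_rate_Hz = 30e6, m_shots = m_shots,
                      repeats = repeats, seed = seed,
                      phase_jitter_std_rad = 0)
  )
  if (is.null(noise_density)) {
    ref <- config
    ref$sample$name <- "paraffin_like"
    ref$chain$noise_density_V <- 0
    config$chain$noise_density_V <- calibrate_noise(scene_from_config(ref),
                                                    target_snr = 1)
  }
  structure(config, class = "run_config")
}

#' Build a simulation scene from a run configuration
#'
#' @param config A `run_config` (e.g. from [make_fixture()] or
#'   [read_config()]).
#' @return A [sim_scene()].
#' @export
scene_from_config <- function(config) {
  cb <- config$comb
  env <- cb$envelope %||% list(type = "uniform", total_power_W = 24e-3)
  envelope <- switch(env$type,
    uniform = envelope_uniform(env$total_power_W),
    gaussian = envelope_gaussian(env$total_power_W, fwhm = env$fwhm_Hz,
                                 center = env$center_Hz %||% NULL),
    tabulated = envelope_tabulated(env$nu_Hz, env$power, env$total_power_W),
    abort("unknown envelope type in config.")
  )
  anchor <- if (!is.null(cb$anchor_f_us_Hz)) {
    c(f_us = cb$anchor_f_us_Hz, nu = cb$anchor_nu_Hz)
  }
  pair <- build_comb_pair(cb$f_rep1_Hz, cb$delta_f_rep_Hz,
                          nu_center = cb$band_center_Hz,
                          bandwidth = cb$band_width_Hz,
                          envelope = envelope, anchor = anchor)
  sm <- config$sample
  sample <- if (!is.null(sm$name)) {
    builtin_sample(sm$name)
  } else {
    spectrum_from_peaks(
      peak_model(centers = sm$centers_Hz, fwhms = sm$fwhms_Hz,
                 heights = sm$heights_per_m, baseline = sm$baseline_per_m %||% 0,
                 shape = sm$shape %||% "gaussian"),
      nu_grid = seq(cb$band_center_Hz - 0.6 * cb$band_width_Hz,
                    cb$band_center_Hz + 0.6 * cb$band_width_Hz,
                    length.out = 2001),
      thickness = sm$thickness_m %||% 240e-6, beta = sm$beta %||% 1)
  }
  tr <- config$transducer
  transducer <- if (!is.null(tr$curve_csv)) {
    d <- readr::read_csv(tr$curve_csv, show_col_types = FALSE)
    tabulated_transducer(d[[1]], d[[2]])
  } else {
    make_transducer(tr$f_peak_Hz, tr$bandwidth_Hz, tr$shape %||% "gaussian")
  }
  ch <- config$chain
  chain <- detection_chain(gain_db = ch$gain_db %||% 80,
                           lowpass_cutoff = ch$lowpass_Hz %||% 15e6,
                           lowpass_order = ch$lowpass_order %||% 4,
                           noise_density = ch$noise_density_V %||% 0,
                           t_acoustic = ch$t_acoustic_s %||% 14e-6)
  sim <- config$simulation %||% list()
  sim_scene(pair, sample, transducer, chain,
            sample_rate = sim$sample_rate_Hz %||% 30e6,
            phase_jitter_std = sim$phase_jitter_std_rad %||% 0,
            seed = sim$seed %||% 0)
}

processing_from_config <- function(config) {
  pc <- config$processing %||% list()
  processing_config(
    apodization_width = pc$apodization_width_s %||% 4.8e-6,
    apodization_shape = pc$apodization_shape %||% "rectangular",
    mask_threshold = pc$mask_threshold %||% 0.05)
}

#' Read/write run configurations
#'
#' YAML (if the `yaml` package is available and the path ends in `.yml`/
#' `.yaml`) or JSON nested key-value files; all physical quantities carry
#' unit suffixes in their key names (`_Hz`, `_s`, `_W`, `_V`).
#'
#' @param path File path.
#' @param config A `run_config`.
#' @return `read_config()` returns a `run_config`; `write_config()` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the `yaml` package.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("writing YAML configs requires the `yaml` package.")
    }
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Run the full simulation + recovery pipeline to disk
#'
#' Simulates the configured scene, recovers the absorption spectrum, and
#' writes an artifact bundle: beat-note table, averaged interferograms (CSV +
#' JSON sidecars), recovered spectrum, SNR summary, optional spectral-SNR
#' table over repeated noise realizations, and a provenance log. Identical
#' configs produce byte-identical numerical outputs.
#'
#' @param config A `run_config`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create output dir `%s`.", outdir))
  scene <- scene_from_config(config)
  pconf <- processing_from_config(config)
  sim <- config$simulation %||% list()
  m <- sim$m_shots %||% 1
  files <- list()
  p <- function(f) file.path(outdir, f)

  readr::write_csv(
    setNames(beat_notes(scene$pair),
             c("index", "nu_optical_Hz", "f_acoustic_Hz", "amplitude_W",
               "phase_rad")),
    files$beat_notes <- p("beat_notes.csv"))

  avg <- if (scene$phase_jitter_std > 0) {
    shots <- lapply(seq_len(m) - 1, function(i) simulate_shot(scene, i))
    refs <- lapply(shots, `[[`, "reference")
    list(reference = coherent_average(refs, correct_phase = TRUE),
         pa = coherent_average(lapply(shots, `[[`, "pa"),
                               correct_phase = TRUE, reference = refs))
  } else {
    simulate_average(scene, m)
  }
  write_interferogram_csv(avg$reference,
                          files$reference <- p("interferogram_reference.csv"))
  write_interferogram_csv(avg$pa, files$pa <- p("interferogram_pa.csv"))

  rec <- recover_absorption(scene, m_shots = m, config = pconf)
  readr::write_csv(
    dplyr::select(rec$spectra,
                  nu_optical_Hz = "nu_optical", f_acoustic_Hz = "f_acoustic",
                  excitation_mag = "excitation", pa_raw_mag = "pa_raw",
                  pa_normalized = "pa_normalized", masked = "masked"),
    files$spectrum <- p("recovered_spectrum.csv"))

  snr <- time_domain_snr(remove_acoustic_delay(avg$pa, scene$chain$t_acoustic))
  jsonlite::write_json(as.list(snr), files$snr <- p("snr_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  repeats <- sim$repeats %||% 0
  if (repeats >= 8) {
    specs <- lapply(seq_len(repeats), function(r) {
      scene_r <- scene
      scene_r$seed <- derive_seed(scene$seed, 7000 + r)
      rec_r <- recover_absorption(scene_r, m_shots = m, config = pconf)
      s <- rec_r$spectra[!rec_r$spectra$masked, ]
      tibble(f_acoustic = s$f_acoustic, nu_optical = s$nu_optical,
             magnitude = s$pa_normalized)
    })
    readr::write_csv(spectral_snr(specs), files$spectral_snr <- p("spectral_snr.csv"))
  }

  jsonlite::write_json(
    list(config = unclass(config),
         package = list(name = "dcpas",
                        version = as.character(utils::packageVersion("dcpas")),
                        r_version = R.version.string),
         record = list(n_samples = length(avg$pa$samples),
                       sample_rate_Hz = avg$pa$sample_rate)),
    files$provenance <- p("provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(files)
}

#' Reduced-scale demonstration scene
#'
#' A desk-scale scene preserving the structure of the full configuration
#' (160 MHz combs, transducer-centered band, 14 us delay) but with a larger
#' repetition-rate difference (16 kHz) so one interferogram period is 2000
#' samples instead of ~450,000. Useful for Monte-Carlo experiments where many
#' averaged records are needed.
#'
#' @param sample An `absorption_spectrum` (default pdms-like).
#' @param noise_density Detector noise (V/sample before gain), default 0.
#' @param delta_f_rep Repetition-rate difference (Hz), default 16 kHz.
#' @param band_width Optical bandwidth (Hz), default 64 GHz (about 400 teeth).
#' @param sample_rate Digitizer rate (Hz), default 32 MS/s.
#' @param seed,phase_jitter_std Passed to [sim_scene()].
#' @param beta Photoacoustic conversion scale applied to the sample.
#' @return A [sim_scene()].
#' @export
demo_scene <- function(sample = builtin_sample("pdms_like"),
                       noise_density = 0, delta_f_rep = 16e3,
                       band_width = 64e9, sample_rate = 32e6, seed = 0,
                       phase_jitter_std = 0, beta = NULL) {
  if (!is.null(beta)) sample$beta <- beta
  center <- 171.2e12
  pair <- build_comb_pair(160e6, delta_f_rep, nu_center = center,
                          bandwidth = band_width,
                          anchor = c(f_us = 7.5e6, nu = center))
  sim_scene(pair, sample,
            chain = detection_chain(noise_density = noise_density),
            sample_rate = sample_rate, seed = seed,
            phase_jitter_std = phase_jitter_std)
}
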