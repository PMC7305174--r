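#' Processing configuration for spectrum recovery
#'
#' @param apodization_width Apodization window width (s), default 4.8 us —
#'   trades spectral resolution (~1/width in acoustic frequency) for
#'   per-element SNR.
#' @param apodization_shape `"rectangular"` (default; boxcar averaging of
#'   independent spectral samples) or `"hann"`.
#' @param zero_pad Keep the record length after windowing (zeros outside the
#'   window), so the spectrum stays on the beat-note bin grid. Default `TRUE`.
#' @param mask_threshold Fraction of peak below which excitation/response bins
#'   are excluded from normalization (default 0.05).
#' @return An object of class `processing_config`.
#' @export
processing_config <- function(apodization_width = 4.8e-6,
                              apodization_shape = c("rectangular", "hann"),
                              zero_pad = TRUE, mask_threshold = 0.05) {
  apodization_shape <- match.arg(apodization_shape)
  check_number(apodization_width, "apodization_width", positive = TRUE)
  check_number(mask_threshold, "mask_threshold", nonneg = TRUE)
  if (mask_threshold >= 1) abort("`mask_threshold` must be < 1.")
  structure(list(apodization_width = apodization_width,
                 apodization_shape = apodization_shape,
                 zero_pad = zero_pad, mask_threshold = mask_threshold),
            class = "processing_config")
}

#' Apodize an interferogram
#'
#' Zeroes all samples whose circular distance from the centerburst (`t0`)
#' exceeds half the window width, and weights the remainder by the window
#' shape. The record length is unchanged (zero-padding outside the window).
#'
#' @param igm An `interferogram`.
#' @param config A [processing_config()].
#' @return The apodized `interferogram`.
#' @export
apodize <- function(igm, config = processing_config()) {
  stopifnot(inherits(igm, "interferogram"), inherits(config, "processing_config"))
  n <- length(igm$samples)
  period <- n / igm$sample_rate
  w <- config$apodization_width
  if (w >= period) return(igm)   # window covers the record: identity
  t <- (seq_len(n) - 1) / igm$sample_rate
  d <- circular_distance(t, igm$t0, period)
  inside <- d <= w / 2
  win <- as.double(inside)
  if (config$apodization_shape == "hann") {
    win[inside] <- 0.5 * (1 + cos(2 * pi * d[inside] / w))
  }
  igm$samples <- igm$samples * win
  igm
}

#' One-sided magnitude spectrum of an interferogram
#'
#' Bin spacing is `sample_rate / length` — exactly `|delta_f_rep|` for a
#' full-period record, so every beat note has its own bin. The amplitude
#' calibration makes an on-grid unit cosine (no apodization) read 1 at its
#' bin. DC and the Nyquist bin are dropped.
#'
#' @param igm An `interferogram`.
#' @return A tibble with `f_acoustic` (Hz) and `magnitude` (V).
#' @export
magnitude_spectrum <- function(igm) {
  stopifnot(inherits(igm, "interferogram"))
  n <- length(igm$samples)
  if (n == 0) abort("empty record.")
  x <- fft(igm$samples)
  k <- seq_len(ceiling(n / 2) - 1)   # 1 .. floor((n-1)/2)
  tibble(f_acoustic = k * igm$sample_rate / n,
         magnitude = 2 * Mod(x[k + 1]) / n)
}

#' Relabel an acoustic spectrum onto the optical axis
#'
#' Applies the exact linear mapping `nu = nu0 + scale * f_acoustic` bin by
#' bin; magnitudes are untouched.
#'
#' @param spec A spectrum tibble with `f_acoustic`.
#' @param pair A [build_comb_pair()] object.
#' @return The tibble with a `nu_optical` column.
#' @export
map_to_optical <- function(spec, pair) {
  stopifnot(inherits(pair, "comb_pair"))
  dplyr::mutate(spec, nu_optical = optical_from_ultrasound(pair, .data$f_acoustic))
}

# Evaluate a normalization response: transducer object, plain function of f,
# or numeric vector aligned with the grid.
eval_response <- function(response, f) {
  if (inherits(response, "transducer_response")) return(transducer_gain(response, f))
  if (is.function(response)) return(response(f))
  if (is.numeric(response) && length(response) == length(f)) return(response)
  abort("`response` must be a transducer_response, a function of f, or a numeric vector.")
}

#' Normalize a photoacoustic spectrum by excitation and instrument response
#'
#' Computes the normalized response `V_pa / (I0 * |H|)` bin by bin, which is
#' proportional to `beta * mu_a` in the weak-absorption regime. Bins where
#' either the excitation or the response falls below `mask_threshold` of its
#' peak are masked (`NA`) rather than amplified into noise.
#'
#' @param pa PA-channel spectrum tibble (`f_acoustic`, `magnitude`).
#' @param excitation Reference-channel spectrum on the identical grid.
#' @param response Instrument amplitude response: a `transducer_response`, a
#'   function of acoustic frequency, or a numeric vector (use the full
#'   detection-chain response to cancel the electronics exactly).
#' @param config A [processing_config()] (supplies `mask_threshold`).
#' @return A tibble with `f_acoustic`, `nu_optical` (if present), `excitation`,
#'   `pa_raw`, `response`, `pa_normalized`, `masked`.
#' @export
normalize_pa <- function(pa, excitation, response, config = processing_config()) {
  if (nrow(pa) != nrow(excitation) ||
      any(abs(pa$f_acoustic - excitation$f_acoustic) >
            1e-9 * max(pa$f_acoustic))) {
    abort("`pa` and `excitation` must share an identical acoustic grid.")
  }
  resp <- eval_response(response, pa$f_acoustic)
  keep <- excitation$magnitude >= config$mask_threshold * max(excitation$magnitude) &
    resp >= config$mask_threshold * max(resp)
  if (!any(keep)) abort("all bins masked; nothing to normalize.")
  vhat <- ifelse(keep, pa$magnitude / (excitation$magnitude * resp), NA_real_)
  out <- tibble(
    f_acoustic = pa$f_acoustic,
    excitation = excitation$magnitude,
    pa_raw = pa$magnitude,
    response = resp,
    pa_normalized = vhat,
    masked = !keep
  )
  if ("nu_optical" %in% names(pa)) {
    out <- dplyr::mutate(out, nu_optical = pa$nu_optical, .after = "f_acoustic")
  }
  out
}

#' End-to-end absorption-spectrum recovery
#'
#' Runs the full chain: simulate `m_shots` interferogram periods, coherently
#' average them (with reference-channel phase correction when the scene has
#' phase jitter), remove the acoustic propagation delay from the PA channel,
#' apodize both channels identically, Fourier transform, map the acoustic
#' axis to optical frequency, and normalize the PA spectrum by the excitation
#' spectrum and the detection-chain response.
#'
#' @param scene A [sim_scene()].
#' @param m_shots Number of coherently averaged shots (`>= 1`).
#' @param config A [processing_config()].
#' @return An object of class `recovered_spectrum`: `spectra` tibble (see
#'   [normalize_pa()]), plus `pair`, `config`, `n_shots`, `averaging_time`.
#' @export
recover_absorption <- function(scene, m_shots = 1, config = processing_config()) {
  stopifnot(inherits(scene, "sim_scene"))
  if (m_shots < 1) abort("`m_shots` must be >= 1.")
  if (scene$phase_jitter_std > 0) {
    shots <- lapply(seq_len(m_shots) - 1, function(i) simulate_shot(scene, i))
    refs <- lapply(shots, `[[`, "reference")
    ref <- coherent_average(refs, correct_phase = TRUE)
    pa <- coherent_average(lapply(shots, `[[`, "pa"),
                           correct_phase = TRUE, reference = refs)
  } else {
    avg <- simulate_average(scene, m_shots)
    ref <- avg$reference
    pa <- avg$pa
  }
  pa <- remove_acoustic_delay(pa, scene$chain$t_acoustic)
  ref_spec <- magnitude_spectrum(apodize(ref, config))
  pa_spec <- magnitude_spectrum(apodize(pa, config))
  pa_spec <- map_to_optical(pa_spec, scene$pair)
  spectra <- normalize_pa(pa_spec, ref_spec,
                          function(f) chain_response(scene$transducer, scene$chain, f),
                          config)
  period <- length(ref$samples) / ref$sample_rate
  structure(list(spectra = spectra, pair = scene$pair, config = config,
                 n_shots = m_shots, averaging_time = m_shots * period),
            class = "recovered_spectrum")
}

#' @export
print.recovered_spectrum <- function(x, ...) {
  s <- x$spectra
  cat("<recovered_spectrum>\n")
  cat(sprintf("  bins      : %d (%d unmasked)\n", nrow(s), sum(!s$masked)))
  cat(sprintf("  optical   : %.3f - %.3f THz\n",
              min(s$nu_optical) / 1e12, max(s$nu_optical) / 1e12))
  cat(sprintf("  shots     : %d (averaging time %.3g s)\n",
              x$n_shots, x$averaging_time))
  invisible(x)
}

#' @method tidy recovered_spectrum
#' @export
tidy.recovered_spectrum <- function(x, ...) x$spectra

#' @method glance recovered_spectrum
#' @export
glance.recovered_spectrum <- function(x, ...) {
  s <- x$spectra[!x$spectra$masked, ]
  tibble(n_bins = nrow(x$spectra), n_unmasked = nrow(s),
         nu_min = min(s$nu_optical), nu_max = max(s$nu_optical),
         peak_nu = s$nu_optical[which.max(s$pa_normalized)],
         n_shots = x$n_shots, averaging_time = x$averaging_time)
}

#' Locate peaks in a recovered spectrum
#'
#' Local maxima of the normalized response over unmasked bins, after light
#' running-mean smoothing to suppress bin-to-bin ripple, keeping peaks above
#' `min_height` of the global maximum and separated by at least
#' `min_separation`.
#'
#' @param rec A `recovered_spectrum` (or its `spectra` tibble).
#' @param min_height Fraction of the maximum response (default 0.3).
#' @param min_separation Minimum peak spacing on the optical axis (Hz),
#'   default 300 GHz.
#' @param smooth_bins Running-mean half-width in bins (default 25).
#' @return Tibble with `nu_optical`, `f_acoustic`, `value`, ordered by
#'   descending value.
#' @export
spectrum_peaks <- function(rec, min_height = 0.3, min_separation = 3e11,
                           smooth_bins = 25) {
  s <- if (inherits(rec, "recovered_spectrum")) rec$spectra else rec
  s <- s[!s$masked, ]
  y <- s$pa_normalized
  if (smooth_bins > 0) {
    k <- rep(1, 2 * smooth_bins + 1)
    y <- as.numeric(stats::filter(y, k / sum(k), sides = 2))
  }
  ok <- !is.na(y)
  idx <- which(ok)[which(diff(sign(diff(y[ok]))) == -2) + 1]
  idx <- idx[y[idx] >= min_height * max(y, na.rm = TRUE)]
  out <- tibble(nu_optical = s$nu_optical[idx], f_acoustic = s$f_acoustic[idx],
                value = y[idx])
  out <- dplyr::arrange(out, dplyr::desc(.data$value))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    too_close <- abs(out$nu_optical - out$nu_optical[i]) < min_separation
    too_close[seq_len(i)] <- FALSE
    keep[too_close] <- FALSE
  }
  out[keep, ]
}

#' Full width at half maximum of a sampled peak
#'
#' Linear-interpolation FWHM of the tallest peak in `y` over `x`.
#'
#' @param x Ordered abscissa.
#' @param y Values (one dominant peak).
#' @return FWHM in units of `x`.
#' @export
estimate_fwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  left <- which(y[seq_len(i)] <= half)
  right <- i - 1 + which(y[i:length(y)] <= half)
  if (!length(left) || !length(right)) abort("peak not resolved within the grid.")
  li <- max(left)
  ri <- min(right)
  xl <- x[li] + (half - y[li]) / (y[li + 1] - y[li]) * (x[li + 1] - x[li])
  xr <- x[ri - 1] + (half - y[ri - 1]) / (y[ri] - y[ri - 1]) * (x[ri] - x[ri - 1])
  xr - xl
}

#' Apodization SNR gain from spectral averaging
#'
#' Averaging `n_avg` independent 160 MHz-spaced spectral samples into one
#' resolution element (e.g. 500 GHz / 160 MHz = 3125) reduces white spectral
#' noise by `sqrt(n_avg)`. The Monte-Carlo mode measures the per-element vs
#' per-bin noise ratio on simulated white spectra.
#'
#' @param n_avg Bins per resolution element.
#' @param method `"analytic"` (returns `sqrt(n_avg)`) or `"montecarlo"`.
#' @param n_bins Total bins per simulated spectrum (Monte-Carlo).
#' @param repeats Monte-Carlo repetitions (default 100).
#' @param seed Seed for the Monte-Carlo draw.
#' @return SNR gain factor (dimensionless).
#' @export
apodization_snr_gain <- function(n_avg, method = c("analytic", "montecarlo"),
                                 n_bins = 100 * n_avg, repeats = 100, seed = 1) {
  method <- match.arg(method)
  check_number(n_avg, "n_avg", positive = TRUE)
  if (method == "analytic") return(sqrt(n_avg))
  n_blocks <- floor(n_bins / n_avg)
  if (n_blocks < 2) abort("`n_bins` must hold at least 2 resolution elements.")
  # pool raw samples and block means over all repeats so both standard
  # deviations are estimated from large samples (avoids 1/sd small-n bias)
  with_seed(seed, {
    raw <- rnorm(repeats * n_blocks * n_avg)
    blocks <- colMeans(matrix(raw, nrow = n_avg))
    sd(raw) / sd(blocks)
  })
}
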