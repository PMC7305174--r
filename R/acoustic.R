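#' Analytic ultrasound transducer response
#'
#' Normalized pressure-to-voltage responsivity `|H(f)|` peaked at `f_peak`
#' with the given FWHM. The default (Gaussian, 7.5 MHz peak, 7.5 MHz FWHM)
#' emulates a focused immersion transducer whose passband sets which beat
#' notes are detectable. `raised_cosine` falls to exactly zero one FWHM from
#' the peak.
#'
#' @param f_peak Peak-response frequency (Hz), `> 0`.
#' @param bandwidth_fwhm Full width at half maximum of `|H|` (Hz), `> 0`.
#' @param shape `"gaussian"` or `"raised_cosine"`.
#' @return An object of class `transducer_response`.
#' @export
make_transducer <- function(f_peak = 7.5e6, bandwidth_fwhm = 7.5e6,
                            shape = c("gaussian", "raised_cosine")) {
  shape <- match.arg(shape)
  check_number(f_peak, "f_peak", positive = TRUE)
  check_number(bandwidth_fwhm, "bandwidth_fwhm", positive = TRUE)
  structure(list(type = "analytic", shape = shape, f_peak = f_peak,
                 bandwidth_fwhm = bandwidth_fwhm),
            class = "transducer_response")
}

#' Tabulated transducer response from a calibration curve
#'
#' @param f Acoustic frequencies (Hz), increasing.
#' @param magnitude Responsivity samples; rescaled so the maximum is 1.
#' @return A `transducer_response` interpolating the curve (0 outside its
#'   range).
#' @export
tabulated_transducer <- function(f, magnitude) {
  if (length(f) != length(magnitude) || length(f) < 2L) {
    abort("`f` and `magnitude` must be equal-length vectors (length >= 2).")
  }
  if (any(magnitude < 0)) abort("`magnitude` must be >= 0.")
  structure(list(type = "tabulated", f = as.double(f),
                 magnitude = magnitude / max(magnitude),
                 f_peak = f[which.max(magnitude)]),
            class = "transducer_response")
}

#' Evaluate a transducer response magnitude
#'
#' @param transducer A `transducer_response`.
#' @param f Acoustic frequencies (Hz).
#' @return `|H(f)|`, normalized to 1 at the peak.
#' @export
transducer_gain <- function(transducer, f) {
  stopifnot(inherits(transducer, "transducer_response"))
  if (transducer$type == "tabulated") {
    out <- approx(transducer$f, transducer$magnitude, xout = f)$y
    out[is.na(out)] <- 0
    return(out)
  }
  x <- (f - transducer$f_peak) / transducer$bandwidth_fwhm
  switch(transducer$shape,
    gaussian = exp(-4 * log(2) * x^2),
    raised_cosine = ifelse(abs(x) <= 1, 0.5 * (1 + cos(pi * x)), 0)
  )
}

#' Detection electronics behind the transducer
#'
#' Amplifier gain, post-amplifier low-pass filter (Butterworth magnitude
#' model), additive white Gaussian detector noise injected at the transducer
#' output (before gain), and the acoustic propagation delay of the water path
#' between sample and transducer.
#'
#' @param gain_db Voltage gain in dB (default 80, i.e. x1e4).
#' @param lowpass_cutoff Low-pass -3 dB cutoff (Hz), default 15 MHz.
#' @param lowpass_order Butterworth order (default 4).
#' @param noise_density Noise standard deviation per sample at the transducer
#'   output, before gain (V).
#' @param t_acoustic Acoustic propagation delay (s), default 14 us.
#' @return An object of class `detection_chain`.
#' @export
detection_chain <- function(gain_db = 80, lowpass_cutoff = 15e6,
                            lowpass_order = 4, noise_density = 0,
                            t_acoustic = 14e-6) {
  check_number(gain_db, "gain_db")
  check_number(lowpass_cutoff, "lowpass_cutoff", positive = TRUE)
  check_number(noise_density, "noise_density", nonneg = TRUE)
  check_number(t_acoustic, "t_acoustic", nonneg = TRUE)
  structure(list(gain_db = gain_db, lowpass_cutoff = lowpass_cutoff,
                 lowpass_order = lowpass_order,
                 noise_density = noise_density, t_acoustic = t_acoustic),
            class = "detection_chain")
}

# Butterworth amplitude response |LP(f)|.
lowpass_gain <- function(chain, f) {
  1 / sqrt(1 + (f / chain$lowpass_cutoff)^(2 * chain$lowpass_order))
}

# Combined pressure-to-recorded-voltage amplitude response of the detection
# chain (transducer x low-pass x gain); used for instrument normalization.
chain_response <- function(transducer, chain, f) {
  10^(chain$gain_db / 20) * transducer_gain(transducer, f) *
    lowpass_gain(chain, f)
}

#' Apply the detection chain to pressure beat notes
#'
#' Converts per-beat pressure amplitudes to recorded voltage amplitudes:
#' `V_n = gain * |H(f_n)| * |LP(f_n)| * p_n`, and delays the phase by the
#' acoustic propagation time (`-2 pi f_n t_acoustic`).
#'
#' @param beats A [pa_source_amplitudes()] tibble (needs `f_acoustic`,
#'   `pressure`, `phase`).
#' @param transducer A `transducer_response`.
#' @param chain A `detection_chain`.
#' @return The tibble with added `voltage` (V) and updated `phase`.
#' @export
apply_chain <- function(beats, transducer, chain) {
  stopifnot(inherits(chain, "detection_chain"))
  if (!"pressure" %in% names(beats)) {
    abort("`beats` must carry a `pressure` column (see pa_source_amplitudes()).")
  }
  dplyr::mutate(
    beats,
    voltage = chain_response(transducer, chain, .data$f_acoustic) * .data$pressure,
    phase = .data$phase - 2 * pi * .data$f_acoustic * chain$t_acoustic
  )
}

#' Seeded detector-noise time series
#'
#' Zero-mean white Gaussian noise with per-sample standard deviation
#' `noise_density`, optionally scaled by the amplifier gain and band-limited
#' by the low-pass magnitude model (applied on the FFT grid).
#'
#' @param chain A `detection_chain`.
#' @param n Number of samples, `> 0`.
#' @param sample_rate Sampling rate (Hz), used by the low-pass model.
#' @param seed Integer seed; identical seeds give identical series.
#' @param filtered Apply gain and low-pass (default `TRUE`); `FALSE` returns
#'   the raw white series.
#' @return Numeric vector of length `n` (V).
#' @export
noise_samples <- function(chain, n, sample_rate, seed, filtered = TRUE) {
  stopifnot(inherits(chain, "detection_chain"))
  if (n <= 0) abort("`n` must be > 0.")
  x <- with_seed(seed, rnorm(n, sd = chain$noise_density))
  if (!filtered || chain$noise_density == 0) return(x)
  f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * sample_rate / n
  h <- lowpass_gain(chain, abs(f))
  x <- Re(fft(fft(x) * h, inverse = TRUE)) / n
  10^(chain$gain_db / 20) * x
}
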