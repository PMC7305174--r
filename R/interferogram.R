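#' @rdname synthesize
#' @param samples Voltage samples (V).
#' @param t0 Time of the nominal centerburst (s).
#' @param channel `"reference"` or `"pa"`.
#' @param n_averaged Number of coherently co-added shots the record represents.
#' @export
interferogram <- function(samples, sample_rate, t0 = 0,
                          channel = c("reference", "pa"), n_averaged = 1) {
  channel <- match.arg(channel)
  structure(list(samples = as.double(samples), sample_rate = sample_rate,
                 t0 = t0, channel = channel, n_averaged = n_averaged),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %s channel, %d samples @ %.4g MS/s (%.4g ms), t0 = %.3g us, %d shot(s)\n",
              x$channel, length(x$samples), x$sample_rate / 1e6,
              length(x$samples) / x$sample_rate * 1e3, x$t0 * 1e6, x$n_averaged))
  invisible(x)
}

#' @method tidy interferogram
#' @export
tidy.interferogram <- function(x, ...) {
  n <- length(x$samples)
  tibble(t = (seq_len(n) - 1) / x$sample_rate, volts = x$samples)
}

# One-period record length for a sampling rate and beat spacing; the actual
# rate is the nearest integer multiple of |delta_f_rep| so all beat notes are
# exactly on FFT bins.
record_geometry <- function(sample_rate, delta_f_rep) {
  n <- round(sample_rate / abs(delta_f_rep))
  if (n < 4) abort("record would hold fewer than 4 samples.")
  list(n = n, fs = n * abs(delta_f_rep))
}

# Complex (analytic) on-grid synthesis: z_j = sum_n A_n exp(i(2 pi n j / N + phi_n)).
# The physical record is Re(z); keeping z makes global phase rotation cheap.
synthesize_complex <- function(index, amplitude, phase, n) {
  keep <- index >= 1
  index <- index[keep]; amplitude <- amplitude[keep]; phase <- phase[keep]
  if (length(index) && max(index) >= n / 2) {
    abort("aliasing: beat-note index reaches the Nyquist bin; raise sample_rate.")
  }
  x <- complex(length.out = n)
  x[index + 1] <- n * amplitude * exp(1i * phase)
  fft(x, inverse = TRUE) / n
}

#' Synthesize one interferogram period from beat notes
#'
#' Places each beat note on its exact FFT bin of a one-period record
#' (`length = round(sample_rate / |delta_f_rep|)`) and inverse-transforms:
#' `samples(t) = sum_n A_n cos(2 pi f_n t + phi_n)`. The DC term (index 0) is
#' excluded. The realized sampling rate is coerced to the nearest integer
#' multiple of `|delta_f_rep|` so every tone is on-grid.
#'
#' @param beats Tibble with `index`, `phase` and an amplitude column.
#' @param sample_rate Requested sampling rate (Hz); must exceed twice the
#'   highest beat frequency.
#' @param delta_f_rep Repetition-rate difference (Hz) defining the period.
#' @param amplitude Name of the amplitude column (default `"amplitude"`).
#' @param phase_offset Global phase added to every tone (rad).
#' @return An `interferogram` (list: `samples`, `sample_rate`, `t0`,
#'   `channel`, `n_averaged`).
#' @export
synthesize <- function(beats, sample_rate, delta_f_rep,
                       amplitude = "amplitude", phase_offset = 0,
                       channel = "reference") {
  geom <- record_geometry(sample_rate, delta_f_rep)
  z <- synthesize_complex(beats$index, beats[[amplitude]],
                          beats$phase + phase_offset, geom$n)
  interferogram(Re(z), geom$fs, t0 = 0, channel = channel)
}

#' Simulated measurement configuration
#'
#' Bundles the comb pair, sample, transducer, detection chain and acquisition
#' settings of one dual-comb photoacoustic measurement. Validates the
#' non-aliasing condition and requires `sample_rate >= 2.5 x` the highest
#' beat frequency.
#'
#' @param pair A [build_comb_pair()] object.
#' @param sample An `absorption_spectrum`.
#' @param transducer A `transducer_response`.
#' @param chain A `detection_chain`.
#' @param sample_rate Digitizer rate (Hz), default 30 MS/s.
#' @param phase_jitter_std Per-shot global phase jitter (rad), default 0.
#' @param seed Base seed for noise and jitter streams.
#' @param beer_mode Beer-law mode for the source term (`"exact"` default).
#' @return An object of class `sim_scene`.
#' @export
sim_scene <- function(pair, sample, transducer = make_transducer(),
                      chain = detection_chain(), sample_rate = 30e6,
                      phase_jitter_std = 0, seed = 0,
                      beer_mode = c("exact", "linearized")) {
  stopifnot(inherits(pair, "comb_pair"), inherits(sample, "absorption_spectrum"),
            inherits(transducer, "transducer_response"),
            inherits(chain, "detection_chain"))
  beer_mode <- match.arg(beer_mode)
  check_number(phase_jitter_std, "phase_jitter_std", nonneg = TRUE)
  alias <- check_alias_free(pair)
  if (!alias$pass) {
    abort(sprintf("comb pair is not alias-free (max beat %.3g Hz > %.3g Hz).",
                  alias$max_beat, alias$limit))
  }
  if (sample_rate < 2.5 * alias$max_beat) {
    abort("`sample_rate` must be >= 2.5 x the highest beat frequency.")
  }
  structure(list(pair = pair, sample = sample, transducer = transducer,
                 chain = chain, sample_rate = sample_rate,
                 phase_jitter_std = phase_jitter_std, seed = seed,
                 beer_mode = beer_mode),
            class = "sim_scene")
}

# Deterministic (noise-free, jitter-free) complex signals of both channels,
# computed once per scene and reusable across shots.
scene_signals <- function(scene) {
  geom <- record_geometry(scene$sample_rate, scene$pair$delta_f_rep)
  beats <- beat_notes(scene$pair)
  src <- pa_source_amplitudes(scene$sample, beats, mode = scene$beer_mode)
  pa <- apply_chain(src, scene$transducer, scene$chain)
  list(
    geom = geom,
    reference = synthesize_complex(beats$index, beats$amplitude, beats$phase, geom$n),
    pa = synthesize_complex(pa$index, pa$voltage, pa$phase, geom$n)
  )
}

#' Simulate one interferogram shot
#'
#' One period of the reference (photodetector) and photoacoustic (transducer)
#' channels. Both share a per-shot global phase offset drawn from
#' `N(0, phase_jitter_std^2)`; the PA channel additionally carries the
#' acoustic-delay phase and seeded additive detector noise.
#'
#' @param scene A [sim_scene()].
#' @param shot_index Integer shot number (determines the noise/jitter
#'   sub-seeds).
#' @return List with elements `reference` and `pa` (interferograms).
#' @export
simulate_shot <- function(scene, shot_index = 0) {
  stopifnot(inherits(scene, "sim_scene"))
  sig <- scene_signals(scene)
  phi <- if (scene$phase_jitter_std > 0) {
    with_seed(derive_seed(scene$seed, 2 * shot_index + 1),
              rnorm(1, sd = scene$phase_jitter_std))
  } else 0
  rot <- exp(1i * phi)
  ref <- interferogram(Re(rot * sig$reference), sig$geom$fs, channel = "reference")
  pa_samples <- Re(rot * sig$pa)
  t0_pa <- scene$chain$t_acoustic
  if (scene$chain$noise_density > 0) {
    pa_samples <- pa_samples +
      noise_samples(scene$chain, sig$geom$n, sig$geom$fs,
                    seed = derive_seed(scene$seed, 2 * shot_index + 2))
  }
  list(reference = ref,
       pa = interferogram(pa_samples, sig$geom$fs, t0 = t0_pa, channel = "pa"))
}

#' Simulate a coherent average of M shots directly
#'
#' For zero phase jitter, the mean of `M` independent shots equals the
#' deterministic signal plus white noise of standard deviation
#' `noise / sqrt(M)`; this draws that average in one step instead of looping
#' over shots. Errors if the scene has phase jitter (use [simulate_shot()] +
#' [coherent_average()] there).
#'
#' @param scene A [sim_scene()] with `phase_jitter_std = 0`.
#' @param m Number of averaged shots (`>= 1`).
#' @param stream Integer stream id decorrelating repeated draws.
#' @return List with elements `reference` and `pa`; `n_averaged = m`.
#' @export
simulate_average <- function(scene, m = 1, stream = 0) {
  stopifnot(inherits(scene, "sim_scene"))
  if (scene$phase_jitter_std > 0) {
    abort("simulate_average() requires phase_jitter_std = 0; average shots instead.")
  }
  if (m < 1) abort("`m` must be >= 1.")
  sig <- scene_signals(scene)
  pa_samples <- Re(sig$pa)
  if (scene$chain$noise_density > 0) {
    pa_samples <- pa_samples +
      noise_samples(scene$chain, sig$geom$n, sig$geom$fs,
                    seed = derive_seed(scene$seed, stream)) / sqrt(m)
  }
  list(
    reference = interferogram(Re(sig$reference), sig$geom$fs,
                              channel = "reference", n_averaged = m),
    pa = interferogram(pa_samples, sig$geom$fs, t0 = scene$chain$t_acoustic,
                       channel = "pa", n_averaged = m)
  )
}

# Analytic signal of a real record (negative frequencies zeroed).
analytic_signal <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Global phase of a shot at its centerburst (analytic-signal argument at t0).
centerburst_phase <- function(igm) {
  z <- analytic_signal(igm$samples)
  i0 <- (round(igm$t0 * igm$sample_rate) %% length(z)) + 1
  Arg(z[i0])
}

#' Coherently average interferogram shots
#'
#' Sample-wise mean of repeated shots, with optional global phase correction:
#' each shot's phase is estimated from the centerburst of the corresponding
#' reference-channel record (or from the shot itself when no reference is
#' given) via the analytic signal, and the shot is counter-rotated before
#' co-adding. With white noise the averaged SNR grows as `sqrt(M)`.
#'
#' @param shots List of `interferogram`s (same length, rate, channel).
#' @param correct_phase Apply per-shot phase correction (default `FALSE`).
#' @param reference Optional list of reference-channel `interferogram`s used
#'   for the phase estimates (the high-SNR channel).
#' @return An `interferogram` with `n_averaged` summed over inputs.
#' @export
coherent_average <- function(shots, correct_phase = FALSE, reference = NULL) {
  if (length(shots) == 0) abort("`shots` is empty.")
  n <- length(shots[[1]]$samples)
  fs <- shots[[1]]$sample_rate
  ch <- shots[[1]]$channel
  ok <- vapply(shots, function(s) {
    length(s$samples) == n && s$sample_rate == fs && s$channel == ch
  }, logical(1))
  if (!all(ok)) abort("shots differ in length, sample_rate or channel.")
  if (!is.null(reference) && length(reference) != length(shots)) {
    abort("`reference` must match `shots` in length.")
  }
  acc <- rep(0, n)
  for (m in seq_along(shots)) {
    x <- shots[[m]]$samples
    if (correct_phase) {
      phi <- centerburst_phase((reference %||% shots)[[m]])
      x <- Re(exp(-1i * phi) * analytic_signal(x))
    }
    acc <- acc + x
  }
  interferogram(acc / length(shots), fs, t0 = shots[[1]]$t0, channel = ch,
                n_averaged = sum(vapply(shots, function(s) s$n_averaged, numeric(1))))
}

#' Undo the acoustic propagation delay
#'
#' Circularly shifts the (periodic) record so a centerburst delayed by the
#' water-path propagation time lines up with `t0`. Shifts beyond one period
#' wrap with a warning.
#'
#' @param igm An `interferogram`.
#' @param t_acoustic Propagation delay to remove (s), `>= 0`.
#' @return The shifted `interferogram`.
#' @export
remove_acoustic_delay <- function(igm, t_acoustic) {
  stopifnot(inherits(igm, "interferogram"))
  check_number(t_acoustic, "t_acoustic", nonneg = TRUE)
  k <- round(t_acoustic * igm$sample_rate)
  if (k >= length(igm$samples)) {
    warn("delay exceeds the record length; shift wraps (periodic record).")
  }
  igm$samples <- circular_shift(igm$samples, -k)
  igm$t0 <- igm$t0 - k / igm$sample_rate
  igm
}

#' Interferogram CSV export/import
#'
#' Columnar `t_s, volts` CSV plus a JSON sidecar (`<path>.json`) holding
#' `sample_rate`, `t0`, `channel` and `n_averaged`.
#'
#' @param igm An `interferogram`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `read_interferogram_csv()` returns an `interferogram`;
#'   `write_interferogram_csv()` returns `path` invisibly.
#' @export
write_interferogram_csv <- function(igm, path) {
  stopifnot(inherits(igm, "interferogram"))
  readr::write_csv(setNames(tidy(igm), c("t_s", "volts")), path)
  jsonlite::write_json(
    list(sample_rate = igm$sample_rate, t0 = igm$t0, channel = igm$channel,
         n_averaged = igm$n_averaged),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_interferogram_csv
#' @export
read_interferogram_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t_s", "volts") %in% names(d))) {
    abort("interferogram CSV needs columns t_s, volts.")
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(sample_rate = 1 / stats::median(diff(d$t_s)), t0 = 0,
         channel = "pa", n_averaged = 1)
  }
  interferogram(d$volts, meta$sample_rate, t0 = meta$t0,
                channel = meta$channel, n_averaged = meta$n_averaged)
}
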