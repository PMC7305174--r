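#' Time-domain SNR of an interferogram
#'
#' Peak height of the centerburst divided by the standard deviation of the
#' samples outside an exclusion region around it. Regions are circular
#' around `t0`. Noiseless records report `Inf` with `infinite = TRUE`.
#'
#' @param igm An `interferogram`.
#' @param centerburst_halfwidth Half-width of the peak-search region (s),
#'   default 2.4 us (half the default apodization window).
#' @param exclusion_halfwidth Half-width of the region excluded from the
#'   noise estimate (s), default 3x the centerburst half-width.
#' @param power Optional optical power annotation carried into fits.
#' @return One-row tibble: `value`, `kind`, `averaging_time`, `n_shots`,
#'   `power`, `infinite`.
#' @export
time_domain_snr <- function(igm, centerburst_halfwidth = 2.4e-6,
                            exclusion_halfwidth = 3 * centerburst_halfwidth,
                            power = NA_real_) {
  stopifnot(inherits(igm, "interferogram"))
  if (exclusion_halfwidth < centerburst_halfwidth) {
    abort("`exclusion_halfwidth` must be >= `centerburst_halfwidth`.")
  }
  n <- length(igm$samples)
  period <- n / igm$sample_rate
  t <- (seq_len(n) - 1) / igm$sample_rate
  d <- circular_distance(t, igm$t0, period)
  inside <- d <= centerburst_halfwidth
  outside <- d > exclusion_halfwidth
  if (!any(outside)) abort("noise region is empty; shrink the exclusion window.")
  peak <- max(abs(igm$samples[inside]))
  noise <- sd(igm$samples[outside])
  tibble(value = if (noise == 0) Inf else peak / noise,
         kind = "time_domain",
         averaging_time = igm$n_averaged * period,
         n_shots = igm$n_averaged,
         power = power,
         infinite = noise == 0)
}

#' Spectral SNR over repeated measurements
#'
#' Per-bin mean magnitude divided by per-bin standard deviation over at least
#' 8 repeated spectra on identical grids.
#'
#' @param repeat_spectra List of spectrum tibbles (`f_acoustic`, `magnitude`)
#'   from independent noise realizations.
#' @return Tibble with `f_acoustic` (and `nu_optical` if present), `mean`,
#'   `sd`, `snr`, `infinite`.
#' @export
spectral_snr <- function(repeat_spectra) {
  if (length(repeat_spectra) < 8) {
    abort("need >= 8 repeated spectra for a spectral SNR estimate.")
  }
  f <- repeat_spectra[[1]]$f_acoustic
  same <- vapply(repeat_spectra, function(s) {
    nrow(s) == length(f) && all(abs(s$f_acoustic - f) <= 1e-9 * max(f))
  }, logical(1))
  if (!all(same)) abort("repeated spectra must share an identical grid.")
  mags <- vapply(repeat_spectra, function(s) s$magnitude,
                 numeric(length(f)))
  mu <- rowMeans(mags)
  sig <- apply(mags, 1, sd)
  out <- tibble(f_acoustic = f, mean = mu, sd = sig,
                snr = ifelse(sig == 0, Inf, mu / sig),
                infinite = sig == 0)
  if ("nu_optical" %in% names(repeat_spectra[[1]])) {
    out <- dplyr::mutate(out, nu_optical = repeat_spectra[[1]]$nu_optical,
                         .after = "f_acoustic")
  }
  out
}

#' Fit the square-root averaging-time law
#'
#' Fits `SNR = A * sqrt(tau)` with the exponent fixed at 1/2 (least squares
#' in log space), and also reports the free-exponent log-log estimate as a
#' white-noise diagnostic: exponents near 0.5 indicate white-noise-limited
#' averaging; values near 1 indicate coherent drift.
#'
#' @param points Tibble of SNR results with `value` and `averaging_time`
#'   columns (e.g. rows from [time_domain_snr()]); needs `>= 4` points
#'   spanning at least one decade in `averaging_time`.
#' @return An `snr_fit` object; see [tidy.snr_fit()].
#' @export
fit_sqrt_tau <- function(points) {
  v <- points$value
  tau <- points$averaging_time
  if (any(!is.finite(v)) || any(v <= 0) || any(tau <= 0)) {
    abort("SNR values and averaging times must be finite and > 0.")
  }
  if (length(v) < 4 || max(tau) / min(tau) < 10) {
    abort("need >= 4 points spanning >= 1 decade in averaging time.")
  }
  a <- exp(mean(log(v) - 0.5 * log(tau)))
  free <- lm(log(v) ~ log(tau))
  sm <- suppressWarnings(summary(free))
  structure(list(A = a, exponent = unname(coef(free)[2]),
                 exponent_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 law = "snr_sqrt_tau", n = length(v),
                 white_noise_consistent = abs(unname(coef(free)[2]) - 0.5) < 0.1),
            class = "snr_fit")
}

#' Fit the SNR-versus-power linearity
#'
#' Least-squares linear fit of SNR against optical excitation power, with a
#' free-exponent log-log fit as the linearity diagnostic (exponent ~1 for
#' detector-noise-limited operation; ~0.5 indicates shot-noise limiting).
#'
#' @param points Tibble with `value` and `power` columns, `>= 3` points at
#'   distinct powers.
#' @return An `snr_fit` object with `slope`, `intercept`, `exponent`.
#' @export
fit_power_linear <- function(points) {
  v <- points$value
  p <- points$power
  if (length(v) < 3 || length(unique(p)) < 2) {
    abort("need >= 3 points at >= 2 distinct powers.")
  }
  if (any(!is.finite(v)) || any(v <= 0) || any(p <= 0)) {
    abort("SNR values and powers must be finite and > 0.")
  }
  lin <- lm(v ~ p)
  free <- lm(log(v) ~ log(p))
  sm_free <- suppressWarnings(summary(free))
  sm_lin <- suppressWarnings(summary(lin))
  structure(list(slope = unname(coef(lin)[2]), intercept = unname(coef(lin)[1]),
                 exponent = unname(coef(free)[2]),
                 exponent_se = sm_free$coefficients[2, 2],
                 r_squared = sm_lin$r.squared,
                 law = "snr_power_linear", n = length(v),
                 detector_noise_consistent = abs(unname(coef(free)[2]) - 1) < 0.1),
            class = "snr_fit")
}

#' @export
print.snr_fit <- function(x, ...) {
  cat(sprintf("<snr_fit: %s> n = %d\n", x$law, x$n))
  if (x$law == "snr_sqrt_tau") {
    cat(sprintf("  A = %.4g, free exponent = %.3f (se %.3f), white-noise consistent: %s\n",
                x$A, x$exponent, x$exponent_se, x$white_noise_consistent))
  } else {
    cat(sprintf("  slope = %.4g, intercept = %.4g, log-log exponent = %.3f (se %.3f)\n",
                x$slope, x$intercept, x$exponent, x$exponent_se))
  }
  invisible(x)
}

#' Tidy/glance methods for SNR fits
#'
#' @param x An `snr_fit` from [fit_sqrt_tau()] or [fit_power_linear()].
#' @param ... Unused.
#' @return `tidy()` returns one row per fitted term; `glance()` one-row model
#'   summary.
#' @method tidy snr_fit
#' @export
tidy.snr_fit <- function(x, ...) {
  if (x$law == "snr_sqrt_tau") {
    tibble(term = c("A", "exponent"),
           estimate = c(x$A, x$exponent),
           std.error = c(NA_real_, x$exponent_se))
  } else {
    tibble(term = c("slope", "intercept", "exponent"),
           estimate = c(x$slope, x$intercept, x$exponent),
           std.error = c(NA_real_, NA_real_, x$exponent_se))
  }
}

#' @rdname tidy.snr_fit
#' @method glance snr_fit
#' @export
glance.snr_fit <- function(x, ...) {
  tibble(law = x$law, n = x$n, exponent = x$exponent,
         r.squared = x$r_squared)
}

#' Acquisition-time scaling calculator
#'
#' Propagates the scaling laws of detector-noise-limited dual-comb
#' photoacoustics: required averaging time scales as `1/f_rep` (power per
#' tooth grows with tooth spacing at fixed total power), inversely with the
#' square of absorbance and optical power (SNR is linear in both), and with
#' the square of the detector noise density. At fixed averaging time the SNR
#' improves by `sqrt(1/time_factor)`.
#'
#' @param f_rep_factor Proposed/baseline repetition-rate ratio.
#' @param absorbance_factor Proposed/baseline absorption-coefficient ratio.
#' @param power_factor Proposed/baseline optical-power ratio.
#' @param noise_factor Proposed/baseline detector-noise ratio.
#' @param baseline_time Baseline acquisition time (s), default 7200 (2 h).
#' @return One-row tibble: `time_factor`, `snr_factor`, `projected_time` (s).
#' @examples
#' # 500 GHz combs (3000x the 160 MHz rate) + 10x stronger absorbance:
#' acquisition_time_scale(f_rep_factor = 3000, absorbance_factor = 10)
#' @export
acquisition_time_scale <- function(f_rep_factor = 1, absorbance_factor = 1,
                                   power_factor = 1, noise_factor = 1,
                                   baseline_time = 7200) {
  for (nm in c("f_rep_factor", "absorbance_factor", "power_factor",
               "noise_factor", "baseline_time")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  tf <- (1 / f_rep_factor) * (1 / absorbance_factor^2) *
    (1 / power_factor^2) * noise_factor^2
  tibble(time_factor = tf, snr_factor = sqrt(1 / tf),
         projected_time = baseline_time * tf)
}

#' Detector noise level giving a target single-shot SNR
#'
#' Solves for the `noise_density` that makes one interferogram period of the
#' scene reach the requested time-domain SNR (analytically: the centerburst
#' peak divided by target SNR and the chain's gain/filter factor on white
#' noise). Used to place simulated scenes at a stated operating point.
#'
#' @param scene A [sim_scene()] (its current `noise_density` is ignored).
#' @param target_snr Desired single-shot time-domain SNR (default 1).
#' @return Noise density (V per sample at the transducer output).
#' @export
calibrate_noise <- function(scene, target_snr = 1) {
  stopifnot(inherits(scene, "sim_scene"))
  check_number(target_snr, "target_snr", positive = TRUE)
  sig <- scene_signals(scene)
  peak <- max(abs(Re(sig$pa)))
  # measured noise std after gain & low-pass, per unit noise_density
  probe <- scene$chain
  probe$noise_density <- 1
  unit <- sd(noise_samples(probe, sig$geom$n, sig$geom$fs, seed = 1))
  peak / (target_snr * unit)
}

#' Shots needed to reach a target time-domain SNR
#'
#' Doubles the number of coherently averaged shots until the time-domain SNR
#' reaches `threshold`, then bisects. Each evaluation draws an independent
#' averaged noise realization via [simulate_average()].
#'
#' @param scene A [sim_scene()] with nonzero noise and zero phase jitter.
#' @param threshold Target time-domain SNR (default 20).
#' @param max_shots Search cap (default `2^24`).
#' @param stream Stream id offsetting the noise draws.
#' @return Number of shots (integer).
#' @export
shots_to_reach_snr <- function(scene, threshold = 20, max_shots = 2^24,
                               stream = 0) {
  stopifnot(inherits(scene, "sim_scene"))
  if (scene$chain$noise_density <= 0) abort("scene has no noise; SNR is infinite.")
  eval_snr <- function(m, k) {
    avg <- simulate_average(scene, m, stream = stream * 1000 + k)
    time_domain_snr(avg$pa)$value
  }
  m <- 1
  k <- 0
  while (eval_snr(m, k <- k + 1) < threshold) {
    m <- m * 2
    if (m > max_shots) abort("target SNR not reached within `max_shots`.")
  }
  if (m == 1) return(1)
  lo <- m / 2
  hi <- m
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (eval_snr(mid, k <- k + 1) >= threshold) hi <- mid else lo <- mid
  }
  hi
}
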