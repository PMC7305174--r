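#' Analytic peak model for an absorption spectrum
#'
#' Describes an absorption coefficient as a baseline plus a sum of Gaussian or
#' Lorentzian peaks — a stand-in for a measured (spectrophotometer) spectrum.
#'
#' @param centers Peak positions (Hz).
#' @param fwhms Full widths at half maximum (Hz), `> 0`; recycled.
#' @param heights Peak contributions to the absorption coefficient (1/m),
#'   `>= 0`; recycled.
#' @param baseline Constant absorption offset (1/m), `>= 0`.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return An object of class `peak_model`.
#' @export
peak_model <- function(centers = numeric(), fwhms = numeric(),
                       heights = numeric(), baseline = 0,
                       shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  k <- length(centers)
  fwhms <- rep_len(as.double(fwhms), k)
  heights <- rep_len(as.double(heights), k)
  check_number(baseline, "baseline", nonneg = TRUE)
  if (k > 0 && (any(!is.finite(centers)) || any(fwhms <= 0) || any(heights < 0))) {
    abort("peaks need finite centers, fwhms > 0 and heights >= 0.")
  }
  structure(list(centers = as.double(centers), fwhms = fwhms,
                 heights = heights, baseline = baseline, shape = shape),
            class = "peak_model")
}

peak_profile <- function(x, shape) {
  # x = (nu - center) / fwhm; unit height, unit FWHM.
  switch(shape,
    gaussian = exp(-4 * log(2) * x^2),
    lorentzian = 1 / (1 + (2 * x)^2)
  )
}

#' Evaluate a peak model on an optical frequency grid
#'
#' @param model A [peak_model()].
#' @param nu_grid Strictly increasing optical frequencies (Hz).
#' @param thickness Absorbing path length L (m), `> 0`.
#' @param beta Photoacoustic conversion factor (pressure per absorbed power;
#'   relative units), `> 0`.
#' @return An `absorption_spectrum`: list with `nu` (Hz), `mu_a` (1/m, base-e),
#'   `thickness` (m) and `beta`.
#' @export
spectrum_from_peaks <- function(model, nu_grid, thickness = 240e-6, beta = 1) {
  stopifnot(inherits(model, "peak_model"))
  nu_grid <- as.double(nu_grid)
  if (anyNA(nu_grid) || any(diff(nu_grid) <= 0)) {
    abort("`nu_grid` must be strictly increasing and free of NA.")
  }
  check_number(thickness, "thickness", positive = TRUE)
  check_number(beta, "beta", positive = TRUE)
  mu <- rep(model$baseline, length(nu_grid))
  for (k in seq_along(model$centers)) {
    mu <- mu + model$heights[k] *
      peak_profile((nu_grid - model$centers[k]) / model$fwhms[k], model$shape)
  }
  structure(list(nu = nu_grid, mu_a = mu, thickness = thickness, beta = beta,
                 model = model),
            class = "absorption_spectrum")
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat("<absorption_spectrum>\n")
  cat(sprintf("  grid      : %d points, %.3f - %.3f THz\n",
              length(x$nu), min(x$nu) / 1e12, max(x$nu) / 1e12))
  cat(sprintf("  mu_a      : %.3g - %.3g 1/m\n", min(x$mu_a), max(x$mu_a)))
  cat(sprintf("  thickness : %.3g m, beta = %.3g\n", x$thickness, x$beta))
  invisible(x)
}

#' @method tidy absorption_spectrum
#' @export
tidy.absorption_spectrum <- function(x, ...) {
  tibble(nu = x$nu, mu_a = x$mu_a)
}

#' Built-in sample spectra
#'
#' Analytic emulations of three photoacoustic targets in the 165-180 THz
#' (C-H overtone) window, on a common 2001-point grid spanning 160-182 THz:
#'
#' * `vacnt_like` — a spectrally flat strong absorber (carbon-nanotube film):
#'   absorbed fraction ~1 across the band.
#' * `pdms_like` — weak absorber with peaks at 171.6, 176.0 and 177.4 THz;
#'   peak heights calibrated so its photoacoustic interferogram amplitude is
#'   ~100x below the flat absorber under the canonical measurement
#'   configuration (peak single-pass absorbed fraction ~0.045).
#' * `paraffin_like` — weak absorber with peaks at 169.8 and 173.1 THz,
#'   calibrated to ~50x below the flat absorber, i.e. ~2x the pdms_like
#'   signal (peak absorbed fraction ~0.069).
#'
#' Peak FWHMs default to 1.5 THz, typical of condensed-phase overtone bands;
#' the closely spaced 176.0/177.4 THz pair uses 0.8 THz so the two bands stay
#' spectrally distinct (overtone features span hundreds of GHz to a few THz).
#'
#' @param name One of `"vacnt_like"`, `"pdms_like"`, `"paraffin_like"`.
#' @param nu_grid Optical grid (Hz); default `seq(160e12, 182e12, length.out
#'   = 2001)`.
#' @return An `absorption_spectrum`.
#' @export
builtin_sample <- function(name, nu_grid = seq(160e12, 182e12, length.out = 2001)) {
  samples <- list(
    vacnt_like = list(
      model = peak_model(baseline = 4e5), thickness = 25e-6),
    pdms_like = list(
      model = peak_model(centers = c(171.6e12, 176.0e12, 177.4e12),
                         fwhms = c(1.5e12, 0.8e12, 0.8e12),
                         heights = 189.5 * c(1, 0.8, 0.6)),
      thickness = 240e-6),
    paraffin_like = list(
      model = peak_model(centers = c(169.8e12, 173.1e12),
                         fwhms = 1.5e12, heights = 575.3 * c(0.85, 1)),
      thickness = 120e-6)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(samples)) {
    abort(sprintf("unknown sample; valid names: %s",
                  paste(names(samples), collapse = ", ")))
  }
  s <- samples[[name]]
  spectrum_from_peaks(s$model, nu_grid, thickness = s$thickness, beta = 1)
}

#' Fraction of incident power absorbed (Beer-Lambert)
#'
#' Exact single-pass absorbed fraction `1 - exp(-mu_a * L)` or its weak-
#' absorption linearization `mu_a * L`, interpolated onto arbitrary optical
#' frequencies inside the spectrum grid.
#'
#' @param spec An `absorption_spectrum`.
#' @param nu Optical frequencies (Hz) within the spectrum grid.
#' @param mode `"exact"` or `"linearized"`.
#' @return Dimensionless absorbed fraction, same length as `nu`.
#' @export
absorbed_fraction <- function(spec, nu, mode = c("exact", "linearized")) {
  stopifnot(inherits(spec, "absorption_spectrum"))
  mode <- match.arg(mode)
  if (any(nu < min(spec$nu)) || any(nu > max(spec$nu))) {
    abort("`nu` outside the spectrum grid; refusing to extrapolate.")
  }
  mu <- approx(spec$nu, spec$mu_a, xout = nu)$y
  x <- mu * spec$thickness
  if (mode == "exact") -expm1(-x) else x
}

#' Photoacoustic source amplitude per beat note
#'
#' The pressure-wave amplitude driven by each intensity beat note:
#' `beta * absorbed_fraction(nu_n) * I0(nu_n)`, where `I0(nu_n)` is the
#' beat-note intensity amplitude. This is the source term before transducer
#' and electronics weighting.
#'
#' @param spec An `absorption_spectrum`.
#' @param beats A [beat_notes()] tibble.
#' @param mode Beer-law mode passed to [absorbed_fraction()].
#' @return The `beats` tibble with an added `pressure` column (relative Pa).
#' @export
pa_source_amplitudes <- function(spec, beats, mode = c("exact", "linearized")) {
  mode <- match.arg(mode)
  af <- absorbed_fraction(spec, beats$nu_optical, mode = mode)
  dplyr::mutate(beats, pressure = spec$beta * af * .data$amplitude)
}

#' Read/write absorption spectra as two-column CSV
#'
#' Interchange format `nu_Hz, mu_a_per_m` for user-supplied spectrophotometer
#' data.
#'
#' @param path File path.
#' @param spec An `absorption_spectrum`.
#' @param thickness,beta Sample parameters attached on read.
#' @return `read_spectrum_csv()` returns an `absorption_spectrum`;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, thickness = 240e-6, beta = 1) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("nu_Hz", "mu_a_per_m") %in% names(d))) {
    abort("spectrum CSV needs columns nu_Hz, mu_a_per_m.")
  }
  d <- dplyr::arrange(d, .data$nu_Hz)
  structure(list(nu = d$nu_Hz, mu_a = d$mu_a_per_m,
                 thickness = thickness, beta = beta, model = NULL),
            class = "absorption_spectrum")
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "absorption_spectrum"))
  readr::write_csv(tibble(nu_Hz = spec$nu, mu_a_per_m = spec$mu_a), path)
  invisible(path)
}
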