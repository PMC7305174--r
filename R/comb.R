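#' Spectral envelope specifications for a comb pair
#'
#' An envelope distributes a total average optical power over the modeled comb
#' teeth. `envelope_uniform()` gives every tooth the same power,
#' `envelope_gaussian()` weights teeth by a Gaussian profile of given FWHM, and
#' `envelope_tabulated()` interpolates a user-supplied power curve (e.g. from a
#' measured optical spectrum).
#'
#' @param total_power Total average optical power of the two combs combined (W).
#' @param fwhm Full width at half maximum of the Gaussian envelope (Hz).
#' @param center Center of the Gaussian envelope (Hz); defaults to the band
#'   center when the envelope is attached to a comb pair.
#' @param nu,power Tabulated optical frequencies (Hz) and relative powers for
#'   `envelope_tabulated()`; `power` is rescaled so the teeth sum to
#'   `total_power`.
#' @return An object of class `comb_envelope`.
#' @export
envelope_uniform <- function(total_power = 24e-3) {
  check_number(total_power, "total_power", positive = TRUE)
  structure(list(type = "uniform", total_power = total_power),
            class = "comb_envelope")
}

#' @rdname envelope_uniform
#' @export
envelope_gaussian <- function(total_power = 24e-3, fwhm, center = NULL) {
  check_number(total_power, "total_power", positive = TRUE)
  check_number(fwhm, "fwhm", positive = TRUE)
  if (!is.null(center)) check_number(center, "center", positive = TRUE)
  structure(list(type = "gaussian", total_power = total_power,
                 fwhm = fwhm, center = center),
            class = "comb_envelope")
}

#' @rdname envelope_uniform
#' @export
envelope_tabulated <- function(nu, power, total_power = 24e-3) {
  if (length(nu) != length(power) || length(nu) < 2L) {
    abort("`nu` and `power` must be equal-length vectors (length >= 2).")
  }
  if (any(power < 0)) abort("tabulated `power` must be >= 0 elementwise.")
  structure(list(type = "tabulated", total_power = total_power,
                 nu = as.double(nu), power = as.double(power)),
            class = "comb_envelope")
}

# Relative per-tooth weights of an envelope on the tooth frequency grid.
envelope_weights <- function(envelope, nu, band_center) {
  switch(envelope$type,
    uniform = rep(1, length(nu)),
    gaussian = {
      c0 <- envelope$center %||% band_center
      exp(-4 * log(2) * ((nu - c0) / envelope$fwhm)^2)
    },
    tabulated = {
      w <- approx(envelope$nu, envelope$power, xout = nu, rule = 1)$y
      if (anyNA(w)) abort("tabulated envelope does not cover the comb band.")
      w
    },
    abort("unknown envelope type.")
  )
}

#' Build a dual-comb pair and its multi-heterodyne mapping
#'
#' Constructs two frequency combs with repetition rates `f_rep1` and
#' `f_rep1 + delta_f_rep` whose tooth grids span the optical band
#' `[nu_center - bandwidth/2, nu_center + bandwidth/2)`, together with the
#' constants of the linear acoustic-to-optical mapping
#' `nu = nu0 + scale * f_us` with
#' `scale = (f_rep1 + f_rep2) / (2 |delta_f_rep|)`.
#'
#' Tooth index 0 is the overlapping pair at the offset frequency `nu0`. By
#' default `nu0` is placed at the lower band edge so the band's beat notes
#' start at DC; passing `anchor = c(f_us = ..., nu = ...)` instead solves for
#' `nu0` so that acoustic frequency `f_us` maps to optical frequency `nu`
#' (e.g. `c(f_us = 7.5e6, nu = 171.2e12)` centers the band on the transducer
#' passband).
#'
#' @param f_rep1 Repetition rate of comb 1 (Hz).
#' @param delta_f_rep Repetition-rate difference `f_rep2 - f_rep1` (Hz),
#'   nonzero.
#' @param nu_center Optical band center (Hz).
#' @param bandwidth Optical bandwidth (Hz); must exceed `f_rep1`.
#' @param envelope A [comb envelope][envelope_uniform] distributing power over
#'   the teeth.
#' @param anchor Optional anchor `c(f_us = ..., nu = ...)` fixing `nu0`.
#' @param phase Per-tooth beat-note phase (radian): scalar or vector recycled
#'   over teeth. Default 0 (transform-limited, symmetric centerburst).
#' @return An object of class `comb_pair` with elements `comb1`, `comb2`
#'   (each `f_rep`, `nu0`, `index`, `tooth_power`), `delta_f_rep`, `scale`,
#'   `nu0`, `phase`.
#' @examples
#' pair <- build_comb_pair(160e6, 66.81, nu_center = 171.2e12,
#'                         bandwidth = 15e12,
#'                         anchor = c(f_us = 7.5e6, nu = 171.2e12))
#' pair$scale       # ~2.39e6 bandwidth compression factor
#' @export
build_comb_pair <- function(f_rep1, delta_f_rep, nu_center, bandwidth,
                            envelope = envelope_uniform(),
                            anchor = NULL, phase = 0) {
  check_number(f_rep1, "f_rep1", positive = TRUE)
  check_number(delta_f_rep, "delta_f_rep")
  check_number(nu_center, "nu_center", positive = TRUE)
  check_number(bandwidth, "bandwidth", positive = TRUE)
  if (delta_f_rep == 0) {
    abort("`delta_f_rep` = 0: the optical-to-acoustic mapping is degenerate.")
  }
  if (bandwidth <= f_rep1) {
    abort("`bandwidth` must exceed `f_rep1` so the band holds at least one tooth.")
  }
  if (!inherits(envelope, "comb_envelope")) {
    abort("`envelope` must be created with envelope_uniform()/gaussian()/tabulated().")
  }

  f_rep2 <- f_rep1 + delta_f_rep
  scale <- (f_rep1 + f_rep2) / (2 * abs(delta_f_rep))
  lower <- nu_center - bandwidth / 2
  upper <- nu_center + bandwidth / 2

  if (is.null(anchor)) {
    nu0 <- lower
  } else {
    anchor <- as.list(anchor)
    if (is.null(anchor$f_us) || is.null(anchor$nu)) {
      abort("`anchor` must supply `f_us` and `nu`.")
    }
    nu0 <- anchor$nu - scale * anchor$f_us
  }

  # Half-open grid convention [lower, upper); tooth n sits at the pair mean
  # frequency nu0 + n * (f_rep1 + f_rep2)/2, consistent with the exact mapping.
  spacing <- (f_rep1 + f_rep2) / 2
  n_lo <- ceiling((lower - nu0) / spacing)
  n_hi <- ceiling((upper - nu0) / spacing) - 1
  if (n_lo < 0) {
    abort("band extends below nu0: teeth would map to negative acoustic frequencies.")
  }
  if (n_hi < n_lo) abort("no comb teeth fall inside the requested band.")
  index <- seq.int(n_lo, n_hi)
  nu_teeth <- nu0 + index * spacing

  w <- envelope_weights(envelope, nu_teeth, nu_center)
  if (sum(w) <= 0) abort("envelope weights vanish over the band.")
  # Each comb carries half the combined power.
  p_tooth <- (envelope$total_power / 2) * w / sum(w)
  phase <- rep_len(as.double(phase), length(index))

  comb <- function(f_rep) {
    list(f_rep = f_rep, nu0 = nu0, index = index, tooth_power = p_tooth)
  }
  structure(
    list(comb1 = comb(f_rep1), comb2 = comb(f_rep2),
         delta_f_rep = delta_f_rep, scale = scale, nu0 = nu0,
         phase = phase, band = c(lower = lower, upper = upper)),
    class = "comb_pair"
  )
}

#' @export
print.comb_pair <- function(x, ...) {
  cat("<comb_pair>\n")
  cat(sprintf("  f_rep1      : %.6f MHz\n", x$comb1$f_rep / 1e6))
  cat(sprintf("  delta_f_rep : %.4g Hz\n", x$delta_f_rep))
  cat(sprintf("  scale       : %.6g (optical Hz per acoustic Hz)\n", x$scale))
  cat(sprintf("  nu0         : %.6f THz\n", x$nu0 / 1e12))
  cat(sprintf("  teeth       : %d (indices %d..%d)\n",
              length(x$comb1$index), min(x$comb1$index), max(x$comb1$index)))
  cat(sprintf("  band        : %.3f - %.3f THz\n",
              x$band[["lower"]] / 1e12, x$band[["upper"]] / 1e12))
  invisible(x)
}

#' Beat notes of a comb pair
#'
#' One row per tooth pair: the n-th pair beats at exactly
#' `f_acoustic = n * |delta_f_rep|`, at the optical pair-mean frequency
#' `nu_optical = nu0 + n * (f_rep1 + f_rep2) / 2`, with intensity beat
#' amplitude `2 * sqrt(P1n * P2n)`.
#'
#' @param pair A [build_comb_pair()] object.
#' @return A tibble with columns `index`, `nu_optical` (Hz), `f_acoustic`
#'   (Hz), `amplitude` (W), `phase` (rad).
#' @export
beat_notes <- function(pair) {
  stopifnot(inherits(pair, "comb_pair"))
  n <- pair$comb1$index
  spacing <- (pair$comb1$f_rep + pair$comb2$f_rep) / 2
  tibble(
    index = n,
    nu_optical = pair$nu0 + n * spacing,
    f_acoustic = n * abs(pair$delta_f_rep),
    amplitude = 2 * sqrt(pair$comb1$tooth_power * pair$comb2$tooth_power),
    phase = pair$phase
  )
}

#' Map between acoustic and optical frequencies
#'
#' The exact linear mapping `nu = nu0 + scale * f_us` and its inverse
#' `f_us = (nu - nu0) / scale`. A 15 THz optical band compresses to
#' `15e12 / scale` of acoustic bandwidth (about 6.3 MHz for 160 MHz combs with
#' `delta_f_rep` = 66.81 Hz).
#'
#' @param pair A [build_comb_pair()] object.
#' @param f_us Acoustic (ultrasound) frequency, Hz, `>= 0`. Vectorized.
#' @param nu Optical frequency, Hz, `>= nu0`. Vectorized.
#' @return Mapped frequencies (Hz).
#' @export
optical_from_ultrasound <- function(pair, f_us) {
  stopifnot(inherits(pair, "comb_pair"))
  if (any(f_us < 0)) abort("`f_us` must be >= 0.")
  pair$nu0 + pair$scale * f_us
}

#' @rdname optical_from_ultrasound
#' @export
ultrasound_from_optical <- function(pair, nu) {
  stopifnot(inherits(pair, "comb_pair"))
  if (any(nu < pair$nu0)) {
    abort("`nu` below nu0 would map to a negative acoustic frequency.")
  }
  (nu - pair$nu0) / pair$scale
}

#' Check the dual-comb non-aliasing condition
#'
#' The optical-to-acoustic mapping is one-to-one only while the highest beat
#' note stays below half the repetition rate; beyond that, beat orders fold
#' back and distinct teeth share an acoustic frequency.
#'
#' @param pair A [build_comb_pair()] object.
#' @return A tibble with `max_beat` (Hz), `limit` (`f_rep1 / 2`, Hz),
#'   `margin` (Hz) and logical `pass`.
#' @export
check_alias_free <- function(pair) {
  stopifnot(inherits(pair, "comb_pair"))
  max_beat <- max(pair$comb1$index) * abs(pair$delta_f_rep)
  limit <- pair$comb1$f_rep / 2
  tibble(max_beat = max_beat, limit = limit,
         margin = limit - max_beat, pass = max_beat < limit)
}
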