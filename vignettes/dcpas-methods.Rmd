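---
title: "Dual-comb photoacoustic spectroscopy: model and processing choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-comb photoacoustic spectroscopy: model and processing choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcpas)
```

## The measurement being simulated

Dual-comb photoacoustic spectroscopy (DCPAS) excites a sample with the
combined light of two frequency combs whose repetition rates differ by a
small amount `Δf_rep`. Each pair of comb teeth beats at a unique radio
frequency `f_n = n · Δf_rep`, so the optical spectrum is imprinted on the
intensity of the light as a set of megahertz-scale amplitude modulations.
Where the sample absorbs, those modulations drive thermoelastic pressure
waves; an ultrasound transducer converts them to a voltage. The voltage
record over one repetition-difference period `1/Δf_rep` is an interferogram
whose Fourier transform is the photoacoustic spectrum on the acoustic axis,
and the exact linear map

    ν_optical = ν₀ + [ (f_rep,1 + f_rep,2) / (2 · Δf_rep) ] · f_US

relabels it onto the optical axis. With 160 MHz combs and
`Δf_rep = 66.81 Hz` the compression factor is ≈ 2.39 × 10⁶: a 15 THz optical
band folds into ≈ 6.3 MHz of acoustic bandwidth, inside the passband of an
ordinary immersion transducer.

`dcpas` simulates this chain end to end at baseband — the optical carrier is
never sampled. Only the multi-heterodyne beat amplitudes and phases exist in
the model, which is what makes desk-scale simulation of the full
configuration possible: one period at the canonical parameters is
`round(30 MS/s / 66.81 Hz) ≈ 449,000` samples carrying ≈ 94,000 on-grid
tones, synthesized by placing each beat note on its exact FFT bin and
inverse-transforming.

## Physical model, term by term

**Comb pair** (`build_comb_pair()`). Tooth index 0 is the overlapping pair
at the offset frequency ν₀; the modeled band is a half-open window
`[center − BW/2, center + BW/2)`. The per-pair optical frequency is the
tooth-pair mean `ν₀ + n (f_rep,1 + f_rep,2)/2`, which makes the linear map
above exact rather than approximate (the difference from quoting either
comb's own tooth is `≤ n·Δf_rep/2`, a few MHz on 170 THz, relative ~2×10⁻⁸).
ν₀ itself depends on carrier-envelope offsets that the model does not carry,
so it is fixed either at the lower band edge (beats start at DC) or by an
anchor pair such as "7.5 MHz ↔ 171.2 THz", which centers the folded band on
the transducer. Beat amplitudes are intensity beats, `2√(P₁ₙP₂ₙ)` for
per-tooth powers `P`; the spectral envelope (uniform, Gaussian, or a
tabulated curve) distributes a configured total power, 24 mW by default.
Beat phases default to zero — a transform-limited pulse whose interferogram
has a symmetric centerburst at t = 0.

**Sample** (`builtin_sample()`, `spectrum_from_peaks()`). Absorbers are
analytic: a baseline plus Gaussian or Lorentzian peaks in the base-e
absorption coefficient μ_A(ν), with a thickness L and a scalar
photoacoustic conversion factor β (assumed frequency-independent over the
few-MHz acoustic band). The pressure source per beat note is
`β · [1 − exp(−μ_A L)] · I₀(ν_n)`, with a linearized `μ_A L` variant for the
weak-absorption regime. Three built-ins emulate the canonical targets:

* `vacnt_like` — a flat, optically thick absorber (absorbed fraction ≈ 1),
  the alignment/characterization target;
* `pdms_like` — C–H overtone peaks at 171.6, 176.0 and 177.4 THz;
* `paraffin_like` — peaks at 169.8 and 173.1 THz.

No absolute μ_A or β is available for these targets, so only ratios are
meaningful. The polymer peak heights are calibrated so that, under the
canonical configuration, the photoacoustic interferogram amplitudes are
100× (pdms) and 50× (paraffin) below the flat absorber — equivalently,
paraffin is 2× pdms. Note the two calibrations pin the *signal* ratios, not
the peak absorbed fractions, which land at ≈ 0.045 and ≈ 0.069: the
centerburst is a band-integrated, transducer-weighted quantity, so pinning
peak absorbed fractions instead would overshoot the intended signal ratios
several-fold. The 176.0/177.4 THz pair is given 0.8 THz FWHM (the other
peaks 1.5 THz) so that two bands 1.4 THz apart remain distinct at the
500 GHz processing resolution; condensed-phase overtone features span
hundreds of GHz to a few THz, so both widths are physically reasonable.

**Detection** (`make_transducer()`, `detection_chain()`). The transducer is
a normalized amplitude response, by default Gaussian with 7.5 MHz peak and
7.5 MHz FWHM ("bandwidth" is read as FWHM; a raised-cosine shape and
tabulated calibration curves are alternatives). The electronics apply 80 dB
of voltage gain and a 4th-order Butterworth amplitude low-pass at 15 MHz
(the filter order is a realism choice, not a stated property of any
particular instrument). Acoustic propagation through the water path is a
pure delay, 14 µs by default, carried as a linear spectral phase
`−2π f t_acoustic`. Detector noise is additive white Gaussian voltage noise
injected at the transducer output before gain — the white-noise model is
what makes SNR grow as √(averaging time), and signal-independence is what
makes SNR linear in optical power. The reference (photodetector) channel is
treated as noiseless: it is the high-SNR channel used for phase estimates.

## Processing chain

`recover_absorption()` composes the recovery exactly as a measurement would
be processed:

1. coherently average M interferogram periods (with reference-channel phase
   correction when per-shot phase jitter is enabled);
2. remove the acoustic delay by circularly shifting the periodic record;
3. apodize both channels with the same window — 4.8 µs rectangular by
   default — zero-padding outside the window so the spectrum stays on the
   beat-note bin grid;
4. Fourier transform to one-sided amplitude spectra (an on-grid unit cosine
   reads 1.0 at its bin);
5. relabel acoustic bins to optical frequency with the exact linear map;
6. normalize the photoacoustic spectrum by the excitation spectrum and the
   detection-chain amplitude response.

The apodization trades resolution for per-element SNR: a 4.8 µs window
smooths the spectrum to `1/4.8 µs × scale ≈ 500 GHz` on the optical axis
(the recovered line shape of an unresolved absorber is the window's sinc,
FWHM `1.2067/w` mapped by the same factor), and averaging
`500 GHz / 160 MHz = 3125` independent spectral samples per element buys a
`√3125 ≈ 56` gain in per-element SNR. The rectangular default matches that
boxcar-averaging arithmetic; Hann is available.

Two normalization choices deserve a note. First, the response divided out is
the *full* chain response — transducer × low-pass (× gain) — not the
transducer alone; the in-band Butterworth roll-off is ≈ 13 % across the
folded band, and dividing it out is what lets a flat absorber normalize to a
constant at the 10⁻⁶ level. Second, bins where the excitation spectrum or
the response falls below 5 % of its peak are masked (`NA`) rather than
divided into noise blow-ups at the band edges. Amplitude (magnitude)
spectra are used throughout; phase-sensitive spectroscopy is out of scope.

## SNR definitions and scaling laws

The time-domain SNR is the centerburst peak divided by the standard
deviation of the samples outside an exclusion region (`time_domain_snr()`).
The window defaults — 2.4 µs centerburst half-width (half the apodization
window) and 3× that for the exclusion region — are package choices; no
standard values exist. Two estimator caveats are documented rather than
hidden: near SNR ≈ 1 the "peak" is really the maximum of noise over the
search window, so the estimator is biased upward there (tests therefore
anchor low-SNR operating points after averaging, e.g. a unit single-shot
SNR scene reads ≈ 32 after 1024 coherent averages); and the spectral SNR of
*magnitude* bins follows Rician statistics, so its √M growth holds only
once bins are signal-dominated — for pure noise the per-bin mean/sd ratio
is the Rayleigh constant ≈ 1.91, not zero.

`fit_sqrt_tau()` and `fit_power_linear()` fit `SNR = A√τ` and SNR-vs-power
lines, each with a free-exponent log-log diagnostic (≈ 0.5 and ≈ 1.0
respectively for detector-noise-limited operation).
`acquisition_time_scale()` propagates the design arithmetic: required
averaging time ∝ `1/f_rep` (at fixed total power, wider tooth spacing puts
more power in each tooth, up to the point where the spacing matches the
desired resolution), ∝ `1/absorbance²` and `1/power²` (SNR is linear in
both), and ∝ `noise²`. A 500 GHz comb (3000× the 160 MHz rate) alone gives
√3000 ≈ 55× SNR at fixed time; combined with 10× stronger absorbance the
averaging time falls 300,000-fold — a 2 h acquisition projecting to 24 ms.

## Simulation mechanics and numerical choices

* **On-grid synthesis.** The record length is `N = round(fs / |Δf_rep|)`
  and the realized rate is `N · |Δf_rep|`, so every beat lands exactly on an
  FFT bin; the requested rate is honored to ~10⁻⁶ relative. Off-grid tones
  and multi-period records are deliberately unsupported — one record is one
  interferogram period, and averaging is shot-wise.
* **Scene default 30 MS/s.** The canonical band anchored at
  7.5 MHz ↔ 171.2 THz reaches 10.6 MHz of top beat frequency; 30 MS/s keeps
  2.5× headroom above it.
* **Phase jitter and correction.** Per-shot jitter is a single global phase
  (rigid interferogram rotation), emulating the residual phase noise that
  real-time correction removes; per-tooth decoherence is out of scope. The
  correction estimates each shot's phase from the analytic signal at the
  reference centerburst and counter-rotates both channels. Uncorrected
  averaging of shots with Gaussian phase jitter of spread σ attenuates the
  signal by the phasor mean `exp(−σ²/2)`.
* **Exact fast averaging.** For zero jitter, the mean of M i.i.d.-noise
  shots is the deterministic signal plus white noise of spread σ/√M;
  `simulate_average()` draws that mean directly instead of looping, which is
  a distributional identity, not an approximation. It refuses scenes with
  jitter, where order matters.
* **Reproducibility.** Every stochastic quantity (noise, jitter) derives
  from a scene seed and a stream/shot index through a fixed integer
  recurrence; identical configurations give byte-identical pipeline output.
* **Monte-Carlo problem sizes.** Scaling experiments use a reduced-scale
  scene (`demo_scene()`: `Δf_rep = 16 kHz`, 64 GHz band, 2000-sample
  periods) that preserves the structure of the full configuration while
  making thousands of averaged records cheap; the full ≈ 449,000-sample
  configuration is used where the optical axis matters (parameter recovery,
  resolution). The averaging-time-ratio experiment uses 20 noise seeds with
  a doubling-plus-bisection search for the shot count reaching time-domain
  SNR 20.

## What the generator does and does not emulate

The generator reproduces the *structure* of the measurement — exact comb
mapping, band-limited detection, delay, additive detector noise, coherent
averaging — so passing tests demonstrate that the processing chain is
self-consistent and that the scaling laws follow from the stated noise
model. It does not emulate acoustic diffraction or focusing (propagation is
a pure delay with scalar coupling), thermal-diffusion physics (collapsed
into β), comb line widths or carrier-envelope dynamics, digitizer
quantization, or sample inhomogeneity; absolute voltages and absolute μ_A
are not meaningful, only ratios are. Agreement of a simulated spectrum with
its generator is parameter recovery, not validation against a physical
instrument.

## Known limitations

* The full-scale tooth count is ≈ 94,000 over 15 THz (160 MHz spacing);
  quoted "≈ 95,000 teeth" style figures are rounded statements, and the
  package reports the computed count.
* Depth-resolved inversion (treating the delay spectrum as an axial image)
  is out of scope, as is any reference-sample system-response calibration.
* The spectral-SNR estimator needs many repeats (≥ 8 enforced; 32 is
  comfortable) — with few repeats the per-bin standard deviation is noisy
  and the max-over-bins statistic is substantially inflated.
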