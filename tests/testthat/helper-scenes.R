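# Shared fixtures, built in code.

# Canonical-regime comb pair, anchored so 7.5 MHz maps to 171.2 THz.
canonical_pair <- function(bandwidth = 15e12) {
  build_comb_pair(160e6, 66.81, nu_center = 171.2e12, bandwidth = bandwidth,
                  anchor = c(f_us = 7.5e6, nu = 171.2e12))
}

# Small pair with nu0 at the band edge: tooth indices 0..(n-1), beats on a
# delta_f grid starting at DC. Handy for synthesis unit tests.
edge_pair <- function(n_teeth = 8, f_rep = 100e6, delta_f = 1e4,
                      total_power = 1) {
  build_comb_pair(f_rep, delta_f, nu_center = 2e14,
                  bandwidth = n_teeth * f_rep * 1.0001,
                  envelope = envelope_uniform(total_power))
}

# Reduced-scale pdms scene with calibrated or explicit detector noise.
pdms_demo <- function(noise = 0, seed = 0, beta = NULL) {
  demo_scene(sample = builtin_sample("pdms_like"), noise_density = noise,
             seed = seed, beta = beta)
}

# Evaluate `code` under a local seed without disturbing the session RNG.
with_seed_helper <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Time-domain SNR of an M-shot average with the acoustic delay removed.
averaged_snr <- function(scene, m, stream = 0, power = NA_real_) {
  avg <- simulate_average(scene, m, stream = stream)
  time_domain_snr(remove_acoustic_delay(avg$pa, scene$chain$t_acoustic),
                  power = power)
}
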