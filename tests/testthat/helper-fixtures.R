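# Shared fixtures, built in code at test time.

# Small three-block dataset: one age-informative block, one weak, one noise.
make_small_dataset <- function(n = 120, seed = 42,
                               missingness = "none", miss_rate = 0,
                               mar_slope = 0) {
  cfg <- simulation_config(
    n_subjects = n,
    block_specs = list(
      block_spec("strong", 15, shared_signal_weight = 1.5, noise_sd = 1),
      block_spec("weak", 15, shared_signal_weight = 0.5, noise_sd = 2,
                 missingness = missingness, miss_rate = miss_rate,
                 mar_slope = mar_slope),
      block_spec("noise", 15, shared_signal_weight = 0,
                 private_signal_weight = 1, health_weight = 0,
                 noise_sd = 1)),
    seed = seed)
  simulate_multimodal(cfg)
}

# Synthetic 1/f + optional Gaussian-bump spectrum, built analytically.
make_bump_spectrum <- function(bumps = list(c(center = 10, width = 1,
                                              height = 2)),
                               freqs = seq(0.5, 45, by = 0.25),
                               slope = 1) {
  base <- freqs^(-slope)
  for (b in bumps) {
    base <- base + b[["height"]] * exp(-(freqs - b[["center"]])^2 /
                                         (2 * b[["width"]]^2))
  }
  power_spectrum(freqs, base)
}

random_spd <- function(p, jitter = 1) {
  a <- matrix(rnorm(p * p), p)
  crossprod(a) / p + jitter * diag(p)
}
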