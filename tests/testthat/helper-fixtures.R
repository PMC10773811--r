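# Shared fixtures: small configurations that keep unit tests fast.

tiny_synth <- function(n = 40, seed = 1, effect = 0.3, noise = 0.01,
                       channels = 8, res = 16, windows = list(c(3, 5))) {
  synth_config(n_seeds = n, imbalance = 0.5, n_channels = channels,
               informative_windows = windows, effect_size = effect,
               noise_sd = noise, scatter_sd = 0.02, drift_amp = 0.01,
               resolution = res, seed = seed)
}

tiny_net <- function(channels = 8, size = 16) {
  net_config(channels, width = 8, input_size = size)
}

# Benchmark-scale generator: the package's default desk conditions with the
# planted 12-of-60 informative window used by the recovery benchmarks.
bench_synth <- function(n = 400, seed = 1) {
  synth_config(n_seeds = n, n_channels = 60,
               informative_windows = list(c(25, 36)),
               effect_size = 0.08, seed = seed)
}

split_parts <- function(ds, seed = 1) {
  idx <- split_dataset(ds$samples, seed = seed)
  lapply(idx, function(i) ds$samples[i])
}

label_of <- function(samples) vapply(samples, function(s) s$label, 0L)
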