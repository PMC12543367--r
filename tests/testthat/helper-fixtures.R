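# Shared fixtures, all generated in code.

# Small 3-channel configuration for fast simulator tests: short record,
# 16x16 px regions, noise on.
tiny_config <- function(occlusion_window_s = c(2, 4), ...) {
  synth_config(
    n_subjects = 1, seed = 7, duration_s = 6,
    channels = default_channels()[c(1, 4, 7), ],
    occlusion_window_s = occlusion_window_s,
    region_px = 16,
    ...
  )
}

# Single-channel, high-pixel-count configuration for ensemble statistics.
ensemble_config <- function(mean_counts = 5000, duration_s = 0.05,
                            noise = noise_params(read_sigma = 0,
                                                 dark_offset = 0,
                                                 conversion_factor = 1,
                                                 shot = FALSE),
                            ...) {
  ch <- default_channels()[1, ]
  ch$mean_counts <- mean_counts
  synth_config(n_subjects = 1, seed = 5, duration_s = duration_s,
               channels = ch, occlusion_window_s = NULL,
               pulsatility = 0, region_px = 100, noise = noise, ...)
}

# Deterministic pseudo-ECG-free pulsatile test trace.
sin_trace <- function(freq_hz, n = 1560, fs = 65, amplitude = 1,
                      noise_sd = 0, seed = 1) {
  t <- (seq_len(n) - 1) / fs
  set.seed(seed)
  amplitude * sin(2 * pi * freq_hz * t) +
    if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
}
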