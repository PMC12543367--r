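# Simulator forward model: cardiac waveform, layer flows, channel mixing,
# speckle visibility, frame synthesis, dark frames, closed-form oracles.

test_that("cardiac waveform is unit-mean, periodic, pulsatility-spanned", {
  t24 <- (0:1559) / 65

  # degenerate flat waveform
  expect_equal(cardiac_waveform(1.0, 0, t24), rep(1, length(t24)))

  # periodicity at 1 Hz
  w <- cardiac_waveform(1.0, 0.3, t24)
  expect_equal(cardiac_waveform(1.0, 0.3, t24 + 1.0), w, tolerance = 1e-9)

  # unit mean over an integer number of cycles; span tracks pulsatility
  for (hr in c(0.9, 1.0, 1.17)) {
    n_cyc <- floor(24 * hr)
    tt <- seq(0, n_cyc / hr, length.out = 4000 + 1)[-(4000 + 1)]
    ww <- cardiac_waveform(hr, 0.25, tt)
    expect_lt(abs(mean(ww) - 1), 1e-6)
    expect_equal(max(ww) - min(ww), 0.25, tolerance = 1e-4)
    # span exactly proportional to pulsatility on a common grid
    w2 <- cardiac_waveform(hr, 0.5, tt)
    expect_equal((max(w2) - min(w2)) / (max(ww) - min(ww)), 2,
                 tolerance = 1e-12)
  }

  # dominant FFT peak at the nominal 1 Hz adult heart rate
  psd <- power_spectrum(w, 65)
  expect_equal(psd$freq[which.max(psd$power)], 1.0, tolerance = 1e-9)

  expect_error(cardiac_waveform(0, 0.3, t24), "positive")
  expect_error(cardiac_waveform(-1, 0.3, t24), "positive")
})

test_that("layer flows: occlusion suppresses scalp only, with ramps", {
  cfg <- synth_config(n_subjects = 1, seed = 1, heart_rate_hz = 1,
                      scalp_suppression = 0.35,
                      occlusion_window_s = c(8, 16))
  fl <- simulate_layer_flows(cfg, 1)

  # fully-suppressed core (ramps are 0.5 s): integer cycle counts at 1 Hz
  core <- fl$t >= 9 & fl$t < 15
  pre <- fl$t >= 1 & fl$t < 7
  expect_equal(mean(fl$scalp[core]) / mean(fl$scalp[pre]), 0.35,
               tolerance = 1e-2)

  # brain trace untouched by the occlusion, identical to control with the
  # same seed (conservation invariant)
  cfg0 <- synth_config(n_subjects = 1, seed = 1, heart_rate_hz = 1,
                       occlusion_window_s = NULL)
  fl0 <- simulate_layer_flows(cfg0, 1)
  expect_identical(fl$brain, fl0$brain)
  expect_equal(fl0$scalp, fl0$brain)   # control scalp is unsuppressed

  # control config: stationary pulsatile series, equal segment means
  expect_equal(mean(fl0$scalp[core]), mean(fl0$scalp[pre]), tolerance = 1e-3)
})

test_that("channel mixing is linear with normalized weights", {
  ch <- data.frame(channel = 1:3, sd_distance_cm = c(0.6, 1.6, 2.6),
                   scalp_sensitivity = c(1, 0.5, 0),
                   brain_sensitivity = c(0, 0.5, 1),
                   mean_counts = c(3000, 1000, 300))
  cfg <- synth_config(n_subjects = 1, seed = 1, channels = ch,
                      heart_rate_hz = 1)
  fl <- simulate_layer_flows(cfg, 1)
  mx <- mix_channels(cfg, fl$scalp, fl$brain)

  expect_equal(mx$composite[, 1], fl$scalp, ignore_attr = TRUE)
  expect_equal(mx$composite[, 3], fl$brain, ignore_attr = TRUE)
  expect_equal(mx$composite[, 2], 0.5 * fl$scalp + 0.5 * fl$brain,
               ignore_attr = TRUE)
  # decorrelation rate proportional to the composite
  expect_equal(mx$inv_tau_c, mx$composite / cfg$tau_c_baseline_s)

  # brain-only channel unaffected by occlusion; during/pre composite ratio
  # non-decreasing with channel index for a monotone sensitivity profile
  core <- fl$t >= 9 & fl$t < 15
  pre <- fl$t >= 1 & fl$t < 7
  ratios <- colMeans(mx$composite[core, ]) / colMeans(mx$composite[pre, ])
  expect_false(is.unsorted(ratios))
  expect_equal(unname(ratios[3]), 1, tolerance = 1e-3)
})

test_that("speckle visibility function: limits and closed forms", {
  # static-scatterer limit K^2 -> beta
  expect_equal(speckle_visibility(1e-9, 1, 0.8), 0.8, tolerance = 1e-6)
  # x = 1, beta = 1: (e^-2 - 1 + 2)/2
  expect_equal(speckle_visibility(1, 1, 1), (exp(-2) + 1) / 2,
               tolerance = 1e-12)
  expect_equal(speckle_visibility(1, 1, 1), 0.5676676, tolerance = 1e-7)
  # the 8 ms / 1 ms operating point: K^2 = beta * (2*8 - 1 + e^-16)/128
  expect_equal(speckle_visibility(0.008, 0.001, 0.3),
               0.3 * (15 + exp(-16)) / 128, tolerance = 1e-12)
  expect_equal(speckle_visibility(0.008, 0.001, 1), 0.1171875,
               tolerance = 1e-6)
  # strictly decreasing in x
  x <- 10^seq(-3, 2, length.out = 60)
  k2 <- speckle_visibility(1, 1 / x, 0.5)
  expect_true(all(diff(k2) < 0))
  expect_error(speckle_visibility(0.008, -1, 0.5), "positive")
})

test_that("synthesized stacks have the stated geometry and are deterministic", {
  cfg <- synth_config(n_subjects = 2, seed = 42, region_px = 8)
  sim <- synthesize_frames(cfg, 1)
  # 24 s at 65 FPS -> 1560 frames, 7 channel regions
  expect_equal(dim(sim$stack$frames), c(1560, 8, 56))
  expect_equal(nrow(sim$layout), 7)
  expect_s3_class(sim$stack, "frame_stack")

  # bit-identical regeneration from the same (config, seed, subject)
  sim2 <- synthesize_frames(cfg, 1)
  expect_identical(sim$stack$frames, sim2$stack$frames)
  # different subject -> different stream
  simB <- synthesize_frames(cfg, 2)
  expect_false(identical(sim$stack$frames, simB$stack$frames))

  # constant composite flow -> constant true contrast
  cfg_const <- ensemble_config()
  tr <- synthesize_frames(cfg_const, 1)$truth
  expect_equal(diff(range(tr$k_true_sq)), 0)

  expect_error(synthesize_frames(cfg, 5), "subject_index")
})

test_that("gamma speckle ensemble reproduces K_true^2 (moment identity)", {
  # noiseless: no shot/read/offset, CF 1 => counts are the gamma draws
  cfg <- ensemble_config()
  sim <- synthesize_frames(cfg, 1)
  k_true <- sim$truth$k_true_sq[1, 1]
  ens <- split_channels(sim$stack, sim$layout)[[1]]
  n_px <- nrow(ens)
  expect_gte(n_px, 1e4)
  for (f in seq_len(ncol(ens))) {
    k_hat <- var(ens[, f]) / mean(ens[, f])^2
    # Monte-Carlo bound ~ 3 * sd(K^2)/K^2 ~ 3 * sqrt((2 + 6 K^2)/N)
    expect_lt(abs(k_hat - k_true) / k_true,
              3 * sqrt((2 + 6 * k_true) / n_px) + 0.01)
  }
})

test_that("saturation triggers a warning", {
  ch <- default_channels()[1, ]
  ch$mean_counts <- 90000   # far beyond the 16-bit ceiling
  cfg <- synth_config(n_subjects = 1, seed = 1, duration_s = 0.05,
                      channels = ch, occlusion_window_s = NULL,
                      region_px = 16)
  expect_warning(synthesize_frames(cfg, 1), "saturation")
})

test_that("dark frames: offset, variance, clipping", {
  nz0 <- noise_params(read_sigma = 0, dark_offset = 100)
  dk0 <- synthesize_dark_frames(nz0, 3, dims = c(8, 8), seed = 1)
  expect_true(all(dk0$frames == 100))

  nz <- noise_params(read_sigma = 2, dark_offset = 100)
  dk <- synthesize_dark_frames(nz, 40, dims = c(50, 50), seed = 2)
  # 1e5 Gaussian samples: sample variance ~ 4 +/- 0.1 (plus ~1/12
  # quantization variance from rounding)
  expect_equal(var(as.numeric(dk$frames)), 4 + 1 / 12, tolerance = 0.05)
  expect_true(all(dk$frames >= 0 & dk$frames <= 65535))

  expect_error(synthesize_dark_frames(nz, 1, seed = 1), "at least 2")
})

test_that("expected_segment_ratios: control, algebraic and brain-only cases", {
  # control -> identically 1
  cfg0 <- synth_config(n_subjects = 1, seed = 1, occlusion_window_s = NULL)
  r0 <- expected_segment_ratios(cfg0)
  expect_true(all(r0$ratio_mean_ba == 1 & r0$ratio_mean_ca == 1))

  # ramp-free, pulseless flow oracle: during/pre = 1 - w (1 - s)
  ch <- data.frame(channel = 1:3, sd_distance_cm = c(0.6, 1.6, 2.6),
                   scalp_sensitivity = c(1, 0.5, 0),
                   brain_sensitivity = c(0, 0.5, 1),
                   mean_counts = c(3000, 1000, 300))
  cfg <- synth_config(n_subjects = 1, seed = 1, channels = ch,
                      pulsatility = 0, ramp_s = 0,
                      scalp_suppression = 0.4,
                      occlusion_window_s = c(8, 16))
  r <- expected_segment_ratios(cfg, metric = "flow")
  expect_equal(r$ratio_mean_ba, 1 - c(1, 0.5, 0) * (1 - 0.4),
               tolerance = 1e-12)
  # brain-only channel: ratio 1 regardless of suppression
  expect_equal(r$ratio_mean_ba[3], 1)
  expect_equal(r$ratio_mean_ca, rep(1, 3), tolerance = 1e-12)

  # monotone sensitivity profile -> non-decreasing ratios (default config)
  cfg_d <- synth_config(n_subjects = 1, seed = 1)
  rd <- expected_segment_ratios(cfg_d, metric = "bfi")
  expect_false(is.unsorted(rd$ratio_mean_ba))
})

test_that("config validation enforces the stated invariants", {
  expect_error(synth_config(occlusion_window_s = c(8, 30)), "inside")
  expect_error(synth_config(occlusion_window_s = c(16, 8)), "start < end")
  expect_error(synth_config(pulsatility = 1.2), "pulsatility")
  expect_error(synth_config(beta = 0), "beta")
  bad <- default_channels()
  bad$scalp_sensitivity <- rev(bad$scalp_sensitivity)  # increasing: warn
  bad$brain_sensitivity <- 1 - bad$scalp_sensitivity
  bad$scalp_sensitivity_vol <- bad$scalp_sensitivity
  bad$brain_sensitivity_vol <- bad$brain_sensitivity
  w <- capture_warnings(synth_config(channels = bad))
  expect_length(w, 2)
  expect_match(w, "decreasing", all = TRUE)
})

test_that("truth_series matches the forward model and pipeline layout", {
  cfg <- tiny_config()
  ts <- truth_series(cfg, 1)
  expect_setequal(unique(ts$channel), cfg$channels$channel)
  s1 <- ts[ts$channel == 1, ]
  expect_equal(nrow(s1), 390)
  expect_equal(s1$bfi, 1 / s1$k_adj_sq)
  expect_equal(range(s1$nbfi), c(0, 1))
})
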