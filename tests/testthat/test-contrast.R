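# Contrast extraction and hemodynamic indices (raw/adjusted K^2, BFI, BVI).

test_that("split_channels yields the stated pixel ensembles", {
  frames <- array(seq_len(2 * 8 * 8) %% 256, dim = c(2, 8, 8))
  stack <- frame_stack(frames, 65, 0.008)

  full <- channel_layout(data.frame(channel = 1, sd_distance_cm = 0.6,
                                    row0 = 0, row1 = 8, col0 = 0, col1 = 8))
  ens <- split_channels(stack, full)
  expect_equal(dim(ens[[1]]), c(64, 2))
  expect_setequal(ens[[1]][, 1], as.vector(frames[1, , ]))

  two <- channel_layout(data.frame(channel = 1:2, sd_distance_cm = c(0.6, 1),
                                   row0 = c(0, 4), row1 = c(4, 8),
                                   col0 = c(0, 4), col1 = c(4, 8)))
  ens2 <- split_channels(stack, two)
  expect_equal(vapply(ens2, nrow, 1L), c(ch1 = 16L, ch2 = 16L))

  # out-of-bounds and overlapping rectangles are layout errors
  oob <- data.frame(channel = 1, sd_distance_cm = 0.6,
                    row0 = 0, row1 = 9, col0 = 0, col1 = 8)
  expect_error(split_channels(stack, channel_layout(oob)), "outside")
  ovl <- data.frame(channel = 1:2, sd_distance_cm = c(0.6, 1),
                    row0 = c(0, 2), row1 = c(4, 6),
                    col0 = c(0, 2), col1 = c(4, 6))
  expect_error(channel_layout(ovl), "overlap")
})

test_that("dark calibration: offset, pooled variance, gamma unit", {
  const <- frame_stack(array(100L, dim = c(3, 4, 4)), 65, 0.008)
  cal <- compute_dark_calibration(const, gain = 1, conversion_factor = 0.46)
  expect_equal(cal$dark_offset, 100)
  expect_equal(cal$dark_variance, 0)
  # gamma = gain / CF = 1 / 0.46
  expect_equal(cal$gamma, 2.173913, tolerance = 1e-6)

  nz <- noise_params(read_sigma = 2, dark_offset = 100)
  dk <- synthesize_dark_frames(nz, 50, dims = c(50, 50), seed = 4)
  cal2 <- compute_dark_calibration(dk)
  expect_equal(cal2$dark_variance, 4, tolerance = 0.05)

  expect_error(frame_stack(array(100L, dim = c(1, 4, 4)), 65, 0.008),
               "at least 2")
})

test_that("raw contrast matches hand arithmetic and gamma moments", {
  expect_equal(raw_contrast(c(50, 50, 50, 50))[c("mu", "var", "k_raw_sq")],
               list(mu = 50, var = 0, k_raw_sq = 0))

  rc <- raw_contrast(c(2, 4, 6, 8))
  expect_equal(rc$mu, 5)
  expect_equal(rc$var, 20 / 3)
  expect_equal(rc$k_raw_sq, 20 / 3 / 25)
  expect_equal(rc$k_raw_sq, 0.26667, tolerance = 1e-4)

  set.seed(1)
  g <- rgamma(1e5, shape = 4, scale = 25)
  expect_equal(raw_contrast(g)$k_raw_sq, 0.25, tolerance = 0.02)

  expect_error(raw_contrast(numeric(0)), "at least 2")
  # offset pushing the mean non-positive flags the frame, no exception
  inv <- raw_contrast(c(2, 4, 6, 8), offset = 10)
  expect_false(inv$valid)
  expect_true(is.na(inv$k_raw_sq))
})

test_that("noise correction subtracts the stated terms and floors", {
  cal0 <- camera_calibration(gain = 1e-12, conversion_factor = 1,
                             dark_variance = 0)
  # zero-noise identity (gamma ~ 0)
  adj <- noise_corrected_contrast(100, 0.04, cal0)
  expect_equal(adj$k_adj_sq, 0.04, tolerance = 1e-10)

  # explicit arithmetic: all three terms
  cal <- camera_calibration(gain = 1, conversion_factor = 0.5,
                            dark_variance = 9, include_quantization = TRUE)
  adj2 <- noise_corrected_contrast(30, 0.1, cal)
  expect_equal(adj2$k_adj_sq, 0.1 - 2 / 30 - 1 / (12 * 900) - 9 / 900)

  # noise floor: k_raw 0.26667, mu 5, gamma 2.1739 -> negative, invalid
  cal3 <- camera_calibration(gain = 1, conversion_factor = 0.46)
  adj3 <- noise_corrected_contrast(5, 0.26667, cal3)
  expect_false(adj3$valid)
  expect_true(is.na(adj3$k_adj_sq))

  # ordering invariant: k_adj <= k_raw wherever valid
  mu <- seq(50, 5000, length.out = 40)
  kr <- 0.03 + 2.1739 / mu
  a <- noise_corrected_contrast(mu, kr, cal3)
  expect_true(all(a$k_adj_sq <= kr, na.rm = TRUE))
})

test_that("Poisson-only stacks null out after shot-noise correction", {
  nz <- noise_params(read_sigma = 1.5, dark_offset = 100,
                     conversion_factor = 0.46, gain = 1)
  flat <- synthesize_flat_frames(1000, nz, n_frames = 400, dims = c(48, 48),
                                 seed = 8)
  dark <- synthesize_dark_frames(nz, 200, dims = c(48, 48), seed = 9)
  calib <- compute_dark_calibration(dark)
  lay <- channel_layout(data.frame(channel = 1, sd_distance_cm = 0.6,
                                   row0 = 0, row1 = 48, col0 = 0, col1 = 48))
  ens <- split_channels(flat, lay)[[1]]
  mu <- colMeans(ens) - calib$dark_offset
  k_raw <- apply(ens, 2, var) / mu^2
  # raw contrast is pure shot + camera noise: ~ gamma/mu
  expect_equal(mean(k_raw), mean(calib$gamma / mu + calib$dark_variance / mu^2),
               tolerance = 0.02)
  adj <- noise_corrected_contrast(mu, k_raw, calib, floor_epsilon = -Inf)
  # mean adjusted contrast within 3 standard errors of zero
  se <- sd(adj$k_adj_sq) / sqrt(length(adj$k_adj_sq))
  expect_lt(abs(mean(adj$k_adj_sq)), 3 * se)
})

test_that("BFI is the reciprocal of adjusted contrast", {
  expect_equal(bfi_from_contrast(0.25), 4)
  expect_equal(bfi_from_contrast(1), 1)
  expect_true(is.na(bfi_from_contrast(NA_real_)))
  # doubling flow in the long-exposure regime: exact visibility ratio
  k1 <- speckle_visibility(0.008, 0.001, 1)
  k2 <- speckle_visibility(0.008, 0.0005, 1)
  expect_equal(bfi_from_contrast(k2) / bfi_from_contrast(k1),
               1.935484, tolerance = 1e-4)   # = (15+e^-16)/(31+e^-32)*4
  expect_equal(bfi_from_contrast(k2) / bfi_from_contrast(k1), 2,
               tolerance = 0.04)             # asymptotic-regime check
})

test_that("normalization maps min/max to 0/1, idempotently, masking invalids", {
  expect_equal(normalize_trace(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(3, 7, 1, 9, 5)
  expect_equal(normalize_trace(normalize_trace(x)), normalize_trace(x))
  withmask <- normalize_trace(c(2, 100, 6), valid = c(TRUE, FALSE, TRUE))
  expect_equal(withmask, c(0, NA, 1))
  expect_error(normalize_trace(c(5, 5, 5)), "degenerate")
  expect_error(normalize_trace(c(5, NA)), "valid samples")
})

test_that("BVI follows the Beer-Lambert log form and its linearization", {
  t <- 0:9
  mu <- rep(100, 10)
  b <- bvi_from_intensity(mu, t, baseline_window_s = c(0, 7))
  expect_equal(b$bvi, rep(0, 10))
  expect_equal(b$i0, 100)

  mu2 <- c(rep(100, 7), 50, 50, 50)
  b2 <- bvi_from_intensity(mu2, t)
  expect_equal(b2$bvi[8], log10(2))
  expect_equal(b2$bvi[8], 0.30103, tolerance = 1e-5)

  mu3 <- c(rep(1000, 7), 990, 990, 990)
  blog <- bvi_from_intensity(mu3, t, method = "log")
  blin <- bvi_from_intensity(mu3, t, method = "linear")
  expect_equal(blog$bvi[8], 0.0043648, tolerance = 1e-4)
  expect_equal(blin$bvi[8], 0.0043429, tolerance = 1e-4)
  # as-printed coefficient of 2 remains available
  blin2 <- bvi_from_intensity(mu3, t, method = "linear", coefficient = 2)
  expect_equal(blin2$bvi[8], 2 * 0.01 / 1)

  # linear (1/ln 10) vs log agreement < 1% for intensity changes < 2%
  for (drop in c(0.002, 0.005, 0.01, 0.019)) {
    muX <- c(rep(1000, 7), 1000 * (1 - drop))
    tX <- 0:7
    lg <- bvi_from_intensity(muX, tX)$bvi[8]
    ln <- bvi_from_intensity(muX, tX, method = "linear")$bvi[8]
    expect_lt(abs(ln - lg) / lg, 0.01)
  }

  expect_error(bvi_from_intensity(mu, t, baseline_window_s = c(20, 25)),
               "baseline")
})

test_that("process_stack recovers the simulator truth on a small stack", {
  cfg <- tiny_config()
  sim <- synthesize_frames(cfg, 1)
  dark <- synthesize_dark_frames(cfg$noise, 100,
                                 dims = dim(sim$stack$frames)[2:3], seed = 3)
  calib <- compute_dark_calibration(dark)
  ser <- process_stack(sim$stack, sim$layout, calib)

  expect_setequal(names(ser),
                  c("channel", "sd_distance_cm", "t", "mu", "var",
                    "k_raw_sq", "k_adj_sq", "valid", "bfi", "nbfi",
                    "bvi", "nbvi"))
  # per-channel: k_adj <= k_raw, nbfi attains both bounds
  for (ch in unique(ser$channel)) {
    s <- ser[ser$channel == ch & ser$valid, ]
    expect_true(all(s$k_adj_sq <= s$k_raw_sq))
    expect_equal(range(s$nbfi), c(0, 1))
    expect_true(all(s$nbfi >= 0 & s$nbfi <= 1))
  }
  # channel 1 (16x16 px, high counts): adjusted contrast tracks truth
  s1 <- ser[ser$channel == 1, ]
  kt <- sim$truth$k_true_sq[, 1]
  expect_lt(median(abs(s1$k_adj_sq - kt) / kt, na.rm = TRUE), 0.25)
  expect_gt(cor(s1$k_adj_sq, kt, use = "complete.obs"), 0.5)
})
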