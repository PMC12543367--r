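# Speckle contrast and hemodynamic index extraction.
#
# Per frame and channel the pipeline computes the raw squared contrast
# K_raw^2 = var(I) / mean(I)^2 over the channel's pixel ensemble, subtracts
# the shot-noise (gamma/mu), quantization (1/(12 mu^2), optional) and
# camera-noise (sigma_dark^2/mu^2) variance contributions, and converts the
# adjusted contrast to a blood flow index BFI = 1/K_adj^2.  Blood volume is
# tracked as the log10 attenuation of the channel mean intensity relative to
# a baseline window.  All arithmetic is in analog-to-digital units (counts).

#' Frame stack container
#'
#' @param frames integer array, time x rows x cols, counts in
#'   `[0, 2^bit_depth - 1]`.
#' @param frame_rate_hz acquisition frame rate, Hz.
#' @param exposure_s camera exposure, seconds.
#' @param bit_depth ADC bit depth.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz, exposure_s, bit_depth = 16) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stopf("`frames` must be a 3-D array (time x rows x cols)")
  if (dim(frames)[1] < 2) stopf("a frame stack needs at least 2 frames")
  assert_scalar_number(frame_rate_hz, "frame_rate_hz", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(exposure_s, "exposure_s", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(bit_depth, "bit_depth", lower = 1, upper = 16)
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stopf("counts outside [0, %d]", 2^as.integer(bit_depth) - 1)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 exposure_s = exposure_s,
                 bit_depth = as.integer(bit_depth)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "frame_stack: %d frames of %dx%d px, %g fps, %g ms exposure, %d-bit\n",
    d[1], d[2], d[3], x$frame_rate_hz, 1000 * x$exposure_s, x$bit_depth))
  invisible(x)
}

stack_times <- function(stack) {
  (seq_len(dim(stack$frames)[1]) - 1) / stack$frame_rate_hz
}

#' Channel layout: pixel regions and source-detector distances
#'
#' Rectangles use 0-based, half-open pixel coordinates
#' (`row0 <= r < row1`, `col0 <= c < col1`).  Rectangles must be pairwise
#' disjoint and `sd_distance_cm` strictly increasing with channel id.
#'
#' @param regions data.frame with columns `channel`, `sd_distance_cm`,
#'   `row0`, `row1`, `col0`, `col1`.
#' @return an object of class `channel_layout` (a validated data.frame).
#' @export
channel_layout <- function(regions) {
  needed <- c("channel", "sd_distance_cm", "row0", "row1", "col0", "col1")
  if (!is.data.frame(regions) || !all(needed %in% names(regions)))
    stopf("layout needs columns: %s", paste(needed, collapse = ", "))
  regions <- regions[order(regions$channel), , drop = FALSE]
  if (any(regions$row1 <= regions$row0) || any(regions$col1 <= regions$col0))
    stopf("layout rectangles must have positive extent")
  if (any(regions$row0 < 0) || any(regions$col0 < 0))
    stopf("layout rectangles must have non-negative origins")
  if (is.unsorted(regions$sd_distance_cm, strictly = TRUE))
    stopf("sd_distance_cm must be strictly increasing with channel id")
  n <- nrow(regions)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- regions[i, ]; b <- regions[j, ]
      if (a$row0 < b$row1 && b$row0 < a$row1 &&
          a$col0 < b$col1 && b$col0 < a$col1)
        stopf("layout rectangles for channels %s and %s overlap",
              a$channel, b$channel)
    }
  }
  class(regions) <- c("channel_layout", "data.frame")
  regions
}

#' Split a frame stack into per-channel pixel ensembles
#'
#' @param stack a [frame_stack()].
#' @param layout a [channel_layout()]; rectangles must fit inside the frame.
#' @return named list (`ch1`, `ch2`, ...) of matrices, pixels x time.
#' @export
split_channels <- function(stack, layout) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!inherits(layout, "channel_layout")) layout <- channel_layout(layout)
  d <- dim(stack$frames)
  if (any(layout$row1 > d[2]) || any(layout$col1 > d[3]))
    stopf("layout rectangle extends outside the %dx%d frame", d[2], d[3])
  out <- lapply(seq_len(nrow(layout)), function(i) {
    r <- layout[i, ]
    sub <- stack$frames[, (r$row0 + 1):r$row1, (r$col0 + 1):r$col1,
                        drop = FALSE]
    n_t <- d[1]
    # pixels x time
    t(matrix(sub, nrow = n_t))
  })
  names(out) <- paste0("ch", layout$channel)
  out
}

#' Camera calibration container
#'
#' Holds the gain, conversion factor (electrons per count), their ratio
#' `gamma = gain/conversion_factor` (the factor scaling Poisson shot noise
#' into count units), the dark offset and the dark variance, all in
#' analog-to-digital units.
#'
#' @param gain camera gain (dimensionless).
#' @param conversion_factor electrons per count (> 0).
#' @param dark_offset mean dark level, counts.
#' @param dark_variance dark-frame variance, counts^2 (>= 0).
#' @param include_quantization include the 1/(12 mu^2) quantization term in
#'   the contrast correction (off by default: negligible at 16-bit depth).
#' @return an object of class `camera_calibration`.
#' @export
camera_calibration <- function(gain = 1, conversion_factor = 0.46,
                               dark_offset = 0, dark_variance = 0,
                               include_quantization = FALSE) {
  assert_scalar_number(gain, "gain", lower = 0, strict_lower = TRUE)
  assert_scalar_number(conversion_factor, "conversion_factor", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(dark_offset, "dark_offset", lower = 0)
  if (any(dark_variance < 0)) stopf("dark_variance must be >= 0")
  structure(list(gain = gain, conversion_factor = conversion_factor,
                 gamma = gain / conversion_factor,
                 dark_offset = dark_offset, dark_variance = dark_variance,
                 include_quantization = isTRUE(include_quantization)),
            class = "camera_calibration")
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf(
    "camera_calibration: gain %g, CF %g e-/count, gamma %.4f, offset %g, dark var %g\n",
    x$gain, x$conversion_factor, x$gamma, x$dark_offset,
    mean(x$dark_variance)))
  invisible(x)
}

#' Calibrate camera noise from a dark-frame stack
#'
#' The dark offset is the mean over all dark pixels; the dark variance is
#' the pooled (temporal plus spatial) unbiased variance of the dark counts.
#' Readout noise is measured rather than taken from the data sheet.
#'
#' @param dark a [frame_stack()] of dark frames (>= 2 frames).
#' @param gain,conversion_factor camera settings; their ratio is `gamma`.
#' @param include_quantization see [camera_calibration()].
#' @return a [camera_calibration()].
#' @export
compute_dark_calibration <- function(dark, gain = 1,
                                     conversion_factor = 0.46,
                                     include_quantization = FALSE) {
  stopifnot(inherits(dark, "frame_stack"))
  if (dim(dark$frames)[1] < 2)
    stopf("dark calibration needs at least 2 frames")
  v <- as.numeric(dark$frames)
  camera_calibration(gain = gain, conversion_factor = conversion_factor,
                     dark_offset = mean(v), dark_variance = var(v),
                     include_quantization = include_quantization)
}

#' Raw speckle contrast of one pixel ensemble
#'
#' `K_raw^2 = var(I) / mu(I)^2` with the unbiased sample variance of the raw
#' counts and the mean taken after dark-offset subtraction (an offset shift
#' does not change the variance, but the mean must represent signal counts
#' for the shot-noise term to hold).  Frames whose offset-subtracted mean is
#' non-positive are flagged invalid rather than raising an error.
#'
#' @param ensemble numeric vector of pixel counts (one frame, one channel).
#' @param offset dark offset to subtract from the mean, counts.
#' @return list with `mu`, `var`, `k_raw_sq`, `valid`.
#' @export
raw_contrast <- function(ensemble, offset = 0) {
  if (length(ensemble) < 2) stopf("ensemble needs at least 2 pixels")
  mu <- mean(ensemble) - offset
  v <- var(ensemble)
  if (mu <= 0) {
    list(mu = mu, var = v, k_raw_sq = NA_real_, valid = FALSE)
  } else {
    list(mu = mu, var = v, k_raw_sq = v / mu^2, valid = TRUE)
  }
}

# Vectorized raw contrast over a pixels x time matrix.
raw_contrast_series <- function(m, offset = 0) {
  mu <- .colMeans(m, nrow(m), ncol(m)) - offset
  v <- col_vars(m)
  valid <- mu > 0
  k <- ifelse(valid, v / mu^2, NA_real_)
  list(mu = mu, var = v, k_raw_sq = k, valid = valid)
}

#' Noise-corrected squared speckle contrast
#'
#' Subtracts the shot-noise, quantization and camera (read/dark) noise
#' variance contributions from the raw squared contrast:
#' `K_adj^2 = K_raw^2 - gamma/mu - 1/(12 mu^2) - sigma_dark^2/mu^2`
#' (the quantization term only when enabled in the calibration).  Values at
#' or below `floor_epsilon` - the photon count approaching the camera noise
#' floor - are flagged invalid and returned as `NA`.
#'
#' @param mu offset-subtracted mean counts (vectorized).
#' @param k_raw_sq raw squared contrast (vectorized).
#' @param calib a [camera_calibration()].
#' @param floor_epsilon validity floor for the adjusted contrast.
#' @return list with `k_adj_sq` and `valid`.
#' @export
noise_corrected_contrast <- function(mu, k_raw_sq, calib,
                                     floor_epsilon = 1e-6) {
  stopifnot(inherits(calib, "camera_calibration"))
  ok <- !is.na(mu) & mu > 0 & !is.na(k_raw_sq)
  k_shot <- calib$gamma / mu
  k_quant <- if (calib$include_quantization) 1 / (12 * mu^2) else 0
  k_cam <- calib$dark_variance / mu^2
  k_adj <- k_raw_sq - k_shot - k_quant - k_cam
  valid <- ok & k_adj > floor_epsilon
  k_adj[!valid] <- NA_real_
  list(k_adj_sq = k_adj, valid = valid)
}

#' Blood flow index from adjusted contrast
#'
#' `BFI = 1 / K_adj^2`; relative flow, not a physical-unit measure.
#' Invalid (floored) contrast values propagate as `NA`.
#'
#' @param k_adj_sq noise-corrected squared contrast (vectorized).
#' @return blood flow index values.
#' @export
bfi_from_contrast <- function(k_adj_sq) {
  out <- 1 / k_adj_sq
  out[!is.na(k_adj_sq) & k_adj_sq <= 0] <- NA_real_
  out
}

#' Min-max normalize a trace to [0, 1]
#'
#' Affine, order-preserving map sending the minimum over the valid samples
#' of the measurement period to 0 and the maximum to 1.  Invalid samples are
#' excluded from the min/max and left as `NA`.
#'
#' @param trace numeric vector.
#' @param valid logical mask (defaults to non-`NA`).
#' @return normalized trace.
#' @export
normalize_trace <- function(trace, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(trace)
  valid <- valid & !is.na(trace)
  if (sum(valid) < 2) stopf("need at least 2 valid samples to normalize")
  lo <- min(trace[valid]); hi <- max(trace[valid])
  if (hi == lo) stopf("degenerate trace: max equals min")
  out <- (trace - lo) / (hi - lo)
  out[!valid] <- NA_real_
  out
}

#' Blood volume index from channel mean intensity
#'
#' Log attenuation relative to a baseline window (modified Beer-Lambert):
#' `BVI(t) = log10(I0 / mu(t))` with `I0` the mean intensity over the
#' baseline window (default the first 7 s).  The `"linear"` method uses the
#' first-order approximation `coefficient * (I0 - mu)/I0`; the first-order
#' Taylor coefficient of the log form is `1/ln(10)` (the default), a
#' coefficient of 2 is also in circulation and can be requested explicitly.
#'
#' @param mu channel mean intensity per frame, counts (offset-subtracted).
#' @param t frame times, seconds.
#' @param baseline_window_s `c(start, end)` of the baseline period.
#' @param method `"log"` or `"linear"`.
#' @param coefficient linear-method coefficient.
#' @return list with `bvi`, `i0`, `valid`.
#' @export
bvi_from_intensity <- function(mu, t, baseline_window_s = c(0, 7),
                               method = c("log", "linear"),
                               coefficient = 1 / log(10)) {
  method <- match.arg(method)
  if (length(mu) != length(t)) stopf("mu and t lengths differ")
  ok <- !is.na(mu) & mu > 0
  in_base <- ok & t >= baseline_window_s[1] & t < baseline_window_s[2]
  if (!any(in_base)) stopf("baseline window contains no valid frames")
  i0 <- mean(mu[in_base])
  bvi <- rep(NA_real_, length(mu))
  if (method == "log") {
    bvi[ok] <- log10(i0 / mu[ok])
  } else {
    bvi[ok] <- coefficient * (i0 - mu[ok]) / i0
  }
  list(bvi = bvi, i0 = i0, valid = ok)
}

#' Process a frame stack into per-channel hemodynamic series
#'
#' Runs the full per-frame chain - ensemble statistics, raw contrast,
#' noise correction, BFI, min-max normalization, BVI - for every channel of
#' the layout and returns one tidy data.frame.
#'
#' @param stack a [frame_stack()].
#' @param layout a [channel_layout()].
#' @param calib a [camera_calibration()].
#' @param floor_epsilon validity floor for the adjusted contrast.
#' @param baseline_window_s baseline window for the volume index, seconds.
#' @param bvi_method,bvi_coefficient see [bvi_from_intensity()].
#' @return data.frame with columns `channel`, `sd_distance_cm`, `t`, `mu`,
#'   `var`, `k_raw_sq`, `k_adj_sq`, `valid`, `bfi`, `nbfi`, `bvi`, `nbvi`.
#' @export
process_stack <- function(stack, layout, calib, floor_epsilon = 1e-6,
                          baseline_window_s = c(0, 7),
                          bvi_method = "log",
                          bvi_coefficient = 1 / log(10)) {
  ens <- split_channels(stack, layout)
  t <- stack_times(stack)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    rc <- raw_contrast_series(ens[[i]], offset = calib$dark_offset)
    dark_var <- if (length(calib$dark_variance) > 1)
      calib$dark_variance[i] else calib$dark_variance
    cal_i <- calib
    cal_i$dark_variance <- dark_var
    adj <- noise_corrected_contrast(rc$mu, rc$k_raw_sq, cal_i,
                                    floor_epsilon = floor_epsilon)
    bfi <- bfi_from_contrast(adj$k_adj_sq)
    nbfi <- normalize_trace(bfi, adj$valid)
    bv <- bvi_from_intensity(rc$mu, t, baseline_window_s,
                             method = bvi_method,
                             coefficient = bvi_coefficient)
    nbvi <- normalize_trace(bv$bvi, bv$valid)
    data.frame(
      channel = layout$channel[i],
      sd_distance_cm = layout$sd_distance_cm[i],
      t = t, mu = rc$mu, var = rc$var,
      k_raw_sq = rc$k_raw_sq, k_adj_sq = adj$k_adj_sq,
      valid = adj$valid, bfi = bfi, nbfi = nbfi,
      bvi = bv$bvi, nbvi = nbvi
    )
  })
  do.call(rbind, rows)
}
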