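# Synthetic two-layer (scalp/brain) speckle-camera simulator.
#
# The generator states a known world: a pulsatile scalp flow that is
# suppressed during a manual artery occlusion, an unperturbed brain flow,
# per-channel linear mixing of the two layers with depth-dependent weights,
# a speckle forward model (gamma-distributed intensity with shape 1/K^2),
# Poisson photodetection, Gaussian read noise, quantization and 16-bit
# clipping.  Every stage of the analysis pipeline can be checked against the
# closed-form ground truth this module also computes.

default_sd_grid_cm <- c(0.6, 1.0, 1.3, 1.6, 2.0, 2.3, 2.6)

# Scalp sensitivity falls off with source-detector distance following a
# logistic profile; midpoint/slope are stated once (see the methods
# vignette) and produce w_scalp ~0.91 at 0.6 cm and ~0.01 at 2.6 cm.
scalp_weight_profile <- function(sd_cm, midpoint_cm = 1.25, slope_cm = 0.28) {
  1 / (1 + exp((sd_cm - midpoint_cm) / slope_cm))
}

# Blood-volume (absorption) contrast between grey matter and scalp is weaker
# than the flow contrast (roughly 2.5x vs 6x), so the volume channel weights
# are derived from the flow weights by shrinking the brain:scalp odds.
volume_weights_from_flow <- function(scalp_flow_weight,
                                     flow_to_volume_specificity = 6 / 2.5) {
  odds_brain <- (1 - scalp_flow_weight) / scalp_flow_weight
  1 / (1 + odds_brain / flow_to_volume_specificity)
}

#' Default seven-channel configuration table
#'
#' One row per fiber channel: source-detector distance, scalp/brain mixing
#' weights for the flow and volume signals, and baseline mean signal counts.
#' Baseline counts decay exponentially with distance (decay length
#' `rho0_cm`), scaled so the farthest channel sits near, but above, the
#' camera noise floor.
#'
#' @param sd_distance_cm source-detector distances in cm (strictly
#'   increasing).
#' @param mean_counts_ch1 baseline signal counts of the closest channel.
#' @param rho0_cm exponential intensity decay length in cm.
#' @return data.frame with columns `channel`, `sd_distance_cm`,
#'   `scalp_sensitivity`, `brain_sensitivity`, `scalp_sensitivity_vol`,
#'   `brain_sensitivity_vol`, `mean_counts`.
#' @export
default_channels <- function(sd_distance_cm = default_sd_grid_cm,
                             mean_counts_ch1 = 3000,
                             rho0_cm = 0.55) {
  ws <- scalp_weight_profile(sd_distance_cm)
  wv <- volume_weights_from_flow(ws)
  data.frame(
    channel = seq_along(sd_distance_cm),
    sd_distance_cm = sd_distance_cm,
    scalp_sensitivity = ws,
    brain_sensitivity = 1 - ws,
    scalp_sensitivity_vol = wv,
    brain_sensitivity_vol = 1 - wv,
    mean_counts = mean_counts_ch1 *
      exp(-(sd_distance_cm - sd_distance_cm[1]) / rho0_cm)
  )
}

#' Camera noise parameters for the simulator
#'
#' @param read_sigma Gaussian read-noise standard deviation, counts.
#' @param dark_offset fixed dark level, counts.
#' @param conversion_factor electrons per count.
#' @param gain camera gain (dimensionless).
#' @param bit_depth ADC bit depth; counts are clipped to `[0, 2^bit_depth-1]`.
#' @param shot logical; include Poisson photodetection noise.  The shot stage
#'   can be switched off to test the speckle ensemble statistics in
#'   isolation.
#' @export
noise_params <- function(read_sigma = 2, dark_offset = 100,
                         conversion_factor = 0.46, gain = 1,
                         bit_depth = 16, shot = TRUE) {
  assert_scalar_number(read_sigma, "read_sigma", lower = 0)
  assert_scalar_number(dark_offset, "dark_offset", lower = 0)
  assert_scalar_number(conversion_factor, "conversion_factor",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(gain, "gain", lower = 0, strict_lower = TRUE)
  assert_scalar_number(bit_depth, "bit_depth", lower = 1, upper = 16)
  list(read_sigma = read_sigma, dark_offset = dark_offset,
       conversion_factor = conversion_factor, gain = gain,
       bit_depth = as.integer(bit_depth), shot = isTRUE(shot))
}

#' Synthetic cohort configuration
#'
#' States the world the simulator generates: acquisition timing, channel
#' layout, cardiac and occlusion parameters, and camera noise.  Defaults
#' reproduce the acquisition geometry of a seven-channel fiber SCOS
#' recording: 24 s at 65 frames/s with 8 ms exposure, S-D distances
#' 0.6-2.6 cm, and a manual scalp-artery occlusion from 8 to 16 s.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param seed integer cohort seed; per-subject streams are derived from it.
#' @param duration_s record duration, seconds.
#' @param frame_rate_hz camera frame rate, Hz.
#' @param exposure_s camera exposure, seconds.
#' @param channels channel table, see [default_channels()].
#' @param heart_rate_hz per-subject heart rates (scalar or length
#'   `n_subjects`); `NULL` spreads subjects evenly over 0.9-1.25 Hz.
#' @param pulsatility fractional peak-to-trough cardiac modulation of flow,
#'   in `[0, 1)`.
#' @param pulsatility_vol fractional cardiac modulation of blood volume.
#' @param occlusion_window_s `c(start, end)` seconds, or `NULL` for a control
#'   (non-occlusive) recording.
#' @param scalp_suppression factor multiplying scalp flow during occlusion.
#' @param volume_suppression factor multiplying scalp blood volume during
#'   occlusion.
#' @param beta speckle coherence factor in `(0, 1]`; the ceiling of K^2.
#' @param bvi_scale log10-attenuation per unit fractional volume change.
#' @param ramp_s raised-cosine ramp duration at each occlusion edge (manual
#'   pressure is not instantaneous).
#' @param tau_c_baseline_s speckle decorrelation time at unit composite flow;
#'   `1/tau_c` scales linearly with the composite flow index.
#' @param region_px side length of the square pixel region per channel.
#' @param noise camera noise parameters, see [noise_params()].
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20,
                         seed = 1,
                         duration_s = 24,
                         frame_rate_hz = 65,
                         exposure_s = 0.008,
                         channels = default_channels(),
                         heart_rate_hz = NULL,
                         pulsatility = 0.3,
                         pulsatility_vol = 0.08,
                         occlusion_window_s = c(8, 16),
                         scalp_suppression = 0.35,
                         volume_suppression = 0.6,
                         beta = 0.2,
                         bvi_scale = 0.15,
                         ramp_s = 0.5,
                         tau_c_baseline_s = 0.001,
                         region_px = 48,
                         noise = noise_params()) {
  assert_scalar_number(n_subjects, "n_subjects", lower = 1)
  if (!is_scalar_number(seed)) stopf("`seed` must be a single integer")
  assert_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(frame_rate_hz, "frame_rate_hz", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(exposure_s, "exposure_s", lower = 0, strict_lower = TRUE)
  assert_scalar_number(pulsatility, "pulsatility", lower = 0, upper = 1 - 1e-9)
  assert_scalar_number(pulsatility_vol, "pulsatility_vol", lower = 0,
                       upper = 1 - 1e-9)
  assert_scalar_number(scalp_suppression, "scalp_suppression", lower = 0,
                       upper = 1)
  assert_scalar_number(volume_suppression, "volume_suppression", lower = 0,
                       upper = 1)
  assert_scalar_number(beta, "beta", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(ramp_s, "ramp_s", lower = 0)
  assert_scalar_number(tau_c_baseline_s, "tau_c_baseline_s", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(region_px, "region_px", lower = 2)

  needed <- c("channel", "sd_distance_cm", "scalp_sensitivity",
              "brain_sensitivity", "mean_counts")
  if (!all(needed %in% names(channels)))
    stopf("`channels` is missing columns: %s",
          paste(setdiff(needed, names(channels)), collapse = ", "))
  if (is.unsorted(channels$sd_distance_cm, strictly = TRUE))
    stopf("sd_distance_cm must be strictly increasing with channel")
  rownames(channels) <- NULL
  if (is.null(channels$scalp_sensitivity_vol)) {
    channels$scalp_sensitivity_vol <-
      volume_weights_from_flow(channels$scalp_sensitivity)
    channels$brain_sensitivity_vol <- 1 - channels$scalp_sensitivity_vol
  }
  mix_sum <- channels$scalp_sensitivity + channels$brain_sensitivity
  if (any(abs(mix_sum - 1) > 1e-8)) {
    warnf("scalp + brain sensitivities renormalized to 1")
    channels$scalp_sensitivity <- channels$scalp_sensitivity / mix_sum
    channels$brain_sensitivity <- channels$brain_sensitivity / mix_sum
  }
  if (is.unsorted(rev(channels$scalp_sensitivity), strictly = TRUE))
    warnf("scalp_sensitivity is not strictly decreasing with distance")
  if (is.unsorted(channels$brain_sensitivity))
    warnf("brain_sensitivity is not non-decreasing with distance")

  if (!is.null(occlusion_window_s)) {
    if (length(occlusion_window_s) != 2 ||
        occlusion_window_s[1] >= occlusion_window_s[2])
      stopf("occlusion_window_s must be c(start, end) with start < end")
    if (occlusion_window_s[1] < 0 || occlusion_window_s[2] > duration_s)
      stopf("occlusion window [%g, %g] must lie inside [0, %g]",
            occlusion_window_s[1], occlusion_window_s[2], duration_s)
  }
  if (!is.null(heart_rate_hz)) {
    if (!length(heart_rate_hz) %in% c(1L, as.integer(n_subjects)))
      stopf("heart_rate_hz must be scalar or length n_subjects")
    if (any(heart_rate_hz <= 0)) stopf("heart rates must be positive")
  }

  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    duration_s = duration_s, frame_rate_hz = frame_rate_hz,
    exposure_s = exposure_s, channels = channels,
    heart_rate_hz = heart_rate_hz, pulsatility = pulsatility,
    pulsatility_vol = pulsatility_vol,
    occlusion_window_s = occlusion_window_s,
    scalp_suppression = scalp_suppression,
    volume_suppression = volume_suppression,
    beta = beta, bvi_scale = bvi_scale, ramp_s = ramp_s,
    tau_c_baseline_s = tau_c_baseline_s,
    region_px = as.integer(region_px), noise = noise
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "synthetic SCOS cohort: %d subject(s), %g s at %g fps, %d channels\n",
    x$n_subjects, x$duration_s, x$frame_rate_hz, nrow(x$channels)))
  if (is.null(x$occlusion_window_s)) {
    cat("  control recording (no occlusion)\n")
  } else {
    cat(sprintf("  occlusion %g-%g s, scalp flow x%g, scalp volume x%g\n",
                x$occlusion_window_s[1], x$occlusion_window_s[2],
                x$scalp_suppression, x$volume_suppression))
  }
  invisible(x)
}

config_time_grid <- function(config) {
  n <- round(config$duration_s * config$frame_rate_hz)
  (seq_len(n) - 1) / config$frame_rate_hz
}

subject_heart_rate <- function(config, subject_index) {
  hr <- config$heart_rate_hz
  if (!is.null(hr)) {
    if (length(hr) == 1L) return(hr)
    return(hr[subject_index])
  }
  n <- config$n_subjects
  if (n == 1L) return(1.0)
  seq(0.9, 1.25, length.out = n)[subject_index]
}

#' Unit-mean pulsatile cardiac waveform
#'
#' Two Gaussian bumps per period (systolic peak plus a dicrotic bump),
#' wrapped periodically, shifted to zero mean and scaled to unit
#' peak-to-trough span, so the returned waveform has mean 1 over any integer
#' number of cycles and peak-to-trough span exactly equal to `pulsatility`.
#' The default widths keep the spectral fundamental well above the second
#' harmonic (3-4x in power), as in physiological pulse waveforms, so an
#' FFT peak picker recovers the heart rate rather than a harmonic.
#'
#' @param heart_rate_hz heart rate in Hz (> 0).
#' @param pulsatility fractional peak-to-trough span in `[0, 1)`.
#' @param t_grid sample times, seconds.
#' @param systolic_phase,systolic_width,dicrotic_phase,dicrotic_width,dicrotic_amp
#'   shape parameters as fractions of the cycle.
#' @return numeric vector, same length as `t_grid`.
#' @export
cardiac_waveform <- function(heart_rate_hz, pulsatility, t_grid,
                             systolic_phase = 0.18, systolic_width = 0.12,
                             dicrotic_phase = 0.55, dicrotic_width = 0.12,
                             dicrotic_amp = 0.25) {
  if (!is_scalar_number(heart_rate_hz) || heart_rate_hz <= 0)
    stopf("heart_rate_hz must be a positive number")
  assert_scalar_number(pulsatility, "pulsatility", lower = 0,
                       upper = 1 - 1e-12)
  shape <- function(phase) {
    out <- 0
    for (k in -1:1) {  # wrapped copies; widths << 1 so k in -1..1 suffices
      out <- out +
        exp(-0.5 * ((phase - systolic_phase - k) / systolic_width)^2) +
        dicrotic_amp *
          exp(-0.5 * ((phase - dicrotic_phase - k) / dicrotic_width)^2)
    }
    out
  }
  dense <- shape((seq_len(4096) - 0.5) / 4096)
  m <- mean(dense)
  span <- max(dense) - min(dense)
  s <- (shape(t_grid * heart_rate_hz - floor(t_grid * heart_rate_hz)) - m) /
    span
  1 + pulsatility * s
}

# Raised-cosine occlusion window: 0 outside [start, end], smooth 0->1 ramps
# of duration ramp_s at both edges, 1 in the fully-occluded core.  With
# ramp_s = 0 the window degenerates to a right-continuous step on
# [start, end), matching the half-open segment convention.
occlusion_ramp <- function(t, window, ramp_s) {
  if (is.null(window)) return(numeric(length(t)))
  r <- min(ramp_s, diff(window) / 2)
  if (r <= 0) return(as.numeric(t >= window[1] & t < window[2]))
  up <- pmin(pmax((t - window[1]) / r, 0), 1)
  down <- pmin(pmax((window[2] - t) / r, 0), 1)
  smooth <- function(u) 0.5 - 0.5 * cos(pi * u)
  smooth(up) * smooth(down)
}

#' Scalp and brain layer traces for one subject
#'
#' Both layers share the subject's cardiac waveform.  The occlusion window
#' multiplies the scalp flow by `scalp_suppression` (and scalp volume by
#' `volume_suppression`) with raised-cosine ramps at the edges; the brain
#' traces are untouched, reflecting that a superficial-temporal-artery
#' occlusion blocks scalp supply only.
#'
#' @param config a [synth_config()].
#' @param subject_index subject number in `1:n_subjects`.
#' @return list with `t`, `hr_hz`, flow traces `scalp`, `brain`, and volume
#'   traces `scalp_vol`, `brain_vol`.
#' @export
simulate_layer_flows <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  t <- config_time_grid(config)
  hr <- subject_heart_rate(config, subject_index)
  card <- cardiac_waveform(hr, config$pulsatility, t)
  card_v <- cardiac_waveform(hr, config$pulsatility_vol, t)
  ramp <- occlusion_ramp(t, config$occlusion_window_s, config$ramp_s)
  list(
    t = t, hr_hz = hr,
    scalp = card * (1 - (1 - config$scalp_suppression) * ramp),
    brain = card,
    scalp_vol = card_v * (1 - (1 - config$volume_suppression) * ramp),
    brain_vol = card_v
  )
}

#' Mix layer traces into per-channel composites
#'
#' Linear two-compartment mixing: `composite(ch, t) = w_scalp(ch) * scalp(t)
#' + w_brain(ch) * brain(t)`.  For the flow signal the decorrelation rate is
#' proportional to the composite: `1/tau_c = composite / tau_c_baseline_s`.
#'
#' @param config a [synth_config()].
#' @param scalp,brain layer traces.
#' @param kind `"flow"` (uses flow sensitivities, returns `inv_tau_c`) or
#'   `"volume"` (uses volume sensitivities).
#' @return list with `composite` (time x channel matrix) and, for flow,
#'   `inv_tau_c`.
#' @export
mix_channels <- function(config, scalp, brain, kind = c("flow", "volume")) {
  stopifnot(inherits(config, "synth_config"))
  kind <- match.arg(kind)
  ch <- config$channels
  if (kind == "flow") {
    ws <- ch$scalp_sensitivity
  } else {
    ws <- ch$scalp_sensitivity_vol
  }
  composite <- outer(scalp, ws) + outer(brain, 1 - ws)
  colnames(composite) <- paste0("ch", ch$channel)
  out <- list(composite = composite)
  if (kind == "flow") out$inv_tau_c <- composite / config$tau_c_baseline_s
  out
}

#' Squared speckle contrast of a time-integrated speckle field
#'
#' The integrated speckle visibility function: with `x = exposure / tau_c`,
#' `K^2 = beta * (exp(-2x) - 1 + 2x) / (2 x^2)`, which tends to `beta` for a
#' static field (x -> 0) and falls off as `beta/x` when the exposure is much
#' longer than the decorrelation time.
#'
#' @param exposure_s camera exposure, seconds.
#' @param tau_c_s speckle decorrelation time, seconds (vectorized).
#' @param beta coherence factor in `(0, 1]`.
#' @return K^2 values, same length as `tau_c_s`.
#' @export
speckle_visibility <- function(exposure_s, tau_c_s, beta) {
  assert_scalar_number(exposure_s, "exposure_s", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(beta, "beta", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (any(tau_c_s <= 0)) stopf("tau_c_s must be positive")
  x <- exposure_s / tau_c_s
  k2 <- ifelse(x < 1e-4,
               1 - 2 * x / 3 + x^2 / 3,          # series, avoids 0/0
               (exp(-2 * x) - 1 + 2 * x) / (2 * x^2))
  beta * k2
}

# Ground truth for one subject: K_true^2(t), bfi_true(t) (composite flow,
# arbitrary units) and bvi_true(t) (log10 attenuation) per channel.
subject_truth <- function(config, subject_index) {
  flows <- simulate_layer_flows(config, subject_index)
  fl <- mix_channels(config, flows$scalp, flows$brain, "flow")
  vol <- mix_channels(config, flows$scalp_vol, flows$brain_vol, "volume")
  k2 <- apply(fl$inv_tau_c, 2, function(rate)
    speckle_visibility(config$exposure_s, 1 / rate, config$beta))
  list(
    t = flows$t, hr_hz = flows$hr_hz,
    k_true_sq = k2,
    bfi_true = fl$composite,
    bvi_true = config$bvi_scale * (vol$composite - 1),
    channels = config$channels
  )
}

synth_frame_dims <- function(config) {
  c(config$region_px, config$region_px * nrow(config$channels))
}

#' Channel layout matching the simulator's frame geometry
#'
#' Square `region_px` x `region_px` regions tiled left to right in channel
#' order, covering the whole frame.
#'
#' @param config a [synth_config()].
#' @return a [channel_layout()].
#' @export
synth_layout <- function(config) {
  p <- config$region_px
  ch <- config$channels
  channel_layout(data.frame(
    channel = ch$channel,
    sd_distance_cm = ch$sd_distance_cm,
    row0 = 0L, row1 = p,
    col0 = p * (seq_len(nrow(ch)) - 1L), col1 = p * seq_len(nrow(ch))
  ))
}

#' Synthesize a multi-channel speckle frame stack for one subject
#'
#' Per frame and channel, pixel intensities are drawn from a gamma
#' distribution with shape `1/K_true^2(t)` and mean equal to the expected
#' photoelectron count; photodetection adds Poisson noise (unless
#' `noise$shot` is off); electrons are converted to counts with
#' `gain/conversion_factor`, the dark offset and Gaussian read noise are
#' added, and the result is rounded and clipped to the ADC range.  The mean
#' photoelectron level decays exponentially with source-detector distance
#' (through `channels$mean_counts`) and is modulated by the true volume
#' signal as `mu_e(t) = mu_e0 * 10^(-bvi_true(t))`.
#'
#' @param config a [synth_config()].
#' @param subject_index subject number; fixes the RNG stream.
#' @return list with `stack` (a [frame_stack()]), `truth` (ground-truth
#'   traces: `t`, `hr_hz`, `k_true_sq`, `bfi_true`, `bvi_true`) and
#'   `layout`.
#' @export
synthesize_frames <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (!is_scalar_number(subject_index) ||
      subject_index < 1 || subject_index > config$n_subjects)
    stopf("subject_index must be in 1..n_subjects")
  truth <- subject_truth(config, subject_index)
  nz <- config$noise
  p <- config$region_px
  npx <- p * p
  n_t <- length(truth$t)
  dims <- synth_frame_dims(config)
  maxval <- 2^nz$bit_depth - 1

  set.seed(subject_seed(config$seed, subject_index))
  frames <- array(0L, dim = c(n_t, dims[1], dims[2]))
  n_sat <- 0
  for (ci in seq_len(nrow(config$channels))) {
    mu_counts <- config$channels$mean_counts[ci] * 10^(-truth$bvi_true[, ci])
    mu_e <- mu_counts * nz$conversion_factor / nz$gain
    k2 <- truth$k_true_sq[, ci]
    shape <- rep(1 / k2, each = npx)
    intensity <- rgamma(npx * n_t, shape = shape,
                        scale = rep(mu_e * k2, each = npx))
    electrons <- if (nz$shot) rpois(npx * n_t, intensity) else intensity
    counts <- electrons * nz$gain / nz$conversion_factor + nz$dark_offset
    if (nz$read_sigma > 0)
      counts <- counts + rnorm(npx * n_t, sd = nz$read_sigma)
    counts <- pmin(pmax(round(counts), 0), maxval)
    n_sat <- n_sat + sum(counts >= maxval)
    frames[, , (p * (ci - 1) + 1):(p * ci)] <-
      aperm(array(as.integer(counts), dim = c(p, p, n_t)), c(3, 1, 2))
  }
  if (n_sat > 0.01 * length(frames))
    warnf("saturation: %.1f%% of pixels at the ADC ceiling",
          100 * n_sat / length(frames))
  list(
    stack = frame_stack(frames, config$frame_rate_hz, config$exposure_s,
                        nz$bit_depth),
    truth = truth,
    layout = synth_layout(config)
  )
}

#' Synthesize dark (shutter-closed) frames
#'
#' Frames contain only the dark offset plus Gaussian read noise, quantized
#' and clipped; no signal component.
#'
#' @param noise camera noise parameters, see [noise_params()].
#' @param n_frames number of frames (>= 2).
#' @param dims frame dimensions `c(rows, cols)`.
#' @param seed RNG seed.
#' @param frame_rate_hz,exposure_s acquisition metadata for the stack.
#' @return a [frame_stack()].
#' @export
synthesize_dark_frames <- function(noise, n_frames, dims = c(48, 336),
                                   seed = 1, frame_rate_hz = 65,
                                   exposure_s = 0.008) {
  if (!is_scalar_number(n_frames) || n_frames < 2)
    stopf("need at least 2 dark frames")
  set.seed(as.integer(seed))
  n <- n_frames * dims[1] * dims[2]
  counts <- rep(noise$dark_offset, n)
  if (noise$read_sigma > 0) counts <- counts + rnorm(n, sd = noise$read_sigma)
  counts <- pmin(pmax(round(counts), 0), 2^noise$bit_depth - 1)
  frame_stack(array(as.integer(counts), dim = c(n_frames, dims[1], dims[2])),
              frame_rate_hz, exposure_s, noise$bit_depth)
}

#' Synthesize flat-illumination frames (shot + read noise, no speckle)
#'
#' A null stack for the noise-correction pipeline: constant illumination at
#' `mean_counts` signal counts with Poisson photodetection, dark offset,
#' read noise and quantization.  The noise-corrected contrast of such a
#' stack should be statistically indistinguishable from zero.
#'
#' @inheritParams synthesize_dark_frames
#' @param mean_counts mean signal level, counts (offset excluded).
#' @return a [frame_stack()].
#' @export
synthesize_flat_frames <- function(mean_counts, noise, n_frames,
                                   dims = c(48, 48), seed = 1,
                                   frame_rate_hz = 65, exposure_s = 0.008) {
  assert_scalar_number(mean_counts, "mean_counts", lower = 0,
                       strict_lower = TRUE)
  if (!is_scalar_number(n_frames) || n_frames < 1)
    stopf("n_frames must be >= 1")
  set.seed(as.integer(seed))
  n <- n_frames * dims[1] * dims[2]
  mu_e <- mean_counts * noise$conversion_factor / noise$gain
  electrons <- rpois(n, mu_e)
  counts <- electrons * noise$gain / noise$conversion_factor +
    noise$dark_offset
  if (noise$read_sigma > 0) counts <- counts + rnorm(n, sd = noise$read_sigma)
  counts <- pmin(pmax(round(counts), 0), 2^noise$bit_depth - 1)
  frame_stack(array(as.integer(counts), dim = c(n_frames, dims[1], dims[2])),
              frame_rate_hz, exposure_s, noise$bit_depth)
}

#' Noiseless per-channel series from the generator's ground truth
#'
#' The high-SNR limit of the pipeline: per-channel BFI/BVI traces computed
#' directly from the forward model (no speckle sampling, no camera noise),
#' in the same tidy layout as [process_stack()] output.  Useful for testing
#' the segmentation and waveform machinery in isolation from finite-pixel
#' estimator noise.
#'
#' @param config a [synth_config()].
#' @param subject_index subject number.
#' @return data.frame with columns `channel`, `sd_distance_cm`, `t`, `mu`,
#'   `k_adj_sq`, `valid`, `bfi`, `nbfi`, `bvi`, `nbvi`.
#' @export
truth_series <- function(config, subject_index = 1L) {
  truth <- subject_truth(config, subject_index)
  ch <- config$channels
  do.call(rbind, lapply(seq_len(nrow(ch)), function(ci) {
    bfi <- 1 / truth$k_true_sq[, ci]
    bvi <- truth$bvi_true[, ci]
    data.frame(
      channel = ch$channel[ci], sd_distance_cm = ch$sd_distance_cm[ci],
      t = truth$t,
      mu = ch$mean_counts[ci] * 10^(-bvi),
      k_adj_sq = truth$k_true_sq[, ci],
      valid = TRUE,
      bfi = bfi, nbfi = normalize_trace(bfi),
      bvi = bvi, nbvi = normalize_trace(bvi)
    )
  }))
}

#' Closed-form expected segment ratios of the generator
#'
#' Independent oracle for the occlusion analysis: integrates the generator's
#' composite formulas directly (no speckle sampling, no camera noise) over
#' the three segments and returns the expected during/pre (`ratio_mean_ba`)
#' and post/pre (`ratio_mean_ca`) ratios per channel.
#'
#' `metric = "flow"` integrates the composite flow itself; `"bfi"` maps the
#' flow through the exact visibility function to the blood flow index
#' `1/K_true^2` first (the quantity the pipeline actually estimates, affine
#' but not proportional to flow at finite exposure-to-decorrelation ratio);
#' `"nbfi"` additionally applies the min-max normalization used in the
#' reported ratio curves.  Control configurations (no occlusion window) have
#' expected ratios identically 1.
#'
#' @param config a [synth_config()].
#' @param subject_index subject (heart rate) used for the cardiac
#'   modulation.
#' @param metric `"bfi"` (default), `"flow"` or `"nbfi"`.
#' @param seg segment definition; defaults to the occlusion window.
#' @return data.frame with `channel`, `sd_distance_cm`, `ratio_mean_ba`,
#'   `ratio_mean_ca`.
#' @export
expected_segment_ratios <- function(config, subject_index = 1L,
                                    metric = c("bfi", "flow", "nbfi"),
                                    seg = NULL) {
  stopifnot(inherits(config, "synth_config"))
  metric <- match.arg(metric)
  ch <- config$channels
  if (is.null(config$occlusion_window_s)) {
    return(data.frame(channel = ch$channel,
                      sd_distance_cm = ch$sd_distance_cm,
                      ratio_mean_ba = 1, ratio_mean_ca = 1))
  }
  if (is.null(seg))
    seg <- segment_definition(0, config$occlusion_window_s[1],
                              config$occlusion_window_s[2],
                              config$duration_s)
  truth <- subject_truth(config, subject_index)
  trace <- switch(metric,
                  flow = truth$bfi_true,
                  bfi = 1 / truth$k_true_sq,
                  nbfi = apply(1 / truth$k_true_sq, 2, function(x)
                    (x - min(x)) / (max(x) - min(x))))
  ia <- truth$t >= seg$start_s & truth$t < seg$occl_start_s
  ib <- truth$t >= seg$occl_start_s & truth$t < seg$occl_end_s
  ic <- truth$t >= seg$occl_end_s & truth$t <= seg$end_s
  data.frame(
    channel = ch$channel,
    sd_distance_cm = ch$sd_distance_cm,
    ratio_mean_ba = colMeans(trace[ib, , drop = FALSE]) /
      colMeans(trace[ia, , drop = FALSE]),
    ratio_mean_ca = colMeans(trace[ic, , drop = FALSE]) /
      colMeans(trace[ia, , drop = FALSE])
  )
}
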