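# Spectral and beat-level analytics: FFT heart-rate extraction, a
# frequency-domain SNR with the 10 dB usability threshold, beat detection on
# a band-passed trace, phase-normalized beat averaging, and peak-to-trough
# amplitude ratios across the occlusion segments.

#' One-sided power spectral density of a (possibly gappy) trace
#'
#' Invalid samples are filled by linear interpolation (their fraction is
#' reported), the mean is removed, and the one-sided periodogram
#' `P(f) = 2 |FFT|^2 / (fs N)` is returned on the grid `f = k fs / N`.
#'
#' @param x trace values.
#' @param frame_rate_hz sampling rate, Hz.
#' @param valid logical mask (defaults to non-`NA`).
#' @return object of class `scos_psd`: list with `freq`, `power`, `df`,
#'   `interpolated_fraction`.
#' @export
power_spectrum <- function(x, frame_rate_hz, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(x)
  valid <- valid & !is.na(x)
  n <- length(x)
  if (sum(valid) < 64)
    stopf("need at least 64 valid samples for a spectrum (got %d)",
          sum(valid))
  if (!all(valid)) {
    idx <- seq_len(n)
    x <- stats::approx(idx[valid], x[valid], xout = idx, rule = 2)$y
  }
  x <- x - mean(x)
  nf <- floor(n / 2)
  p <- (2 / (frame_rate_hz * n)) * Mod(stats::fft(x)[2:(nf + 1)])^2
  structure(list(freq = (1:nf) * frame_rate_hz / n, power = p,
                 df = frame_rate_hz / n,
                 interpolated_fraction = 1 - mean(valid)),
            class = "scos_psd")
}

#' Heart rate from the spectral peak
#'
#' Frequency of maximum power inside the search band (default 0.7-3 Hz,
#' covering resting adult rates with margin); ties break toward the lower
#' frequency.
#'
#' @param psd a [power_spectrum()].
#' @param band_hz search band `c(lo, hi)`, Hz.
#' @return heart rate in Hz.
#' @export
estimate_heart_rate <- function(psd, band_hz = c(0.7, 3.0)) {
  stopifnot(inherits(psd, "scos_psd"))
  in_band <- psd$freq >= band_hz[1] & psd$freq <= band_hz[2]
  if (!any(in_band)) stopf("no spectral bins inside the search band")
  p <- psd$power[in_band]
  if (all(p <= 0)) stopf("no in-band spectral power")
  psd$freq[in_band][which.max(p)]
}

#' Frequency-domain SNR of a pulsatile trace, in dB
#'
#' `10 log10(P_signal / P_noise)`: the signal power is the total power
#' within `signal_halfwidth_hz` of the cardiac peak; the noise floor is the
#' median PSD level over `noise_band_hz`, rescaled to the mean of an
#' exponentially-distributed periodogram (divided by `ln 2`) and scaled to
#' the signal bandwidth, so white noise scores ~0 dB.
#'
#' @param psd a [power_spectrum()].
#' @param heart_rate_hz cardiac peak frequency, Hz.
#' @param signal_halfwidth_hz half-width of the signal band (default 0.2).
#' @param noise_band_hz band used for the noise floor (default 3-10 Hz).
#' @return SNR in decibels.
#' @export
snr_db <- function(psd, heart_rate_hz, signal_halfwidth_hz = 0.2,
                   noise_band_hz = c(3, 10)) {
  stopifnot(inherits(psd, "scos_psd"))
  sig <- abs(psd$freq - heart_rate_hz) <= signal_halfwidth_hz
  noi <- psd$freq >= noise_band_hz[1] & psd$freq <= noise_band_hz[2]
  if (!any(sig)) stopf("no spectral bins in the signal band")
  if (!any(noi)) stopf("no spectral bins in the noise band")
  floor_level <- stats::median(psd$power[noi]) / log(2)
  if (floor_level <= 0)
    stopf("zero noise floor: SNR undefined for a noiseless trace")
  10 * log10(sum(psd$power[sig]) / (floor_level * sum(sig)))
}

# Zero-phase band-pass by zeroing FFT bins outside [lo, hi] Hz.
bandpass_fft <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  spec <- stats::fft(x - mean(x))
  spec[f < lo | f > hi] <- 0
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Detect cardiac beats in a pulsatile trace
#'
#' The trace is band-passed around the heart rate (`[0.5, 3] x HR`); beats
#' are local maxima separated by at least `min_separation_frac / HR`
#' seconds, and each beat's onset is the local minimum preceding its peak.
#'
#' @param x trace values (invalid samples interpolated).
#' @param t sample times, seconds.
#' @param heart_rate_hz heart rate, Hz.
#' @param min_separation_frac minimum peak separation as a fraction of the
#'   cardiac period (default 0.6).
#' @return list with `peaks_t`, `onsets_t`, `n_beats`,
#'   `rejected_fraction`.
#' @export
detect_beats <- function(x, t, heart_rate_hz, min_separation_frac = 0.6) {
  if (!is_scalar_number(heart_rate_hz) || heart_rate_hz <= 0)
    stopf("heart_rate_hz must be positive")
  n <- length(x)
  if (n < 8 || n != length(t)) stopf("x and t must be equal-length, n >= 8")
  if (anyNA(x)) {
    ok <- !is.na(x)
    x <- stats::approx(t[ok], x[ok], xout = t, rule = 2)$y
  }
  fs <- 1 / stats::median(diff(t))
  b <- bandpass_fft(x, fs, 0.5 * heart_rate_hz,
                    min(3 * heart_rate_hz, 0.49 * fs))
  d <- diff(sign(diff(b)))
  cand <- which(d == -2) + 1L
  if (length(cand) == 0)
    return(list(peaks_t = numeric(0), onsets_t = numeric(0), n_beats = 0L,
                rejected_fraction = 0))
  min_sep <- min_separation_frac / heart_rate_hz
  cand <- cand[order(b[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) || all(abs(t[i] - t[accepted]) >= min_sep))
      accepted <- c(accepted, i)
  }
  n_rejected <- length(cand) - length(accepted)
  peaks <- sort(accepted)
  # a first peak closer than one period to the record start has no reliable
  # preceding minimum: drop it rather than emit a phase-misaligned beat
  if (length(peaks) &&
      peaks[1] - round(fs / heart_rate_hz) < 1)
    peaks <- peaks[-1]
  if (!length(peaks))
    return(list(peaks_t = numeric(0), onsets_t = numeric(0), n_beats = 0L,
                rejected_fraction = 0))
  onsets <- vapply(seq_along(peaks), function(k) {
    lo <- if (k == 1) peaks[k] - as.integer(round(fs / heart_rate_hz))
          else peaks[k - 1]
    seg <- lo:peaks[k]
    seg[which.min(b[seg])]
  }, 1L)
  list(peaks_t = t[peaks], onsets_t = t[onsets],
       n_beats = length(peaks),
       rejected_fraction = n_rejected / length(cand))
}

#' Beat-averaged cardiac waveform
#'
#' Each beat (the interval between consecutive onsets, duration-gated to
#' `[0.5, 1.5]` cardiac periods when a heart rate is supplied) is resampled
#' onto a common phase grid and averaged.  The average is then
#' harmonic-limited: only the first `n_harmonics` Fourier components of the
#' phase waveform are kept, which suppresses residual measurement noise
#' without distorting physiological morphology (pulse waveforms carry
#' little power beyond ~10 harmonics).  The waveform amplitude `I` is the
#' peak-to-trough span of the smoothed average.
#'
#' @param x trace values.
#' @param t sample times, seconds.
#' @param onsets_t beat onset times from [detect_beats()].
#' @param n_phase_bins phase-grid resolution (default 100).
#' @param min_beats minimum number of complete beats (default 3).
#' @param heart_rate_hz optional heart rate for duration gating.
#' @param n_harmonics harmonics retained in the averaged waveform; `Inf`
#'   disables smoothing.
#' @return object of class `cardiac_waveform`: list with `phase`, `value`,
#'   `n_beats`, `amplitude`.  `NULL` if fewer than `min_beats` beats
#'   survive.
#' @export
average_waveform <- function(x, t, onsets_t, n_phase_bins = 100,
                             min_beats = 3, heart_rate_hz = NULL,
                             n_harmonics = 10) {
  if (length(onsets_t) < 2) return(NULL)
  if (anyNA(x)) {
    ok <- !is.na(x)
    x <- stats::approx(t[ok], x[ok], xout = t, rule = 2)$y
  }
  phase <- (seq_len(n_phase_bins) - 0.5) / n_phase_bins
  beats <- list()
  for (k in seq_len(length(onsets_t) - 1)) {
    t0 <- onsets_t[k]; t1 <- onsets_t[k + 1]
    if (!is.null(heart_rate_hz)) {
      dur <- t1 - t0
      if (dur < 0.5 / heart_rate_hz || dur > 1.5 / heart_rate_hz) next
    }
    beats[[length(beats) + 1]] <-
      stats::approx(t, x, xout = t0 + phase * (t1 - t0), rule = 2)$y
  }
  if (length(beats) < min_beats) return(NULL)
  avg <- Reduce(`+`, beats) / length(beats)
  if (is.finite(n_harmonics) && n_harmonics < floor(n_phase_bins / 2)) {
    spec <- stats::fft(avg)
    k <- c(0, seq_len(n_phase_bins - 1))
    k <- pmin(k, n_phase_bins - k)
    spec[k > n_harmonics] <- 0
    avg <- Re(stats::fft(spec, inverse = TRUE)) / n_phase_bins
  }
  structure(list(phase = phase, value = avg, n_beats = length(beats),
                 amplitude = max(avg) - min(avg)),
            class = "cardiac_waveform")
}

#' @export
print.cardiac_waveform <- function(x, ...) {
  cat(sprintf("cardiac_waveform: %d beats averaged, amplitude %.4g\n",
              x$n_beats, x$amplitude))
  invisible(x)
}

#' Per-segment beat-averaged waveform amplitudes for one channel trace
#'
#' Estimates the heart rate from the full trace (unless supplied), detects
#' beats once on the full record - avoiding band-pass edge artifacts on
#' short windows - assigns each complete beat to the segment containing it,
#' and returns the averaged-waveform amplitude `I` for segments a, b, c.
#'
#' @param t sample times, seconds.
#' @param x trace values (typically `nbfi` or `nbvi`).
#' @param seg a [segment_definition()].
#' @param frame_rate_hz sampling rate, Hz.
#' @param heart_rate_hz optional known heart rate.
#' @param n_phase_bins,min_beats see [average_waveform()].
#' @return list with `heart_rate_hz`, `amplitudes` (named numeric for a, b,
#'   c; `NA` where a waveform could not be formed) and `waveforms`.
#' @export
segment_waveform_metrics <- function(t, x, seg, frame_rate_hz,
                                     heart_rate_hz = NULL,
                                     n_phase_bins = 100, min_beats = 3) {
  if (is.null(heart_rate_hz)) {
    psd <- power_spectrum(x, frame_rate_hz)
    heart_rate_hz <- estimate_heart_rate(psd)
  }
  beats <- detect_beats(x, t, heart_rate_hz)
  onsets <- beats$onsets_t
  bounds <- list(a = c(seg$start_s, seg$occl_start_s),
                 b = c(seg$occl_start_s, seg$occl_end_s),
                 c = c(seg$occl_end_s, seg$end_s + 1e-9))
  amps <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  wfs <- list()
  for (s in names(bounds)) {
    # a beat belongs to a segment when both its onsets fall inside it
    keep <- onsets >= bounds[[s]][1] & onsets < bounds[[s]][2]
    runs <- which(keep[-length(keep)] & keep[-1])
    if (!length(runs)) next
    seg_onsets <- onsets[sort(unique(c(runs, runs + 1L)))]
    wf <- average_waveform(x, t, seg_onsets,
                           n_phase_bins = n_phase_bins,
                           min_beats = min_beats,
                           heart_rate_hz = heart_rate_hz)
    if (!is.null(wf)) {
      amps[s] <- wf$amplitude
      wfs[[s]] <- wf
    }
  }
  list(heart_rate_hz = heart_rate_hz, amplitudes = amps, waveforms = wfs)
}

#' Waveform amplitude-ratio curves for flow and volume
#'
#' For every subject, channel and metric (`nbfi` for flow, `nbvi` for
#' volume) this computes the per-segment beat-averaged waveform amplitudes
#' and their during/pre (`ratio_amp_ba`) and post/pre (`ratio_amp_ca`)
#' ratios; channels without a valid waveform are omitted with a warning at
#' aggregation time.
#'
#' @param series_by_subject list of tidy series data.frames (one per
#'   subject) as returned by [process_stack()].
#' @param seg a [segment_definition()].
#' @param frame_rate_hz sampling rate, Hz.
#' @param metrics trace columns to analyse.
#' @param heart_rates_hz optional per-subject heart rates.
#' @return data.frame with one row per subject x channel x metric:
#'   amplitudes `amp_a`, `amp_b`, `amp_c` and the two ratios.
#' @export
amplitude_ratio_curve <- function(series_by_subject, seg, frame_rate_hz,
                                  metrics = c("nbfi", "nbvi"),
                                  heart_rates_hz = NULL) {
  rows <- list()
  for (si in seq_along(series_by_subject)) {
    series <- series_by_subject[[si]]
    hr <- if (is.null(heart_rates_hz)) NULL else heart_rates_hz[si]
    for (ch in unique(series$channel)) {
      s <- series[series$channel == ch, ]
      for (m in metrics) {
        wm <- tryCatch(
          segment_waveform_metrics(s$t, s[[m]], seg, frame_rate_hz,
                                   heart_rate_hz = hr),
          error = function(e) NULL)
        if (is.null(wm)) next
        a <- wm$amplitudes
        rows[[length(rows) + 1]] <- data.frame(
          subject = si, channel = ch,
          sd_distance_cm = s$sd_distance_cm[1], metric = m,
          heart_rate_hz = wm$heart_rate_hz,
          amp_a = a["a"], amp_b = a["b"], amp_c = a["c"],
          ratio_amp_ba = if (!is.na(a["a"]) && a["a"] > 0)
            a["b"] / a["a"] else NA_real_,
          ratio_amp_ca = if (!is.na(a["a"]) && a["a"] > 0)
            a["c"] / a["a"] else NA_real_,
          row.names = NULL
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate amplitude-ratio curves across subjects
#'
#' @param amp output of [amplitude_ratio_curve()].
#' @param exclude optional data.frame (`subject`, `channel`) of
#'   subject-channels to drop (e.g. below the SNR threshold).
#' @return data.frame per channel x metric with group means and
#'   across-subject standard deviations of the two ratios.
#' @export
aggregate_amplitude_ratios <- function(amp, exclude = NULL) {
  out <- list()
  for (m in unique(amp$metric)) {
    for (ch in sort(unique(amp$channel))) {
      r <- amp[amp$metric == m & amp$channel == ch, ]
      if (!is.null(exclude)) {
        drop <- exclude$subject[exclude$channel == ch]
        r <- r[!r$subject %in% drop, ]
      }
      r <- r[!is.na(r$ratio_amp_ba), ]
      if (nrow(r) == 0) {
        warnf("channel %s (%s): no valid waveforms, omitted", ch, m)
        next
      }
      out[[length(out) + 1]] <- data.frame(
        metric = m, channel = ch, sd_distance_cm = r$sd_distance_cm[1],
        n_subjects_used = nrow(r),
        ratio_amp_ba_mean = mean(r$ratio_amp_ba),
        ratio_amp_ba_sd = if (nrow(r) >= 2) sd(r$ratio_amp_ba) else 0,
        ratio_amp_ca_mean = mean(r$ratio_amp_ca, na.rm = TRUE),
        ratio_amp_ca_sd = if (sum(!is.na(r$ratio_amp_ca)) >= 2)
          sd(r$ratio_amp_ca, na.rm = TRUE) else 0
      )
    }
  }
  do.call(rbind, out)
}
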