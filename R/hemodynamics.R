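# Occlusion-segmented statistics: per-segment means and standard deviations
# of the normalized flow index, their during/pre and post/pre ratios per
# channel, aggregation across subjects, and the source-detector distance at
# which the occlusion curve converges to the control curve.

#' Segment definition around an occlusion window
#'
#' Three half-open segments: pre-occlusion `a = [start, occl_start)`, during
#' occlusion `b = [occl_start, occl_end)` and post-occlusion
#' `c = [occl_end, end]` (the final sample is included in `c`).
#'
#' @param start_s,occl_start_s,occl_end_s,end_s segment boundaries, seconds,
#'   with `start < occl_start < occl_end <= end`.
#' @return an object of class `segment_definition`.
#' @export
segment_definition <- function(start_s = 0, occl_start_s = 8,
                               occl_end_s = 16, end_s = 24) {
  if (!(start_s < occl_start_s && occl_start_s < occl_end_s &&
        occl_end_s <= end_s))
    stopf("need start < occl_start < occl_end <= end (got %g, %g, %g, %g)",
          start_s, occl_start_s, occl_end_s, end_s)
  structure(list(start_s = start_s, occl_start_s = occl_start_s,
                 occl_end_s = occl_end_s, end_s = end_s),
            class = "segment_definition")
}

#' Assign samples of a trace to the three occlusion segments
#'
#' @param t sample times, seconds.
#' @param x trace values.
#' @param seg a [segment_definition()].
#' @param valid logical mask (defaults to non-`NA` values of `x`).
#' @return named list of data.frames `a`, `b`, `c` with columns `t`, `x`
#'   (valid samples only).
#' @export
segment_trace <- function(t, x, seg, valid = NULL) {
  stopifnot(inherits(seg, "segment_definition"))
  if (is.null(valid)) valid <- !is.na(x)
  valid <- valid & !is.na(x)
  idx <- list(
    a = which(valid & t >= seg$start_s & t < seg$occl_start_s),
    b = which(valid & t >= seg$occl_start_s & t < seg$occl_end_s),
    c = which(valid & t >= seg$occl_end_s & t <= seg$end_s)
  )
  empty <- names(idx)[vapply(idx, length, 1L) == 0]
  if (length(empty))
    stopf("segment '%s' contains no valid samples", empty[1])
  lapply(idx, function(i) data.frame(t = t[i], x = x[i]))
}

#' Mean and standard deviation per segment
#'
#' Unbiased standard deviation over the valid samples of each segment; with
#' fewer than 2 valid samples the standard deviation is reported as `NA`
#' while the mean is still computed.
#'
#' @inheritParams segment_trace
#' @return data.frame with columns `segment`, `mean`, `sd`, `n_valid`.
#' @export
segment_stats <- function(t, x, seg, valid = NULL) {
  parts <- segment_trace(t, x, seg, valid)
  do.call(rbind, lapply(names(parts), function(s) {
    v <- parts[[s]]$x
    data.frame(segment = s, mean = mean(v),
               sd = if (length(v) >= 2) sd(v) else NA_real_,
               n_valid = length(v))
  }))
}

#' During/pre and post/pre segment ratios
#'
#' @param stats output of [segment_stats()].
#' @return one-row data.frame with `ratio_mean_ba`, `ratio_mean_ca`,
#'   `ratio_std_ba`, `ratio_std_ca`; ratios with a non-positive denominator
#'   are `NA`.
#' @export
ratio_metrics <- function(stats) {
  g <- function(seg, col) {
    v <- stats[[col]][stats$segment == seg]
    if (length(v) != 1) NA_real_ else v
  }
  safe_ratio <- function(num, den) {
    if (is.na(den) || den <= 0) NA_real_ else num / den
  }
  data.frame(
    ratio_mean_ba = safe_ratio(g("b", "mean"), g("a", "mean")),
    ratio_mean_ca = safe_ratio(g("c", "mean"), g("a", "mean")),
    ratio_std_ba = safe_ratio(g("b", "sd"), g("a", "sd")),
    ratio_std_ca = safe_ratio(g("c", "sd"), g("a", "sd"))
  )
}

#' Per-channel segment statistics and ratios for one subject's series
#'
#' @param series tidy series data.frame from [process_stack()].
#' @param seg a [segment_definition()].
#' @param metric column to analyse (`"nbfi"` matches the reported
#'   normalized-flow ratio curves; `"bfi"` gives unnormalized ratios).
#' @return data.frame, one row per channel, with segment means/sds and the
#'   four ratios.
#' @export
analyze_segments <- function(series, seg, metric = "nbfi") {
  if (!metric %in% names(series)) stopf("series has no column '%s'", metric)
  chans <- unique(series$channel)
  do.call(rbind, lapply(chans, function(ch) {
    s <- series[series$channel == ch, ]
    st <- segment_stats(s$t, s[[metric]], seg, s$valid)
    r <- ratio_metrics(st)
    cbind(data.frame(channel = ch,
                     sd_distance_cm = s$sd_distance_cm[1],
                     mean_a = st$mean[st$segment == "a"],
                     mean_b = st$mean[st$segment == "b"],
                     mean_c = st$mean[st$segment == "c"],
                     sd_a = st$sd[st$segment == "a"],
                     sd_b = st$sd[st$segment == "b"],
                     sd_c = st$sd[st$segment == "c"],
                     n_valid = sum(st$n_valid)),
          r)
  }))
}

#' Aggregate per-subject ratio curves across a cohort
#'
#' Per channel, the mean and unbiased across-subject standard deviation of
#' each ratio.  Subject-channels listed in `exclude` (e.g. below an SNR
#' threshold) or carrying `NA` ratios are dropped from that channel's
#' aggregate, with bookkeeping of how many subjects were used and excluded.
#'
#' @param ratios stacked per-subject output of [analyze_segments()] with a
#'   `subject` column.
#' @param exclude optional data.frame with columns `subject`, `channel` of
#'   subject-channels to drop.
#' @return data.frame, one row per channel: group mean and sd of each ratio,
#'   `n_subjects_used`, `n_excluded`.
#' @export
group_aggregate <- function(ratios, exclude = NULL) {
  if (!"subject" %in% names(ratios))
    stopf("`ratios` must carry a `subject` column")
  cohort <- length(unique(ratios$subject))
  cols <- c("ratio_mean_ba", "ratio_mean_ca", "ratio_std_ba", "ratio_std_ca")
  out <- lapply(sort(unique(ratios$channel)), function(ch) {
    r <- ratios[ratios$channel == ch, ]
    if (!is.null(exclude)) {
      drop <- exclude$subject[exclude$channel == ch]
      r <- r[!r$subject %in% drop, ]
    }
    r <- r[stats::complete.cases(r[, cols]), ]
    if (nrow(r) == 0) {
      warnf("channel %s: no valid subjects, omitted from the aggregate", ch)
      return(NULL)
    }
    row <- data.frame(channel = ch, sd_distance_cm = r$sd_distance_cm[1],
                      n_subjects_used = nrow(r),
                      n_excluded = cohort - nrow(r))
    for (cc in cols) {
      row[[paste0(cc, "_mean")]] <- mean(r[[cc]])
      row[[paste0(cc, "_sd")]] <- if (nrow(r) >= 2) sd(r[[cc]]) else 0
    }
    row
  })
  do.call(rbind, out)
}

#' Source-detector distance at which two ratio curves converge
#'
#' The smallest distance at which the occlusion curve lies within
#' `tolerance` of the control curve and stays within tolerance for all
#' larger distances; `NA` if never satisfied.
#'
#' @param sd_distance_cm common distance grid.
#' @param occlusion,control ratio values on that grid.
#' @param tolerance absolute tolerance (default 0.05).
#' @return a distance in cm, or `NA`.
#' @export
convergence_distance <- function(sd_distance_cm, occlusion, control,
                                 tolerance = 0.05) {
  n <- length(sd_distance_cm)
  if (length(occlusion) != n || length(control) != n)
    stopf("occlusion and control curves must share the distance grid")
  ok <- abs(occlusion - control) <= tolerance
  ok[is.na(ok)] <- FALSE
  sustained <- rev(cumprod(rev(ok))) == 1
  if (!any(sustained)) return(NA_real_)
  sd_distance_cm[which(sustained)[1]]
}
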