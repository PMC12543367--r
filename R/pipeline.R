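# End-to-end orchestration: simulate -> calibrate -> process -> analyze ->
# report, with a manifest tying every table to the config hash and seed.

#' Simulate and process a synthetic cohort
#'
#' For each subject: synthesize a frame stack, process it into hemodynamic
#' series with a dark-frame calibration shared across the cohort, and keep
#' the (small) series table plus the per-subject ground truth summary.
#' Stacks are discarded after processing unless `keep_stacks = TRUE`.
#'
#' @param config a [synth_config()].
#' @param n_dark_frames dark frames used for the calibration.
#' @param floor_epsilon,baseline_window_s passed to [process_stack()].
#' @param keep_stacks retain the simulated [frame_stack()]s (memory-heavy).
#' @return object of class `scos_study`: list with `config`, `calib`,
#'   `series` (per-subject list), `heart_rates_hz`, `truth_hr`, `oracle`
#'   (closed-form expected segment ratios, bfi metric) and optionally
#'   `stacks`.
#' @export
run_synthetic_study <- function(config, n_dark_frames = 200,
                                floor_epsilon = 1e-6,
                                baseline_window_s = c(0, 7),
                                keep_stacks = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  dark <- synthesize_dark_frames(config$noise, n_dark_frames,
                                 dims = synth_frame_dims(config),
                                 seed = subject_seed(config$seed, 0L))
  calib <- compute_dark_calibration(dark, gain = config$noise$gain,
                                    conversion_factor =
                                      config$noise$conversion_factor)
  series <- vector("list", config$n_subjects)
  stacks <- if (keep_stacks) vector("list", config$n_subjects) else NULL
  hr <- numeric(config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sim <- synthesize_frames(config, i)
    hr[i] <- sim$truth$hr_hz
    series[[i]] <- process_stack(sim$stack, sim$layout, calib,
                                 floor_epsilon = floor_epsilon,
                                 baseline_window_s = baseline_window_s)
    if (keep_stacks) stacks[[i]] <- sim$stack
  }
  structure(list(
    config = config, calib = calib, series = series,
    heart_rates_hz = hr,
    oracle = if (!is.null(config$occlusion_window_s))
      expected_segment_ratios(config, metric = "bfi") else NULL,
    stacks = stacks
  ), class = "scos_study")
}

#' @export
print.scos_study <- function(x, ...) {
  cat(sprintf("scos_study: %d subject series, gamma %.3f\n",
              length(x$series), x$calib$gamma))
  invisible(x)
}

#' Spectral summary (heart rate, SNR) per subject and channel
#'
#' @param study a [run_synthetic_study()] result (or any list of series).
#' @param metric trace column used for the spectrum.
#' @return data.frame with `subject`, `channel`, `sd_distance_cm`,
#'   `heart_rate_hz`, `snr_db`.
#' @export
spectral_summary <- function(study, metric = "nbfi") {
  fs <- study$config$frame_rate_hz
  rows <- list()
  for (si in seq_along(study$series)) {
    series <- study$series[[si]]
    for (ch in unique(series$channel)) {
      s <- series[series$channel == ch, ]
      row <- tryCatch({
        psd <- power_spectrum(s[[metric]], fs, s$valid)
        hr <- estimate_heart_rate(psd)
        data.frame(subject = si, channel = ch,
                   sd_distance_cm = s$sd_distance_cm[1],
                   heart_rate_hz = hr, snr_db = snr_db(psd, hr))
      }, error = function(e)
        data.frame(subject = si, channel = ch,
                   sd_distance_cm = s$sd_distance_cm[1],
                   heart_rate_hz = NA_real_, snr_db = NA_real_))
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Full occlusion analysis of a processed cohort
#'
#' Computes per-subject segment ratios, applies the SNR exclusion rule
#' (subject-channels below `snr_threshold_db` are dropped before
#' aggregation), aggregates across subjects, and derives the beat-averaged
#' waveform amplitude-ratio curves for flow (`nbfi`) and volume (`nbvi`).
#'
#' @param study a [run_synthetic_study()] result.
#' @param seg segment definition; defaults to the config's occlusion window,
#'   or to 8-16 s for control cohorts.
#' @param metric series column for the segment ratios (default `"nbfi"`).
#' @param snr_threshold_db usability threshold in dB (default 10).
#' @return list with `per_subject`, `group`, `spectra`, `excluded`,
#'   `amplitude`, `amplitude_group`, `seg`.
#' @export
analyze_study <- function(study, seg = NULL, metric = "nbfi",
                          snr_threshold_db = 10) {
  config <- study$config
  if (is.null(seg)) {
    win <- config$occlusion_window_s
    if (is.null(win)) win <- c(8, 16)
    seg <- segment_definition(0, win[1], win[2], config$duration_s)
  }
  per_subject <- do.call(rbind, lapply(seq_along(study$series), function(i)
    cbind(subject = i,
          analyze_segments(study$series[[i]], seg, metric = metric))))
  spectra <- spectral_summary(study, metric = metric)
  excluded <- spectra[!is.na(spectra$snr_db) &
                        spectra$snr_db < snr_threshold_db |
                        is.na(spectra$snr_db),
                      c("subject", "channel")]
  group <- group_aggregate(per_subject, exclude = excluded)
  amplitude <- amplitude_ratio_curve(study$series, seg,
                                     config$frame_rate_hz,
                                     heart_rates_hz = study$heart_rates_hz)
  amplitude_group <- aggregate_amplitude_ratios(amplitude,
                                                exclude = excluded)
  list(per_subject = per_subject, group = group, spectra = spectra,
       excluded = excluded, amplitude = amplitude,
       amplitude_group = amplitude_group, seg = seg)
}

#' Run the full simulate -> report pipeline and write a result bundle
#'
#' Executes dark-frame calibration, per-subject processing, the occlusion
#' analysis and the waveform report for an occlusion cohort and (optionally)
#' a matched control cohort, writing tidy CSV tables, a convergence
#' estimate, and a manifest (config hash, seed, package version, exclusion
#' counts) to `out_dir`.  Identical config and seed give byte-identical
#' outputs.
#'
#' @param config a [synth_config()] for the occlusion cohort, or a path to
#'   its JSON serialization.
#' @param out_dir output directory (created if missing).
#' @param control `TRUE` to also run the matched control cohort (same
#'   subjects and seed, occlusion window removed), `FALSE` to skip.
#' @param seg optional [segment_definition()].
#' @param snr_threshold_db,convergence_tolerance analysis thresholds.
#' @return (invisibly) list with the analysis objects and output paths.
#' @export
run_pipeline <- function(config, out_dir, control = TRUE, seg = NULL,
                         snr_threshold_db = 10,
                         convergence_tolerance = 0.05) {
  if (is.character(config)) config <- read_synth_config(config)
  stopifnot(inherits(config, "synth_config"))
  if (is.null(config$occlusion_window_s))
    stopf("run_pipeline expects an occlusion config; control is derived")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  study <- stage("process", run_synthetic_study(config))
  ana <- stage("analyze", analyze_study(study, seg = seg,
                                        snr_threshold_db = snr_threshold_db))

  write_tbl <- function(df, name) {
    p <- file.path(out_dir, name)
    write_series_csv(df, p)
    paths[[name]] <<- p
  }
  stage("report", {
    write_calibration(study$calib, file.path(out_dir, "calibration.json"))
    for (i in seq_along(study$series))
      write_tbl(study$series[[i]], sprintf("series_subject%02d.csv", i))
    write_tbl(ana$per_subject, "ratios_per_subject.csv")
    write_tbl(ana$group, "ratios_group.csv")
    write_tbl(ana$spectra, "spectral_summary.csv")
    write_tbl(ana$amplitude_group, "amplitude_ratios_group.csv")
    write_tbl(study$oracle, "ratio_oracle.csv")
  })

  conv <- NULL
  ana_ctrl <- NULL
  if (isTRUE(control)) {
    cfg_ctrl <- config
    cfg_ctrl$occlusion_window_s <- NULL
    study_ctrl <- stage("process-control", run_synthetic_study(cfg_ctrl))
    ana_ctrl <- stage("analyze-control",
                      analyze_study(study_ctrl, seg = ana$seg,
                                    snr_threshold_db = snr_threshold_db))
    stage("report-control", {
      write_tbl(ana_ctrl$group, "ratios_group_control.csv")
      write_tbl(ana_ctrl$amplitude_group,
                "amplitude_ratios_group_control.csv")
    })
    shared <- intersect(ana$group$channel, ana_ctrl$group$channel)
    g1 <- ana$group[ana$group$channel %in% shared, ]
    g0 <- ana_ctrl$group[ana_ctrl$group$channel %in% shared, ]
    conv <- convergence_distance(g1$sd_distance_cm, g1$ratio_mean_ba_mean,
                                 g0$ratio_mean_ba_mean,
                                 tolerance = convergence_tolerance)
  }

  manifest <- list(
    package = "speckleflow",
    version = as.character(utils::packageVersion("speckleflow")),
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    n_subjects = config$n_subjects,
    n_excluded_subject_channels = nrow(ana$excluded),
    invalid_frame_fraction = mean(!do.call(rbind, study$series)$valid),
    convergence_distance_cm = conv,
    tables = names(paths)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(study = study, analysis = ana, analysis_control = ana_ctrl,
                 convergence_distance_cm = conv, paths = paths,
                 manifest = manifest))
}
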