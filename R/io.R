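# On-disk formats.
#
# Frame stacks are stored as raw little-endian uint16 binary (frame-major,
# row-major within a frame) next to a JSON sidecar declaring dtype, shape
# and acquisition metadata; layouts, calibrations and configs are JSON;
# tabular outputs are tidy CSV.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a frame stack as raw binary plus a JSON sidecar
#'
#' @param stack a [frame_stack()].
#' @param path data-file path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @param extra named list of extra metadata stored in the sidecar (e.g.
#'   seed, config hash, channel layout).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  v <- as.integer(aperm(stack$frames, c(3, 2, 1)))  # col fastest -> row-major
  bytes <- as.raw(rbind(v %% 256L, v %/% 256L))     # little-endian uint16
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  meta <- c(list(dtype = "uint16", shape = d, byte_order = "little",
                 pixel_order = "frame-row-major",
                 frame_rate_hz = stack$frame_rate_hz,
                 exposure_s = stack$exposure_s,
                 bit_depth = stack$bit_depth),
            extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path data-file path.
#' @param sidecar sidecar path (defaults to `paste0(path, ".json")`).
#' @return a [frame_stack()]; extra sidecar metadata is attached as the
#'   `"meta"` attribute.
#' @export
read_frame_stack <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stopf("no such stack file: %s", path)
  if (!file.exists(sidecar)) stopf("missing sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("dtype", "shape", "frame_rate_hz", "exposure_s", "bit_depth")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stopf("sidecar is missing keys: %s", paste(missing, collapse = ", "))
  if (!identical(meta$dtype, "uint16"))
    stopf("unsupported dtype '%s': only 16-bit (uint16) stacks are supported",
          meta$dtype)
  if (meta$bit_depth > 16)
    stopf("bit depth %d exceeds the 16-bit container", meta$bit_depth)
  d <- as.integer(meta$shape)
  if (length(d) != 3) stopf("sidecar shape must have 3 entries")
  expected_bytes <- 2 * prod(d)
  if (file.info(path)$size != expected_bytes)
    stopf("stack file size %d does not match sidecar shape (expected %d bytes)",
          file.info(path)$size, expected_bytes)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, integer(), n = prod(d), size = 2, signed = FALSE,
               endian = "little")
  frames <- aperm(array(v, dim = rev(d)), c(3, 2, 1))
  out <- frame_stack(frames, meta$frame_rate_hz, meta$exposure_s,
                     meta$bit_depth)
  attr(out, "meta") <- meta[setdiff(names(meta), required)]
  out
}

#' Write / read a channel layout as JSON
#' @param layout a [channel_layout()].
#' @param path file path.
#' @return the path (write) or a [channel_layout()] (read).
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(as.data.frame(layout), path, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  channel_layout(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a camera calibration as JSON
#' @param calib a [camera_calibration()].
#' @param path file path.
#' @return the path (write) or a [camera_calibration()] (read).
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "camera_calibration"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_calibration(gain = x$gain, conversion_factor = x$conversion_factor,
                     dark_offset = x$dark_offset,
                     dark_variance = x$dark_variance,
                     include_quantization = isTRUE(x$include_quantization))
}

#' Write / read a synthetic cohort configuration as JSON
#' @param config a [synth_config()].
#' @param path file path.
#' @return the path (write) or a [synth_config()] (read).
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  occl <- x$occlusion_window_s
  if (!is.null(occl) && length(occl) == 0) occl <- NULL
  nz <- do.call(noise_params, x$noise[c("read_sigma", "dark_offset",
                                        "conversion_factor", "gain",
                                        "bit_depth", "shot")])
  synth_config(
    n_subjects = x$n_subjects, seed = x$seed, duration_s = x$duration_s,
    frame_rate_hz = x$frame_rate_hz, exposure_s = x$exposure_s,
    channels = as.data.frame(x$channels),
    heart_rate_hz = x$heart_rate_hz, pulsatility = x$pulsatility,
    pulsatility_vol = x$pulsatility_vol, occlusion_window_s = occl,
    scalp_suppression = x$scalp_suppression,
    volume_suppression = x$volume_suppression, beta = x$beta,
    bvi_scale = x$bvi_scale, ramp_s = x$ramp_s,
    tau_c_baseline_s = x$tau_c_baseline_s, region_px = x$region_px,
    noise = nz
  )
}

#' Write / read a tidy series table as CSV
#' @param df a data.frame.
#' @param path file path.
#' @return the path (write) or a data.frame (read).
#' @export
write_series_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path)
}

# Stable md5 hash of any jsonlite-serializable object.
config_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Export ground truth as tidy CSV
#'
#' Long format: `subject`, `channel`, `t`, `k_true_sq`, `bfi_true`,
#' `bvi_true`.
#'
#' @param truth ground truth from [synthesize_frames()].
#' @param subject subject id recorded in the table.
#' @return data.frame.
#' @export
truth_to_df <- function(truth, subject = 1L) {
  nch <- ncol(truth$k_true_sq)
  do.call(rbind, lapply(seq_len(nch), function(ci) data.frame(
    subject = subject, channel = truth$channels$channel[ci],
    t = truth$t,
    k_true_sq = truth$k_true_sq[, ci],
    bfi_true = truth$bfi_true[, ci],
    bvi_true = truth$bvi_true[, ci]
  )))
}
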