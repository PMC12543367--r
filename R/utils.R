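#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is_scalar_number(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g (got %g)", name, lower, x)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%g, %g] (got %g)", name, lower, upper, x)
  invisible(x)
}

#' Irradiance of a circular laser spot
#'
#' Average irradiance delivered by a beam of total power `power_mw` over a
#' circular spot of diameter `spot_diameter_mm`.  Used to verify that an
#' illumination setting respects the ANSI skin maximum-permissible-exposure
#' limit for 830 nm light (see [ansi_skin_limit_mw_mm2]).
#'
#' @param power_mw total optical power in milliwatts.
#' @param spot_diameter_mm spot diameter in millimetres.
#' @return irradiance in mW/mm^2.
#' @examples
#' spot_irradiance(60, 5)   # ~3.06 mW/mm^2, below the 3.63 ANSI limit
#' @export
spot_irradiance <- function(power_mw, spot_diameter_mm) {
  assert_scalar_number(power_mw, "power_mw", lower = 0, strict_lower = TRUE)
  assert_scalar_number(spot_diameter_mm, "spot_diameter_mm",
                       lower = 0, strict_lower = TRUE)
  power_mw / (pi * (spot_diameter_mm / 2)^2)
}

#' ANSI maximum permissible skin exposure at 830 nm, in mW/mm^2
#' @export
ansi_skin_limit_mw_mm2 <- 3.63

#' Speckle density from the speckle-to-pixel length ratio
#'
#' With a one-dimensional speckle-to-pixel length ratio `s/p`, the areal
#' speckle density is `(s/p)^2` speckles per pixel.
#'
#' @param sp_ratio one-dimensional speckle-to-pixel length ratio.
#' @return speckles per pixel.
#' @examples
#' speckle_density(0.3)  # 0.09, i.e. ~0.1 speckle per pixel
#' @export
speckle_density <- function(sp_ratio) {
  assert_scalar_number(sp_ratio, "sp_ratio", lower = 0, strict_lower = TRUE)
  sp_ratio^2
}

# Unbiased sample variance of the columns of a matrix, without copies.
col_vars <- function(m) {
  n <- nrow(m)
  mu <- .colMeans(m, n, ncol(m))
  (colSums(m * m) - n * mu^2) / (n - 1)
}

# Deterministic per-subject RNG stream derived from the cohort seed.
subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) + 7919 * subject_index) %% 2147483647)
}
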