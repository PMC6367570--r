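#' Rod-shaped cell volume (cylinder plus hemispherical caps)
#'
#' A fission-yeast cell is approximated as a cylinder with one hemisphere
#' at each end. With radius `r = width / 2`:
#' `V = pi * r^2 * (length - 2 r) + (4/3) * pi * r^3`.
#' At `length == width` this degenerates to a sphere.
#'
#' @param length Cell length(s), micrometers; must be `>= width`.
#' @param width Cell width(s), micrometers; must be positive.
#' @return Volume(s) in cubic micrometers. Vectorized.
#' @examples
#' cell_volume(10, 4)  # (104/3) * pi
#' @export
cell_volume <- function(length, width) {
  if (any(width <= 0)) stop("width must be positive")
  if (any(length < width)) stop("length must be at least width (rod assumption)")
  r <- width / 2
  pi * r^2 * (length - 2 * r) + (4 / 3) * pi * r^3
}

#' Growth rates from a single-cell length/width time series
#'
#' Elongation and widening rates are ordinary least-squares slopes of
#' length and width against time; the volume-expansion rate is the OLS
#' slope of the per-time-point [cell_volume()] against time (volume is
#' derived from the other two measurements, then regressed).
#'
#' @param series `data.frame` for one cell with strictly increasing `time`
#'   (minutes) and `length`, `width` columns (micrometers); at least two
#'   time points.
#' @return List with `elongation` and `widening` (micrometers/minute) and
#'   `volume_expansion` (cubic micrometers/minute).
#' @export
growth_rates <- function(series) {
  req <- c("time", "length", "width")
  if (!all(req %in% names(series))) {
    stop("series must have columns time, length and width")
  }
  if (nrow(series) < 2L) stop("at least two time points are required")
  if (any(diff(series$time) <= 0)) stop("times must be strictly increasing")
  slope <- function(y) {
    unname(stats::coef(stats::lm(y ~ t, data.frame(y = y, t = series$time)))[2L])
  }
  list(elongation = slope(series$length),
       widening = slope(series$width),
       volume_expansion = slope(cell_volume(series$length, series$width)))
}

#' Normalize secreted acid-phosphatase activity to cell density
#'
#' ACP activity read out as OD405 of the hydrolyzed substrate is divided by
#' the culture density OD595 measured at the same time point, giving a
#' dimensionless per-cell-density activity.
#'
#' @param od405 Activity absorbance(s); non-negative.
#' @param od595 Cell-density absorbance(s); positive.
#' @return `od405 / od595`. Vectorized.
#' @export
normalize_acp <- function(od405, od595) {
  if (any(od595 <= 0)) stop("od595 must be positive")
  if (any(od405 < 0)) stop("od405 must be non-negative")
  od405 / od595
}

#' FRAP recovery fraction
#'
#' Post-bleach fluorescence of a region normalized to the signal of the
#' same region prior to bleaching.
#'
#' @param signal Intensity series of the bleached region.
#' @param pre_bleach Pre-bleach intensity of the same region; positive.
#' @return Recovery fraction series (typically in `[0, 1]` plus noise).
#' @export
frap_recovery <- function(signal, pre_bleach) {
  if (pre_bleach <= 0) stop("pre_bleach must be positive")
  signal / pre_bleach
}
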