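#' Internal calibration curve for IU/ml interpolation
#'
#' The immunoassay carries an internal calibration curve (anti-IgE spots probed
#' with reference IgE at known concentrations). After background subtraction
#' the fluorescence of each allergen spot is interpolated against this curve to
#' obtain a concentration in IU/ml. The reference standards span 0.35-50 IU/ml
#' and the assay's reportable range ends at 100 IU/ml.
#'
#' @param concentration numeric vector of standard concentrations (IU/ml),
#'   strictly increasing, within \[0.35, 100\].
#' @param signal numeric vector of background-subtracted fluorescence at each
#'   standard, strictly increasing with concentration.
#'
#' @return A tibble of class `ige_calibration` with columns `concentration`
#'   and `signal`.
#' @export
#' @examples
#' calibration_curve(c(0.35, 1, 3.5, 10, 50), c(120, 340, 1100, 3100, 15000))
calibration_curve <- function(concentration, signal) {
  if (length(concentration) != length(signal)) {
    abort("`concentration` and `signal` must have the same length.")
  }
  if (length(concentration) < 2) abort("calibration curve needs >= 2 points")
  if (any(concentration < 0.35) || any(concentration > 100)) {
    abort("calibration concentrations must lie within [0.35, 100] IU/ml")
  }
  if (is.unsorted(concentration, strictly = TRUE)) {
    abort("calibration concentrations must be strictly increasing")
  }
  if (any(signal <= 0)) abort("calibration signals must be positive")
  if (is.unsorted(signal, strictly = TRUE)) {
    abort("calibration signals must be strictly increasing with concentration")
  }
  structure(tibble::tibble(concentration = as.numeric(concentration),
                           signal = as.numeric(signal)),
            class = c("ige_calibration", class(tibble::tibble())))
}

#' Subtract the local background from a fluorescence signal
#'
#' Negative differences are floored at zero: a spot dimmer than its local
#' background carries no evidence of bound IgE.
#'
#' @param signal,background non-negative fluorescence values (vectorised).
#' @return `pmax(signal - background, 0)`.
#' @export
#' @examples
#' subtract_background(1000, 200)
#' subtract_background(150, 200) # floored at 0
subtract_background <- function(signal, background) {
  if (any(signal < 0) || any(background < 0)) {
    abort("fluorescence values must be non-negative")
  }
  pmax(signal - background, 0)
}

#' Interpolate fluorescence to IU/ml on the calibration curve
#'
#' Interpolation is piecewise linear in (log10 concentration, log10 signal)
#' space, the locally power-law regime typical of immunoassay response curves.
#' Signals at a calibration knot map exactly to the knot concentration.
#' Signals below the lowest standard are below the detection limit of
#' 0.35 IU/ml and are reported as 0 (class 0); signals above the highest
#' standard extrapolate log-linearly on the last segment and clamp to the
#' 100 IU/ml assay ceiling.
#'
#' @param signal non-negative background-subtracted fluorescence (vectorised).
#' @param curve a [calibration_curve()].
#' @return Concentrations in IU/ml, within \[0, 100\].
#' @export
signal_to_iu <- function(signal, curve) {
  if (!inherits(curve, "ige_calibration")) {
    curve <- calibration_curve(curve[[1]], curve[[2]])
  }
  if (any(signal < 0)) abort("fluorescence values must be non-negative")
  ls <- log10(curve$signal)
  lc <- log10(curve$concentration)
  n <- length(ls)
  out <- numeric(length(signal))
  above <- signal >= curve$signal[1]
  if (any(above)) {
    x <- log10(signal[above])
    seg <- findInterval(x, ls, rightmost.closed = FALSE, all.inside = TRUE)
    slope <- (lc[seg + 1] - lc[seg]) / (ls[seg + 1] - ls[seg])
    conc <- 10^(lc[seg] + slope * (x - ls[seg]))
    out[above] <- pmin(conc, 100)
  }
  out
}

#' Default specific-IgE class-score scale
#'
#' The clinical reporting scale bins IU/ml into six ordinal classes:
#' class 0 below 0.35, 1 for 0.35-0.7, 2 for 0.71-3.5, 3 for 3.51-17.5,
#' 4 for 17.51-50 and 5 for 50.01-100 IU/ml. The printed band edges reflect
#' 2-decimal rounding; the implemented bins are contiguous half-open intervals
#' cut at band midpoints (0.705, 3.505, 17.505, 50.005) so the scale covers
#' \[0, 100\] with no gaps while agreeing with every printed label at printed
#' precision.
#'
#' @return A tibble with columns `class`, `lower`, `upper` (upper edge
#'   exclusive except for the terminal class).
#' @export
class_scale <- function() {
  tibble::tibble(class = 0:5,
                 lower = c(0, 0.35, 0.705, 3.505, 17.505, 50.005),
                 upper = c(0.35, 0.705, 3.505, 17.505, 50.005, 100))
}

#' Encode IU/ml concentrations as 0-5 class scores
#'
#' @param iu non-negative concentrations in IU/ml (vectorised). Values above
#'   100 IU/ml are clamped to class 5 with a warning (the scale ends at 100).
#' @param scale bin table as returned by [class_scale()]; override to use a
#'   non-default scale (must have 6 contiguous classes covering \[0, 100\]).
#' @return Integer class scores in 0-5.
#' @export
#' @examples
#' iu_to_class(c(0.34, 0.35, 10, 60))
iu_to_class <- function(iu, scale = class_scale()) {
  if (any(iu < 0)) abort("IU/ml values must be non-negative")
  stopifnot(nrow(scale) == 6L, all(scale$lower[-1] == scale$upper[-6]))
  if (any(iu > scale$upper[6])) {
    warn(sprintf("%d value(s) above %s IU/ml clamped to class 5",
                 sum(iu > scale$upper[6]), format(scale$upper[6])))
  }
  findInterval(pmin(iu, scale$upper[6]), scale$lower) - 1L
}

#' Quantify a raw fluorescence matrix into class scores
#'
#' Applies background subtraction, calibration-curve interpolation to IU/ml and
#' class-score encoding elementwise, preserving the table shape.
#'
#' @param raw a reactivity table with unit `"signal"`.
#' @param curve a [calibration_curve()].
#' @param background scalar, per-subject vector, or matrix of background
#'   fluorescence (default 0, i.e. signals already background-subtracted).
#' @param scale class-score bin table, see [iu_to_class()].
#' @return A reactivity table with unit `"class_score"` (same subjects and
#'   allergens).
#' @export
quantify_matrix <- function(raw, curve, background = 0, scale = class_scale()) {
  if (!identical(reactivity_unit(raw), "signal")) {
    abort("`raw` must be a reactivity table with unit \"signal\"")
  }
  m <- reactivity_values(raw)
  net <- subtract_background(m, background)
  iu <- signal_to_iu(as.vector(net), curve)
  cls <- iu_to_class(iu, scale)
  out <- matrix(cls, nrow(m), ncol(m))
  reactivity_tbl(out, raw$subject_id, allergen_ids(raw), unit = "class_score")
}
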