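#' Local-baseline-corrected peak intensity
#'
#' Measures the height of a band near `center`: within the window
#' `center +/- halfwidth`, the local linear baseline is the chord joining
#' the medians of the outermost `edge_width` cm^-1 of points on each side
#' (five points per side on the default 1 cm^-1 grid), and the intensity
#' is the maximum of (value - baseline) over the window. Negative
#' corrected heights are clipped to zero and flagged.
#'
#' @param s A `raman_spectrum`.
#' @param center Nominal band position (cm^-1).
#' @param halfwidth Window half-width in cm^-1 (default 15, tolerant of a
#'   few cm^-1 of calibration drift without capturing neighbouring bands).
#' @param edge_width Width in cm^-1 of each chord-defining edge region
#'   (default 4).
#' @return A one-row tibble: `center`, `halfwidth`, `intensity` (cps),
#'   `position_found` (cm^-1), `clipped`.
#' @export
peak_intensity <- function(s, center, halfwidth = 15, edge_width = 4) {
  stopifnot(is_raman_spectrum(s))
  lo <- center - halfwidth
  hi <- center + halfwidth
  if (lo < min(s$wavenumber) || hi > max(s$wavenumber)) {
    rlang::abort(sprintf("Peak window %g-%g cm-1 lies outside the spectrum support.",
                         lo, hi),
                 class = "ramanbca_domain_error")
  }
  sel <- which(s$wavenumber >= lo & s$wavenumber <= hi)
  if (length(sel) < 5) {
    rlang::abort("Peak window too narrow for the sampling step.",
                 class = "ramanbca_domain_error")
  }
  x <- s$wavenumber[sel]
  y <- s$intensity[sel]
  n <- length(sel)
  left <- which(x <= lo + edge_width)
  right <- which(x >= hi - edge_width)
  if (length(left) < 2) left <- 1:2
  if (length(right) < 2) right <- (n - 1):n
  x1 <- stats::median(x[left])
  y1 <- stats::median(y[left])
  x2 <- stats::median(x[right])
  y2 <- stats::median(y[right])
  baseline <- y1 + (y2 - y1) * (x - x1) / (x2 - x1)
  corrected <- y - baseline
  i <- which.max(corrected)
  intensity <- corrected[i]
  clipped <- intensity < 0
  tibble::tibble(
    center = center, halfwidth = halfwidth,
    intensity = max(intensity, 0),
    position_found = x[i], clipped = clipped
  )
}

#' Lipid saturation ratio (1665 / 1440 cm^-1)
#'
#' The intensity ratio of the C=C stretching band near 1665 cm^-1 to the
#' CH2 deformation band near 1440 cm^-1 is a proxy for the unsaturation
#' degree of phospholipids (0.58 for monounsaturated oleic acid). It is
#' computed on the extracted organellar lipid spectrum, after light
#' Savitzky-Golay smoothing (the max-picking peak estimator is otherwise
#' biased upward by noise extremes), and is invariant to uniform scaling
#' of the spectrum.
#'
#' When the 1440 band does not rise above `noise_floor` the ratio is
#' unmeasurable and `NA` is returned (the "-" cells of sparse-lipid
#' fixed-nucleus measurements).
#'
#' @param lipid The extracted lipid `raman_spectrum`.
#' @param noise_floor Minimum 1440 cm^-1 peak intensity in cps (default 0;
#'   callers typically pass 3x the residual SD).
#' @param halfwidth Peak window half-width (cm^-1).
#' @param smooth_window Savitzky-Golay window applied before peak picking
#'   (1 disables).
#' @return The dimensionless ratio, or `NA` if unmeasurable.
#' @export
saturation_ratio <- function(lipid, noise_floor = 0, halfwidth = 15,
                             smooth_window = 11) {
  stopifnot(is_raman_spectrum(lipid))
  s <- if (smooth_window > 1) {
    smooth_spectrum(lipid, window = smooth_window, order = 3)
  } else {
    lipid
  }
  p1440 <- peak_intensity(s, 1440, halfwidth)
  if (p1440$intensity <= noise_floor || p1440$intensity == 0) {
    return(NA_real_)
  }
  p1665 <- peak_intensity(s, 1665, halfwidth)
  p1665$intensity / p1440$intensity
}
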