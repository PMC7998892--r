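#' Signal and reference band windows
#'
#' Wavelength windows bracketing the two photonic stopbands: the signal band
#' overlaps the cargo molecule's absorption (its height falls as loading
#' rises), the reference band lies far from it. Defaults bracket the
#' experimentally observed band positions; simulation work with other
#' structures should supply windows from [bragg_wavelengths()].
#'
#' @param signal,reference Length-2 numeric `(lambda_lo, lambda_hi)` in nm.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(signal = c(430, 560), reference = c(600, 800)) {
  chk <- function(w, nm) {
    if (length(w) != 2 || !is.numeric(w) || w[1] >= w[2])
      err_invalid(sprintf("`%s` window must be (lo, hi) with lo < hi", nm))
  }
  chk(signal, "signal"); chk(reference, "reference")
  if (max(signal[1], reference[1]) < min(signal[2], reference[2]))
    err_invalid("signal and reference windows must not overlap")
  structure(list(signal = as.numeric(signal), reference = as.numeric(reference)),
            class = "band_definition")
}

# Optional centered moving average for noisy flow-cell intensity data.
.smooth_values <- function(v, width) {
  if (is.null(width) || width <= 1) return(v)
  width <- as.integer(width)
  if (width %% 2 == 0) width <- width + 1L
  stats::filter(v, rep(1 / width, width), sides = 2) |>
    (\(f) ifelse(is.na(f), v, as.numeric(f)))()
}

#' Locate the maximum of a band within a window
#'
#' Returns the wavelength and height of the largest spectrum value inside
#' the window; ties break toward the shorter wavelength. No baseline
#' subtraction is applied: the observable is the raw in-window maximum.
#'
#' @param spec A [spectrum()].
#' @param window Length-2 numeric `(lambda_lo, lambda_hi)` in nm.
#' @param smooth_width Optional odd moving-average width (in samples)
#'   applied before peak-picking; default none.
#' @return A list of class `band_reading` with `peak_wavelength`,
#'   `peak_height`, `window`.
#' @export
locate_band_max <- function(spec, window, smooth_width = NULL) {
  stopifnot(inherits(spec, "naagif_spectrum"))
  if (length(window) != 2 || window[1] >= window[2])
    err_invalid("`window` must be (lo, hi) with lo < hi")
  sel <- spec$wavelength_nm >= window[1] & spec$wavelength_nm <= window[2]
  if (sum(sel) < 3)
    err_range("window intersects the wavelength grid in fewer than 3 samples")
  v <- .smooth_values(spec$value, smooth_width)[sel]
  w <- spec$wavelength_nm[sel]
  i <- which.max(v)   # first maximum = shortest wavelength on ties
  structure(list(peak_wavelength = w[i], peak_height = v[i],
                 window = as.numeric(window)),
            class = "band_reading")
}

#' Signal/reference band height ratio
#'
#' The loading observable: the ratio of the in-window maximum of the signal
#' band to that of the reference band. Scale-invariant, so it applies
#' equally to raw flow-cell intensity and calibrated reflectance.
#'
#' @param spec A [spectrum()].
#' @param bands A [band_definition()].
#' @param smooth_width Optional moving-average width for noisy data.
#' @return A single positive number.
#' @export
band_ratio <- function(spec, bands = band_definition(), smooth_width = NULL) {
  stopifnot(inherits(bands, "band_definition"))
  s <- locate_band_max(spec, bands$signal, smooth_width)
  r <- locate_band_max(spec, bands$reference, smooth_width)
  if (r$peak_height == 0)
    err_degenerate("reference band peak height is zero; ratio undefined")
  s$peak_height / r$peak_height
}

#' Stopband redshift between two spectra
#'
#' Difference of in-window peak wavelengths, `after - before`; positive when
#' the band moves to longer wavelengths (e.g. pores filling with a
#' higher-index medium on wetting).
#'
#' @param before,after [spectrum()] objects on compatible grids.
#' @param window Length-2 numeric window (nm).
#' @param smooth_width Optional moving-average width.
#' @return Shift in nm.
#' @examples
#' g <- seq(400, 600, 1)
#' peak <- function(c0) spectrum(g, exp(-(g - c0)^2 / 200), "intensity")
#' redshift(peak(496), peak(518), c(430, 560))   # 22
#' @export
redshift <- function(before, after, window, smooth_width = NULL) {
  b <- locate_band_max(before, window, smooth_width)
  a <- locate_band_max(after, window, smooth_width)
  a$peak_wavelength - b$peak_wavelength
}
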