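#' Wavelength grid for spectral measurements
#'
#' Builds the regularly spaced wavelength grid on which all spectral
#' computations in the package take place. The default, 300--700 nm at 1 nm,
#' covers the spectral range bees are sensitive to; all model math is done
#' after resampling every input spectrum onto one shared grid so that
#' numerical integration is deterministic.
#'
#' @param start_nm First wavelength in nm (default 300).
#' @param stop_nm Last wavelength in nm (default 700).
#' @param step_nm Wavelength increment in nm (default 1).
#' @return A numeric vector of wavelengths in nm.
#' @examples
#' head(spectra_grid())
#' @export
spectra_grid <- function(start_nm = 300, stop_nm = 700, step_nm = 1) {
  if (!(start_nm < stop_nm)) abort("`start_nm` must be < `stop_nm`.")
  if (step_nm <= 0) abort("`step_nm` must be > 0.")
  seq(start_nm, stop_nm, by = step_nm)
}

#' Validate a spectra table
#'
#' A spectra table is a tibble with a `wavelength_nm` column (strictly
#' increasing) and one numeric column per named spectrum. Values must be
#' non-negative; reflectance values may exceed 1 up to `ceiling` (calibrated
#' reflectance can exceed 100% slightly when a stimulus out-reflects the
#' white standard).
#'
#' @param spectra A data frame with `wavelength_nm` plus spectrum columns.
#' @param kind One of `"reflectance"`, `"irradiance"`, `"sensitivity"`.
#'   Only `"reflectance"` enforces the ceiling.
#' @param ceiling Upper bound applied to reflectance values (default 1.2).
#' @return The validated table, as a tibble (invisibly usable in pipes).
#' @export
as_spectra <- function(spectra, kind = c("reflectance", "irradiance", "sensitivity"),
                       ceiling = 1.2) {
  kind <- match.arg(kind)
  spectra <- tibble::as_tibble(spectra)
  if (!"wavelength_nm" %in% names(spectra)) {
    abort("Spectra table must have a `wavelength_nm` column.")
  }
  wl <- spectra$wavelength_nm
  if (anyNA(spectra)) abort("Spectra table contains missing values.")
  if (is.unsorted(wl, strictly = TRUE)) {
    abort("`wavelength_nm` must be strictly increasing.")
  }
  vals <- dplyr::select(spectra, -"wavelength_nm")
  if (ncol(vals) < 1L) abort("Spectra table needs at least one value column.")
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("All spectrum columns must be numeric.")
  }
  if (any(as.matrix(vals) < 0)) abort("Spectral values must be non-negative.")
  if (kind == "reflectance" && any(as.matrix(vals) > ceiling)) {
    abort(sprintf("Reflectance values exceed the ceiling of %.3g.", ceiling))
  }
  spectra
}

spectrum_names <- function(spectra) setdiff(names(spectra), "wavelength_nm")

#' Resample spectra onto a target wavelength grid
#'
#' Linear interpolation of every spectrum column onto `wavelength`. The source
#' grid must cover the target range; extrapolation is refused because
#' reflectance outside the measured range is unknown, not zero.
#'
#' @param spectra A spectra table (see [as_spectra()]).
#' @param wavelength Target wavelengths in nm (e.g. [spectra_grid()]).
#' @return A tibble on the target grid with the same spectrum columns.
#' @examples
#' sp <- tibble::tibble(wavelength_nm = c(300, 700), s = c(0, 1))
#' resample_spectra(sp, c(300, 500, 700))
#' @export
resample_spectra <- function(spectra, wavelength) {
  spectra <- as_spectra(spectra, kind = "sensitivity")
  wl <- spectra$wavelength_nm
  if (min(wavelength) < min(wl) || max(wavelength) > max(wl)) {
    abort(sprintf(
      "Target grid [%g, %g] nm extends beyond the source range [%g, %g] nm.",
      min(wavelength), max(wavelength), min(wl), max(wl)
    ))
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelength))
  for (nm in spectrum_names(spectra)) {
    out[[nm]] <- stats::approx(wl, spectra[[nm]], xout = wavelength,
                               method = "linear", ties = "ordered")$y
  }
  out
}

#' Convert raw spectrometer counts to reflectance
#'
#' Standard dark/white normalisation: reflectance = (raw - black) /
#' (white - black), computed per wavelength against a white standard and a
#' black standard recorded on the same grid, then clipped at zero. The result
#' is invariant under a common affine rescaling of all three inputs.
#'
#' @param spectra Wide spectra table holding the raw stimulus columns and the
#'   two calibration columns.
#' @param white,black Names of the white- and black-standard columns.
#' @return Tibble with the stimulus columns converted to reflectance; the
#'   calibration columns are dropped.
#' @export
raw_to_reflectance <- function(spectra, white = "white", black = "black") {
  spectra <- as_spectra(spectra, kind = "irradiance")
  missing <- setdiff(c(white, black), names(spectra))
  if (length(missing)) {
    abort(paste0("Calibration column(s) not found: ", toString(missing)))
  }
  w <- spectra[[white]]
  b <- spectra[[black]]
  denom <- w - b
  if (any(denom <= 0)) {
    abort("White standard must exceed black standard at every wavelength.")
  }
  out <- tibble::tibble(wavelength_nm = spectra$wavelength_nm)
  for (nm in setdiff(spectrum_names(spectra), c(white, black))) {
    out[[nm]] <- pmax((spectra[[nm]] - b) / denom, 0)
  }
  out
}

# CIE standard illuminant D65, relative spectral power distribution,
# 300-780 nm at 5 nm (value 100 at 560 nm by convention).
d65_table <- function() {
  tibble::tibble(
    wavelength_nm = seq(300, 780, by = 5),
    power = c(
      0.0341, 1.6643, 3.2945, 11.7652, 20.2360, 28.6447, 37.0535,
      38.5011, 39.9488, 42.4302, 44.9117, 45.7750, 46.6383, 49.3637,
      52.0891, 51.0323, 49.9755, 52.3118, 54.6482, 68.7015, 82.7549,
      87.1204, 91.4860, 92.4589, 93.4318, 90.0570, 86.6823, 95.7736,
      104.8650, 110.9360, 117.0080, 117.4100, 117.8120, 116.3360,
      114.8610, 115.3920, 115.9230, 112.3670, 108.8110, 109.0820,
      109.3540, 108.5780, 107.8020, 106.2960, 104.7900, 106.2390,
      107.6890, 106.0470, 104.4050, 104.2250, 104.0460, 102.0230,
      100.0000, 98.1671, 96.3342, 96.0611, 95.7880, 92.2368, 88.6856,
      89.3459, 90.0062, 89.8026, 89.5991, 88.6489, 87.6987, 85.4936,
      83.2886, 83.4939, 83.6992, 81.8630, 80.0268, 80.1207, 80.2146,
      81.2462, 82.2778, 80.2810, 78.2842, 74.0027, 69.7213, 70.6652,
      71.6091, 72.9790, 74.3490, 67.9765, 61.6040, 65.7448, 69.8856,
      72.4863, 75.0874, 69.3398, 63.5927, 55.0054, 46.4182, 56.6118,
      66.8054, 65.0941, 63.3828
    )
  )
}

#' Standard daylight illuminant D65
#'
#' The CIE D65 relative spectral power distribution, linearly interpolated
#' from the embedded 5 nm tabulation onto the requested grid and rescaled so
#' its mean over the grid is 1. The von Kries adaptation step of the hexagon
#' model cancels any global illuminant scale, so this normalisation is purely
#' a convention.
#'
#' @param wavelength Wavelengths in nm; must lie within the tabulated
#'   300--780 nm range.
#' @return Tibble with columns `wavelength_nm` and `d65`.
#' @examples
#' mean(illuminant_d65(spectra_grid())$d65) # 1
#' @export
illuminant_d65 <- function(wavelength = spectra_grid()) {
  tab <- d65_table()
  if (min(wavelength) < 300 || max(wavelength) > 780) {
    abort("D65 is tabulated for 300-780 nm only.")
  }
  v <- stats::approx(tab$wavelength_nm, tab$power, xout = wavelength)$y
  tibble::tibble(wavelength_nm = as.numeric(wavelength), d65 = v / mean(v))
}

#' Spectrally flat illuminant
#'
#' @param wavelength Wavelengths in nm.
#' @return Tibble with columns `wavelength_nm` and `flat` (all 1).
#' @export
illuminant_flat <- function(wavelength = spectra_grid()) {
  tibble::tibble(wavelength_nm = as.numeric(wavelength), flat = rep(1, length(wavelength)))
}

#' Visual pigment sensitivity template
#'
#' Generates an A1 visual-pigment spectral sensitivity curve for a given peak
#' wavelength using the alpha band of the Govardovskii et al. (2000) nomogram,
#' peak-normalised to 1. The UV beta band is omitted so the template stays
#' unimodal; its contribution is negligible after background adaptation. Used
#' to construct the trichromatic bee receptor set when measured sensitivity
#' curves are not supplied.
#'
#' @param lambda_max Peak wavelength in nm, in \[300, 650\].
#' @param wavelength Wavelengths (nm) at which to evaluate the template.
#' @return Numeric vector of sensitivities in (0, 1\].
#' @examples
#' s <- receptor_template(544, spectra_grid())
#' max(s) # 1
#' @export
receptor_template <- function(lambda_max, wavelength = spectra_grid()) {
  if (lambda_max < 300 || lambda_max > 650) {
    abort("`lambda_max` must lie in [300, 650] nm.")
  }
  x <- lambda_max / wavelength
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  s / max(s)
}

#' Trichromatic bee receptor set
#'
#' Sensitivity curves for the UV, blue and green photoreceptors, generated
#' from [receptor_template()] at the honeybee peak wavelengths (344, 436 and
#' 544 nm by default). Measured curves can be swapped in by reading a spectra
#' CSV instead ([read_spectra_csv()]).
#'
#' @param wavelength Wavelengths in nm.
#' @param lambda_max Named numeric vector of peaks for `uv`, `blue`, `green`.
#' @return Spectra tibble with columns `wavelength_nm`, `uv`, `blue`, `green`.
#' @export
bee_receptors <- function(wavelength = spectra_grid(),
                          lambda_max = c(uv = 344, blue = 436, green = 544)) {
  stopifnot(all(c("uv", "blue", "green") %in% names(lambda_max)))
  tibble::tibble(
    wavelength_nm = as.numeric(wavelength),
    uv    = receptor_template(lambda_max[["uv"]], wavelength),
    blue  = receptor_template(lambda_max[["blue"]], wavelength),
    green = receptor_template(lambda_max[["green"]], wavelength)
  )
}

#' Read and write spectra CSV files
#'
#' The interchange format is a plain CSV with a `wavelength_nm` column and one
#' named column per spectrum. A write followed by a read preserves names, grid
#' and values.
#'
#' @param path File path.
#' @return `read_spectra_csv()` returns a validated spectra tibble.
#' @export
read_spectra_csv <- function(path) {
  sp <- readr::read_csv(path, show_col_types = FALSE)
  as_spectra(sp, kind = "sensitivity")
}

#' @param spectra Spectra tibble to write.
#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  spectra <- as_spectra(spectra, kind = "sensitivity")
  readr::write_csv(spectra, path)
  invisible(path)
}
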