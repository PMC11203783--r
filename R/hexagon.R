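#' Quantum catches of the bee photoreceptors
#'
#' For each stimulus reflectance spectrum, computes the background-adapted
#' quantum catch of the UV, blue and green receptors:
#' \deqn{P_i = R_i \int I_S(\lambda)\, S_i(\lambda)\, D(\lambda)\, d\lambda,
#'       \qquad R_i = 1 / \int I_B(\lambda)\, S_i(\lambda)\, D(\lambda)\, d\lambda,}
#' where \eqn{I_S} is the stimulus reflectance, \eqn{I_B} the background
#' reflectance, \eqn{S_i} the receptor sensitivity and \eqn{D} the
#' illuminant. The von Kries factor \eqn{R_i} adapts each receptor to the
#' background, so a stimulus identical to the background yields
#' \eqn{P = (1, 1, 1)}. Integrals use the trapezoidal rule on the shared
#' wavelength grid.
#'
#' All spectral inputs are resampled onto the stimulus grid, which must be
#' covered by each input's own range.
#'
#' @param spectra Spectra tibble of stimulus reflectances (`wavelength_nm`
#'   plus one column per stimulus).
#' @param background Either the name of a column of `spectra` to use as the
#'   adapting background, or a one-spectrum tibble.
#' @param illuminant Illuminant tibble (default D65 on the stimulus grid).
#' @param receptors Receptor set tibble (default [bee_receptors()]).
#' @return Tibble with one row per stimulus: `name`, `p_uv`, `p_blue`,
#'   `p_green`.
#' @examples
#' sp <- gen_cardboard_spectra()
#' quantum_catch(sp, background = "green_background")
#' @export
quantum_catch <- function(spectra, background,
                          illuminant = illuminant_d65(spectra$wavelength_nm),
                          receptors = bee_receptors(spectra$wavelength_nm)) {
  spectra <- as_spectra(spectra)
  wl <- spectra$wavelength_nm

  if (is.character(background)) {
    if (!background %in% names(spectra)) {
      abort(sprintf("Background column '%s' not found in `spectra`.", background))
    }
    bg <- spectra[[background]]
    stim_names <- setdiff(spectrum_names(spectra), background)
  } else {
    background <- resample_spectra(background, wl)
    bg <- background[[spectrum_names(background)[1]]]
    stim_names <- spectrum_names(spectra)
  }
  if (!length(stim_names)) abort("No stimulus spectra left after removing the background.")

  illuminant <- resample_spectra(illuminant, wl)
  receptors <- resample_spectra(receptors, wl)
  if (!all(c("uv", "blue", "green") %in% names(receptors))) {
    abort("`receptors` must have columns uv, blue, green.")
  }
  d <- illuminant[[spectrum_names(illuminant)[1]]]

  catch_one <- function(refl, sens) trapz_(wl, refl * sens * d)
  adapt <- vapply(c("uv", "blue", "green"),
                  function(r) catch_one(bg, receptors[[r]]), numeric(1))
  if (any(adapt <= 0)) {
    abort("Background quantum-catch integral is zero for at least one receptor; the adapting background is degenerate.")
  }

  purrr::map_dfr(stim_names, function(nm) {
    p <- vapply(c("uv", "blue", "green"),
                function(r) catch_one(spectra[[nm]], receptors[[r]]), numeric(1)) / adapt
    tibble::tibble(name = nm, p_uv = p[[1]], p_blue = p[[2]], p_green = p[[3]])
  })
}

#' Receptor excitation from quantum catch
#'
#' Saturating transform `E = P / (P + 1)`, mapping the adapting background
#' (P = 1) to half-maximal excitation 0.5 in every receptor.
#'
#' @param catch Tibble from [quantum_catch()] (columns `p_uv`, `p_blue`,
#'   `p_green`), or any tibble with those columns.
#' @return The input with columns `e_uv`, `e_blue`, `e_green` added.
#' @export
excitation <- function(catch) {
  catch <- tibble::as_tibble(catch)
  need <- c("p_uv", "p_blue", "p_green")
  if (!all(need %in% names(catch))) abort("`catch` must have columns p_uv, p_blue, p_green.")
  p <- as.matrix(catch[need])
  if (any(p <= 0)) abort("Quantum catches must be strictly positive.")
  dplyr::mutate(catch,
    e_uv    = .data$p_uv    / (.data$p_uv + 1),
    e_blue  = .data$p_blue  / (.data$p_blue + 1),
    e_green = .data$p_green / (.data$p_green + 1)
  )
}

#' Hexagon colour loci from receptor excitations
#'
#' Places each stimulus in the 2-D hexagon colour space:
#' \deqn{x = \frac{\sqrt{3}}{2}(E_g - E_u), \qquad
#'       y = E_b - \tfrac{1}{2}(E_u + E_g).}
#' The adapting background maps to the centre (0, 0). `center_distance` is the
#' Euclidean distance of a locus from the centre — the quantity this package's
#' study design calls achromatic contrast (in much of the colour-vision
#' literature it is called chromatic contrast or spectral purity; the
#' conventional green-receptor contrast is exposed separately as
#' `green_contrast`). `angle_deg` is the hue direction, 0 degrees at
#' vertical-up, by default increasing clockwise so the green vertex lies at
#' 120 degrees.
#'
#' @param excitation Tibble with columns `e_uv`, `e_blue`, `e_green`
#'   (see [excitation()]).
#' @param orientation `"clockwise"` (default) or `"counterclockwise"` sense
#'   for the hue angle.
#' @param tol Loci closer than `tol` to the centre get `angle_deg = NA`
#'   (hue undefined at the achromatic point).
#' @return Input tibble with `x`, `y`, `center_distance`, `angle_deg` and
#'   `green_contrast` columns added.
#' @export
hexagon_locus <- function(excitation, orientation = c("clockwise", "counterclockwise"),
                          tol = 1e-6) {
  orientation <- match.arg(orientation)
  excitation <- tibble::as_tibble(excitation)
  need <- c("e_uv", "e_blue", "e_green")
  if (!all(need %in% names(excitation))) {
    abort("`excitation` must have columns e_uv, e_blue, e_green.")
  }
  e <- as.matrix(excitation[need])
  if (any(e < 0 | e > 1)) abort("Excitations must lie in [0, 1].")
  out <- dplyr::mutate(excitation,
    x = sqrt(3) / 2 * (.data$e_green - .data$e_uv),
    y = .data$e_blue - (.data$e_uv + .data$e_green) / 2,
    center_distance = sqrt(.data$x^2 + .data$y^2),
    angle_deg = color_angle(.data$x, .data$y, orientation = orientation, tol = tol),
    green_contrast = abs(.data$e_green - 0.5)
  )
  out
}

#' Hue angle of a hexagon locus
#'
#' Angle of the direction from the hexagon centre to a locus, in degrees in
#' \[0, 360), with 0 at vertical-up (+y). The default clockwise orientation
#' puts the green vertex at 120 degrees.
#'
#' @param x,y Hexagon coordinates.
#' @param orientation `"clockwise"` or `"counterclockwise"`.
#' @param tol Radius below which the angle is undefined (`NA`).
#' @return Numeric vector of angles in degrees; `NA` at the centre.
#' @export
color_angle <- function(x, y, orientation = c("clockwise", "counterclockwise"),
                        tol = 1e-6) {
  orientation <- match.arg(orientation)
  ang <- atan2(x, y) * 180 / pi          # clockwise from +y
  if (orientation == "counterclockwise") ang <- -ang
  ang <- ang %% 360
  ang[sqrt(x^2 + y^2) < tol] <- NA_real_
  ang
}

#' Hexagon contrast report for a set of stimuli
#'
#' Runs the full receptor model for every stimulus against a common adapting
#' background and reports loci, centre distances (achromatic contrast in the
#' sense used by the accompanying study design), hue angles, the conventional
#' green-receptor contrast, and all pairwise Euclidean distances between loci
#' (colour distances in hexagon units).
#'
#' @inheritParams quantum_catch
#' @inheritParams hexagon_locus
#' @return A tibble of class `bee_loci` with one row per stimulus (`name`,
#'   `x`, `y`, `center_distance`, `angle_deg`, `green_contrast`, plus the
#'   catch and excitation columns). The pairwise distance table is attached
#'   as attribute `"pairwise"` and returned by [hexagon_distances()].
#' @examples
#' sp <- gen_cardboard_spectra()
#' loci <- contrast_report(sp, background = "green_background")
#' hexagon_distances(loci)
#' @export
contrast_report <- function(spectra, background,
                            illuminant = illuminant_d65(spectra$wavelength_nm),
                            receptors = bee_receptors(spectra$wavelength_nm),
                            orientation = c("clockwise", "counterclockwise")) {
  orientation <- match.arg(orientation)
  loci <- quantum_catch(spectra, background, illuminant, receptors) |>
    excitation() |>
    hexagon_locus(orientation = orientation)
  pw <- pairwise_distances(loci)
  attr(loci, "pairwise") <- pw
  class(loci) <- c("bee_loci", class(loci))
  loci
}

pairwise_distances <- function(loci) {
  n <- nrow(loci)
  if (n < 2) {
    return(tibble::tibble(name_a = character(), name_b = character(),
                          distance = numeric()))
  }
  idx <- utils::combn(n, 2)
  tibble::tibble(
    name_a = loci$name[idx[1, ]],
    name_b = loci$name[idx[2, ]],
    distance = sqrt((loci$x[idx[1, ]] - loci$x[idx[2, ]])^2 +
                      (loci$y[idx[1, ]] - loci$y[idx[2, ]])^2)
  )
}

#' Pairwise colour distances between hexagon loci
#'
#' @param loci A `bee_loci` tibble from [contrast_report()], or any tibble
#'   with `name`, `x`, `y` columns.
#' @return Tibble with `name_a`, `name_b`, `distance` (hexagon units).
#' @export
hexagon_distances <- function(loci) {
  pw <- attr(loci, "pairwise")
  if (!is.null(pw)) return(pw)
  pairwise_distances(tibble::as_tibble(loci))
}
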