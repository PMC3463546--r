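#' Schematic-eye and model constants
#'
#' Base constants of the pseudophakic schematic eye.  The starting point is
#' the Liou--Brennan finite schematic eye (Liou & Brennan 1997, J Opt Soc Am
#' A 14:1684-1695), whose anatomical layout and media indices this model
#' personalizes: individual biometry and measured corneal elevation replace
#' the schematic cornea and axial distances, while the media, pupil
#' decentration, angle kappa, retinal curvature and photopic weighting stay
#' at the schematic values because they are not measured in routine clinics.
#'
#' All lengths are millimetres, wavelengths micrometres, powers dioptres.
#'
#' @format A named list:
#' \describe{
#'   \item{n_cornea, n_aqueous, n_vitreous}{refractive indices at 0.555 um
#'     (1.376, 1.336, 1.336).}
#'   \item{cornea_anterior_radius, cornea_anterior_Q}{schematic anterior
#'     cornea: 7.77 mm, Q = -0.18 (used as synthetic-topography defaults).}
#'   \item{cornea_posterior_radius, cornea_posterior_Q}{schematic posterior
#'     cornea: 6.40 mm, Q = -0.60.}
#'   \item{cornea_thickness}{schematic central corneal thickness, 0.50 mm.}
#'   \item{pupil_diameter}{stop diameter, 4.0 mm (photopic refraction
#'     conditions).}
#'   \item{pupil_decentration}{pupil decentred 0.5 mm from the optical
#'     axis (nasal, +x by convention).}
#'   \item{kappa_deg}{angle between visual and optical axis, 5 degrees,
#'     same meridian as the decentration.}
#'   \item{retina_radius}{spherical retina, 12 mm radius of curvature,
#'     concave towards the pupil.}
#'   \item{sc_alpha}{Stiles-Crawford apodization coefficient, 0.05 /mm^2.}
#'   \item{wavelengths, spectral_weights}{photopic sampling 0.510, 0.555,
#'     0.610 um with relative weights 1, 2, 1.}
#'   \item{equator_fraction}{fraction of lens thickness from the lens front
#'     to its equator, 0.395, used to place the IOL.}
#' }
#' @export
eye_constants <- list(
  n_cornea                = 1.376,
  n_aqueous               = 1.336,
  n_vitreous              = 1.336,
  cornea_anterior_radius  = 7.77,
  cornea_anterior_Q       = -0.18,
  cornea_posterior_radius = 6.40,
  cornea_posterior_Q      = -0.60,
  cornea_thickness        = 0.50,
  pupil_diameter          = 4.0,
  pupil_decentration      = 0.5,
  kappa_deg               = 5.0,
  retina_radius           = 12.0,
  sc_alpha                = 0.05,
  wavelengths             = c(0.510, 0.555, 0.610),
  spectral_weights        = c(1, 2, 1),
  equator_fraction        = 0.395
)

#' Optical medium with chromatic dispersion
#'
#' @param name character label.
#' @param n_555 refractive index at the 0.555 um photopic anchor; must lie
#'   in [1.0, 1.6).
#' @param dispersive apply the ocular dispersion polynomial (default
#'   `TRUE`); use `FALSE` for air/vacuum, whose index is constant.
#' @return An object of class `medium`.
#' @seealso [refractive_index()]
#' @export
medium <- function(name, n_555, dispersive = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(n_555) || length(n_555) != 1L || n_555 < 1.0 || n_555 >= 1.6)
    stop("n_555 must be a single number in [1.0, 1.6), got ", n_555)
  structure(list(name = name, n_555 = n_555, dispersive = isTRUE(dispersive)),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s, n(0.555 um) = %.4f\n", x$name, x$n_555))
  invisible(x)
}

#' Refractive index of an ocular medium at a given wavelength
#'
#' All ocular media share one empirical dispersion polynomial added to the
#' medium's index at the 0.555 um anchor:
#' `n(lambda) = n_555 + 0.0512 - 0.1455*lambda + 0.0961*lambda^2`
#' (lambda in micrometres).  The polynomial has a small residual of
#' +4.9e-5 at the 0.555 um anchor itself; it is kept as published and not
#' renormalized, so `refractive_index(m, 0.555)` is `n_555 + 4.9e-5`,
#' not exactly `n_555`.
#'
#' @param med a [medium()] object (or a bare numeric n_555).
#' @param wavelength wavelength in micrometres, within [0.4, 0.75]
#'   (the visible range over which the fit is valid).
#' @return refractive index (vectorized over `wavelength`).
#' @examples
#' aq <- medium("aqueous", 1.336)
#' refractive_index(aq, 0.510) > refractive_index(aq, 0.610)  # normal dispersion
#' @export
refractive_index <- function(med, wavelength) {
  n_555 <- if (inherits(med, "medium")) med$n_555 else med
  stopifnot(is.numeric(n_555), is.numeric(wavelength))
  if (any(wavelength < 0.4 | wavelength > 0.75))
    stop("wavelength outside the dispersion fit validity range [0.4, 0.75] um")
  if (inherits(med, "medium") && !med$dispersive)
    return(rep_len(n_555, length(wavelength)))
  n_555 + 0.0512 - 0.1455 * wavelength + 0.0961 * wavelength^2
}

#' Stiles-Crawford apodization weight
#'
#' Rays entering near the pupil margin contribute less to the photopic
#' retinal image than rays through the pupil centre.  The directional
#' sensitivity is modelled as an intensity apodization of the pupil,
#' `I(r) = 10^(-(alpha/2) r^2)` with `alpha = 0.05` and `r` the radial
#' distance from the pupil centre in mm.
#'
#' @param r radial distance from the pupil centre, mm, >= 0 (vectorized).
#' @param alpha apodization coefficient (default 0.05); 0 disables
#'   apodization.
#' @return intensity weight in (0, 1].
#' @examples
#' stiles_crawford_weight(2)   # 10^-0.1 = 0.7943
#' @export
stiles_crawford_weight <- function(r, alpha = eye_constants$sc_alpha) {
  stopifnot(is.numeric(r))
  if (any(r < 0)) stop("radial distance r must be non-negative")
  10^(-(alpha / 2) * r^2)
}

#' Photopic spectral weighting
#'
#' Receptor photopic sensitivity is approximated by three wavelengths,
#' 510, 555 and 610 nm, with relative weights 1, 2 and 1.  Weights are
#' normalized to sum to one on use.
#'
#' @param wavelengths wavelengths in micrometres.
#' @param weights positive relative weights, same length.
#' @return An object of class `spectral_weighting` with normalized weights.
#' @export
spectral_weighting <- function(wavelengths = eye_constants$wavelengths,
                               weights = eye_constants$spectral_weights) {
  stopifnot(length(wavelengths) == length(weights), all(weights > 0),
            all(wavelengths > 0))
  structure(list(wavelengths = wavelengths, weights = weights / sum(weights)),
            class = "spectral_weighting")
}
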