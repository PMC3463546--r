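#' Ocular biometry for one eye
#'
#' Pre-operative axial biometry.  Anterior chamber depth is measured from
#' the corneal endothelium to the crystalline lens front.  The eye's axial
#' length is the sum `corneal_thickness + acd_pre + lens_thickness +
#' vitreous_depth`.
#'
#' @param acd_pre anterior chamber depth, mm (endothelium to lens).
#' @param lens_thickness crystalline lens thickness, mm.
#' @param vitreous_depth vitreous chamber depth, mm.
#' @param corneal_thickness central corneal thickness, mm; if missing, the
#'   schematic 0.5 mm is used and the object is flagged.
#' @param keratometric_radius optional keratometric radius, mm, carried for
#'   comparator formulas.
#' @param bounds validation bounds, a list with `acd = c(lo, hi)` and
#'   `lt = c(lo, hi)`.
#' @return An object of class `biometry`; `axial_length` is precomputed.
#' @examples
#' b <- biometry(3.04, 3.87, 16.96, 0.55)
#' b$axial_length  # 24.42
#' @export
biometry <- function(acd_pre, lens_thickness, vitreous_depth,
                     corneal_thickness = NULL, keratometric_radius = NULL,
                     bounds = list(acd = c(1.5, 5.5), lt = c(2.5, 6.0))) {
  cct_assumed <- is.null(corneal_thickness)
  if (cct_assumed) corneal_thickness <- eye_constants$cornea_thickness
  vals <- c(acd_pre, lens_thickness, vitreous_depth, corneal_thickness)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all biometry values must be positive and finite")
  if (acd_pre < bounds$acd[1] || acd_pre > bounds$acd[2])
    stop(sprintf("acd_pre = %.2f mm outside plausible bounds (%.1f, %.1f)",
                 acd_pre, bounds$acd[1], bounds$acd[2]))
  if (lens_thickness < bounds$lt[1] || lens_thickness > bounds$lt[2])
    stop(sprintf("lens_thickness = %.2f mm outside plausible bounds (%.1f, %.1f)",
                 lens_thickness, bounds$lt[1], bounds$lt[2]))
  structure(list(acd_pre = acd_pre, lens_thickness = lens_thickness,
                 vitreous_depth = vitreous_depth,
                 corneal_thickness = corneal_thickness,
                 cct_assumed = cct_assumed,
                 keratometric_radius = keratometric_radius,
                 axial_length = corneal_thickness + acd_pre +
                   lens_thickness + vitreous_depth),
            class = "biometry")
}

#' @export
print.biometry <- function(x, ...) {
  cat(sprintf(
    "<biometry> ACD %.2f, LT %.2f, VD %.2f, CCT %.2f%s -> AL %.2f mm\n",
    x$acd_pre, x$lens_thickness, x$vitreous_depth, x$corneal_thickness,
    if (x$cct_assumed) " (assumed)" else "", x$axial_length))
  invisible(x)
}

#' Estimate the post-operative anterior chamber depth
#'
#' The IOL optic is assumed to settle at the equator of the removed
#' crystalline lens, a fraction 0.395 of the lens thickness behind the lens
#' front: `ACD_post = ACD + 0.395 * LT`, measured from the corneal
#' endothelium to the anterior IOL surface.  The estimate uses individual
#' biometry only, with no population regression term.
#'
#' @param acd_pre pre-operative ACD, mm (endothelium to lens front).
#' @param lens_thickness crystalline lens thickness, mm.
#' @return estimated ACD_post, mm (vectorized).
#' @examples
#' estimate_acd_post(3.04, 3.87)  # 4.569
#' @export
estimate_acd_post <- function(acd_pre, lens_thickness) {
  stopifnot(is.numeric(acd_pre), is.numeric(lens_thickness))
  if (any(acd_pre <= 0) || any(lens_thickness < 0))
    stop("acd_pre must be positive and lens_thickness non-negative")
  acd_pre + eye_constants$equator_fraction * lens_thickness
}

#' Thick-lens power of an IOL in aqueous
#'
#' `P = (n - n_aq) (1/R1 - 1/R2) + (n - n_aq)^2 t / (n R1 R2)`, radii in
#' mm, power in dioptres.  Sign convention: positive radius = centre of
#' curvature towards the retina, so a biconvex lens has `R1 > 0 > R2`.
#'
#' @param anterior_radius,posterior_radius surface radii, mm (`Inf` = flat).
#' @param thickness central thickness, mm.
#' @param n lens refractive index at 0.555 um.
#' @param n_medium surrounding index (default aqueous, 1.336).
#' @return power in dioptres.
#' @export
thick_lens_power <- function(anterior_radius, posterior_radius, thickness,
                             n, n_medium = eye_constants$n_aqueous) {
  c1 <- ifelse(is.infinite(anterior_radius), 0, 1 / anterior_radius)
  c2 <- ifelse(is.infinite(posterior_radius), 0, 1 / posterior_radius)
  dn <- n - n_medium
  1000 * (dn * (c1 - c2) + dn^2 * thickness * c1 * c2 / n)
}

#' Construct an IOL design
#'
#' @param labeled_power labeled power, dioptres.
#' @param anterior_radius,posterior_radius surface radii, mm.
#' @param thickness central thickness, mm.
#' @param n_555 lens index at 0.555 um.
#' @param asphericity per-surface conic constants, length-2 (default 0, 0:
#'   spherical optics).
#' @return An object of class `iol_design`.  The geometry must reproduce
#'   the labeled power in aqueous within 0.25 D (manufacturing tolerance),
#'   otherwise an error.
#' @seealso [iol_from_power()] to solve the geometry from a labeled power.
#' @export
iol_design <- function(labeled_power, anterior_radius, posterior_radius,
                       thickness, n_555, asphericity = c(0, 0)) {
  stopifnot(thickness > 0, length(asphericity) == 2)
  P <- thick_lens_power(anterior_radius, posterior_radius, thickness, n_555)
  if (abs(P - labeled_power) > 0.25)
    stop(sprintf(
      "geometry gives %.3f D, labeled %.2f D: outside the 0.25 D tolerance",
      P, labeled_power))
  structure(list(labeled_power = labeled_power,
                 anterior_radius = anterior_radius,
                 posterior_radius = posterior_radius,
                 thickness = thickness, n_555 = n_555,
                 asphericity = asphericity),
            class = "iol_design")
}

#' @export
print.iol_design <- function(x, ...) {
  cat(sprintf(
    "<iol_design> %.2f D: R1 %.3f / R2 %.3f mm, t %.2f mm, n %.3f\n",
    x$labeled_power, x$anterior_radius, x$posterior_radius, x$thickness,
    x$n_555))
  invisible(x)
}

#' Solve IOL geometry from a labeled power
#'
#' The IOL is parameterized by its labeled power plus a family
#' configuration (shape factor, thickness, index); surface radii are solved
#' exactly from the thick-lens equation in aqueous at 0.555 um.  The
#' Coddington shape factor `X = (R2 + R1) / (R2 - R1)` is 0 for an
#' equiconvex lens (the default family), +1 plano-convex (flat back),
#' -1 convex-plano.
#'
#' @param labeled_power power in dioptres; 0 yields a plane parallel plate.
#' @param shape_factor Coddington shape factor (default 0).
#' @param thickness optic thickness, mm (default 1.0).
#' @param n_555 optic index at 0.555 um (default 1.47, a typical acrylic).
#' @param power_range admissible labeled powers (default 5 to 35 D);
#'   widen to pass special designs such as plano lenses.
#' @return An [iol_design()].
#' @export
iol_from_power <- function(labeled_power, shape_factor = 0, thickness = 1.0,
                           n_555 = 1.47, power_range = c(5, 35)) {
  if (labeled_power != 0 &&
      (labeled_power < power_range[1] || labeled_power > power_range[2]))
    stop(sprintf("labeled power %.2f D outside the family range [%g, %g] D",
                 labeled_power, power_range[1], power_range[2]))
  na <- eye_constants$n_aqueous
  dn <- n_555 - na
  if (labeled_power == 0)
    return(iol_design(0, Inf, Inf, thickness, n_555))
  X <- shape_factor
  if (abs(X + 1) < 1e-12) {         # convex-plano: R2 flat
    R1 <- 1000 * dn / labeled_power
    return(iol_design(labeled_power, R1, Inf, thickness, n_555))
  }
  k <- (X - 1) / (X + 1)            # 1/R2 = k / R1
  P <- labeled_power / 1000         # mm^-1
  a2 <- dn^2 * thickness * k / n_555
  a1 <- dn * (1 - k)
  if (abs(a2) < 1e-15) {
    u <- P / a1
  } else {
    disc <- a1^2 + 4 * a2 * P
    if (disc < 0) stop("no real lens geometry for this power/shape/thickness")
    r1 <- (-a1 + sqrt(disc)) / (2 * a2)
    r2 <- (-a1 - sqrt(disc)) / (2 * a2)
    u0 <- P / a1                    # thin-lens curvature
    u <- if (abs(r1 - u0) < abs(r2 - u0)) r1 else r2
  }
  R1 <- 1 / u
  R2 <- if (abs(k) < 1e-15) Inf else R1 / k
  iol_design(labeled_power, R1, R2, thickness, n_555)
}

#' Assemble a personalized pseudophakic eye
#'
#' Positions the optical surfaces of a post-cataract eye along the optical
#' axis (+z towards the retina, anterior corneal vertex at 0):
#' anterior cornea (measured spline surface), posterior cornea (spline,
#' vertex at the corneal thickness), pupil stop and IOL at the estimated
#' post-operative chamber depth ([estimate_acd_post()]), and a spherical
#' retina whose apex sits at the biometric axial length.  The pupil is a
#' 4.0 mm stop decentred 0.5 mm, and the incoming beam makes the 5 degree
#' angle kappa with the optical axis, both in the +x meridian by default.
#'
#' @param anterior,posterior [fit_surface()] corneal surfaces (posterior
#'   may be `NULL`: a schematic posterior cornea, 6.40 mm / Q = -0.60, is
#'   then used).
#' @param biom a [biometry()] object.
#' @param iol an [iol_design()].
#' @param settings named list overriding defaults: `pupil_diameter` (4),
#'   `pupil_decentration` (0.5 mm), `kappa_deg` (5), `retina_radius` (12),
#'   `iris_offset` (0 = stop at the IOL front vertex), `stiles_crawford`
#'   (TRUE), `sc_alpha` (0.05), `acd_post` (override of the estimate).
#' @return An object of class `pseudophakic_eye` holding the ordered
#'   surface list, media, stop geometry and retina.
#' @export
build_pseudophakic_eye <- function(anterior, posterior = NULL, biom, iol,
                                   settings = list()) {
  stopifnot(inherits(anterior, "corneal_surface"), inherits(biom, "biometry"),
            inherits(iol, "iol_design"))
  def <- list(pupil_diameter = eye_constants$pupil_diameter,
              pupil_decentration = eye_constants$pupil_decentration,
              kappa_deg = eye_constants$kappa_deg,
              retina_radius = eye_constants$retina_radius,
              iris_offset = 0,
              stiles_crawford = TRUE,
              sc_alpha = eye_constants$sc_alpha,
              acd_post = NULL)
  unknown <- setdiff(names(settings), names(def))
  if (length(unknown)) stop("unknown settings: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, settings)

  cct <- biom$corneal_thickness
  acd_post <- cfg$acd_post %||%
    estimate_acd_post(biom$acd_pre, biom$lens_thickness)
  z_iol <- cct + acd_post
  z_ret <- biom$axial_length
  # the stop defaults to the IOL front vertex; keep it numerically just
  # before the vertex so an axial ray cannot intersect both at t = 0
  z_stop <- z_iol - max(cfg$iris_offset, 1e-9)

  if (is.null(posterior)) {
    post_grid <- synth_conic_grid(eye_constants$cornea_posterior_radius,
                                  eye_constants$cornea_posterior_Q,
                                  surface_label = "posterior")
    posterior <- fit_surface(post_grid, vertex_position = cct)
  }
  anterior$vertex_position <- 0
  posterior$vertex_position <- cct

  if (!(0 < cct && cct < z_stop && z_stop <= z_iol &&
        z_iol + iol$thickness < z_ret))
    stop(sprintf(
      "surface ordering violated: cornea %.2f, stop %.2f, IOL %.2f-%.2f, retina %.2f mm",
      cct, z_stop, z_iol, z_iol + iol$thickness, z_ret))

  air      <- medium("air", 1.0, dispersive = FALSE)
  cornea   <- medium("cornea", eye_constants$n_cornea)
  aqueous  <- medium("aqueous", eye_constants$n_aqueous)
  lens     <- medium("IOL", iol$n_555)
  vitreous <- medium("vitreous", eye_constants$n_vitreous)

  a_iol <- 3.0  # IOL optic semi-diameter (6 mm optic)
  surfaces <- list(
    list(kind = "spline", surface = anterior, z = 0,
         n_in = air, n_out = cornea, label = "cornea_anterior"),
    list(kind = "spline", surface = posterior, z = cct,
         n_in = cornea, n_out = aqueous, label = "cornea_posterior"),
    list(kind = "stop", z = z_stop,
         center = c(cfg$pupil_decentration, 0),
         radius = cfg$pupil_diameter / 2,
         n_in = aqueous, n_out = aqueous, label = "pupil_stop"),
    list(kind = "conic", R = iol$anterior_radius, Q = iol$asphericity[1],
         z = z_iol, aperture = a_iol,
         n_in = aqueous, n_out = lens, label = "iol_front"),
    list(kind = "conic", R = iol$posterior_radius, Q = iol$asphericity[2],
         z = z_iol + iol$thickness, aperture = a_iol,
         n_in = lens, n_out = vitreous, label = "iol_back"),
    list(kind = "conic", R = -cfg$retina_radius, Q = 0,
         z = z_ret, aperture = cfg$retina_radius * 0.95,
         n_in = vitreous, n_out = vitreous, label = "retina"))

  structure(list(surfaces = surfaces,
                 pupil_diameter = cfg$pupil_diameter,
                 pupil_center = c(cfg$pupil_decentration, 0),
                 stop_z = z_stop,
                 kappa_deg = cfg$kappa_deg,
                 retina_radius = cfg$retina_radius,
                 retina_z = z_ret,
                 axial_length = z_ret,
                 acd_post = acd_post,
                 stiles_crawford = cfg$stiles_crawford,
                 sc_alpha = cfg$sc_alpha,
                 biometry = biom, iol = iol),
            class = "pseudophakic_eye")
}

#' @export
print.pseudophakic_eye <- function(x, ...) {
  cat(sprintf(
    "<pseudophakic_eye> AL %.2f mm, IOL %.2f D at ACDpost %.2f mm, pupil %.1f mm\n",
    x$axial_length, x$iol$labeled_power, x$acd_post, x$pupil_diameter))
  cat(sprintf("  decentration %.2f mm, kappa %.1f deg, retina R %.1f mm\n",
              x$pupil_center[1], x$kappa_deg, x$retina_radius))
  invisible(x)
}
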