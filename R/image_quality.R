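#' Pupil function from a trace
#'
#' Reconstructs the complex pupil function on the bundle's pupil grid.
#' The wavefront error is the per-ray optical path length minus the
#' best-fit piston-and-tilt reference, i.e. the reference sphere is
#' centred on the retinal chief-ray point (tilt carries no image-quality
#' information; defocus and higher aberrations remain).  Amplitude is the
#' square root of the ray's intensity weight (Stiles-Crawford apodization),
#' zero for lost rays and outside the pupil circle.
#'
#' @param tr a completed [trace_rays()] result.
#' @param eye the traced eye (geometry for image-space scaling).
#' @return An object of class `pupil_function`: `amplitude` and
#'   `wavefront` (mm) matrices over the pupil grid, grid pitch `du` (mm),
#'   `wavelength` (um), image-space index `n_image`, reference distance
#'   `R_ref` (exit pupil to retina, mm), and `pupil_radius` (mm).
#' @export
pupil_function <- function(tr, eye) {
  stopifnot(inherits(tr, "trace_result"), inherits(eye, "pseudophakic_eye"))
  frac <- sum(tr$alive) / length(tr$alive)
  if (frac < 0.8)
    stop(sprintf("only %.0f%% of rays survived; pupil function unreliable",
                 100 * frac))
  ng <- tr$grid_density
  ok <- tr$alive
  ux <- tr$u[, 1]; uy <- tr$u[, 2]
  # piston + tilt reference (least squares over surviving rays)
  fit <- stats::lm.fit(cbind(1, ux[ok], uy[ok]), tr$opd[ok])
  W <- tr$opd - cbind(1, ux, uy) %*% fit$coefficients
  A_full <- matrix(0, ng, ng)
  W_full <- matrix(0, ng, ng)
  A_full[tr$grid_index] <- ifelse(ok, sqrt(tr$weight), 0)
  W_full[tr$grid_index] <- ifelse(ok, W, 0)
  a <- tr$pupil_radius
  nim <- refractive_index(medium("vitreous", eye_constants$n_vitreous),
                          tr$wavelength)
  structure(list(amplitude = A_full, wavefront = W_full,
                 du = 2 * a / (ng - 1), n = ng,
                 pupil_radius = a,
                 wavelength = tr$wavelength,
                 n_image = nim,
                 R_ref = eye$retina_z - eye$stop_z,
                 survival = frac),
            class = "pupil_function")
}

#' Synthetic pupil function
#'
#' Builds an ideal (or analytically aberrated) pupil function without ray
#' tracing: uniform or apodized amplitude over a circular pupil and a
#' caller-supplied wavefront.  Used for closed-form checks (Airy pattern,
#' pure defocus) and as a building block in tests.
#'
#' @param n grid nodes per axis.
#' @param pupil_radius semi-diameter, mm.
#' @param wavelength um.
#' @param R_ref exit pupil to image distance, mm.
#' @param n_image image-space refractive index.
#' @param wavefront_fn `function(x, y)` returning wavefront error in mm
#'   (default 0).
#' @param apodize_alpha Stiles-Crawford alpha (0 = uniform amplitude).
#' @return a `pupil_function`.
#' @export
ideal_pupil_function <- function(n = 64, pupil_radius = 2,
                                 wavelength = 0.555, R_ref = 20,
                                 n_image = 1.0,
                                 wavefront_fn = NULL, apodize_alpha = 0) {
  u <- seq(-pupil_radius, pupil_radius, length.out = n)
  X <- matrix(u, n, n, byrow = TRUE); Y <- matrix(u, n, n)
  inside <- X^2 + Y^2 <= pupil_radius^2 + 1e-12
  A <- matrix(0, n, n)
  A[inside] <- if (apodize_alpha > 0)
    sqrt(stiles_crawford_weight(sqrt(X^2 + Y^2)[inside], apodize_alpha))
  else 1
  W <- matrix(0, n, n)
  if (!is.null(wavefront_fn)) W[inside] <- wavefront_fn(X[inside], Y[inside])
  structure(list(amplitude = A, wavefront = W,
                 du = 2 * pupil_radius / (n - 1), n = n,
                 pupil_radius = pupil_radius,
                 wavelength = wavelength, n_image = n_image,
                 R_ref = R_ref, survival = 1),
            class = "pupil_function")
}

# Image-plane sampling pitch (mm) of the FFT of a pupil function.
.psf_pitch <- function(pf, n_fft) {
  lambda_med <- pf$wavelength * 1e-3 / pf$n_image
  lambda_med * pf$R_ref / (n_fft * pf$du)
}

#' Polychromatic point spread function
#'
#' Incoherent PSF per wavelength via the squared magnitude of the Fourier
#' transform of the pupil function, interpolated onto a common image-plane
#' grid and combined with the photopic weights (1, 2, 1 by default).
#'
#' @param pfs list of `pupil_function`s, one per wavelength, identical
#'   grids.
#' @param weights relative weights, recycled to `length(pfs)` and
#'   normalized.
#' @param pad zero-padding factor for the FFT (default 4).
#' @return An object of class `psf`: `intensity` (normalized to unit sum),
#'   `pitch` (mm/sample), `wavelengths`, and the per-wavelength components.
#' @export
psf_polychromatic <- function(pfs, weights = eye_constants$spectral_weights,
                              pad = 4) {
  if (inherits(pfs, "pupil_function")) pfs <- list(pfs)
  stopifnot(length(pfs) >= 1)
  ns <- vapply(pfs, function(p) p$n, 0)
  dus <- vapply(pfs, function(p) p$du, 0)
  if (length(unique(ns)) != 1 || diff(range(dus)) > 1e-12)
    stop("pupil functions have mismatched sampling")
  weights <- rep_len(weights, length(pfs))
  weights <- weights / sum(weights)
  n <- ns[1]; N <- pad * n
  comp <- vector("list", length(pfs))
  pitches <- numeric(length(pfs))
  for (i in seq_along(pfs)) {
    pf <- pfs[[i]]
    lam_mm <- pf$wavelength * 1e-3 / pf$n_image
    P <- matrix(0 + 0i, N, N)
    P[1:n, 1:n] <- pf$amplitude * exp(2i * pi * pf$wavefront / lam_mm)
    psf <- Mod(stats::fft(P))^2
    # centre the DC term
    psf <- psf[c((N / 2 + 1):N, 1:(N / 2)), c((N / 2 + 1):N, 1:(N / 2))]
    comp[[i]] <- psf / sum(psf)
    pitches[i] <- .psf_pitch(pf, N)
  }
  # resample side wavelengths onto the reference (first) grid
  ref <- 1L
  ax <- (seq_len(N) - (N / 2 + 1)) * pitches[ref]
  total <- matrix(0, N, N)
  for (i in seq_along(comp)) {
    if (abs(pitches[i] - pitches[ref]) < 1e-15) {
      res <- comp[[i]]
    } else {
      src <- (seq_len(N) - (N / 2 + 1)) * pitches[i]
      gi <- findInterval(ax, src, all.inside = TRUE)
      w1 <- (ax - src[gi]) / (src[gi + 1] - src[gi])
      w1 <- pmin(pmax(w1, 0), 1)
      rows <- comp[[i]][gi, , drop = FALSE] * (1 - w1) +
        comp[[i]][pmin(gi + 1, N), , drop = FALSE] * w1
      res <- rows[, gi, drop = FALSE] * rep(1 - w1, each = N) +
        rows[, pmin(gi + 1, N), drop = FALSE] * rep(w1, each = N)
      res <- res / sum(res)
    }
    total <- total + weights[i] * res
  }
  structure(list(intensity = total / sum(total), pitch = pitches[ref],
                 axis = ax,
                 wavelengths = vapply(pfs, function(p) p$wavelength, 0),
                 weights = weights),
            class = "psf")
}

#' MTF from a point spread function
#'
#' Modulation transfer as the magnitude of the PSF's Fourier transform,
#' normalized to 1 at zero frequency.  The radial summary is the mean of
#' the two principal meridians (+x, +y).
#'
#' @param psf a [psf_polychromatic()] result.
#' @return An object of class `mtf_curve`: `frequency` (cycles/mm),
#'   `modulation`, `orientation = "meridian-mean"`.
#' @export
mtf_from_psf <- function(psf) {
  stopifnot(inherits(psf, "psf"))
  I <- psf$intensity
  N <- nrow(I)
  OTF <- stats::fft(I[c((N / 2 + 1):N, 1:(N / 2)), c((N / 2 + 1):N, 1:(N / 2))])
  M <- Mod(OTF) / Mod(OTF[1, 1])
  nf <- floor(N / 2)
  freq <- (0:(nf - 1)) / (N * psf$pitch)
  mx <- M[1, 1:nf]         # variation along columns = x meridian
  my <- M[1:nf, 1]
  mtf_curve(freq, (mx + my) / 2)
}

#' Construct an MTF curve
#'
#' @param frequency cycles/mm on the retina, non-negative, increasing.
#' @param modulation modulation in [0, 1] (tiny numerical overshoots are
#'   clipped).
#' @param orientation descriptive tag (default `"meridian-mean"`).
#' @return object of class `mtf_curve`.
#' @export
mtf_curve <- function(frequency, modulation, orientation = "meridian-mean") {
  stopifnot(length(frequency) == length(modulation), all(diff(frequency) > 0),
            frequency[1] >= 0)
  modulation <- pmin(pmax(modulation, 0), 1)
  structure(list(frequency = frequency, modulation = modulation,
                 orientation = orientation),
            class = "mtf_curve")
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> %d frequencies, %.1f-%.1f cycles/mm (%s)\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$orientation))
  invisible(x)
}

#' @export
plot.mtf_curve <- function(x, ...) {
  graphics::plot(x$frequency, x$modulation, type = "l",
                 xlab = "spatial frequency (cycles/mm)",
                 ylab = "modulation", ylim = c(0, 1), ...)
  invisible(x)
}

#' Diffraction-limited MTF of a circular pupil
#'
#' Closed form for an aberration-free circular aperture:
#' `MTF(nu) = (2/pi) (phi - cos(phi) sin(phi))`, `phi = arccos(nu/nu_c)`,
#' zero above the incoherent cutoff `nu_c = 2 NA / lambda`.  The
#' polychromatic limit is the (1, 2, 1)-weighted mean of the monochromatic
#' curves.
#'
#' @param frequency cycles/mm (vector).
#' @param wavelength wavelength(s), um.
#' @param na image-space numerical aperture(s); if `NULL`, computed
#'   paraxially as `n_image * pupil_diameter / (2 R_ref)`.
#' @param pupil_diameter,R_ref,n_image geometry used when `na` is `NULL`.
#' @param weights spectral weights when several wavelengths are given.
#' @return an [mtf_curve()].
#' @examples
#' # value at half cutoff is 2/pi (pi/3 - cos60 sin60) = 0.3910
#' @export
diffraction_limited_mtf <- function(frequency, wavelength = 0.555, na = NULL,
                                    pupil_diameter = 4, R_ref = 20,
                                    n_image = eye_constants$n_vitreous,
                                    weights = NULL) {
  stopifnot(all(frequency >= 0))
  if (is.null(na)) na <- n_image * pupil_diameter / (2 * R_ref)
  na <- rep_len(na, length(wavelength))
  weights <- if (is.null(weights)) rep(1, length(wavelength)) else weights
  weights <- weights / sum(weights)
  mod <- rep(0, length(frequency))
  for (i in seq_along(wavelength)) {
    nu_c <- 2 * na[i] / (wavelength[i] * 1e-3)   # cycles/mm
    x <- pmin(frequency / nu_c, 1)
    phi <- acos(x)
    mod <- mod + weights[i] * (2 / pi) * (phi - cos(phi) * sin(phi))
  }
  mtf_curve(frequency, mod, orientation = "diffraction-limit")
}

#' Contrast sensitivity weights on a retinal frequency grid
#'
#' Neural contrast sensitivity (band-pass, peaking at a few cycles per
#' degree) evaluated on a retinal spatial-frequency grid.  Retinal
#' frequencies convert to angular ones with 0.3 cycles/degree per
#' cycle/mm, anchored at 100 cycles/mm on the retina = 30 cycles/degree =
#' decimal acuity 1.0.  The default parameterization is the
#' Mannos-Sakrison photopic CSF
#' `S(f) = 2.6 (0.0192 + 0.114 f) exp(-(0.114 f)^1.1)` (f in
#' cycles/degree).
#'
#' @param frequency cycles/mm, within [0, 100].
#' @param model `"mannos"` (default) or `"flat"` (uniform weights, for
#'   sensitivity analyses).
#' @param deg_per_mm conversion factor, cycles/degree per cycle/mm
#'   (default 0.3).
#' @return An object of class `csf_weights`: `frequency`, `weight` (>= 0).
#' @export
csf_weights <- function(frequency = seq(0, 100, by = 2),
                        model = c("mannos", "flat"), deg_per_mm = 0.3) {
  model <- match.arg(model)
  if (any(frequency < 0 | frequency > 100 + 1e-9))
    stop("frequency grid must lie within [0, 100] cycles/mm")
  f_deg <- frequency * deg_per_mm
  w <- switch(model,
    mannos = 2.6 * (0.0192 + 0.114 * f_deg) * exp(-(0.114 * f_deg)^1.1),
    flat = rep(1, length(frequency)))
  structure(list(frequency = frequency, weight = pmax(w, 0), model = model,
                 deg_per_mm = deg_per_mm),
            class = "csf_weights")
}

#' CSF-weighted merit of an MTF against the diffraction limit
#'
#' The image-quality score driving IOL selection: the contrast-sensitivity
#' weighted mean squared deviation of the system MTF from the
#' diffraction-limited MTF over 0-100 cycles/mm,
#' `sum_f csf(f) (MTF_DL(f) - MTF(f))^2 / sum_f csf(f)`.
#' Zero for perfect optics; lower is better.  An absolute-difference mode
#' is available.
#'
#' @param mtf system [mtf_curve()].
#' @param dl diffraction-limited [mtf_curve()] on the same frequency grid.
#' @param csf [csf_weights()] on the same grid.
#' @param mode `"squared"` (default) or `"absolute"`.
#' @return non-negative scalar score.
#' @export
merit <- function(mtf, dl, csf, mode = c("squared", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mtf, "mtf_curve"), inherits(dl, "mtf_curve"),
            inherits(csf, "csf_weights"))
  if (length(mtf$frequency) != length(dl$frequency) ||
      max(abs(mtf$frequency - dl$frequency)) > 1e-9 ||
      length(csf$frequency) != length(mtf$frequency) ||
      max(abs(csf$frequency - mtf$frequency)) > 1e-9)
    stop("merit requires mtf, dl and csf on one common frequency grid")
  gap <- dl$modulation - mtf$modulation
  dev <- if (mode == "squared") gap^2 else abs(gap)
  sum(csf$weight * dev) / sum(csf$weight)
}

# ---- efficient system MTF via pupil autocorrelation --------------------

# Complex OTF of one pupil function at retinal frequencies `freq`
# (cycles/mm) along meridian "x" or "y".  OTF(nu) is the normalized
# autocorrelation of the pupil at shift lambda_med * R_ref * nu; amplitude
# and (unwrapped) wavefront are interpolated separately so large defocus
# does not alias.  Mathematically identical to Fourier-transforming the
# PSF, but sampled exactly on the requested frequencies.
.pupil_otf <- function(pf, freq, meridian = c("x", "y")) {
  meridian <- match.arg(meridian)
  lam_mm <- pf$wavelength * 1e-3 / pf$n_image
  shift_mm <- lam_mm * pf$R_ref * freq
  g <- shift_mm / pf$du                    # shift in grid units
  A <- pf$amplitude; W <- pf$wavefront
  if (meridian == "y") { A <- t(A); W <- t(W) }
  n <- ncol(A)
  norm <- sum(A^2)
  out <- complex(length(freq))
  for (k in seq_along(freq)) {
    gk <- g[k]
    j0 <- floor(gk); fr <- gk - j0
    # columns of the shifted field: value at column j comes from j - gk
    jsrc <- seq_len(n) - j0
    v1 <- jsrc >= 1 & jsrc <= n
    v2 <- (jsrc - 1) >= 1 & (jsrc - 1) <= n
    As <- matrix(0, nrow(A), n); Ws <- matrix(0, nrow(A), n)
    if (any(v1)) {
      As[, v1] <- A[, jsrc[v1], drop = FALSE] * (1 - fr)
      Ws[, v1] <- W[, jsrc[v1], drop = FALSE] * (1 - fr)
    }
    if (any(v2)) {
      As[, v2] <- As[, v2, drop = FALSE] + A[, jsrc[v2] - 1, drop = FALSE] * fr
      Ws[, v2] <- Ws[, v2, drop = FALSE] + W[, jsrc[v2] - 1, drop = FALSE] * fr
    }
    ph <- 2 * pi * (W - Ws) / lam_mm
    re <- sum(A * As * cos(ph)); im <- sum(A * As * sin(ph))
    out[k] <- complex(real = re, imaginary = im) / norm
  }
  out
}

#' Polychromatic system MTF and diffraction limit of an eye
#'
#' Traces the eye at the photopic wavelengths, reconstructs the pupil
#' function per wavelength, and evaluates the polychromatic MTF on a
#' retinal frequency grid.  The per-wavelength complex OTFs (pupil
#' autocorrelation, exactly the Fourier transform of the incoherent PSF)
#' are summed with the photopic weights, which is the OTF of the
#' weighted-sum PSF.  Returns the matching polychromatic diffraction limit
#' computed from the same pupil geometry.
#'
#' @param eye a [build_pseudophakic_eye()].
#' @param frequency retinal frequency grid, cycles/mm (default 0-100 in
#'   steps of 2).
#' @param grid_density pupil ray-grid nodes per axis (default 32).
#' @param sw a [spectral_weighting()].
#' @param front optional cached front bundles from [trace_front()].
#' @param spectacle_power thin trial lens at the spectacle plane, D.
#' @param method `"diffraction"` (pupil autocorrelation, default) or
#'   `"geometric"` (spot-diagram OTF, a cross-check mode that ignores
#'   diffraction).
#' @return list with `mtf`, `dl` ([mtf_curve()]s), `merit_inputs`
#'   diagnostics (per-wavelength survival), and `trace_diag`.
#' @export
eye_mtf <- function(eye, frequency = seq(0, 100, by = 2), grid_density = 36,
                    sw = spectral_weighting(), front = NULL,
                    spectacle_power = 0,
                    method = c("diffraction", "geometric")) {
  method <- match.arg(method)
  nl <- length(sw$wavelengths)
  otf_x <- otf_y <- matrix(0 + 0i, length(frequency), nl)
  dl <- rep(0, length(frequency))
  survival <- numeric(nl)
  snell <- 0
  n_back <- length(eye$surfaces)
  for (i in seq_len(nl)) {
    lam <- sw$wavelengths[i]
    bundle <- if (!is.null(front)) front[[i]] else
      trace_rays(eye, generate_pupil_rays(eye, grid_density = grid_density,
                                     wavelength = lam,
                                     spectacle_power = spectacle_power),
            surface_range = 1:3)
    tr <- trace_rays(eye, bundle, surface_range = 4:n_back)
    snell <- max(snell, tr$snell_residual)
    pf <- pupil_function(tr, eye)
    survival[i] <- pf$survival
    if (method == "diffraction") {
      otf_x[, i] <- .pupil_otf(pf, frequency, "x")
      otf_y[, i] <- .pupil_otf(pf, frequency, "y")
    } else {
      ok <- tr$alive
      w <- tr$weight[ok]
      for (m in 1:2) {
        coord <- if (m == 1) tr$x[ok] else tr$y[ok]
        coord <- coord - stats::weighted.mean(coord, w)
        o <- vapply(frequency, function(f)
          abs(sum(w * exp(-2i * pi * f * coord))) / sum(w), 0)
        if (m == 1) otf_x[, i] <- o else otf_y[, i] <- o
      }
    }
    lam_mm <- lam * 1e-3 / pf$n_image
    nu_c <- 2 * pf$pupil_radius / (lam_mm * pf$R_ref)
    x <- pmin(frequency / nu_c, 1)
    phi <- acos(x)
    dl <- dl + sw$weights[i] * (2 / pi) * (phi - cos(phi) * sin(phi))
  }
  mx <- Mod(otf_x %*% sw$weights)
  my <- Mod(otf_y %*% sw$weights)
  list(mtf = mtf_curve(frequency, (mx + my) / 2),
       dl = mtf_curve(frequency, dl, orientation = "diffraction-limit"),
       survival = survival, snell_residual = snell)
}

#' Cache the corneal leg of a trace for IOL power scans
#'
#' Traces the photopic ray bundles through the cornea and pupil stop only.
#' Everything in front of the IOL is independent of the IOL power, so a
#' power scan can reuse these bundles and re-trace just the IOL and
#' retina.
#'
#' @inheritParams eye_mtf
#' @return list of partially traced bundles, one per wavelength.
#' @export
trace_front <- function(eye, grid_density = 36, sw = spectral_weighting(),
                        spectacle_power = 0) {
  lapply(sw$wavelengths, function(lam)
    trace_rays(eye, generate_pupil_rays(eye, grid_density = grid_density,
                                   wavelength = lam,
                                   spectacle_power = spectacle_power),
          surface_range = 1:3))
}

#' CSF-weighted merit of an eye
#'
#' Convenience wrapper: [eye_mtf()] then [merit()] against the matched
#' diffraction limit with [csf_weights()].
#'
#' @inheritParams eye_mtf
#' @param csf a [csf_weights()] on `frequency` (default Mannos-Sakrison).
#' @param mode merit mode, see [merit()].
#' @return scalar merit score (lower is better).
#' @export
eye_merit <- function(eye, frequency = seq(0, 100, by = 2),
                      grid_density = 36, sw = spectral_weighting(),
                      csf = csf_weights(frequency), front = NULL,
                      spectacle_power = 0, mode = "squared") {
  r <- eye_mtf(eye, frequency, grid_density, sw, front, spectacle_power)
  merit(r$mtf, r$dl, csf, mode)
}
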