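#' Fit a smooth corneal surface to an elevation grid
#'
#' Builds an interpolating bicubic spline surface over the grid: node
#' first-derivative fields are estimated with one-dimensional cubic splines
#' (Forsythe-Malcolm-Moler end conditions) along each grid row and column,
#' and every grid cell carries the bicubic Hermite patch determined by the
#' corner values and derivatives.  The surface passes through every
#' unmasked node exactly, is C1 across cell boundaries, and has analytic
#' partial derivatives, from which surface normals are obtained for ray
#' tracing.
#'
#' Masked corner nodes (outside the circular aperture) are filled with the
#' sag of the best-fitting sphere (or zero for a degenerate plane) before
#' spline fitting; these filler values only support the spline near the rim
#' and evaluation is restricted to the inscribed circle shrunk by one node
#' ring, so they never enter a traced aperture.
#'
#' @param grid an [elevation_grid()].
#' @param vertex_position axial coordinate of the surface apex in eye
#'   coordinates, mm (anterior cornea sits at 0).
#' @return An object of class `corneal_surface`.
#' @examples
#' s <- fit_surface(synth_conic_grid(7.77, -0.18))
#' eval_surface(s, 1, 0)$z       # close to conic_sag(1, 7.77, -0.18)
#' @export
fit_surface <- function(grid, vertex_position = 0) {
  stopifnot(inherits(grid, "elevation_grid"))
  Z <- grid$sag
  n <- nrow(Z)
  # fill masked rim nodes so the rectangular spline is defined everywhere
  if (anyNA(Z)) {
    fill <- .sphere_fill_values(grid)
    Z[is.na(Z)] <- fill[is.na(Z)]
  }
  x <- grid$x; y <- grid$y
  Zx <- t(apply(Z, 1L, function(r) stats::splinefun(x, r, "fmm")(x, deriv = 1)))
  Zy <- apply(Z, 2L, function(cl) stats::splinefun(y, cl, "fmm")(y, deriv = 1))
  Zxy <- apply(Zx, 2L, function(cl) stats::splinefun(y, cl, "fmm")(y, deriv = 1))
  structure(list(Z = Z, Zx = Zx, Zy = Zy, Zxy = Zxy,
                 x = x, y = y, h = grid$spacing,
                 aperture_radius = grid$aperture_diameter / 2 - grid$spacing,
                 vertex_position = vertex_position,
                 surface_label = grid$surface_label),
            class = "corneal_surface")
}

# Best-sphere fill values for masked nodes (plane fallback: 0).
.sphere_fill_values <- function(grid) {
  n <- nrow(grid$sag)
  X <- matrix(grid$x, n, n, byrow = TRUE)
  Y <- matrix(grid$y, n, n)
  ok <- !is.na(grid$sag)
  fit <- tryCatch(
    .sphere_lsq(X[ok], Y[ok], grid$sag[ok]),
    error = function(e) NULL)
  if (is.null(fit)) return(matrix(0, n, n))
  cz <- fit$center[3]; r <- fit$radius
  arg <- r^2 - (X - fit$center[1])^2 - (Y - fit$center[2])^2
  arg[arg < 0] <- 0
  # take the sphere sheet containing the fitted data (apex side)
  if (cz > 0) cz - sqrt(arg) else cz + sqrt(arg)
}

#' @export
print.corneal_surface <- function(x, ...) {
  cat(sprintf(
    "<corneal_surface> %s, vertex z = %.3f mm, usable radius %.2f mm\n",
    x$surface_label, x$vertex_position, x$aperture_radius))
  invisible(x)
}

# Vectorized bicubic Hermite evaluation. Returns list(z, zx, zy); NA for
# query points outside the rectangular grid hull.  No aperture check here:
# callers that expose evaluation to users enforce the aperture.
.bicubic_eval <- function(s, px, py) {
  n <- length(s$x); h <- s$h
  x0 <- s$x[1]; y0 <- s$y[1]
  j <- pmin.int(pmax.int(floor((px - x0) / h) + 1L, 1L), n - 1L)
  i <- pmin.int(pmax.int(floor((py - y0) / h) + 1L, 1L), n - 1L)
  u <- (px - s$x[j]) / h   # along x
  v <- (py - s$y[i]) / h   # along y
  outside <- px < x0 - 1e-12 | px > s$x[n] + 1e-12 |
             py < y0 - 1e-12 | py > s$y[n] + 1e-12
  # corner linear indices (rows = y = i, cols = x = j)
  k00 <- (j - 1L) * n + i        # (i, j)
  k01 <- k00 + n                 # (i, j+1)   x+
  k10 <- k00 + 1L                # (i+1, j)   y+
  k11 <- k01 + 1L
  # Hermite basis (value and slope) and their derivatives, computed once
  u2 <- u * u; v2 <- v * v
  Hu0 <- (1 + 2 * u) * (1 - u)^2; Hu1 <- u2 * (3 - 2 * u)
  Gu0 <- u * (1 - u)^2;           Gu1 <- u2 * (u - 1)
  Hv0 <- (1 + 2 * v) * (1 - v)^2; Hv1 <- v2 * (3 - 2 * v)
  Gv0 <- v * (1 - v)^2;           Gv1 <- v2 * (v - 1)
  dHu0 <- 6 * u2 - 6 * u; dHu1 <- -dHu0
  dGu0 <- 3 * u2 - 4 * u + 1; dGu1 <- 3 * u2 - 2 * u
  dHv0 <- 6 * v2 - 6 * v; dHv1 <- -dHv0
  dGv0 <- 3 * v2 - 4 * v + 1; dGv1 <- 3 * v2 - 2 * v
  # per-row (y) composites in the x direction
  rowmix <- function(bu0, bu1, gu0, gu1) list(
    z0  = bu0 * s$Z[k00]  + bu1 * s$Z[k01]  + h * (gu0 * s$Zx[k00]  + gu1 * s$Zx[k01]),
    z1  = bu0 * s$Z[k10]  + bu1 * s$Z[k11]  + h * (gu0 * s$Zx[k10]  + gu1 * s$Zx[k11]),
    zy0 = bu0 * s$Zy[k00] + bu1 * s$Zy[k01] + h * (gu0 * s$Zxy[k00] + gu1 * s$Zxy[k01]),
    zy1 = bu0 * s$Zy[k10] + bu1 * s$Zy[k11] + h * (gu0 * s$Zxy[k10] + gu1 * s$Zxy[k11]))
  mv  <- rowmix(Hu0, Hu1, Gu0, Gu1)
  mdu <- rowmix(dHu0, dHu1, dGu0, dGu1)
  z  <- Hv0 * mv$z0 + Hv1 * mv$z1 + h * (Gv0 * mv$zy0 + Gv1 * mv$zy1)
  zx <- (Hv0 * mdu$z0 + Hv1 * mdu$z1 + h * (Gv0 * mdu$zy0 + Gv1 * mdu$zy1)) / h
  zy <- (dHv0 * mv$z0 + dHv1 * mv$z1 + h * (dGv0 * mv$zy0 + dGv1 * mv$zy1)) / h
  if (any(outside)) z[outside] <- zx[outside] <- zy[outside] <- NA_real_
  list(z = z, zx = zx, zy = zy)
}

#' Evaluate a corneal surface (sag and partial derivatives)
#'
#' @param surface a [fit_surface()] result.
#' @param x,y transverse coordinates, mm (vectorized, equal length).
#' @param check_aperture error if any point lies outside the usable
#'   aperture (default `TRUE`).
#' @return list with `z` (sag, mm, relative to the surface vertex plane),
#'   `zx`, `zy` (partial derivatives).
#' @export
eval_surface <- function(surface, x, y, check_aperture = TRUE) {
  stopifnot(inherits(surface, "corneal_surface"), length(x) == length(y))
  if (check_aperture && any(x^2 + y^2 > surface$aperture_radius^2 + 1e-9))
    stop(sprintf("evaluation outside the usable aperture (radius %.3f mm)",
                 surface$aperture_radius))
  .bicubic_eval(surface, x, y)
}

#' Unit normal of a corneal surface
#'
#' Normal of z = sag(x, y), oriented with positive z component.
#'
#' @inheritParams eval_surface
#' @return n x 3 matrix of unit normals.
#' @export
surface_normal <- function(surface, x, y) {
  d <- eval_surface(surface, x, y)
  unitize(cbind(-d$zx, -d$zy, rep(1, length(x))))
}

# Algebraic (Kasa) sphere fit: x^2+y^2+z^2 = 2 c.p + (r^2 - |c|^2).
.sphere_lsq <- function(x, y, z) {
  A <- cbind(2 * x, 2 * y, 2 * z, 1)
  b <- x^2 + y^2 + z^2
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("degenerate surface: sphere fit is singular (plane input?)"))
  c <- sol[1:3]
  r2 <- sol[4] + sum(c^2)
  if (r2 <= 0) stop("degenerate sphere fit")
  list(center = c, radius = sqrt(r2))
}

#' Best-fit sphere of a corneal surface
#'
#' Least-squares sphere through the surface's grid nodes within a fit
#' diameter: an algebraic fit initializes the centre, which is then refined
#' by minimizing the variance of node-to-centre distances (the geometric
#' least-squares criterion with the radius profiled out as the mean
#' distance).  The keratometric analogue of the fitted radius is
#' `337.5 / radius` dioptres.
#'
#' @param surface a [fit_surface()] result.
#' @param fit_diameter diameter of the fit zone, mm; clinical keratometry
#'   samples roughly the central 3 mm (default), while a 10 mm fit
#'   characterizes the whole measured surface.
#' @return An object of class `sphere_fit`: `radius` (mm), `center`
#'   (3-vector, mm, in surface-vertex coordinates), `rms_residual` (mm).
#'   A fit radius beyond 1e4 mm signals a degenerate (planar) input and is
#'   an error.
#' @export
best_fit_sphere <- function(surface, fit_diameter = 3) {
  stopifnot(inherits(surface, "corneal_surface"))
  n <- length(surface$x)
  X <- matrix(surface$x, n, n, byrow = TRUE)
  Y <- matrix(surface$y, n, n)
  keep <- X^2 + Y^2 <= (fit_diameter / 2)^2 + 1e-9 &
          X^2 + Y^2 <= surface$aperture_radius^2 + 1e-9
  x <- X[keep]; y <- Y[keep]; z <- surface$Z[keep]
  if (length(x) < 10) stop("fit zone contains too few nodes")
  if (stats::sd(z) < 1e-12)
    stop("degenerate surface: plane input has no finite best-fit sphere")
  init <- .sphere_lsq(x, y, z)
  obj <- function(c) {
    d <- sqrt((x - c[1])^2 + (y - c[2])^2 + (z - c[3])^2)
    sum((d - mean(d))^2)
  }
  opt <- stats::optim(init$center, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  cen <- opt$par
  d <- sqrt((x - cen[1])^2 + (y - cen[2])^2 + (z - cen[3])^2)
  radius <- mean(d)
  if (radius > 1e4)
    stop("degenerate surface: best-fit sphere radius exceeds 1e4 mm")
  structure(list(radius = radius, center = cen,
                 rms_residual = sqrt(mean((d - radius)^2)),
                 fit_diameter = fit_diameter),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit> R = %.4f mm (K = %.2f D) over %.1f mm, rms %.2e mm\n",
    x$radius, 337.5 / x$radius, x$fit_diameter, x$rms_residual))
  invisible(x)
}
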