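#' Vector Snell refraction
#'
#' Refracts direction vectors at a surface with the given unit normals.
#' The refracted ray lies in the plane of incidence and satisfies
#' `n1 sin(theta1) = n2 sin(theta2)` to machine precision.  Normals may
#' point to either side of the surface; they are re-oriented internally.
#'
#' @param direction unit direction(s): length-3 vector or n x 3 matrix.
#' @param normal unit surface normal(s), same shape.
#' @param n1,n2 refractive indices before/after the surface (scalar or
#'   per-ray).
#' @return For vector input, the refracted unit vector, or `NA`s with
#'   attribute `tir = TRUE` on total internal reflection.  For matrix
#'   input, a list with `d` (n x 3 refracted directions, `NA` rows on TIR)
#'   and `tir` (logical).
#' @examples
#' refract(c(0, 0, 1), c(0, 0, -1), 1.0, 1.336)   # normal incidence
#' @export
refract <- function(direction, normal, n1, n2) {
  single <- is.null(dim(direction))
  d <- if (single) matrix(direction, 1) else direction
  N <- if (single) matrix(normal, 1) else normal
  stopifnot(ncol(d) == 3, all(dim(d) == dim(N)), all(n1 > 0), all(n2 > 0))
  res <- .refract_m(d, N, n1, n2)
  if (single) {
    out <- drop(res$d)
    if (res$tir[1]) attr(out, "tir") <- TRUE
    return(out)
  }
  res
}

.refract_m <- function(d, N, n1, n2) {
  # orient normals against the incoming direction
  dn <- rowSums(d * N)
  N <- N * ifelse(dn > 0, -1, 1)
  cosi <- -rowSums(d * N)
  eta <- n1 / n2
  k <- 1 - eta^2 * (1 - cosi^2)
  tir <- k < 0
  k[tir] <- 0
  t <- d * eta + N * (eta * cosi - sqrt(k))
  t <- t / sqrt(rowSums(t^2))
  t[tir, ] <- NA_real_
  list(d = t, tir = tir)
}

#' Ray-conic intersection
#'
#' Nearest forward intersection of rays with a conic surface
#' `z = vertex_z + conic_sag(h, R, Q)`.  A miss (no real forward root on
#' the apex sheet, or landing outside the aperture) is reported per ray,
#' not an error.
#'
#' @param origin ray origin(s): length-3 vector or n x 3 matrix, mm.
#' @param direction unit direction(s), same shape.
#' @param R apical radius of curvature, mm (signed; `Inf` = plane).
#' @param Q conic asphericity.
#' @param vertex_z axial position of the surface vertex, mm.
#' @param aperture_radius clear semi-diameter, mm.
#' @param t_min minimum acceptable path length (excludes re-hitting the
#'   surface just left).
#' @return list with `t` (path length, `NA` on miss), `point` (n x 3),
#'   `normal` (n x 3 unit normals), `hit` (logical).
#' @export
intersect_conic <- function(origin, direction, R, Q = 0, vertex_z = 0,
                            aperture_radius = Inf, t_min = 1e-9) {
  p <- if (is.null(dim(origin))) matrix(origin, 1) else origin
  d <- if (is.null(dim(direction))) matrix(direction, 1) else direction
  n <- nrow(p)
  w0 <- p[, 3] - vertex_z
  if (is.infinite(R)) {
    t <- -w0 / d[, 3]
    ok <- is.finite(t) & t > t_min
  } else {
    cc <- 1 / R
    q1 <- 1 + Q
    A <- cc * (d[, 1]^2 + d[, 2]^2) + cc * q1 * d[, 3]^2
    B <- 2 * cc * (p[, 1] * d[, 1] + p[, 2] * d[, 2]) +
      2 * cc * q1 * w0 * d[, 3] - 2 * d[, 3]
    C <- cc * (p[, 1]^2 + p[, 2]^2) + cc * q1 * w0^2 - 2 * w0
    t <- rep(NA_real_, n)
    lin <- abs(A) < 1e-14
    t[lin] <- -C[lin] / B[lin]
    disc <- B^2 - 4 * A * C
    qok <- !lin & disc >= 0
    sq <- sqrt(pmax(disc, 0))
    qq <- -(B + sign(B + (B == 0)) * sq) / 2
    t1 <- qq / A
    t2 <- ifelse(abs(qq) > 0, C / qq, NA_real_)
    # accept the smallest forward root on the apex sheet
    pick <- function(tt) {
      w <- w0 + tt * d[, 3]
      ok <- qok & is.finite(tt) & tt > t_min & cc * q1 * w < 1 + 1e-9
      ifelse(ok, tt, Inf)
    }
    tbest <- pmin(pick(t1), pick(t2))
    t[!lin] <- ifelse(is.finite(tbest[!lin]), tbest[!lin], NA_real_)
    t[lin & !(is.finite(t) & t > t_min)] <- NA_real_
    ok <- is.finite(t) & t > t_min
  }
  pt <- p + d * t
  h2 <- pt[, 1]^2 + pt[, 2]^2
  ok <- ok & h2 <= aperture_radius^2 + 1e-9
  if (is.infinite(R)) {
    nrm <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  } else {
    w <- pt[, 3] - vertex_z
    nrm <- unitize(cbind(pt[, 1] / R, pt[, 2] / R, (1 + Q) * w / R - 1))
    # orient consistently with spline normals: positive z component
    nrm <- nrm * sign(nrm[, 3])
  }
  t[!ok] <- NA_real_
  pt[!ok, ] <- NA_real_
  nrm[!ok, ] <- NA_real_
  list(t = t, point = pt, normal = nrm, hit = ok)
}

#' Ray-spline intersection
#'
#' Intersects rays with a bicubic-spline corneal surface by damped Newton
#' iteration on `f(t) = z_ray(t) - vertex - sag(x_ray(t), y_ray(t))`,
#' seeded at the vertex-plane crossing; the derivative uses the spline's
#' analytic partials.  Convergence criterion `|f| < 1e-9` mm.  Rays that
#' leave the usable aperture or fail to converge are reported as misses
#' (never silently kept).
#'
#' @param origin,direction as in [intersect_conic()].
#' @param surface a [fit_surface()] result (its `vertex_position` is the
#'   axial location of the apex).
#' @param t_min minimum acceptable path length.
#' @param max_iter Newton iteration cap (default 40).
#' @return list with `t`, `point`, `normal`, `hit` as in
#'   [intersect_conic()], plus `iterations`.
#' @export
intersect_spline <- function(origin, direction, surface, t_min = 1e-9,
                             max_iter = 40) {
  stopifnot(inherits(surface, "corneal_surface"))
  p <- if (is.null(dim(origin))) matrix(origin, 1) else origin
  d <- if (is.null(dim(direction))) matrix(direction, 1) else direction
  n <- nrow(p)
  vz <- surface$vertex_position
  t <- (vz - p[, 3]) / d[, 3]
  fprev <- rep(Inf, n)
  active <- rep(TRUE, n)
  bad <- rep(FALSE, n)
  it <- 0L
  ev <- NULL
  zx <- zy <- rep(NA_real_, n)
  while (any(active) && it < max_iter) {
    it <- it + 1L
    x <- p[active, 1] + t[active] * d[active, 1]
    y <- p[active, 2] + t[active] * d[active, 2]
    e <- .bicubic_eval(surface, x, y)
    out <- !is.finite(e$z)
    f <- (p[active, 3] + t[active] * d[active, 3]) - vz - e$z
    fp <- d[active, 3] - e$zx * d[active, 1] - e$zy * d[active, 2]
    step <- f / fp
    # damp wild steps (shallow-incidence safety)
    step <- pmax(pmin(step, 2), -2)
    conv <- !out & abs(f) < 1e-9
    idx <- which(active)
    zx[idx] <- e$zx; zy[idx] <- e$zy
    bad[idx[out]] <- TRUE
    active[idx[out | conv]] <- FALSE
    keep <- !(out | conv)
    t[idx[keep]] <- t[idx[keep]] - step[keep]
  }
  bad <- bad | active   # non-converged
  pt <- p + d * t
  h2 <- pt[, 1]^2 + pt[, 2]^2
  ok <- !bad & t > t_min & h2 <= surface$aperture_radius^2 + 1e-9
  nrm <- unitize(cbind(-zx, -zy, rep(1, n)))
  t[!ok] <- NA_real_
  pt[!ok, ] <- NA_real_
  nrm[!ok, ] <- NA_real_
  list(t = t, point = pt, normal = nrm, hit = ok, iterations = it)
}

#' Generate the entrance ray bundle filling the pupil
#'
#' Builds a collimated bundle at the field angle (by default the eye's
#' angle kappa) whose rays are aimed at a square grid of nodes on the
#' (decentred) pupil stop.  Aiming through the cornea is calibrated with a
#' two-pass affine correction: probe rays are traced to the stop plane,
#' the launch-to-stop map is fitted, and the bundle is launched through its
#' inverse, which fills the stop grid to well under 1%.  Each ray carries
#' the Stiles-Crawford intensity weight of its pupil node (if enabled in
#' the eye) and the bundle remembers its pupil-grid structure for pupil
#' function sampling.
#'
#' An optional thin spectacle lens at the vertex distance modifies the
#' bundle's vergence, for predicted-refraction calculations.
#'
#' @param eye a [build_pseudophakic_eye()] result.
#' @param field_angle_deg field angle in degrees in the +x meridian
#'   (default: the eye's angle kappa).
#' @param grid_density nodes per axis across the pupil diameter (>= 8;
#'   default 32).
#' @param wavelength wavelength, um.
#' @param spectacle_power thin-lens power at the spectacle plane, D.
#' @param vertex_distance spectacle vertex distance, mm (default 12).
#' @return A `ray_bundle`: positions `p`, directions `d`, `opd`, `weight`,
#'   pupil-node coordinates `u` (relative to the pupil centre), grid
#'   indices, `wavelength`.
#' @export
generate_pupil_rays <- function(eye, field_angle_deg = NULL,
                                grid_density = 36, wavelength = 0.555,
                                spectacle_power = 0, vertex_distance = 12) {
  stopifnot(inherits(eye, "pseudophakic_eye"), grid_density >= 8)
  th <- (field_angle_deg %||% eye$kappa_deg) * pi / 180
  d0 <- c(sin(th), 0, cos(th))
  a <- eye$pupil_diameter / 2
  cx <- eye$pupil_center
  z_stop <- eye$stop_z
  z0 <- -vertex_distance
  ug <- seq(-a, a, length.out = grid_density)
  U <- expand.grid(ux = ug, uy = ug)
  inside <- U$ux^2 + U$uy^2 <= a^2 + 1e-12
  U <- U[inside, ]
  idx <- which(inside)

  naive_launch <- function(aim) {
    # straight-line back-projection from an aim point on the stop plane
    cbind(aim[, 1] - d0[1] / d0[3] * (z_stop - z0),
          aim[, 2] - d0[2] / d0[3] * (z_stop - z0),
          z0)
  }
  stop_hit <- function(aim) {
    p <- naive_launch(aim)
    d <- matrix(d0, nrow(p), 3, byrow = TRUE)
    st <- .trace_to_plane(eye, p, d, wavelength, z_stop)
    st$p[, 1:2, drop = FALSE]
  }
  # affine calibration of the launch -> stop map
  del <- 0.7 * a
  probes <- rbind(c(0, 0), c(del, 0), c(-del, 0), c(0, del), c(0, -del))
  aimp <- sweep(probes, 2, cx, `+`)
  hits <- stop_hit(aimp)
  A0 <- hits[1, ]
  Bx <- (hits[2, ] - hits[3, ]) / (2 * del)
  By <- (hits[4, ] - hits[5, ]) / (2 * del)
  Bm <- cbind(Bx, By)            # d(stop)/d(aim offset)
  Binv <- solve(Bm)
  want <- cbind(U$ux + cx[1], U$uy + cx[2])
  corr <- t(Binv %*% (t(want) - A0))
  aim <- sweep(corr, 2, cx, `+`)
  p <- naive_launch(aim)
  d <- matrix(d0, nrow(p), 3, byrow = TRUE)
  # collimated-beam reference: wavefront plane through the origin, in the
  # launch medium (air for a real eye)
  n_launch <- refractive_index(eye$surfaces[[1]]$n_in, wavelength)
  opd <- n_launch * as.vector(p %*% d0)
  if (spectacle_power != 0) {
    lens_c <- naive_launch(matrix(cx, 1))[1, 1:2]
    r2 <- (p[, 1] - lens_c[1])^2 + (p[, 2] - lens_c[2])^2
    s <- d[, 1:2] / d[, 3]
    s <- s - spectacle_power / 1000 * (p[, 1:2] - rep(lens_c, each = nrow(p)))
    d <- unitize(cbind(s, 1))
    opd <- opd - spectacle_power / 1000 * r2 / 2
  }
  w <- if (isTRUE(eye$stiles_crawford))
    stiles_crawford_weight(sqrt(U$ux^2 + U$uy^2), eye$sc_alpha)
  else rep(1, nrow(U))
  structure(list(p = p, d = d, opd = opd, weight = w,
                 u = cbind(U$ux, U$uy), grid_index = idx,
                 grid_density = grid_density,
                 pupil_radius = a,
                 alive = rep(TRUE, nrow(p)),
                 reason = rep(NA_character_, nrow(p)),
                 wavelength = wavelength,
                 snell_residual = 0),
            class = "ray_bundle")
}

# Trace positions/directions through the corneal surfaces to a plane.
# Internal helper for pupil aiming (no bookkeeping, no stop clipping).
.trace_to_plane <- function(eye, p, d, wavelength, z_plane) {
  for (s in eye$surfaces) {
    if (s$z >= z_plane - 1e-12 || s$kind == "stop") break
    hit <- if (s$kind == "spline")
      intersect_spline(p, d, s$surface)
    else
      intersect_conic(p, d, s$R, s$Q, s$z, s$aperture)
    n1 <- refractive_index(s$n_in, wavelength)
    n2 <- refractive_index(s$n_out, wavelength)
    rf <- .refract_m(d, hit$normal, n1, n2)
    p <- hit$point; d <- rf$d
  }
  t <- (z_plane - p[, 3]) / d[, 3]
  list(p = p + d * t, d = d)
}

#' Trace a ray bundle through a pseudophakic eye
#'
#' Sequential exact ray tracing: each ray is intersected with every surface
#' in order and refracted by the vector Snell law; optical path length
#' `n * d` accumulates per segment.  The pupil stop clips rays outside the
#' decentred pupil; total internal reflection, aperture misses and
#' non-converged spline intersections drop the ray with a recorded reason.
#' Tracing ends on the retina (no refraction there).
#'
#' @param eye a [build_pseudophakic_eye()] result.
#' @param rays a `ray_bundle` from [generate_pupil_rays()], or a partially
#'   traced bundle (see `surface_range`).
#' @param surface_range indices of `eye$surfaces` to traverse (default
#'   all); lets callers cache the corneal leg of a trace and resume behind
#'   the stop when scanning IOL powers.
#' @param max_loss maximum tolerated lost-ray fraction before an error
#'   naming the first failing surface (default 0.2).
#' @return A `trace_result`: retina hit coordinates `x`, `y` (mm), `opd`
#'   (mm), `weight`, `alive`, `reason`, lost-ray summary `lost`, maximum
#'   per-surface Snell residual `snell_residual`, and the bundle's pupil
#'   grid bookkeeping.
#' @export
trace_rays <- function(eye, rays, surface_range = NULL, max_loss = 0.2) {
  stopifnot(inherits(eye, "pseudophakic_eye"), inherits(rays, "ray_bundle"))
  surface_range <- surface_range %||% seq_along(eye$surfaces)
  p <- rays$p; d <- rays$d
  alive <- rays$alive; reason <- rays$reason
  opd <- rays$opd
  lambda <- rays$wavelength
  snell_max <- rays$snell_residual
  final <- max(surface_range) == length(eye$surfaces)
  for (i in surface_range) {
    s <- eye$surfaces[[i]]
    n1 <- refractive_index(s$n_in, lambda)
    idx <- which(alive)
    if (!length(idx)) break
    pa <- p[idx, , drop = FALSE]; da <- d[idx, , drop = FALSE]
    if (s$kind == "stop") {
      t <- (s$z - pa[, 3]) / da[, 3]
      pt <- pa + da * t
      r2 <- (pt[, 1] - s$center[1])^2 + (pt[, 2] - s$center[2])^2
      ok <- t > -1e-9 & r2 <= s$radius^2 + 1e-9
      opd[idx] <- opd[idx] + n1 * t
      p[idx, ] <- pt
      alive[idx[!ok]] <- FALSE
      reason[idx[!ok]] <- "vignetted:pupil_stop"
      next
    }
    hit <- if (s$kind == "spline")
      intersect_spline(pa, da, s$surface)
    else
      intersect_conic(pa, da, s$R, s$Q, s$z, s$aperture)
    ok <- hit$hit
    alive[idx[!ok]] <- FALSE
    reason[idx[!ok]] <- paste0("miss:", s$label)
    keep <- idx[ok]
    if (!length(keep)) next
    opd[keep] <- opd[keep] + n1 * hit$t[ok]
    p[keep, ] <- hit$point[ok, , drop = FALSE]
    if (s$label != "retina") {
      n2 <- refractive_index(s$n_out, lambda)
      rf <- .refract_m(d[keep, , drop = FALSE],
                       hit$normal[ok, , drop = FALSE], n1, n2)
      # Snell residual |n1 sin t1 - n2 sin t2| via cross-product norms
      din <- d[keep, , drop = FALSE]
      N <- hit$normal[ok, , drop = FALSE]
      s1 <- sqrt(pmax(1 - rowSums(din * N)^2, 0))
      live <- !rf$tir
      if (any(live)) {
        s2 <- sqrt(pmax(1 - rowSums(rf$d[live, , drop = FALSE] *
                                      N[live, , drop = FALSE])^2, 0))
        snell_max <- max(snell_max, abs(n1 * s1[live] - n2 * s2))
      }
      d[keep, ] <- rf$d
      alive[keep[rf$tir]] <- FALSE
      reason[keep[rf$tir]] <- paste0("tir:", s$label)
    }
  }
  lost <- table(reason[!alive & !is.na(reason)])
  loss_frac <- 1 - sum(rays$weight[alive]) / sum(rays$weight)
  if (final && loss_frac > max_loss) {
    first <- reason[!alive][1]
    stop(sprintf("%.0f%% of launched rays lost (first failure: %s)",
                 100 * loss_frac, first))
  }
  structure(list(x = ifelse(alive, p[, 1], NA_real_),
                 y = ifelse(alive, p[, 2], NA_real_),
                 p = p, d = d, opd = opd,
                 weight = rays$weight, alive = alive, reason = reason,
                 lost = lost, loss_fraction = loss_frac,
                 snell_residual = snell_max,
                 u = rays$u, grid_index = rays$grid_index,
                 grid_density = rays$grid_density,
                 pupil_radius = rays$pupil_radius,
                 wavelength = lambda,
                 complete = final),
            class = c(if (final) "trace_result" else "ray_bundle", "list"))
}
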