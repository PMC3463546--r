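test_that("vector refraction matches the scalar Snell oracle", {
  # index match and normal incidence leave the direction unchanged
  d <- c(sin(0.3), 0, cos(0.3))
  expect_equal(refract(d, c(0, 0, -1), 1.4, 1.4), d)
  expect_equal(refract(c(0, 0, 1), c(0, 0, -1), 1.0, 1.5), c(0, 0, 1))
  # 45 deg, 1.0 -> 1.5: theta2 = asin(sin(45)/1.5) = 28.1255 deg
  out <- refract(c(sin(pi / 4), 0, cos(pi / 4)), c(0, 0, -1), 1.0, 1.5)
  expect_equal(asin(sqrt(sum(out[1:2]^2))) * 180 / pi,
               asin(sin(pi / 4) / 1.5) * 180 / pi, tolerance = 1e-10)
  expect_equal(asin(out[1]) * 180 / pi, 28.1255, tolerance = 1e-4)
  # 60 deg, 1.5 -> 1.0: sin(theta2) = 1.299 > 1, total internal reflection
  out <- refract(c(sin(pi / 3), 0, cos(pi / 3)), c(0, 0, -1), 1.5, 1.0)
  expect_true(isTRUE(attr(out, "tir")))
})

test_that("Snell residual is machine-precision over random refractions", {
  set.seed(7)
  n <- 1000
  d <- unitize_rows(cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 0.3), abs(rnorm(n)) + 0.3))
  N <- unitize_rows(cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 0.3), -(abs(rnorm(n)) + 0.3)))
  n1 <- runif(n, 1, 1.8); n2 <- runif(n, 1, 1.8)
  res <- refract(d, N, n1, n2)
  keep <- !res$tir
  sin1 <- sqrt(pmax(1 - rowSums(d * N)^2, 0))
  sin2 <- sqrt(pmax(1 - rowSums(res$d * N)^2, 0))
  expect_gt(sum(keep), 900)
  expect_lt(max(abs(n1[keep] * sin1[keep] - n2[keep] * sin2[keep])), 1e-10)
  # reversibility: tracing the refracted ray backwards recovers the input
  rev <- refract(-res$d[keep, ], N[keep, ], n2[keep], n1[keep])
  expect_lt(max(abs(rev$d + d[keep, ])), 1e-9)
})

test_that("conic intersection reproduces closed-form sags and clips apertures", {
  # axial ray hits the apex
  hit <- intersect_conic(c(0, 0, -5), c(0, 0, 1), R = 7.8, Q = 0,
                         vertex_z = 2)
  expect_equal(drop(hit$point), c(0, 0, 2))
  # parallel ray at height 1 on a 10 mm sphere: sag 10 - sqrt(99)
  hit <- intersect_conic(c(1, 0, -5), c(0, 0, 1), R = 10)
  expect_equal(hit$point[1, 3], 10 - sqrt(99), tolerance = 1e-12)
  expect_equal(hit$point[1, 3], 0.05013, tolerance = 1e-4)
  # aperture clip is a miss, not an error
  hit <- intersect_conic(c(3, 0, -5), c(0, 0, 1), R = 10,
                         aperture_radius = 2)
  expect_false(hit$hit[1])
  expect_true(is.na(hit$t[1]))
  # negative-radius surface (retina-like): sag curves towards -z
  hit <- intersect_conic(c(2, 0, -5), c(0, 0, 1), R = -12)
  expect_equal(hit$point[1, 3], conic_sag(2, -12, 0), tolerance = 1e-12)
  expect_lt(hit$point[1, 3], 0)
})

test_that("paraxial focus of a single spherical interface matches vergence", {
  # n2 R / (n2 - n1) = 31.014 mm for R = 7.8, 1.0 -> 1.336
  heights <- c(-0.1, -0.05, 0.05, 0.1)
  zs <- vapply(heights, function(h) {
    hit <- intersect_conic(c(h, 0, -5), c(0, 0, 1), R = 7.8)
    d2 <- refract(c(0, 0, 1), drop(hit$normal), 1.0, 1.336)
    hit$point[1, 3] - hit$point[1, 1] * d2[3] / d2[1]
  }, 0)
  bfd <- 1.336 * 7.8 / 0.336
  expect_true(all(abs(zs - bfd) / bfd < 1e-3))
})

test_that("spline intersection agrees with the conic oracle on random rays", {
  R <- 7.77
  surf <- fit_surface(synth_conic_grid(R, 0))
  set.seed(21)
  n <- 1000
  p <- cbind(runif(n, -3, 3), runif(n, -3, 3), -5)
  d <- unitize_rows(cbind(runif(n, -0.15, 0.15), runif(n, -0.15, 0.15),
                          1))
  hs <- intersect_spline(p, d, surf)
  hc <- intersect_conic(p, d, R = R, Q = 0,
                        aperture_radius = surf$aperture_radius)
  both <- hs$hit & hc$hit
  expect_gt(mean(both), 0.95)
  expect_lt(max(abs(hs$point[both, ] - hc$point[both, ])), 1e-6)
  expect_lt(max(abs(hs$normal[both, ] - hc$normal[both, ])), 1e-5)
})

test_that("plane spline surface intersects at the vertex-plane crossing", {
  surf <- fit_surface(elevation_grid(matrix(0, 21, 21)), vertex_position = 1.5)
  hit <- intersect_spline(c(0.4, -0.3, -2), unitize_rows(c(0.1, 0.05, 1)),
                          surf)
  tt <- (1.5 - (-2)) / unitize_rows(c(0.1, 0.05, 1))[3]
  expect_equal(hit$point[1, 3], 1.5, tolerance = 1e-9)
  expect_equal(hit$t[1], tt, tolerance = 1e-9)
  # leaving the aperture is a miss
  hit <- intersect_spline(c(9, 0, -2), c(0, 0, 1), surf)
  expect_false(hit$hit[1])
})

test_that("pupil ray bundles fill the stop grid with symmetric weights", {
  eye <- std_builder()(19.5)
  rays <- generate_pupil_rays(eye, grid_density = 33)
  a <- eye$pupil_diameter / 2
  ug <- seq(-a, a, length.out = 33)
  U <- expand.grid(ux = ug, uy = ug)
  expect_equal(nrow(rays$p), sum(U$ux^2 + U$uy^2 <= a^2 + 1e-12))
  # central node carries unit weight; weights symmetric about the centre
  ctr <- which(rays$u[, 1] == 0 & rays$u[, 2] == 0)
  expect_length(ctr, 1)
  expect_equal(rays$weight[ctr], 1)
  flip <- order(-rays$u[, 1], -rays$u[, 2])
  ref <- order(rays$u[, 1], rays$u[, 2])
  expect_equal(rays$weight[flip], rays$weight[ref])
  # two-pass aiming: stop-plane footprint within 1% of the aimed nodes
  mid <- trace_rays(eye, rays, surface_range = 1:2)
  t_stop <- (eye$stop_z - mid$p[, 3]) / mid$d[, 3]
  hit_xy <- mid$p[, 1:2] + mid$d[, 1:2] * t_stop
  want <- sweep(rays$u, 2, eye$pupil_center, `+`)
  expect_lt(max(sqrt(rowSums((hit_xy - want)^2))) / a, 0.01)
})

test_that("tracing a matched-index flat system leaves rays undeviated", {
  # non-dispersive medium so the optical path is exactly n * length
  vitreous <- medium("vitreous", 1.336, dispersive = FALSE)
  flat <- function(z, label) list(kind = "conic", R = Inf, Q = 0, z = z,
                                  aperture = 10, n_in = vitreous,
                                  n_out = vitreous, label = label)
  eye <- structure(list(
    surfaces = list(flat(0, "cornea_anterior"), flat(0.5, "cornea_posterior"),
                    list(kind = "stop", z = 5, center = c(0, 0), radius = 2,
                         n_in = vitreous, n_out = vitreous,
                         label = "pupil_stop"),
                    flat(5.001, "iol_front"), flat(6, "iol_back"),
                    flat(24, "retina")),
    pupil_diameter = 4, pupil_center = c(0, 0), stop_z = 5,
    kappa_deg = 0, retina_radius = Inf, retina_z = 24, axial_length = 24,
    acd_post = 4.5, stiles_crawford = FALSE, sc_alpha = 0.05),
    class = "pseudophakic_eye")
  rays <- generate_pupil_rays(eye, grid_density = 16)
  tr <- trace_rays(eye, rays)
  expect_true(all(tr$alive))
  expect_lt(max(abs(tr$d[, 1:2])), 1e-12)
  # opd = index times geometric length from the reference plane at z = 0
  expect_equal(tr$opd, rep(1.336 * 24, nrow(rays$p)), tolerance = 1e-12)
  expect_equal(tr$snell_residual, 0)
})

test_that("full-eye trace agrees with 2x2 transfer-matrix optics paraxially", {
  biom <- std_biometry()
  iol <- iol_from_power(19.5)
  builder <- std_builder(settings = list(pupil_decentration = 0,
                                         kappa_deg = 0,
                                         pupil_diameter = 0.2))
  eye <- builder(19.5)
  rays <- generate_pupil_rays(eye, grid_density = 9)
  tr <- trace_rays(eye, rays, surface_range = 1:5)  # stop before the retina
  # axis crossings of the tangential rays (interior of the tiny pupil)
  sel <- which(tr$alive & abs(rays$u[, 2]) < 1e-9 & abs(rays$u[, 1]) > 0.02 &
                 abs(rays$u[, 1]) < 0.09)
  expect_gte(length(sel), 4)
  zf <- tr$p[sel, 3] - tr$p[sel, 1] * tr$d[sel, 3] / tr$d[sel, 1]
  z_oracle <- paraxial_focus_z(7.74, 6.40, 0.55, 0.55 + 4.56865, iol)
  expect_true(all(abs(zf - z_oracle) / z_oracle < 1e-3))
})

test_that("excessive ray loss raises a diagnostic naming the surface", {
  eye <- std_builder()(19.5)
  # shrink the IOL aperture so most rays vignette
  eye$surfaces[[4]]$aperture <- 0.5
  rays <- generate_pupil_rays(eye, grid_density = 16)
  expect_error(trace_rays(eye, rays), "rays lost.*iol_front")
})
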