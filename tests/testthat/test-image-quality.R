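test_that("pupil function separates wavefront error from piston and tilt", {
  eye <- std_builder()(19.0)
  tr <- trace_rays(eye, generate_pupil_rays(eye, grid_density = 32))
  pf <- pupil_function(tr, eye)
  inside <- pf$amplitude > 0
  # tilt removed: wavefront has no mean slope left
  n <- pf$n
  U <- matrix(seq(-pf$pupil_radius, pf$pupil_radius, length.out = n),
              n, n, byrow = TRUE)
  V <- t(U)
  fit <- lm.fit(cbind(1, U[inside], V[inside]), pf$wavefront[inside])
  expect_lt(max(abs(fit$coefficients[2:3])), 1e-9)
  # Stiles-Crawford on: amplitude falls towards the pupil margin
  r <- sqrt(U^2 + V^2)
  expect_lt(mean(pf$amplitude[inside & r > 1.8]),
            mean(pf$amplitude[inside & r < 0.3]))
  # Stiles-Crawford off: uniform amplitude
  eye2 <- std_builder(settings = list(stiles_crawford = FALSE))(19.0)
  tr2 <- trace_rays(eye2, generate_pupil_rays(eye2, grid_density = 32))
  pf2 <- pupil_function(tr2, eye2)
  expect_true(all(pf2$amplitude[pf2$amplitude > 0] == 1))
  # heavy ray loss is refused
  tr$alive[seq_len(round(0.3 * length(tr$alive)))] <- FALSE
  expect_error(pupil_function(tr, eye), "survived")
})

test_that("a trial lens injects the expected quadratic defocus", {
  eye <- std_builder()(19.0)
  pfs <- lapply(c(0, 0.5, 1), function(s) {
    tr <- trace_rays(eye, generate_pupil_rays(eye, grid_density = 32,
                                              spectacle_power = s))
    pupil_function(tr, eye)
  })
  n <- pfs[[1]]$n
  U <- matrix(seq(-2, 2, length.out = n), n, n, byrow = TRUE); V <- t(U)
  inside <- pfs[[1]]$amplitude > 0 & pfs[[2]]$amplitude > 0 &
    pfs[[3]]$amplitude > 0
  coef_for <- function(pf) {
    dW <- pf$wavefront[inside] - pfs[[1]]$wavefront[inside]
    X <- cbind(1, U[inside], V[inside], U[inside]^2 + V[inside]^2)
    fit <- lm.fit(X, dW)
    r2 <- 1 - sum(fit$residuals^2) / sum((dW - mean(dW))^2)
    c(fit$coefficients[4], r2)
  }
  c1 <- coef_for(pfs[[2]]); c2 <- coef_for(pfs[[3]])
  # dominantly quadratic phase (the small residual is genuine
  # higher-order aberration change), proportional to the injected power
  expect_gt(c1[2], 0.95)
  expect_gt(c2[2], 0.95)
  expect_equal(unname(c2[1] / c1[1]), 2, tolerance = 0.05)
  expect_equal(sign(c1[1]), sign(c2[1]))
  # magnitude: 1 D at the spectacle plane is about
  # (1/1000) * m^2 / 2 per mm^2 at the pupil, m the footprint
  # magnification (order unity)
  expect_gt(abs(c2[1]), 2e-4); expect_lt(abs(c2[1]), 1.2e-3)
})

test_that("aberration-free pupil gives the Airy pattern", {
  pf <- ideal_pupil_function(n = 96, pupil_radius = 2, wavelength = 0.555,
                             R_ref = 20, n_image = 1)
  psf <- psf_polychromatic(list(pf), weights = 1, pad = 8)
  expect_true(all(psf$intensity >= 0))
  expect_equal(sum(psf$intensity), 1, tolerance = 1e-12)
  # radial profile along +x through the centre
  N <- nrow(psf$intensity)
  ctr <- N / 2 + 1
  prof <- psf$intensity[ctr, ctr:(ctr + 40)]
  rfirst <- psf$axis[ctr + which(diff(prof) > 0)[1] - 1] - psf$axis[ctr]
  airy <- 1.22 * 0.555e-3 * 20 / 4
  expect_equal(rfirst, airy, tolerance = 0.1)
})

test_that("identical pupil functions reduce polychromatic to monochromatic", {
  pf <- ideal_pupil_function(n = 48)
  p1 <- psf_polychromatic(list(pf), weights = 1, pad = 4)
  p3 <- psf_polychromatic(list(pf, pf, pf), weights = c(1, 2, 1), pad = 4)
  expect_equal(p3$intensity, p1$intensity, tolerance = 1e-12)
  pf2 <- ideal_pupil_function(n = 32)
  expect_error(psf_polychromatic(list(pf, pf2)), "mismatched")
})

test_that("MTF from PSF handles delta and Gaussian closed forms", {
  N <- 128; pitch <- 2e-4
  I <- matrix(0, N, N); I[N / 2 + 1, N / 2 + 1] <- 1
  delta <- structure(list(intensity = I, pitch = pitch,
                          axis = (seq_len(N) - (N / 2 + 1)) * pitch),
                     class = "psf")
  m <- mtf_from_psf(delta)
  expect_true(all(m$modulation == 1))
  expect_equal(m$modulation[1], 1)
  # Gaussian PSF sigma -> MTF exp(-2 pi^2 sigma^2 nu^2)
  sigma <- 1.5e-3
  ax <- (seq_len(N) - (N / 2 + 1)) * pitch
  G <- exp(-outer(ax^2, ax^2, `+`) / (2 * sigma^2))
  gauss <- structure(list(intensity = G / sum(G), pitch = pitch, axis = ax),
                     class = "psf")
  mg <- mtf_from_psf(gauss)
  keep <- mg$frequency < 250
  expect_equal(mg$modulation[keep],
               exp(-2 * pi^2 * sigma^2 * mg$frequency[keep]^2),
               tolerance = 1e-3)
  # rigid translation of the PSF does not change the MTF
  I2 <- matrix(0, N, N); I2[N / 2 + 9, N / 2 + 6] <- 1
  shifted <- structure(list(intensity = I2, pitch = pitch, axis = ax),
                       class = "psf")
  expect_equal(mtf_from_psf(shifted)$modulation, m$modulation,
               tolerance = 1e-9)
})

test_that("diffraction-limited MTF matches its closed form", {
  nu_c <- 2 * (1.336 * 4 / (2 * 20)) / (0.555e-3)
  dl <- diffraction_limited_mtf(c(0, nu_c / 2, nu_c), wavelength = 0.555,
                                pupil_diameter = 4, R_ref = 20,
                                n_image = 1.336)
  expect_equal(dl$modulation[1], 1)
  expect_equal(dl$modulation[3], 0)
  expect_equal(dl$modulation[2], 0.3910, tolerance = 1e-3)
  expect_equal(dl$modulation[2], (2 / pi) * (pi / 3 - cos(pi / 3) * sin(pi / 3)),
               tolerance = 1e-12)
})

test_that("contrast sensitivity weights are a band-pass with photopic peak", {
  csf <- csf_weights(seq(0, 100, by = 0.25))
  expect_true(all(csf$weight >= 0))
  peak <- csf$frequency[which.max(csf$weight)]
  expect_gt(peak, 6); expect_lt(peak, 27)
  expect_lt(csf$weight[1], 0.2 * max(csf$weight))
  expect_error(csf_weights(c(0, 150)), "100")
  flat <- csf_weights(seq(0, 100, 2), model = "flat")
  expect_true(all(flat$weight == 1))
})

test_that("merit scores deviation from the diffraction limit as specified", {
  f <- c(10, 20)
  dl <- mtf_curve(f, c(0.9, 0.8))
  sys <- mtf_curve(f, c(0.8, 0.6))       # gaps 0.1, 0.2
  csf <- structure(list(frequency = f, weight = c(1, 3), model = "custom",
                        deg_per_mm = 0.3), class = "csf_weights")
  # hand arithmetic: (1 * 0.01 + 3 * 0.04) / 4
  expect_equal(merit(sys, dl, csf), 0.0325, tolerance = 1e-12)
  expect_equal(merit(dl, dl, csf), 0)
  expect_gt(merit(sys, dl, csf), 0)
  expect_equal(merit(sys, dl, csf, mode = "absolute"),
               (1 * 0.1 + 3 * 0.2) / 4, tolerance = 1e-12)
  bad <- mtf_curve(c(10, 30), c(0.8, 0.6))
  expect_error(merit(bad, dl, csf), "common frequency grid")
})

test_that("system MTF stays at or below the diffraction limit", {
  cohort <- simulate_cohort(3, seed = 314)
  for (e in cohort) {
    eye <- cohort_builder(e)(19.5)
    r <- eye_mtf(eye)
    expect_equal(r$mtf$modulation[1], 1)
    expect_lt(max(r$mtf$modulation - r$dl$modulation), 0.01)
  }
})

test_that("merit degrades monotonically with defocus", {
  builder <- std_builder()
  opt <- fine_optimum(builder, window = c(18, 20), step = 0.1)
  eye <- builder(opt$power)
  m <- vapply(c(0, 0.5, 1, 1.5), function(s)
    eye_merit(eye, spectacle_power = s), 0)
  expect_true(all(diff(m) > 0))
  m2 <- vapply(c(0, -0.5, -1, -1.5), function(s)
    eye_merit(eye, spectacle_power = s), 0)
  expect_true(all(diff(m2) > 0))
})

test_that("geometric-MTF cross-check ranks focus like the diffraction MTF", {
  builder <- std_builder()
  powers <- c(17, 19, 21)
  mg <- vapply(powers, function(p) {
    r <- eye_mtf(builder(p), method = "geometric")
    merit(r$mtf, r$dl, csf_weights())
  }, 0)
  md <- vapply(powers, function(p) {
    r <- eye_mtf(builder(p))
    merit(r$mtf, r$dl, csf_weights())
  }, 0)
  expect_equal(which.min(mg), which.min(md))
})
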