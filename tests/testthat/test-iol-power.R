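test_that("SRK/T implementation matches an independent step-by-step oracle", {
  # oracle written directly from the published algorithm, step by step
  srkt_oracle <- function(AL, K, A) {
    r <- 337.5 / K
    lcor <- if (AL > 24.2) -3.446 + 1.716 * AL - 0.0237 * AL^2 else AL
    cw <- -5.41 + 0.58412 * lcor + 0.098 * K
    h <- r - sqrt(max(r^2 - cw^2 / 4, 0))
    acd <- h + (0.62467 * A - 68.747) - 3.336
    l <- AL + 0.65696 - 0.02029 * AL
    (1000 * 1.336 * (1.336 * r - 0.333 * l)) /
      ((l - acd) * (1.336 * r - 0.333 * acd))
  }
  cases <- expand.grid(AL = c(21.8, 23.45, 24.9, 27.3),
                       K = c(40, 43.5, 46.5), A = c(117.2, 118.4, 119.5))
  for (i in seq_len(nrow(cases)))
    expect_equal(srkt_iol_power(cases$AL[i], K = cases$K[i],
                                a_constant = cases$A[i]),
                 srkt_oracle(cases$AL[i], cases$K[i], cases$A[i]),
                 tolerance = 1e-10)
  # frozen spot value from the oracle
  expect_equal(srkt_iol_power(23.45, K = 43.5, a_constant = 118.4),
               20.71506, tolerance = 1e-5)
  # rounding to available IOL steps
  expect_equal(srkt_iol_power(23.45, K = 43.5, a_constant = 118.4,
                              round_step = 0.5), 20.5)
  # monotonicity: longer eyes and steeper corneas need less power
  p_al <- srkt_iol_power(seq(20, 28, 0.5), K = 43.5)
  expect_true(all(diff(p_al) < 0))
  p_k <- srkt_iol_power(23.45, K = seq(38, 48, 0.5))
  expect_true(all(diff(p_k) < 0))
  # validity bounds
  expect_error(srkt_iol_power(17, K = 43), "axial length")
  expect_error(srkt_iol_power(23, K = 53), "corneal power")
  # target refraction: a myopic target needs more power
  expect_gt(srkt_iol_power(23.45, K = 43.5, target_refraction = -1),
            srkt_iol_power(23.45, K = 43.5))
})

test_that("A-constant calibration makes SRK/T agree at the reference eye", {
  A <- calibrate_a_constant(19.0, 24.42, 7.74)
  expect_equal(srkt_iol_power(24.42, radius = 7.74, a_constant = A), 19.0,
               tolerance = 1e-6)
})

test_that("lattice optimizer equals a brute-force half-dioptre scan", {
  cohort <- simulate_cohort(2, seed = 8)
  for (e in cohort) {
    builder <- cohort_builder(e)
    res <- optimize_iol_power(builder, power_range = c(13, 26))
    # brute force, fresh traces, no caching
    powers <- seq(13, 26, by = 0.5)
    merits <- vapply(powers, function(p) eye_merit(builder(p)), 0)
    expect_equal(res$best_power, powers[which.min(merits)])
    expect_equal(res$merit_trace$merit, merits, tolerance = 1e-12)
    expect_false(res$boundary)
  }
})

test_that("single-power scans are flagged as boundary results", {
  builder <- std_builder()
  res <- optimize_iol_power(builder, power_range = c(19, 19))
  expect_equal(res$best_power, 19)
  expect_true(res$boundary)
})

test_that("merit trace is convex around the optimum for a spherical cornea", {
  builder <- std_builder(Q = 0)
  res <- optimize_iol_power(builder, power_range = c(15, 23))
  tr <- res$merit_trace
  i <- which.min(tr$merit)
  expect_gt(i, 2); expect_lt(i, nrow(tr) - 1)
  # unimodal within +/- 2 D of the optimum: strictly decreasing into the
  # minimum, increasing out of it (far from focus the merit saturates)
  lo <- max(1, i - 4); hi <- min(nrow(tr), i + 4)
  expect_true(all(diff(tr$merit[lo:i]) < 0))
  expect_true(all(diff(tr$merit[i:hi]) > 0))
  # positive curvature at the minimum
  expect_gt(tr$merit[i - 1] + tr$merit[i + 1] - 2 * tr$merit[i], 0)
})

test_that("predicted refraction is self-consistent and tracks axial length", {
  builder <- std_builder()
  opt <- fine_optimum(builder, window = c(18, 20), step = 0.05)
  eye <- builder(opt$power)
  r0 <- predicted_refraction(eye)
  expect_lte(abs(r0), 0.05)
  # 1 mm longer vitreous: clearly myopic (about -2.5 D at the spectacle)
  b2 <- biometry(3.04, 3.87, 17.96, 0.55)
  eye2 <- make_eye_builder(synth_conic_grid(7.74, -0.18), NULL,
                           b2)(opt$power)
  r2 <- predicted_refraction(eye2)
  expect_lt(r2, -1.5)
  # round trip: with a +1 D lens held in place, the residual measured on
  # top of it is -1 D
  fine <- seq(-1.6, -0.4, by = 0.05)
  m <- vapply(fine, function(s)
    eye_merit(eye, spectacle_power = 1 + s), 0)
  expect_equal(fine[which.min(m)], -1, tolerance = 0.06)
})

test_that("cohort simulation is deterministic, truncated, and centred", {
  c1 <- simulate_cohort(5, seed = 11)
  c2 <- simulate_cohort(5, seed = 11)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(5, seed = 12)
  expect_false(identical(c1, c3))
  # draws respect the biometry validation bounds
  big <- simulate_cohort(300, seed = 13, grid_n = 9,
                         population = list(acd_sd = 1.2, lt_sd = 1.2))
  acd <- vapply(big, function(e) e$biometry$acd_pre, 0)
  lt <- vapply(big, function(e) e$biometry$lens_thickness, 0)
  expect_true(all(acd > 1.5 & acd < 5.5))
  expect_true(all(lt > 2.5 & lt < 6.0))
  # sample mean of the anterior radius approaches the population mean
  huge <- simulate_cohort(10000, seed = 14, grid_n = 9)
  r <- vapply(huge, function(e) e$biometry$keratometric_radius, 0)
  expect_equal(mean(r), 7.74, tolerance = 0.01 / 7.74)
  expect_error(simulate_cohort(3, population = list(oops = 1)), "oops")
})

test_that("method comparison reproduces closed-form regression cases", {
  x <- c(16, 18, 19.5, 21, 23)
  self <- compare_methods(x, x)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$slope, 1); expect_equal(self$intercept, 0)
  expect_equal(self$mean_abs_diff, 0)
  lin <- compare_methods(2 * x + 1, x)
  expect_equal(lin$slope, 2); expect_equal(lin$intercept, 1)
  expect_equal(lin$pearson_r, 1)
  # textbook Pearson formula on a 5-point toy table
  y <- c(15.5, 18.4, 19.0, 21.7, 22.9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(compare_methods(y, x)$pearson_r, r_hand)
  expect_error(compare_methods(rep(1, 4), rep(1, 4)), "variance")
  expect_error(compare_methods(1:2, 1:2), "length")
})

test_that("myopic ablation shifts the model above keratometric SRK/T", {
  # before vs after a -3 D ablation of the same eye: the gap between the
  # ray-traced power and SRK/T (fed the best-fit-sphere K) must widen,
  # because keratometry under-reads the corneal power loss and the
  # formula's ELP estimate shallows with the flattened K
  A <- get_calibrated_A()
  g0 <- synth_conic_grid(7.74, -0.18)
  g1 <- apply_lasik_ablation(g0, -3, optical_zone = 6)
  b <- std_biometry()
  margin <- function(g) {
    k <- 337.5 / best_fit_sphere(fit_surface(g), 3)$radius
    s <- srkt_iol_power(b$axial_length, K = k, a_constant = A)
    builder <- make_eye_builder(g, NULL, b)
    fine_optimum(builder)$power - s
  }
  m0 <- margin(g0); m1 <- margin(g1)
  expect_gt(m1, m0 + 0.5)
  expect_gt(m1, 0)
})

test_that("ray-traced power decreases as the eye lengthens", {
  grids <- synth_conic_grid(7.74, -0.18)
  powers <- vapply(c(15.96, 16.96, 17.96), function(vd) {
    b <- biometry(3.04, 3.87, vd, 0.55)
    builder <- make_eye_builder(grids, NULL, b)
    optimize_iol_power(builder, power_range = c(12, 26))$best_power
  }, 0)
  expect_true(all(diff(powers) < 0))
})
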