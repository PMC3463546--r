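#' Build an IOL-power-to-eye closure
#'
#' Precomputes everything that does not depend on the IOL power (fitted
#' corneal surfaces, biometry, settings) and returns `function(power)`
#' assembling the eye with that labeled power.  Suitable for
#' [optimize_iol_power()], whose front-trace caching relies on the cornea
#' and stop being identical across powers.
#'
#' @param anterior a [fit_surface()] anterior cornea, or an
#'   [elevation_grid()] (fitted here).
#' @param posterior posterior cornea surface or grid; `NULL` uses the
#'   schematic posterior (6.40 mm, Q = -0.60).
#' @param biom a [biometry()].
#' @param settings eye settings, see [build_pseudophakic_eye()].
#' @param iol_family list of IOL family parameters passed to
#'   [iol_from_power()]: `shape_factor`, `thickness`, `n_555`,
#'   `power_range`.
#' @return `function(power) -> pseudophakic_eye`.
#' @export
make_eye_builder <- function(anterior, posterior = NULL, biom,
                             settings = list(), iol_family = list()) {
  if (inherits(anterior, "elevation_grid")) anterior <- fit_surface(anterior)
  if (inherits(posterior, "elevation_grid"))
    posterior <- fit_surface(posterior,
                             vertex_position = biom$corneal_thickness)
  if (is.null(posterior)) {
    post_grid <- synth_conic_grid(eye_constants$cornea_posterior_radius,
                                  eye_constants$cornea_posterior_Q,
                                  surface_label = "posterior")
    posterior <- fit_surface(post_grid,
                             vertex_position = biom$corneal_thickness)
  }
  force(settings); force(iol_family)
  function(power) {
    iol <- do.call(iol_from_power, c(list(labeled_power = power), iol_family))
    build_pseudophakic_eye(anterior, posterior, biom, iol, settings)
  }
}

#' Select the IOL power optimizing retinal image quality
#'
#' Evaluates the CSF-weighted MTF merit ([eye_merit()]) at every power on
#' the half-dioptre lattice spanning `power_range` and returns the
#' minimizer, reflecting commercially available IOL steps.  Ties break
#' toward the lower power.  The corneal leg of the trace is computed once
#' and reused across powers (the builder must only vary the IOL).
#'
#' @param eye_builder `function(power) -> pseudophakic_eye`, e.g. from
#'   [make_eye_builder()].
#' @param power_range scanned labeled powers, D.
#' @param step lattice step, D (0.5 = available IOL powers).
#' @param grid_density pupil ray grid, nodes per axis.
#' @param frequency merit frequency grid, cycles/mm.
#' @param csf [csf_weights()] on `frequency`.
#' @param sw [spectral_weighting()].
#' @param reuse_front cache the cornea/stop trace across powers (default
#'   `TRUE`).
#' @return An object of class `iol_power_result`: `best_power`,
#'   `merit_trace` (data.frame `power`, `merit`), `boundary` flag,
#'   `diagnostics`.
#' @export
optimize_iol_power <- function(eye_builder, power_range = c(5, 35),
                               step = 0.5, grid_density = 36,
                               frequency = seq(0, 100, by = 2),
                               csf = csf_weights(frequency),
                               sw = spectral_weighting(),
                               reuse_front = TRUE) {
  powers <- seq(power_range[1], power_range[2], by = step)
  if (!length(powers)) stop("empty power range")
  front <- NULL
  merits <- rep(NA_real_, length(powers))
  fail <- character(0)
  for (i in seq_along(powers)) {
    m <- tryCatch({
      eye <- eye_builder(powers[i])
      if (is.null(front) && reuse_front)
        front <- trace_front(eye, grid_density, sw)
      eye_merit(eye, frequency, grid_density, sw, csf,
                front = if (reuse_front) front else NULL)
    }, error = function(e) {
      fail <<- c(fail, sprintf("%.2f D: %s", powers[i], conditionMessage(e)))
      NA_real_
    })
    merits[i] <- m
  }
  if (all(is.na(merits)))
    stop("merit evaluation failed at every scanned power:\n  ",
         paste(utils::head(fail, 3), collapse = "\n  "))
  best <- which.min(merits)   # first minimum = lower power on ties
  structure(list(best_power = powers[best],
                 merit = merits[best],
                 merit_trace = data.frame(power = powers, merit = merits),
                 boundary = best == 1L || best == length(powers),
                 diagnostics = list(failed = fail)),
            class = "iol_power_result")
}

#' @export
print.iol_power_result <- function(x, ...) {
  cat(sprintf("<iol_power_result> best power %.1f D (merit %.4f)%s\n",
              x$best_power, x$merit,
              if (x$boundary) " [at scan boundary]" else ""))
  invisible(x)
}

#' Predicted residual spectacle refraction of an eye
#'
#' Scans a thin trial lens at the spectacle plane and returns the power
#' minimizing the MTF merit, i.e. the spherical-equivalent refraction the
#' pseudophakic eye would need.  Negative = myopic.  The scan is coarse
#' (0.5 D) then fine (0.05 D) around the coarse minimum; a non-unimodal
#' coarse trace triggers a warning and the global minimum is returned.
#'
#' @param eye a [build_pseudophakic_eye()].
#' @param vertex_distance spectacle vertex distance, mm (default 12).
#' @param search_range scanned spectacle powers, D.
#' @param grid_density,frequency,csf,sw as in [optimize_iol_power()].
#' @return refraction in dioptres (0.05 D resolution).
#' @export
predicted_refraction <- function(eye, vertex_distance = 12,
                                 search_range = c(-4, 4),
                                 grid_density = 36,
                                 frequency = seq(0, 100, by = 2),
                                 csf = csf_weights(frequency),
                                 sw = spectral_weighting()) {
  stopifnot(inherits(eye, "pseudophakic_eye"))
  scan <- function(powers) vapply(powers, function(s)
    eye_merit(eye, frequency, grid_density, sw, csf,
              spectacle_power = s), 0)
  coarse <- seq(search_range[1], search_range[2], by = 0.5)
  mc <- scan(coarse)
  # count local minima whose dip is material (> 1% of the scan's range);
  # far from focus the merit is nearly flat and tiny sampling ripples are
  # not competing minima
  tol <- 0.01 * diff(range(mc))
  depth_cut <- min(mc) + 0.5 * diff(range(mc))   # competing minima only
  n_min <- 0L
  for (i in seq_along(mc)) {
    left <- if (i == 1) Inf else mc[i - 1]
    right <- if (i == length(mc)) Inf else mc[i + 1]
    if (mc[i] < left - tol && mc[i] < right - tol && mc[i] < depth_cut)
      n_min <- n_min + 1L
  }
  if (n_min > 1)
    warning("merit scan over spectacle power is not unimodal; ",
            "returning the global minimum")
  c0 <- coarse[which.min(mc)]
  fine <- seq(max(c0 - 0.5, search_range[1]),
              min(c0 + 0.5, search_range[2]), by = 0.05)
  mf <- scan(fine)
  fine[which.min(mf)]
}

#' SRK/T intraocular lens power
#'
#' The Sanders-Retzlaff-Kraft theoretical formula (Retzlaff, Sanders &
#' Kraft 1990, J Cataract Refract Surg 16:333-340, with the published
#' errata), the clinical-standard comparator: corneal-height estimate of
#' the post-operative chamber depth, retinal-thickness-corrected axial
#' length, net corneal power from the keratometric index 1.3375, and a
#' thin-lens vergence solution.  All formula constants are from the
#' original publication.
#'
#' @param axial_length axial length, mm, in (18, 32).
#' @param K corneal power in dioptres (alternative to `radius`), in
#'   (35, 52).
#' @param radius keratometric radius, mm (K = 337.5 / radius).
#' @param a_constant the IOL's A-constant (calibration constant of the
#'   lens family; see [calibrate_a_constant()] for deriving one for a
#'   synthetic family).
#' @param target_refraction desired post-operative refraction, D (default
#'   0 = emmetropia), at `vertex_distance`.
#' @param vertex_distance spectacle vertex distance, mm.
#' @param round_step if non-`NULL`, round the result to this step (0.5 for
#'   available IOL powers).
#' @return IOL power in dioptres (vectorized over `axial_length` and
#'   `K`/`radius`).
#' @export
srkt_iol_power <- function(axial_length, K = NULL, radius = NULL,
                           a_constant = 118.4, target_refraction = 0,
                           vertex_distance = 12, round_step = NULL) {
  if (is.null(K)) {
    if (is.null(radius)) stop("supply K or radius")
    K <- 337.5 / radius
  }
  n <- max(length(axial_length), length(K))
  AL <- rep_len(axial_length, n); K <- rep_len(K, n)
  if (any(AL <= 18 | AL >= 32))
    stop("axial length outside the SRK/T validity bounds (18, 32) mm")
  if (any(K <= 35 | K >= 52))
    stop("corneal power outside the SRK/T validity bounds (35, 52) D")
  r <- 337.5 / K
  LCOR <- ifelse(AL > 24.2, -3.446 + 1.716 * AL - 0.0237 * AL^2, AL)
  Cw <- -5.41 + 0.58412 * LCOR + 0.098 * K
  H <- r - sqrt(pmax(r^2 - Cw^2 / 4, 0))
  acd_const <- 0.62467 * a_constant - 68.747
  ACDest <- H + acd_const - 3.336
  rethick <- 0.65696 - 0.02029 * AL
  L <- AL + rethick
  na <- 1.336; ncm1 <- 0.333
  REF <- target_refraction; V <- vertex_distance
  P <- (1000 * na * (na * r - ncm1 * L) -
          REF * (V * (na * r - ncm1 * L) + L * r)) /
    ((L - ACDest) * (na * r - ncm1 * ACDest) -
       0.001 * REF * (V * (na * r - ncm1 * ACDest) + ACDest * r))
  if (!is.null(round_step)) P <- round(P / round_step) * round_step
  P
}

#' Calibrate an SRK/T A-constant against the ray-traced model
#'
#' A-constants are empirical calibration constants tied to a specific lens
#' design; a synthetic IOL family has none until one is derived.  The
#' standard clinical procedure is A-constant personalization: choose A so
#' the formula's mean prediction error over a set of reference eyes is
#' zero.  Here the reference powers are ray-traced optima: given one or
#' more reference eyes, the returned A makes the mean SRK/T emmetropic
#' power equal the mean ray-traced power.
#'
#' @param model_power ray-traced optimal power(s) for the reference
#'   eye(s), D.
#' @param axial_length,radius the reference eyes' axial lengths (mm) and
#'   keratometric radii (mm), same length as `model_power`.
#' @param interval search interval for A.
#' @return the calibrated A-constant.
#' @export
calibrate_a_constant <- function(model_power, axial_length, radius,
                                 interval = c(110, 126)) {
  f <- function(A) mean(srkt_iol_power(axial_length, radius = radius,
                                       a_constant = A) - model_power)
  stats::uniroot(f, interval, tol = 1e-8)$root
}

#' Compare IOL-power series from two methods
#'
#' The statistical harness for method comparison: Pearson correlation,
#' linear regression `model = B * comparator + A` with standard errors,
#' paired and unpaired t-tests, and mean/median absolute differences.
#'
#' @param model,comparator numeric vectors of IOL powers, D, same length
#'   (at least 3).
#' @return An object of class `method_comparison`.
#' @export
compare_methods <- function(model, comparator) {
  stopifnot(length(model) == length(comparator), length(model) >= 3)
  if (stats::sd(model) == 0 || stats::sd(comparator) == 0)
    stop("zero variance in one of the series; comparison undefined")
  ct <- stats::cor.test(comparator, model)
  fit <- stats::lm(model ~ comparator)
  # a perfect fit (identical methods) is legitimate input; summary.lm
  # warns about it
  sm <- suppressWarnings(summary(fit))$coefficients
  d <- model - comparator
  pt <- tryCatch(stats::t.test(model, comparator, paired = TRUE),
                 error = function(e) list(p.value = NA_real_))
  ut <- stats::t.test(model, comparator, paired = FALSE)
  structure(list(n = length(model),
                 pearson_r = unname(ct$estimate),
                 pearson_p = ct$p.value,
                 intercept = sm[1, 1], intercept_se = sm[1, 2],
                 slope = sm[2, 1], slope_se = sm[2, 2],
                 mean_model = mean(model), sd_model = stats::sd(model),
                 mean_comparator = mean(comparator),
                 sd_comparator = stats::sd(comparator),
                 mean_diff = mean(d),
                 mean_abs_diff = mean(abs(d)),
                 median_abs_diff = stats::median(abs(d)),
                 paired_t_p = pt$p.value,
                 unpaired_t_p = ut$p.value),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> n = %d\n", x$n))
  cat(sprintf("  r = %.3f (p = %.2g); model = %.3f x comparator %+.3f\n",
              x$pearson_r, x$pearson_p, x$slope, x$intercept))
  cat(sprintf("  means %.2f vs %.2f D; mean |diff| %.2f D (median %.2f)\n",
              x$mean_model, x$mean_comparator, x$mean_abs_diff,
              x$median_abs_diff))
  cat(sprintf("  paired t p = %.2g, unpaired t p = %.2g\n",
              x$paired_t_p, x$unpaired_t_p))
  invisible(x)
}
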