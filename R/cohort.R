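#' Simulate a cohort of synthetic eyes
#'
#' Draws biometry from Gaussian population distributions (defaults: the
#' pre-LASIK myopic population means and SDs — anterior corneal radius
#' 7.74 +/- 0.26 mm, ACD 3.04 +/- 0.31 mm, lens thickness 3.87 +/- 0.36 mm,
#' vitreous depth 16.96 +/- 1.05 mm, refraction -3.07 +/- 1.95 D),
#' truncated at the biometry validation bounds by rejection, and generates
#' for each eye conic anterior and posterior elevation grids with
#' topographer-grade correlated sag noise.  The anterior asphericity is
#' Q = -0.18 by default; the posterior surface keeps the schematic
#' posterior-to-anterior radius ratio (6.40 / 7.77) and Q = -0.60, since
#' real corneas maintain a roughly constant ratio between the two
#' surfaces.  With `lasik = TRUE` each eye additionally receives a
#' Munnerlyn myopic ablation of the anterior surface matched to its drawn
#' refraction (or a fixed `correction`).
#'
#' @param n number of eyes.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param population named list overriding any of the defaults
#'   `radius_mean`, `radius_sd`, `acd_mean`, `acd_sd`, `lt_mean`, `lt_sd`,
#'   `vd_mean`, `vd_sd`, `cct`, `Q`, `refraction_mean`, `refraction_sd`.
#' @param noise_sd per-node sag noise SD, mm (default 0.002 =
#'   2 micrometres, elevation-topography repeatability grade).
#' @param lasik apply a myopic ablation per eye (default `FALSE`).
#' @param correction fixed ablation correction in D for all eyes; `NULL`
#'   (default) uses each eye's drawn refraction.
#' @param optical_zone ablation zone, mm.
#' @param grid_n elevation grid nodes per axis.
#' @return An object of class `eye_cohort`: a list of eyes, each with
#'   `id`, `biometry`, `anterior` and `posterior` ([elevation_grid()]s),
#'   `refraction`, and (if ablated) `correction`.
#' @export
simulate_cohort <- function(n, seed = NULL, population = list(),
                            noise_sd = 0.002, lasik = FALSE,
                            correction = NULL, optical_zone = 6,
                            grid_n = 59) {
  stopifnot(n >= 1)
  def <- list(radius_mean = 7.74, radius_sd = 0.26,
              acd_mean = 3.04, acd_sd = 0.31,
              lt_mean = 3.87, lt_sd = 0.36,
              vd_mean = 16.96, vd_sd = 1.05,
              cct = 0.55, Q = -0.18,
              refraction_mean = -3.07, refraction_sd = 1.95)
  unknown <- setdiff(names(population), names(def))
  if (length(unknown)) stop("unknown population fields: ",
                            paste(unknown, collapse = ", "))
  pop <- utils::modifyList(def, population)
  rtrunc <- function(mean, sd, lo, hi) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lo && v < hi) return(v)
    }
  }
  eyes <- with_local_seed(seed, lapply(seq_len(n), function(i) {
    R   <- rtrunc(pop$radius_mean, pop$radius_sd, 6.2, 9.3)
    acd <- rtrunc(pop$acd_mean, pop$acd_sd, 1.5, 5.5)
    lt  <- rtrunc(pop$lt_mean, pop$lt_sd, 2.5, 6.0)
    vd  <- rtrunc(pop$vd_mean, pop$vd_sd, 12, 22)
    refr <- rtrunc(pop$refraction_mean, pop$refraction_sd, -10, 2)
    g <- synth_conic_grid(R, pop$Q, n = grid_n, noise_sd = noise_sd)
    post_ratio <- eye_constants$cornea_posterior_radius /
      eye_constants$cornea_anterior_radius
    gp <- synth_conic_grid(R * post_ratio, eye_constants$cornea_posterior_Q,
                           n = grid_n, noise_sd = noise_sd,
                           surface_label = "posterior")
    corr <- NULL
    if (lasik) {
      corr <- if (is.null(correction)) min(refr, 0) else correction
      g <- apply_lasik_ablation(g, corr, optical_zone)
    }
    list(id = sprintf("eye%03d", i),
         biometry = biometry(acd, lt, vd, pop$cct, keratometric_radius = R),
         anterior = g,
         posterior = gp,
         refraction = refr,
         correction = corr)
  }))
  structure(eyes, class = "eye_cohort")
}

#' @export
print.eye_cohort <- function(x, ...) {
  al <- vapply(x, function(e) e$biometry$axial_length, 0)
  r <- vapply(x, function(e) e$biometry$keratometric_radius, 0)
  cat(sprintf("<eye_cohort> %d eyes, AL %.2f +/- %.2f mm, radius %.2f +/- %.2f mm%s\n",
              length(x), mean(al), stats::sd(al), mean(r), stats::sd(r),
              if (!is.null(x[[1]]$correction)) " (post-LASIK)" else ""))
  invisible(x)
}
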