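#' Corneal elevation grid
#'
#' A square Cartesian grid of corneal sag (axial elevation) samples over a
#' circular aperture, the raw product of elevation topography.  The default
#' geometry is a 59 x 59 grid over a 10 mm diameter.  Sag is measured in mm
#' along the optical axis (+z towards the retina) relative to the plane
#' tangent at the surface apex, so a convex cornea has sag increasing away
#' from the centre.  Rows run along y (superior-inferior), columns along x
#' (temporal-nasal).  Nodes outside the inscribed circle are masked (`NA`).
#'
#' @param sag numeric square matrix of sag values in mm; `NA` marks masked
#'   nodes.
#' @param aperture_diameter grid aperture in mm (default 10).
#' @param surface_label `"anterior"` or `"posterior"`.
#' @return An object of class `elevation_grid` with fields `sag`,
#'   `aperture_diameter`, `spacing`, `surface_label`, and node coordinate
#'   vectors `x`, `y`.
#' @export
elevation_grid <- function(sag, aperture_diameter = 10,
                           surface_label = c("anterior", "posterior")) {
  surface_label <- match.arg(surface_label)
  sag <- as.matrix(sag)
  if (nrow(sag) != ncol(sag))
    stop(sprintf("elevation grid must be square, got %d x %d",
                 nrow(sag), ncol(sag)))
  n <- nrow(sag)
  if (n < 5L) stop("grid too small: need at least 5 x 5 nodes")
  if (!is.numeric(aperture_diameter) || aperture_diameter <= 0)
    stop("aperture_diameter must be positive")
  a <- aperture_diameter / 2
  xy <- seq(-a, a, length.out = n)
  hh <- sqrt(outer(xy^2, xy^2, `+`))  # rows y, cols x; symmetric so order moot
  outside <- hh > a + 1e-9
  sag[outside] <- NA_real_
  inside <- !outside
  if (any(!is.finite(sag[inside]) & !is.na(sag[inside])))
    stop("non-finite sag values inside the aperture")
  structure(list(sag = sag,
                 aperture_diameter = aperture_diameter,
                 spacing = aperture_diameter / (n - 1),
                 surface_label = surface_label,
                 x = xy, y = xy),
            class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  n <- nrow(x$sag)
  cat(sprintf("<elevation_grid> %s surface, %d x %d over %.1f mm aperture\n",
              x$surface_label, n, n, x$aperture_diameter))
  s <- x$sag[!is.na(x$sag)]
  cat(sprintf("  sag range [%.4f, %.4f] mm, %d masked nodes\n",
              min(s), max(s), sum(is.na(x$sag))))
  invisible(x)
}

#' Sag of a conic (rotationally symmetric aspheric) surface
#'
#' `z(h) = h^2 / (R (1 + sqrt(1 - (1+Q) h^2 / R^2)))` for apical radius of
#' curvature `R` and asphericity `Q` (`Q = 0` sphere, `Q < 0` prolate).
#' `R` may be negative (surface curving towards -z) or `Inf` (plane).
#'
#' @param h radial distance from the axis, mm (vectorized).
#' @param R apical radius of curvature, mm.
#' @param Q conic asphericity.
#' @return sag in mm; an error if the conic is not real at some `h`.
#' @export
conic_sag <- function(h, R, Q = 0) {
  if (is.infinite(R)) return(rep(0, length(h)))
  arg <- 1 - (1 + Q) * h^2 / R^2
  if (any(arg < 0))
    stop("conic sag undefined: 1 - (1+Q) h^2/R^2 < 0 within the aperture")
  h^2 / (R * (1 + sqrt(arg)))
}

#' Generate a synthetic conic (optionally toric, noisy) elevation grid
#'
#' Emulates the elevation export of a topographer for an ideal cornea:
#' a conic of apical radius `R` and asphericity `Q`, an optional toric
#' component, and optional Gaussian measurement noise.  The toric term adds
#' paraxial cylinder: curvature along the steep meridian (`axis_deg` from
#' the +x axis) is `1/R_steep` instead of `1/R`, applied as an additional
#' `(1/R_steep - 1/R) * u^2 / 2` sag where `u` is the coordinate along the
#' steep meridian.
#'
#' @param R apical radius of curvature, mm.
#' @param Q conic asphericity (default 0, a sphere).
#' @param aperture_diameter grid aperture, mm (default 10).
#' @param n nodes per axis (default 59).
#' @param toricity `NULL`, or `list(R_steep = , axis_deg = )`.
#' @param noise_sd standard deviation of the sag perturbation, mm
#'   (default 0; reconstructed elevation maps deviate from a best conic by
#'   roughly 1e-3 to 2e-3 mm RMS).
#' @param noise_correlation correlation length of the perturbation, mm
#'   (default 1.0).  Elevation reconstruction yields smooth maps, so the
#'   perturbation field is white noise blurred to this length scale and
#'   rescaled to `noise_sd`; 0 gives (nonphysical) independent per-node
#'   noise.
#' @param seed optional integer seed for the noise (local RNG, does not
#'   disturb the global RNG stream).
#' @param surface_label `"anterior"` (default) or `"posterior"`.
#' @return An [elevation_grid()].
#' @examples
#' g <- synth_conic_grid(R = 7.77, Q = -0.18)
#' @export
synth_conic_grid <- function(R, Q = 0, aperture_diameter = 10, n = 59,
                             toricity = NULL, noise_sd = 0,
                             noise_correlation = 1.0, seed = NULL,
                             surface_label = "anterior") {
  a <- aperture_diameter / 2
  if (!is.infinite(R) && abs(R) <= a)
    stop("apical radius must exceed the aperture radius")
  xy <- seq(-a, a, length.out = n)
  X <- matrix(xy, n, n, byrow = TRUE)   # columns = x
  Y <- matrix(xy, n, n)                 # rows = y
  H2 <- X^2 + Y^2
  sag <- matrix(NA_real_, n, n)
  inside <- H2 <= a^2 + 1e-9
  sag[inside] <- conic_sag(sqrt(H2[inside]), R, Q)
  if (!is.null(toricity)) {
    stopifnot(is.list(toricity), !is.null(toricity$R_steep))
    ax <- (if (is.null(toricity$axis_deg)) 0 else toricity$axis_deg) * pi / 180
    u <- X * cos(ax) + Y * sin(ax)
    dc <- 1 / toricity$R_steep - 1 / R
    sag[inside] <- sag[inside] + dc * u[inside]^2 / 2
  }
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, matrix(stats::rnorm(n * n), n, n))
    spacing <- aperture_diameter / (n - 1)
    if (noise_correlation > 0)
      noise <- .gauss_blur(noise, noise_correlation / spacing)
    noise <- noise * noise_sd / stats::sd(noise)
    sag[inside] <- sag[inside] + noise[inside]
  }
  elevation_grid(sag, aperture_diameter, surface_label)
}

#' Apply a synthetic myopic LASIK ablation to an elevation grid
#'
#' Subtracts tissue from the anterior surface inside the optical zone
#' following the parabolic (Munnerlyn-type) profile: central ablation depth
#' `S^2 |D| / 3` micrometres for an optical zone of `S` mm and a correction
#' of `D` dioptres, tapering quadratically to zero at the zone edge.
#' Removing tissue moves the surface towards the retina, so the sag
#' increases centrally and the front surface flattens by approximately `D`
#' dioptres of keratometric power.  Outside the zone the grid is unchanged.
#'
#' @param grid an [elevation_grid()].
#' @param correction refractive correction in dioptres; negative = myopic
#'   (the profile is the myopic one; positive values steepen centrally and
#'   are only a sign-reversed convenience, not a hyperopic nomogram).
#' @param optical_zone ablation zone diameter, mm (default 6).
#' @return the ablated [elevation_grid()].
#' @export
apply_lasik_ablation <- function(grid, correction, optical_zone = 6) {
  stopifnot(inherits(grid, "elevation_grid"))
  if (optical_zone > grid$aperture_diameter)
    stop("optical_zone exceeds the grid aperture")
  if (correction == 0) return(grid)
  n <- nrow(grid$sag)
  X <- matrix(grid$x, n, n, byrow = TRUE)
  Y <- matrix(grid$y, n, n)
  h <- sqrt(X^2 + Y^2)
  S <- optical_zone
  t0 <- S^2 * abs(correction) / 3 / 1000  # central depth, mm
  depth <- ifelse(h <= S / 2, t0 * (1 - (2 * h / S)^2), 0)
  # myopic (correction < 0): tissue removed centrally, surface recedes
  # towards the retina, sag increases
  sag <- grid$sag + ifelse(correction < 0, 1, -1) * depth
  elevation_grid(sag, grid$aperture_diameter, grid$surface_label)
}

#' Write an elevation grid to the plain-text grid format
#'
#' The format is a small self-describing text file: comment/header lines
#' `aperture_diameter`, `spacing`, `surface`, `rows`, `cols`, followed by
#' the sag matrix, whitespace-separated, one grid row per line, `NA` for
#' masked nodes.  Values are written at full double precision (17
#' significant digits), so a save/load round trip is bit-exact.
#'
#' @param grid an [elevation_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_elevation_grid <- function(grid, path) {
  stopifnot(inherits(grid, "elevation_grid"))
  n <- nrow(grid$sag)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# corneal elevation grid v1",
               sprintf("aperture_diameter %.9g", grid$aperture_diameter),
               sprintf("spacing %.9g", grid$spacing),
               sprintf("surface %s", grid$surface_label),
               sprintf("rows %d", n),
               sprintf("cols %d", n)), con)
  body <- apply(grid$sag, 1L, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Read an elevation grid from the plain-text grid format
#'
#' @param path file written by [save_elevation_grid()] (see there for the
#'   format).
#' @param surface_label optional override of the label stored in the file.
#' @return An [elevation_grid()].
#' @export
load_elevation_grid <- function(path, surface_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[a-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[kv[1]]] <- kv[2]
    i <- i + 1L
  }
  for (key in c("aperture_diameter", "rows", "cols"))
    if (is.null(hdr[[key]]))
      stop("malformed grid file: missing header line '", key, "'")
  nr <- as.integer(hdr$rows); nc <- as.integer(hdr$cols)
  if (nr != nc)
    stop(sprintf("elevation grid must be square, header says %d x %d", nr, nc))
  body <- lines[i:length(lines)]
  if (length(body) != nr)
    stop(sprintf("malformed grid file: expected %d matrix rows, found %d",
                 nr, length(body)))
  sag <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    vals <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(vals) != nc)
      stop(sprintf("malformed grid file: row %d has %d columns, expected %d",
                   r, length(vals), nc))
    v <- suppressWarnings(as.numeric(ifelse(vals == "NA", NA, vals)))
    bad <- which(is.na(v) & vals != "NA")
    if (length(bad))
      stop(sprintf("malformed grid file: row %d column %d is not numeric ('%s')",
                   r, bad[1], vals[bad[1]]))
    sag[r, ] <- v
  }
  elevation_grid(sag, as.numeric(hdr$aperture_diameter),
                 if (is.null(surface_label)) hdr$surface %||% "anterior"
                 else surface_label)
}
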