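#' Run configuration
#'
#' One structure holding every tunable of the pipeline, so all model
#' constants that are not individually measured are visible and
#' overridable in one place.  Unknown keys are rejected (typos should not
#' silently fall back to defaults).
#'
#' @param config named list or path to a YAML file.  Recognized blocks
#'   (with defaults):
#'   \describe{
#'   \item{iol_family}{`shape_factor` 0, `thickness` 1.0, `n_555` 1.47,
#'     `power_range` c(5, 35).}
#'   \item{eye}{settings passed to [build_pseudophakic_eye()]:
#'     `pupil_diameter` 4, `pupil_decentration` 0.5, `kappa_deg` 5,
#'     `retina_radius` 12, `iris_offset` 0, `stiles_crawford` TRUE,
#'     `sc_alpha` 0.05.}
#'   \item{sampling}{`grid_density` 36, `freq_max` 100, `freq_step` 2,
#'     `csf_model` "mannos".}
#'   \item{optimization}{`power_range` c(5, 35), `step` 0.5.}
#'   \item{seed}{integer RNG seed (default 1).}
#'   }
#' @return validated config, class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(
    iol_family = list(shape_factor = 0, thickness = 1.0, n_555 = 1.47,
                      power_range = c(5, 35)),
    eye = list(pupil_diameter = 4, pupil_decentration = 0.5, kappa_deg = 5,
               retina_radius = 12, iris_offset = 0, stiles_crawford = TRUE,
               sc_alpha = 0.05),
    sampling = list(grid_density = 36, freq_max = 100, freq_step = 2,
                    csf_model = "mannos"),
    optimization = list(power_range = c(5, 35), step = 0.5),
    seed = 1L)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (blk in setdiff(names(def), "seed")) {
    extra <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(extra))
      stop(sprintf("unknown config keys in '%s': %s", blk,
                   paste(extra, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config)
  with(cfg$sampling, stopifnot(grid_density >= 8, freq_max > 0,
                               freq_step > 0))
  stopifnot(cfg$optimization$step > 0, cfg$iol_family$thickness > 0)
  structure(cfg, class = "run_config")
}

#' Run the full per-eye pipeline
#'
#' For each row of a biometry table: load the corneal elevation grids, fit
#' the spline surfaces, assemble the personalized pseudophakic eye across
#' the power scan, optimize the IOL power and record the result.  A
#' failing eye is recorded as an error and the run continues.
#'
#' @param biometry_table data frame (or CSV path) with columns `id`,
#'   `acd_pre`, `lens_thickness`, `vitreous_depth`, `corneal_thickness`,
#'   optional `keratometric_radius`, `topo_anterior`, `topo_posterior`
#'   (grid-file paths; `topo_posterior` may be `NA` for the schematic
#'   posterior).
#' @param config a [run_config()] (or list/path coerced through it).
#' @param out optional path for a JSON result bundle.
#' @return list of per-eye results (`id`, `best_power`, `merit`,
#'   `merit_trace`, or `error`), class `run_result`, with attribute
#'   `n_failed`.
#' @export
run_pipeline <- function(biometry_table, config = run_config(), out = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.character(biometry_table))
    biometry_table <- utils::read.csv(biometry_table,
                                      stringsAsFactors = FALSE)
  need <- c("id", "acd_pre", "lens_thickness", "vitreous_depth",
            "topo_anterior")
  miss <- setdiff(need, names(biometry_table))
  if (length(miss))
    stop("biometry table is missing column(s): ",
         paste(miss, collapse = ", "))
  freq <- seq(0, config$sampling$freq_max, by = config$sampling$freq_step)
  csf <- csf_weights(freq, model = config$sampling$csf_model)
  results <- lapply(seq_len(nrow(biometry_table)), function(i) {
    row <- biometry_table[i, ]
    tryCatch({
      biom <- biometry(row$acd_pre, row$lens_thickness, row$vitreous_depth,
                       if ("corneal_thickness" %in% names(row) &&
                           is.finite(row$corneal_thickness))
                         row$corneal_thickness else NULL,
                       keratometric_radius =
                         if ("keratometric_radius" %in% names(row))
                           row$keratometric_radius else NULL)
      ant <- load_elevation_grid(row$topo_anterior, "anterior")
      post <- if ("topo_posterior" %in% names(row) &&
                  !is.na(row$topo_posterior) && nzchar(row$topo_posterior))
        load_elevation_grid(row$topo_posterior, "posterior") else NULL
      builder <- make_eye_builder(ant, post, biom,
                                  settings = config$eye,
                                  iol_family = config$iol_family)
      res <- optimize_iol_power(builder,
                                power_range = config$optimization$power_range,
                                step = config$optimization$step,
                                grid_density = config$sampling$grid_density,
                                frequency = freq, csf = csf)
      list(id = as.character(row$id), best_power = res$best_power,
           merit = res$merit, boundary = res$boundary,
           merit_trace = res$merit_trace)
    }, error = function(e)
      list(id = as.character(row$id), error = conditionMessage(e)))
  })
  n_failed <- sum(vapply(results, function(r) !is.null(r$error), TRUE))
  out_obj <- structure(results, class = "run_result", n_failed = n_failed)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(schema = "pseudophakia/run_result/v1",
           results = lapply(results, function(r) {
             r$merit_trace <- NULL; r
           })),
      out, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  out_obj
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d eyes, %d failed\n", length(x),
              attr(x, "n_failed")))
  for (r in x) {
    if (is.null(r$error))
      cat(sprintf("  %s: %.1f D (merit %.4f)%s\n", r$id, r$best_power,
                  r$merit, if (isTRUE(r$boundary)) " [boundary]" else ""))
    else cat(sprintf("  %s: ERROR %s\n", r$id, r$error))
  }
  invisible(x)
}

#' Write an MTF curve as CSV
#'
#' @param mtf an [mtf_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mtf_csv <- function(mtf, path) {
  stopifnot(inherits(mtf, "mtf_curve"))
  utils::write.csv(data.frame(frequency_cyc_mm = mtf$frequency,
                              modulation = mtf$modulation),
                   path, row.names = FALSE)
  invisible(path)
}
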