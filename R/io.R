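#' Read and write raster maps as CSV with a JSON sidecar
#'
#' Maps travel as plain 2D CSV grids (no header, one row per raster row)
#' with a `<path>.json` sidecar holding the geometry (pixel size, disc
#' centre, laterality) and, for masks, a 0/1 encoding. This keeps every
#' artifact diffable and language-neutral.
#'
#' @param map an `intensity_map` or `reflectance_map`.
#' @param path CSV file path; the sidecar goes to `paste0(path, ".json")`.
#' @export
write_map_csv <- function(map, path) {
  vals <- map_values(map)
  utils::write.table(vals, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(pixel_size_mm = map$pixel_size_mm,
               disc_center = map$disc_center, laterality = map$laterality,
               class = class(map)[1])
  if (inherits(map, "reflectance_map")) {
    meta$normalization_constant <- map$normalization_constant
    utils::write.table(map$valid_mask * 1L, paste0(path, ".valid.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(map$disc_mask * 1L, paste0(path, ".disc.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(map$vessel_mask * 1L, paste0(path, ".vessel.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map_csv
#' @return `read_map_csv` returns the reconstructed map object.
#' @export
read_map_csv <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$class, "reflectance_map")) {
    valid <- as.matrix(utils::read.table(paste0(path, ".valid.csv"),
                                         sep = ",")) == 1
    dimnames(valid) <- NULL
    vals[!valid] <- NA_real_
    new_reflectance_map(vals, valid, meta$pixel_size_mm, meta$disc_center,
                        meta$laterality, meta$normalization_constant)
  } else {
    rd <- function(sfx) {
      m <- as.matrix(utils::read.table(paste0(path, sfx), sep = ",")) == 1
      dimnames(m) <- NULL
      m
    }
    intensity_map(vals, meta$pixel_size_mm, meta$disc_center,
                  rd(".disc.csv"), rd(".vessel.csv"), meta$laterality)
  }
}

#' Serialize a normative model to JSON
#'
#' Full-precision JSON holding the covariate coefficients, reference
#' points, per-superpixel reference distribution and cutoffs, and the map
#' normalization constant.
#'
#' @param model a fitted `nfl_normative`.
#' @param path output JSON path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "nfl_normative"))
  keep <- c("coefficients", "se", "p_values", "reference_age",
            "reference_axl", "method", "n_normal", "n_superpixels",
            "normalization_constant", "mu", "sigma", "q5", "q1")
  obj <- model[keep]
  obj$coefficients <- as.list(model$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json` returns the reconstructed `nfl_normative`
#'   (without the training-cohort adjusted values).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  structure(obj, class = "nfl_normative")
}

#' Write per-eye diagnostic results as CSV
#'
#' One row per eye with stable column order; floats at full precision.
#'
#' @param results data frame from [predict.nfl_normative()] or
#'   [bootstrap_632()].
#' @param path output CSV path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' Write the evaluation tables of [evaluate_cohort()]
#'
#' Each non-`NULL` table goes to `<dir>/<name>.csv`.
#'
#' @param tables list from [evaluate_cohort()].
#' @param dir output directory (created if missing).
#' @return Character vector of paths written.
#' @export
write_evaluation <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]]) || !is.data.frame(tables[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Render a map or significance grid to PNG
#'
#' Grayscale rendering of a reflectance map (clipped to a dB window), or a
#' three-colour rendering of a significance raster. Requires the
#' \pkg{png} package.
#'
#' @param map a `reflectance_map`.
#' @param path output PNG path.
#' @param db_range dB window mapped to black..white.
#' @export
render_map_png <- function(map, path, db_range = c(-8, 4)) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("render_map_png needs the 'png' package")
  v <- map_values(map)
  g <- (v - db_range[1]) / diff(db_range)
  g[!is.finite(g)] <- 0
  g <- pmin(pmax(g, 0), 1)
  png::writePNG(g, path)
  invisible(path)
}

#' Export the superpixel grid as a labelled raster
#'
#' Writes the membership raster as CSV with integer codes 0..159 inside the
#' annulus and -1 outside, plus a JSON sidecar with the grid parameters.
#'
#' @param grid a [build_grid()] result.
#' @param path CSV file path.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "superpixel_grid"))
  lab <- grid$membership - 1L
  lab[is.na(lab)] <- -1L
  utils::write.table(lab, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(n_tracks = grid$n_tracks, n_segments = grid$n_segments,
         r_in = grid$r_in, r_out = grid$r_out, npx = grid$npx,
         pixel_size_mm = grid$pixel_size_mm,
         boundaries = grid$boundaries,
         trajectory = list(type = grid$trajectory$type,
                           curvature = grid$trajectory$curvature)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
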