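#' Normalized NFL reflectance map
#'
#' Result of dividing the summed NFL-band intensity by the mean PPEC-band
#' intensity, inpainting vessels, dividing by a population normalization
#' constant and converting to decibels. Pixels inside the optic disc (and any
#' pixel where the reference band was unusable) are flagged invalid; only the
#' 1.1-2.0 mm peripapillary annulus is analysed downstream.
#'
#' @name reflectance_map
NULL

new_reflectance_map <- function(values_db, valid_mask, pixel_size_mm,
                                disc_center, laterality,
                                normalization_constant,
                                source_laterality = NULL) {
  structure(list(values_db = values_db, valid_mask = valid_mask,
                 pixel_size_mm = pixel_size_mm, disc_center = disc_center,
                 laterality = laterality,
                 source_laterality = source_laterality,
                 normalization_constant = normalization_constant),
            class = "reflectance_map")
}

#' @export
print.reflectance_map <- function(x, ...) {
  v <- x$values_db[x$valid_mask]
  cat(sprintf("<reflectance_map> %dx%d px, %.5f mm/px, %s\n",
              nrow(x$values_db), ncol(x$values_db), x$pixel_size_mm,
              x$laterality))
  cat(sprintf("  valid %d px; dB range [%.2f, %.2f]; norm const %.4g\n",
              sum(x$valid_mask), min(v), max(v), x$normalization_constant))
  invisible(x)
}

#' NFL/PPEC reflectance ratio map
#'
#' Divides the summed NFL-band intensity by the mean PPEC-band intensity
#' pixel by pixel. The ratio cancels attenuation common to both bands (media
#' opacity, defocus, beam coupling). Pixels where the reference intensity is
#' at or below a floor (`1e-6` times the PPEC median over usable pixels) are
#' flagged invalid and treated like vessels by downstream inpainting.
#'
#' @param nfl,ppec `intensity_map` objects on identical geometry.
#' @return A list with `ratio` (matrix), `invalid` (logical matrix of
#'   ppec-floor pixels) and the shared geometry fields.
#' @export
compute_ratio_map <- function(nfl, ppec) {
  stopifnot(inherits(nfl, "intensity_map"), inherits(ppec, "intensity_map"))
  if (!same_geometry(nfl, ppec))
    stop("NFL and PPEC maps differ in geometry")
  if (!identical(nfl$laterality, ppec$laterality))
    stop("NFL and PPEC maps differ in laterality")
  usable <- !(nfl$disc_mask | nfl$vessel_mask)
  eps <- 1e-6 * stats::median(ppec$values[usable & ppec$values > 0])
  if (!is.finite(eps)) stop("PPEC map has no positive usable pixels")
  bad <- ppec$values <= eps
  if (all(bad | nfl$disc_mask)) stop("ratio map has no valid pixels")
  ratio <- nfl$values / pmax(ppec$values, eps)
  ratio[bad] <- NA_real_
  list(ratio = ratio, invalid = bad,
       pixel_size_mm = nfl$pixel_size_mm, disc_center = nfl$disc_center,
       disc_mask = nfl$disc_mask, vessel_mask = nfl$vessel_mask | bad,
       laterality = nfl$laterality)
}

#' Fill vessel pixels from their neighbourhood
#'
#' Large retinal vessels displace nerve fibers, so reflectance under them is
#' not NFL signal. Masked pixels are replaced by iterative 4-neighbour mean
#' diffusion (Jacobi sweeps over masked pixels only) until the largest update
#' falls below `tol`, which converges to the discrete harmonic interpolant of
#' the surrounding values: continuous, order-independent, and incapable of
#' inventing values outside the local range. Unmasked pixels are returned
#' bit-identical.
#'
#' @param values numeric matrix (any scale).
#' @param mask logical matrix; `TRUE` pixels are replaced.
#' @param tol convergence tolerance on the largest per-sweep change.
#' @param max_iter sweep cap.
#' @return Matrix with masked pixels filled.
#' @export
inpaint_vessels <- function(values, mask, tol = 1e-6, max_iter = 2000L) {
  stopifnot(identical(dim(values), dim(mask)))
  if (!any(mask)) return(values)
  if (all(mask | !is.finite(values))) stop("mask covers the entire valid region")
  n <- nrow(values); m <- ncol(values)
  out <- values
  out[mask] <- NA_real_
  idx <- which(mask)
  # neighbour linear indices, NA outside the raster
  ri <- (idx - 1L) %% n + 1L; ci <- (idx - 1L) %/% n + 1L
  nb <- cbind(ifelse(ri > 1L, idx - 1L, NA),
              ifelse(ri < n,  idx + 1L, NA),
              ifelse(ci > 1L, idx - n,  NA),
              ifelse(ci < m,  idx + n,  NA))
  out[idx] <- mean(out[is.finite(out)])
  for (it in seq_len(max_iter)) {
    v <- matrix(out[nb], nrow = length(idx))
    new <- rowMeans(v, na.rm = TRUE)
    delta <- max(abs(new - out[idx]), na.rm = TRUE)
    out[idx] <- new
    if (delta < tol) break
  }
  out
}

#' Convert a normalized ratio map to decibels
#'
#' Divides the ratio map by the population normalization constant (the
#' normal-cohort average of per-eye annulus-mean ratios, see
#' [fit_normative()]) and applies `10 * log10`. The 10-log convention treats
#' OCT intensity as a power quantity; `db_factor = 20` is available for an
#' amplitude convention.
#'
#' @param ratio list from [compute_ratio_map()] (with vessels inpainted) or a
#'   bare matrix plus geometry arguments.
#' @param normalization_constant positive linear-scale scalar.
#' @param db_factor 10 (power, default) or 20 (amplitude).
#' @param extra_invalid optional logical matrix of additional invalid pixels.
#' @return A `reflectance_map`.
#' @export
normalize_to_db <- function(ratio, normalization_constant, db_factor = 10,
                            extra_invalid = NULL) {
  if (!is.numeric(normalization_constant) || normalization_constant <= 0)
    stop("normalization_constant must be positive")
  if (is.list(ratio)) {
    vals <- ratio$ratio
    geom <- ratio
  } else stop("ratio must be the list returned by compute_ratio_map()")
  db <- db_factor * log10(vals / normalization_constant)
  valid <- is.finite(db) & !geom$disc_mask
  if (!is.null(extra_invalid)) valid <- valid & !extra_invalid
  db[!valid] <- NA_real_
  new_reflectance_map(db, valid, geom$pixel_size_mm, geom$disc_center,
                      geom$laterality, normalization_constant)
}

#' Mean reflectance over the peripapillary annulus
#'
#' Mean of valid pixels with disc-centre distance in `[r_in, r_out]`; the
#' default 1.1-2.0 mm band is the analytic zone (inside 1.1 mm the disc and
#' peripapillary atrophy interfere; outside 2.0 mm scan decentration can crop
#' the raster).
#'
#' @param map a `reflectance_map`, or a plain matrix with `pixel_size_mm`
#'   and `disc_center` supplied.
#' @param r_in,r_out annulus radii in mm.
#' @return Scalar mean.
#' @export
annulus_mean <- function(map, r_in = 1.1, r_out = 2.0) {
  stopifnot(inherits(map, "reflectance_map") || is.list(map))
  vals <- if (inherits(map, "reflectance_map")) map$values_db else map$ratio
  valid <- if (inherits(map, "reflectance_map")) map$valid_mask else
    is.finite(vals) & !map$disc_mask
  pc <- map_polar_coords(map)
  sel <- valid & pc$r >= r_in & pc$r <= r_out
  if (!any(sel)) stop("annulus contains no valid pixels")
  mean(vals[sel])
}
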