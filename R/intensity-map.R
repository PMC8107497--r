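#' En-face OCT intensity map
#'
#' Container for a square en-face raster of linear-scale OCT intensity
#' centred on the optic disc, together with the disc and large-vessel masks
#' and the geometry needed to place pixels in millimetres. Two such maps feed
#' the reflectance pipeline: the axially *summed* intensity of the nerve
#' fiber layer (NFL) band and the axially *averaged* intensity of the
#' photoreceptor/pigment-epithelium complex (PPEC) band, the latter serving
#' as the reference that cancels beam-coupling losses.
#'
#' @param values numeric matrix, square, linear-scale intensity, non-negative
#'   outside the disc and vessel masks.
#' @param pixel_size_mm scalar pixel pitch; the default corresponds to a
#'   4.5 mm scan sampled by 400 A-lines.
#' @param disc_center numeric length-2, (x, y) position of the disc centre in
#'   mm relative to the raster centre; x increases rightwards, y upwards.
#' @param disc_mask,vessel_mask logical matrices of the same dimension;
#'   `NULL` means all-`FALSE`.
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @return An object of class `intensity_map`.
#' @export
intensity_map <- function(values, pixel_size_mm = 4.5 / 400,
                          disc_center = c(0, 0),
                          disc_mask = NULL, vessel_mask = NULL,
                          laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("intensity map must be square, got ", nrow(values), "x", ncol(values))
  if (is.null(disc_mask)) disc_mask <- matrix(FALSE, nrow(values), ncol(values))
  if (is.null(vessel_mask)) vessel_mask <- matrix(FALSE, nrow(values), ncol(values))
  stopifnot(identical(dim(disc_mask), dim(values)),
            identical(dim(vessel_mask), dim(values)))
  outside <- !(disc_mask | vessel_mask)
  if (any(values[outside] < 0, na.rm = TRUE))
    stop("negative intensity outside disc/vessel masks")
  half <- nrow(values) * pixel_size_mm / 2
  if (abs(disc_center[1]) >= half || abs(disc_center[2]) >= half)
    stop("disc_center lies outside the raster")
  structure(list(values = values, pixel_size_mm = pixel_size_mm,
                 disc_center = as.numeric(disc_center),
                 disc_mask = disc_mask, vessel_mask = vessel_mask,
                 laterality = laterality),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %dx%d px, %.5f mm/px, %s\n",
              nrow(x$values), ncol(x$values), x$pixel_size_mm, x$laterality))
  cat(sprintf("  disc at (%.3f, %.3f) mm; %d disc px, %d vessel px\n",
              x$disc_center[1], x$disc_center[2],
              sum(x$disc_mask), sum(x$vessel_mask)))
  invisible(x)
}

# Pixel-centre coordinates in mm relative to the disc centre.
# Row 1 is the top of the raster (y largest); column index increases with x.
map_coords <- function(n, pixel_size_mm, disc_center) {
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_size_mm
  list(x = matrix(rep(ax - disc_center[1], each = n), n, n),
       y = matrix(rep(rev(ax) - disc_center[2], times = n), n, n))
}

# Radius (mm) and azimuth (radians, [0, 2*pi), 0 = +x) of every pixel.
map_polar_coords <- function(map) {
  cc <- map_coords(nrow(map_values(map)), map$pixel_size_mm, map$disc_center)
  list(r = sqrt(cc$x^2 + cc$y^2),
       theta = (atan2(cc$y, cc$x)) %% (2 * pi))
}

map_values <- function(map) {
  if (!is.null(map$values_db)) map$values_db
  else if (!is.null(map$values)) map$values
  else map$ratio
}

same_geometry <- function(a, b) {
  identical(dim(map_values(a)), dim(map_values(b))) &&
    isTRUE(all.equal(a$pixel_size_mm, b$pixel_size_mm)) &&
    isTRUE(all.equal(a$disc_center, b$disc_center))
}

#' Mirror a left eye into right-eye orientation
#'
#' All analysis is performed in a common right-eye frame in which +x is
#' temporal. Left-eye (OS) maps are mirrored about the vertical axis so that
#' the nasal/temporal sides swap into the right-eye convention; right-eye
#' maps pass through unchanged. The operation is an involution on OS input
#' applied twice (mirroring restores the original raster).
#'
#' @param map an `intensity_map` or `reflectance_map`.
#' @return The map in right-eye orientation, with `laterality` set to `"OD"`
#'   and the original eye recorded in `source_laterality`.
#' @export
orient_right_eye <- function(map) {
  if (is.null(map$laterality) || !map$laterality %in% c("OD", "OS"))
    stop("laterality must be 'OD' or 'OS'")
  if (map$laterality == "OD") {
    if (is.null(map$source_laterality)) map$source_laterality <- "OD"
    return(map)
  }
  fliph <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  for (fld in c("values", "values_db", "disc_mask", "vessel_mask", "valid_mask"))
    if (!is.null(map[[fld]])) map[[fld]] <- fliph(map[[fld]])
  map$disc_center[1] <- -map$disc_center[1]
  map$source_laterality <- "OS"
  map$laterality <- "OD"
  map
}
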