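#' Nerve-fiber trajectory model
#'
#' Parametric model of the course of peripapillary nerve fiber bundles,
#' mapping an entry angle at the inner annulus radius to the azimuth of the
#' bundle at any radius. The default arcuate form bends bundles
#' progressively with radius, most strongly in the superior and inferior
#' arcuate regions and not at all at the horizontal meridians:
#' `theta(r; theta0) = theta0 + curvature * sin(theta0) * (r - r_in) /
#' (r_out - r_in)`. Trajectories never cross provided `|curvature| < 1`
#' (the Jacobian in `theta0` stays positive). `type = "radial"` gives
#' straight spokes.
#'
#' @param type `"arcuate"` or `"radial"`.
#' @param curvature total bend (radians) accumulated from `r_in` to `r_out`
#'   at the arcuate maxima; must satisfy `|curvature| < 1`.
#' @param r_in,r_out radial range in mm over which the model is used.
#' @return An object of class `trajectory_model` with functions
#'   `azimuth(r, theta0)` and `entry_angle(r, theta)` (its inverse).
#' @export
trajectory_model <- function(type = c("arcuate", "radial"), curvature = 0.5,
                             r_in = 1.1, r_out = 2.0) {
  type <- match.arg(type)
  if (type == "radial") curvature <- 0
  if (abs(curvature) >= 1) stop("|curvature| must be < 1 (non-crossing)")
  g <- function(r) pmin(pmax((r - r_in) / (r_out - r_in), 0), 1)
  azimuth <- function(r, theta0) (theta0 + curvature * sin(theta0) * g(r)) %% (2 * pi)
  entry_angle <- function(r, theta) {
    gg <- g(r)
    th0 <- theta
    for (i in 1:60) {                       # contraction, |curvature| < 1
      new <- theta - curvature * sin(th0) * gg
      if (max(abs(new - th0)) < 1e-12) { th0 <- new; break }
      th0 <- new
    }
    th0 %% (2 * pi)
  }
  structure(list(type = type, curvature = curvature, r_in = r_in,
                 r_out = r_out, azimuth = azimuth, entry_angle = entry_angle),
            class = "trajectory_model")
}

#' Normative angular nerve-fiber flux profile
#'
#' Stylized angular density of nerve fiber cross-sectional flux at the inner
#' annulus radius, built from von Mises bumps reproducing the double-hump
#' normal NFL profile: strong inferotemporal and superotemporal arcuate
#' peaks and a secondary superonasal peak over a flat base. Azimuth 0 is
#' temporal in right-eye orientation, increasing counterclockwise.
#'
#' @return A vectorized function of azimuth (radians) returning a strictly
#'   positive relative flux density.
#' @export
default_flux_profile <- function() {
  peaks <- cbind(mu = c(285, 60, 120) * pi / 180,
                 kappa = c(6, 6, 10),
                 height = c(1.0, 0.9, 0.35))
  function(theta) {
    f <- rep(0.35, length(theta))
    for (i in seq_len(nrow(peaks)))
      f <- f + peaks[i, "height"] *
        exp(peaks[i, "kappa"] * (cos(theta - peaks[i, "mu"]) - 1))
    f
  }
}

#' Equal-flux angular track boundaries
#'
#' Splits the circle into `n_tracks` angular tracks each carrying the same
#' integral of the flux profile, so that every track contains approximately
#' the same number of nerve fibers; tracks are narrow where the NFL is thick
#' (arcuate bundles) and wide where it is thin. Boundaries are found by
#' inverting the cumulative flux integral on a fine grid.
#'
#' @param flux a positive function of azimuth, or a numeric vector sampled
#'   uniformly over `[0, 2*pi)`.
#' @param n_tracks number of tracks.
#' @param origin azimuth (radians) of the first boundary; the default starts
#'   track 1 at the temporal horizontal.
#' @param n_grid integration grid size.
#' @return Sorted numeric vector of `n_tracks` boundary angles in radians,
#'   the first equal to `origin` (mod 2*pi).
#' @export
equal_flux_track_boundaries <- function(flux, n_tracks = 32, origin = 0,
                                        n_grid = 8192) {
  th <- origin + 2 * pi * (seq_len(n_grid) - 0.5) / n_grid
  f <- if (is.function(flux)) flux(th %% (2 * pi))
       else stats::approx(seq(0, 2 * pi, length.out = length(flux) + 1)[-(length(flux) + 1)],
                          flux, xout = th %% (2 * pi), rule = 2)$y
  if (any(!is.finite(f)) || any(f <= 0)) stop("flux profile must be strictly positive")
  cum <- c(0, cumsum(f)) * (2 * pi / n_grid)
  grid <- origin + 2 * pi * (0:n_grid) / n_grid
  targets <- cum[n_grid + 1] * (seq_len(n_tracks) - 1) / n_tracks
  b <- stats::approx(cum, grid, xout = targets, ties = "ordered")$y
  sort(b %% (2 * pi))
}

#' Build the 160-superpixel peripapillary grid
#'
#' Partitions the 1.1-2.0 mm annulus into `n_tracks` trajectory-aligned
#' angular tracks times `n_segments` equal-width radial rings. Each pixel is
#' assigned by tracing its position back along the trajectory model to an
#' entry angle at the inner radius, locating that angle among the equal-flux
#' track boundaries, and binning its radius. Superpixel `s` corresponds to
#' track `(s-1) %/% n_segments + 1` (track 1 starting at the temporal
#' horizontal, counterclockwise in right-eye orientation) and segment
#' `(s-1) %% n_segments + 1` (segment 1 innermost).
#'
#' @param boundaries entry-angle track boundaries from
#'   [equal_flux_track_boundaries()].
#' @param trajectory a [trajectory_model()].
#' @param npx raster size in pixels (square).
#' @param pixel_size_mm pixel pitch in mm.
#' @param disc_center disc-centre offset in mm.
#' @param n_segments radial segments (default 5).
#' @param r_in,r_out annulus radii in mm.
#' @return An object of class `superpixel_grid`: `membership` (integer
#'   matrix, 1..160 inside the annulus, `NA` outside), `n_tracks`,
#'   `n_segments`, `boundaries`, `trajectory`, geometry fields, and per-
#'   superpixel pixel counts.
#' @export
build_grid <- function(boundaries, trajectory = trajectory_model(),
                       npx = 400, pixel_size_mm = 4.5 / 400,
                       disc_center = c(0, 0), n_segments = 5,
                       r_in = 1.1, r_out = 2.0) {
  n_tracks <- length(boundaries)
  cc <- map_coords(npx, pixel_size_mm, disc_center)
  r <- sqrt(cc$x^2 + cc$y^2)
  theta <- atan2(cc$y, cc$x) %% (2 * pi)
  sel <- which(r >= r_in & r <= r_out)
  if (!length(sel)) stop("annulus contains no pixels at this resolution")
  th0 <- trajectory$entry_angle(r[sel], theta[sel])
  b1 <- boundaries[1]
  track <- findInterval((th0 - b1) %% (2 * pi), boundaries - b1,
                        rightmost.closed = FALSE)
  seg <- pmin(pmax(ceiling((r[sel] - r_in) / ((r_out - r_in) / n_segments)), 1L),
              n_segments)
  membership <- matrix(NA_integer_, npx, npx)
  membership[sel] <- (track - 1L) * n_segments + seg
  counts <- tabulate(membership[sel], nbins = n_tracks * n_segments)
  if (any(counts == 0))
    stop("empty superpixel(s) at this resolution: ",
         paste(which(counts == 0), collapse = ", "))
  structure(list(membership = membership, n_tracks = n_tracks,
                 n_segments = n_segments, boundaries = boundaries,
                 trajectory = trajectory, npx = npx,
                 pixel_size_mm = pixel_size_mm, disc_center = disc_center,
                 r_in = r_in, r_out = r_out, counts = counts),
            class = "superpixel_grid")
}

#' @export
print.superpixel_grid <- function(x, ...) {
  cat(sprintf("<superpixel_grid> %d tracks x %d segments = %d superpixels\n",
              x$n_tracks, x$n_segments, x$n_tracks * x$n_segments))
  cat(sprintf("  annulus %.2f-%.2f mm on %dx%d px; %d-%d px per superpixel\n",
              x$r_in, x$r_out, x$npx, x$npx, min(x$counts), max(x$counts)))
  invisible(x)
}

# track and segment index of superpixel s
sp_track <- function(s, n_segments = 5) (s - 1L) %/% n_segments + 1L
sp_segment <- function(s, n_segments = 5) (s - 1L) %% n_segments + 1L

#' Average a reflectance map over the superpixel grid
#'
#' Mean of the valid pixels of each superpixel; superpixels whose valid
#' pixel set is empty (e.g. fully covered by an unusable region) yield `NA`
#' and are excluded from downstream fits rather than imputed.
#'
#' @param map a `reflectance_map` on the grid's geometry.
#' @param grid a `superpixel_grid`.
#' @return Numeric vector of length `n_tracks * n_segments` (dB).
#' @export
aggregate_superpixels <- function(map, grid) {
  stopifnot(inherits(map, "reflectance_map"), inherits(grid, "superpixel_grid"))
  if (!identical(dim(map$values_db), dim(grid$membership)))
    stop("map and grid geometry differ")
  n_sp <- grid$n_tracks * grid$n_segments
  ok <- map$valid_mask & !is.na(grid$membership)
  sums <- rep(NA_real_, n_sp)
  lab <- grid$membership[ok]
  s <- rowsum(map$values_db[ok], lab)
  n <- tabulate(lab, nbins = n_sp)
  out <- rep(NA_real_, n_sp)
  out[as.integer(rownames(s))] <- s[, 1] / n[as.integer(rownames(s))]
  out[n == 0] <- NA_real_
  out
}
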