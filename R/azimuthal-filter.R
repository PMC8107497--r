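#' Polar resampling and azimuthal first-harmonic suppression
#'
#' NFL reflectivity depends strongly on the OCT beam incidence angle, and the
#' incidence angle varies over a scan mainly with the azimuthal position
#' around the disc (it is set by the beam's pupil position and the nasal
#' offset of the nerve head), producing a bias that is well described by the
#' first angular harmonic `A * cos(theta - phi)` at each radius. These
#' functions resample the reflectance map onto a (radius, azimuth) grid and
#' remove that first-degree component while leaving the azimuthal mean and
#' all higher harmonics -- where the glaucomatous wedge defects live --
#' untouched.
#'
#' @name azfilter
NULL

#' Resample a reflectance map onto a polar grid
#'
#' Bilinear sampling at the centres of `n_r x n_theta` (radius, azimuth)
#' bins. A polar sample is invalid when any Cartesian pixel contributing to
#' its bilinear stencil is invalid or off-raster.
#'
#' @param map a `reflectance_map`.
#' @param r_in,r_out radial extent in mm (defaults extend the 1.1-2.0 mm
#'   analytic zone by a resampling margin).
#' @param n_r,n_theta grid size.
#' @return An object of class `polar_map` with fields `values_db`
#'   (`n_r x n_theta`), `r_centers`, `r_edges`, `theta_centers`, `valid_mask`.
#' @export
to_polar <- function(map, r_in = 0.9, r_out = 2.2, n_r = 64, n_theta = 256) {
  stopifnot(inherits(map, "reflectance_map"), r_in < r_out, n_theta >= 8)
  n <- nrow(map$values_db); px <- map$pixel_size_mm
  half <- n * px / 2
  if (r_out > half - max(abs(map$disc_center)))
    stop("polar annulus extends outside the raster")
  r_edges <- seq(r_in, r_out, length.out = n_r + 1)
  r_centers <- (r_edges[-1] + r_edges[-(n_r + 1)]) / 2
  theta_centers <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rr <- matrix(r_centers, n_r, n_theta)
  tt <- matrix(theta_centers, n_r, n_theta, byrow = TRUE)
  samp <- bilinear_cart(map$values_db, map$valid_mask,
                        x = rr * cos(tt), y = rr * sin(tt),
                        px = px, disc_center = map$disc_center)
  structure(list(values_db = matrix(samp$value, n_r, n_theta),
                 valid_mask = matrix(samp$valid, n_r, n_theta),
                 r_centers = r_centers, r_edges = r_edges,
                 theta_centers = theta_centers),
            class = "polar_map")
}

# Bilinear interpolation of a masked Cartesian raster at (x, y) mm relative
# to the disc centre. Returns value and validity per sample point.
bilinear_cart <- function(values, valid, x, y, px, disc_center) {
  n <- nrow(values)
  cfrac <- (x + disc_center[1]) / px + (n + 1) / 2
  rfrac <- (n + 1) / 2 - (y + disc_center[2]) / px
  c0 <- floor(cfrac); r0 <- floor(rfrac)
  fc <- cfrac - c0; fr <- rfrac - r0
  inb <- c0 >= 1 & c0 + 1 <= n & r0 >= 1 & r0 + 1 <= n
  val <- rep(NA_real_, length(cfrac)); ok <- rep(FALSE, length(cfrac))
  if (any(inb)) {
    i00 <- (c0[inb] - 1) * n + r0[inb]
    i10 <- i00 + 1L; i01 <- i00 + n; i11 <- i01 + 1L
    okc <- valid[i00] & valid[i10] & valid[i01] & valid[i11]
    w00 <- (1 - fr[inb]) * (1 - fc[inb]); w10 <- fr[inb] * (1 - fc[inb])
    w01 <- (1 - fr[inb]) * fc[inb];       w11 <- fr[inb] * fc[inb]
    v <- w00 * values[i00] + w10 * values[i10] +
         w01 * values[i01] + w11 * values[i11]
    v[!okc] <- NA_real_
    val[inb] <- v; ok[inb] <- okc
  }
  list(value = val, valid = ok)
}

#' Write a polar map back onto the Cartesian raster
#'
#' Bilinear interpolation in (radius, azimuth), with the azimuth wrapping
#' cyclically, evaluated at every valid Cartesian pixel whose radius lies
#' within the polar grid's radial span (clipped to `[r_in, r_out]` when
#' given). Pixels outside that annulus keep the values of `template`.
#'
#' @param polar a `polar_map`.
#' @param template the `reflectance_map` providing geometry and out-of-annulus
#'   values.
#' @param r_in,r_out optional annulus clip in mm.
#' @return A `reflectance_map`.
#' @export
from_polar <- function(polar, template, r_in = NULL, r_out = NULL) {
  stopifnot(inherits(polar, "polar_map"), inherits(template, "reflectance_map"))
  pc <- map_polar_coords(template)
  lo <- max(min(polar$r_centers), if (is.null(r_in)) -Inf else r_in)
  hi <- min(max(polar$r_centers), if (is.null(r_out)) Inf else r_out)
  sel <- which(template$valid_mask & pc$r >= lo & pc$r <= hi)
  out <- template
  if (!length(sel)) return(out)
  v <- bilinear_polar(polar, pc$r[sel], pc$theta[sel])
  keep <- is.finite(v)
  out$values_db[sel[keep]] <- v[keep]
  out
}

# Bilinear interpolation on the polar grid at (r, theta) with theta wrap.
bilinear_polar <- function(polar, r, theta) {
  rc <- polar$r_centers; n_r <- length(rc)
  n_t <- length(polar$theta_centers); dt <- 2 * pi / n_t
  ri <- (r - rc[1]) / (rc[2] - rc[1]) + 1
  r0 <- pmin(pmax(floor(ri), 1L), n_r - 1L)
  fr <- pmin(pmax(ri - r0, 0), 1)
  ti <- (theta %% (2 * pi)) / dt + 1     # theta_centers start at 0
  t0 <- floor(ti); ft <- ti - t0
  t0 <- ((t0 - 1L) %% n_t) + 1L
  t1 <- (t0 %% n_t) + 1L
  g <- function(i, j) polar$values_db[cbind(i, j)] *
    ifelse(polar$valid_mask[cbind(i, j)], 1, NA)
  (1 - fr) * ((1 - ft) * g(r0, t0) + ft * g(r0, t1)) +
    fr * ((1 - ft) * g(r0 + 1L, t0) + ft * g(r0 + 1L, t1))
}

#' Fit low-degree azimuthal harmonics to one radius row
#'
#' Mask-aware least squares of `a0 + sum_d (a_d cos(d theta) + b_d sin(d
#' theta))` over the valid samples of a row. With a complete uniformly
#' sampled row this is identical to reading the DFT bins; with masked
#' samples it remains well posed as long as the valid samples span more than
#' half the circle.
#'
#' @param values numeric vector (one radius row).
#' @param theta matching azimuth vector in radians.
#' @param mask logical; `FALSE` samples are ignored. Default all valid.
#' @param max_degree highest harmonic degree fitted.
#' @return Named coefficient vector `c(a0, a1, b1, ...)`, or `NULL` (with a
#'   warning) when the angular support is insufficient.
#' @export
fit_azimuthal_harmonics <- function(values, theta, mask = NULL, max_degree = 1) {
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  mask <- mask & is.finite(values)
  if (sum(mask) < 2 * max_degree + 1 || angular_span(theta[mask]) <= pi) {
    warning("insufficient angular support for harmonic fit; row left unfiltered")
    return(NULL)
  }
  X <- harmonic_design(theta[mask], max_degree)
  cf <- stats::lm.fit(X, values[mask])$coefficients
  names(cf) <- colnames(X)
  cf
}

harmonic_design <- function(theta, max_degree) {
  cols <- list(a0 = rep(1, length(theta)))
  for (d in seq_len(max_degree)) {
    cols[[paste0("a", d)]] <- cos(d * theta)
    cols[[paste0("b", d)]] <- sin(d * theta)
  }
  do.call(cbind, cols)
}

# circular span covered by a set of angles: 2*pi minus the largest gap
angular_span <- function(theta) {
  th <- sort(theta %% (2 * pi))
  if (length(th) < 2) return(0)
  gaps <- c(diff(th), 2 * pi - (th[length(th)] - th[1]))
  2 * pi - max(gaps)
}

#' Remove the first azimuthal harmonic from a polar map
#'
#' For every radius row independently, fits `a0 + a1 cos + b1 sin` to the
#' valid samples and subtracts the first-harmonic part `a1 cos + b1 sin`.
#' On complete rows the fit equals the DFT bins, so the row mean (degree 0)
#' and all degrees >= 2 pass through exactly, and any injected
#' `A cos(theta - phi)` is annihilated to machine precision. Rows with
#' insufficient angular support pass through with a warning.
#'
#' @param polar a `polar_map`.
#' @return The filtered `polar_map`, with the per-row fitted bias stored in
#'   the `bias_coefficients` field (columns `a1`, `b1`).
#' @export
azimuthal_bandstop <- function(polar) {
  stopifnot(inherits(polar, "polar_map"))
  out <- polar
  nr <- nrow(polar$values_db)
  bias <- matrix(NA_real_, nr, 2, dimnames = list(NULL, c("a1", "b1")))
  for (i in seq_len(nr)) {
    cf <- fit_azimuthal_harmonics(polar$values_db[i, ], polar$theta_centers,
                                  polar$valid_mask[i, ], max_degree = 1)
    if (is.null(cf)) next
    bias[i, ] <- cf[c("a1", "b1")]
    out$values_db[i, ] <- polar$values_db[i, ] -
      cf["a1"] * cos(polar$theta_centers) - cf["b1"] * sin(polar$theta_centers)
  }
  out$bias_coefficients <- bias
  out
}

#' Azimuthal incidence-bias filter on a reflectance map
#'
#' Removes the first azimuthal harmonic from the peripapillary annulus of a
#' Cartesian reflectance map. The annulus pixels are grouped into `n_r` thin
#' radial rings; within each ring the harmonic `a0 + a1 cos + b1 sin` is
#' fitted by mask-aware least squares directly on the pixels and the
#' first-harmonic part, re-centred so the ring mean is untouched, is
#' subtracted. Fitting on the pixels themselves (rather than round-tripping
#' through a polar resampling) makes the filter an exact linear projection:
#' applying it twice equals applying it once, ring means are preserved
#' exactly, and defect edges are not blurred. Pixels outside the filtered
#' annulus keep their input values but carry no downstream weight.
#'
#' @param map a `reflectance_map`.
#' @param r_in,r_out filtered annulus in mm (defaults cover the analytic
#'   zone plus margin).
#' @param n_r number of radial rings.
#' @return The filtered `reflectance_map`; per-ring bias coefficients are
#'   stored in the `bias_coefficients` field.
#' @export
azimuthal_filter <- function(map, r_in = 0.9, r_out = 2.2, n_r = 64) {
  stopifnot(inherits(map, "reflectance_map"))
  pc <- map_polar_coords(map)
  sel <- which(map$valid_mask & pc$r >= r_in & pc$r <= r_out)
  if (!length(sel)) stop("no valid pixels in the filter annulus")
  bin <- pmin(pmax(ceiling((pc$r[sel] - r_in) / ((r_out - r_in) / n_r)), 1L), n_r)
  th <- pc$theta[sel]; y <- map$values_db[sel]
  out <- map
  bias <- matrix(NA_real_, n_r, 2, dimnames = list(NULL, c("a1", "b1")))
  for (b in unique(bin)) {
    ii <- bin == b
    if (sum(ii) < 8 || angular_span(th[ii]) <= pi) {
      warning("ring ", b, ": insufficient angular support; left unfiltered")
      next
    }
    X <- harmonic_design(th[ii], 1)
    cf <- stats::lm.fit(X, y[ii])$coefficients
    h <- cf["a1"] * X[, "a1"] + cf["b1"] * X[, "b1"]
    out$values_db[sel[ii]] <- y[ii] - (h - mean(h))
    bias[b, ] <- cf[c("a1", "b1")]
  }
  out$bias_coefficients <- bias
  out$filtered <- TRUE
  out
}
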