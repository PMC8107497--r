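#' Simulation configuration for synthetic eyes
#'
#' Collects the generative parameters for synthetic cohorts. The defaults
#' emulate the statistical structure the pipeline assumes in normal eyes:
#' a double-hump angular reflectance template (inferotemporal and
#' superotemporal arcuate peaks plus a secondary superonasal peak), a
#' per-superpixel population SD of 1.8 dB split into an eye-level offset and
#' an angularly correlated field (correlation length roughly 10 degrees), a
#' per-scan first-azimuthal-harmonic incidence bias of random amplitude and
#' phase, radially oriented vessels, and glaucomatous defects of
#' parameterized depth and extent aligned with the fiber trajectories.
#' Covariate group structure follows the study population: 35 normal /
#' 30 preperimetric (PPG) / 35 perimetric (PG) eyes, normal ages
#' 60.0 +/- 10.8 yr truncated to 40-80, axial lengths 23.6 +/- 0.9 mm.
#'
#' @param n_normal,n_ppg,n_pg group sizes.
#' @param npx raster size (400 A-lines over 4.5 mm).
#' @param pixel_size_mm pixel pitch.
#' @param population_sd_db target per-superpixel population SD (dB).
#' @param sigma_eye_db SD of the eye-level offset component (dB).
#' @param bias_sd_db scale of the incidence-bias amplitude: `A = |N(0,
#'   bias_sd_db^2)|` per scan.
#' @param scan_noise_db SD (dB, at superpixel scale) of the angularly
#'   correlated per-scan measurement noise; this is what limits
#'   between-repeat repeatability after filtering.
#' @param pixel_noise_db white per-pixel speckle-like noise SD (dB); averages
#'   out over superpixels.
#' @param beta_age,beta_axl,beta_int covariate effects (dB/yr, dB/mm,
#'   dB/(yr*mm)).
#' @param vessel_density expected number of major vessels.
#' @param disc_radius_mm optic disc radius.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_normal = 35, n_ppg = 30, n_pg = 35,
                       npx = 400, pixel_size_mm = 4.5 / 400,
                       population_sd_db = 1.8, sigma_eye_db = 0.7,
                       bias_sd_db = 0.75, scan_noise_db = 0.55,
                       pixel_noise_db = 0.6,
                       beta_age = -0.03, beta_axl = -0.4, beta_int = 0,
                       vessel_density = 14, disc_radius_mm = 0.75) {
  stopifnot(population_sd_db > 0, sigma_eye_db >= 0,
            sigma_eye_db < population_sd_db)
  structure(as.list(environment()), class = "sim_config")
}

# Angular reflectance template in dB, centred so its annulus mean is 0 dB.
# Shares the double-hump shape of the flux profile.
template_db <- function(theta) {
  f <- default_flux_profile()(theta)
  th <- 2 * pi * (0:4095) / 4096
  10 * (log10(f) - mean(log10(default_flux_profile()(th))))
}

# Angularly correlated noise field: random Fourier series over degrees
# 2..kmax (degree 0 lives in the eye offset; degree 1 is reserved for the
# incidence bias, which the filter removes). The marginal SD is `sd`; when
# `window` (radians) is given, the spectrum is rescaled so that the SD
# *after* averaging over an angular window of that width -- i.e. at
# superpixel scale -- equals `sd` (each harmonic k is attenuated by
# sin(k w/2)/(k w/2) under window averaging).
angular_noise_field <- function(sd, kmax = 24, k0 = 12, window = NULL) {
  ks <- 2:kmax
  s2 <- exp(-(ks / k0)^2)
  att2 <- if (is.null(window)) rep(1, length(ks))
          else (sin(ks * window / 2) / (ks * window / 2))^2
  # var(a cos + b sin) at fixed theta is s2 when a, b ~ N(0, s2) each
  s2 <- s2 * sd^2 / sum(s2 * att2)
  a <- stats::rnorm(length(ks), 0, sqrt(s2))
  b <- stats::rnorm(length(ks), 0, sqrt(s2))
  function(theta) {
    out <- numeric(length(theta))
    for (i in seq_along(ks))
      out <- out + a[i] * cos(ks[i] * theta) + b[i] * sin(ks[i] * theta)
    out
  }
}

# Intrinsic (scan-independent) state of one synthetic eye. The per-
# superpixel population SD budget: eye offset^2 + scan-noise^2 +
# intrinsic field^2 = population_sd_db^2. The intrinsic field blends two
# independent angular fields with radially varying weights (inner vs outer
# annulus), so inner and outer segments decorrelate and noise dips do not
# automatically span full tracks; the blend is variance-normalized, keeping
# the pointwise SD exact.
gen_eye_intrinsic <- function(config, age, axial_length, defects = list(),
                              window = NULL) {
  s2 <- config$population_sd_db^2 - config$sigma_eye_db^2 -
    config$scan_noise_db^2
  if (s2 <= 0) stop("population_sd_db too small for the component SDs")
  f_in <- angular_noise_field(sqrt(s2), window = window)
  f_out <- angular_noise_field(sqrt(s2), window = window)
  field <- function(theta, r) {
    w <- pmin(pmax((2.0 - r) / 0.9, 0), 1)
    (w * f_in(theta) + (1 - w) * f_out(theta)) / sqrt(w^2 + (1 - w)^2)
  }
  list(age = age, axial_length = axial_length,
       eye_offset = stats::rnorm(1, 0, config$sigma_eye_db),
       ang_field = field,
       cov_shift = config$beta_age * (age - 50) +
         config$beta_axl * (axial_length - 23.6) +
         config$beta_int * (age - 50) * (axial_length - 23.6),
       defects = defects,
       vessel_seed = stats::runif(1, 0, 1e9))
}

#' Generate one synthetic eye's intensity map pair
#'
#' Builds NFL and PPEC linear-intensity maps for one scan of a synthetic
#' eye: angular template times covariate and noise factors, multiplied by a
#' per-scan first-harmonic incidence bias `A cos(theta - phi)` (dB), with a
#' beam-coupling field applied to both bands (and therefore cancelled by the
#' ratio), a centred disc mask and a radial vessel mask. The generator is a
#' pure function of the RNG state: seed before calling for reproducibility.
#'
#' @param config a [sim_config()].
#' @param age,axial_length covariates (years, mm).
#' @param bias `c(amplitude_db, phase_rad)`, or `NULL` to draw per scan;
#'   `c(0, 0)` disables the bias.
#' @param noise logical; `FALSE` produces the noise-free template (still
#'   applying covariate shift and bias).
#' @param defects list of defect specifications (see [inject_defect()]).
#' @param laterality `"OD"` or `"OS"`; OS maps are generated mirrored.
#' @param intrinsic optional intrinsic state from a previous call (used by
#'   [make_repeat_scans()]); overrides `age`, `axial_length`, `defects`.
#' @return List with `nfl` and `ppec` ([intensity_map()]s), `intrinsic`
#'   (reusable eye state) and `bias` actually used.
#' @export
make_normal_map <- function(config, age = 60, axial_length = 23.6,
                            bias = NULL, noise = TRUE, defects = list(),
                            laterality = "OD", intrinsic = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sp_window <- 2 * pi / 32
  if (is.null(intrinsic)) {
    intrinsic <- if (noise)
      gen_eye_intrinsic(config, age, axial_length, defects,
                        window = sp_window)
    else list(age = age, axial_length = axial_length, eye_offset = 0,
              ang_field = function(theta, r) numeric(length(theta)),
              cov_shift = config$beta_age * (age - 50) +
                config$beta_axl * (axial_length - 23.6) +
                config$beta_int * (age - 50) * (axial_length - 23.6),
              defects = defects, vessel_seed = 0)
  }
  npx <- config$npx
  cc <- map_coords(npx, config$pixel_size_mm, c(0, 0))
  r <- sqrt(cc$x^2 + cc$y^2)
  theta <- atan2(cc$y, cc$x) %% (2 * pi)

  if (is.null(bias))
    bias <- c(abs(stats::rnorm(1, 0, config$bias_sd_db)),
              stats::runif(1, 0, 2 * pi))
  db <- template_db(theta) + intrinsic$cov_shift + intrinsic$eye_offset +
    intrinsic$ang_field(theta, r) +
    bias[1] * cos(theta - bias[2])
  if (noise) {
    scan_field <- angular_noise_field(config$scan_noise_db,
                                      window = sp_window)
    db <- db + scan_field(theta) +
      stats::rnorm(length(db), 0, config$pixel_noise_db)
  }
  dim(db) <- c(npx, npx)

  for (d in intrinsic$defects)
    db <- db - defect_depth_field(d, r, theta)

  # beam coupling hits both bands equally; the NFL/PPEC ratio cancels it
  coupling <- if (noise) stats::rnorm(1, 0, 1) + 0.5 * cc$x / 2.25 else 0
  ppec_lin <- matrix(10^(coupling / 10), npx, npx)
  nfl_lin <- ppec_lin * 10^(db / 10)

  disc_mask <- r <= config$disc_radius_mm
  vessel_mask <- if (noise && config$vessel_density > 0)
    gen_vessel_mask(config, intrinsic$vessel_seed)
  else matrix(FALSE, npx, npx)

  mirror <- identical(laterality, "OS")
  fliph <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (mirror) {
    nfl_lin <- fliph(nfl_lin); ppec_lin <- fliph(ppec_lin)
    disc_mask <- fliph(disc_mask); vessel_mask <- fliph(vessel_mask)
  }
  list(nfl = intensity_map(nfl_lin, config$pixel_size_mm, c(0, 0),
                           disc_mask, vessel_mask, laterality),
       ppec = intensity_map(ppec_lin, config$pixel_size_mm, c(0, 0),
                            disc_mask, vessel_mask, laterality),
       intrinsic = intrinsic, bias = bias)
}

# dB attenuation field of one defect: full-depth inside the entry-angle
# interval of its tracks (and segment radii when restricted), zero outside.
defect_depth_field <- function(defect, r, theta, trajectory = NULL,
                               boundaries = NULL) {
  if (is.null(trajectory)) trajectory <- defect$trajectory
  if (is.null(boundaries)) boundaries <- defect$boundaries
  th0 <- trajectory$entry_angle(r, theta)
  b1 <- boundaries[1]; nt <- length(boundaries)
  track <- findInterval((th0 - b1) %% (2 * pi), boundaries - b1)
  inside <- track %in% defect$tracks & r >= 0.85 & r <= 2.25
  if (!is.null(defect$segments)) {
    seg <- pmin(pmax(ceiling((r - 1.1) / 0.18), 1L), 5L)
    inside <- inside & seg %in% defect$segments & r >= 1.1 & r <= 2.0
  }
  out <- numeric(length(r))
  out[inside] <- defect$depth_db
  dim(out) <- dim(r)
  out
}

#' Defect specification
#'
#' Describes one reflectance defect in track space so it aligns with the
#' nerve-fiber trajectories: a set of (contiguous) tracks, an optional
#' segment restriction, and a depth in dB. Wedges span all segments of a few
#' tracks; diffuse defects span all segments of more than a quadrant of
#' tracks.
#'
#' @param tracks integer vector of track indices (1-based, cyclic).
#' @param depth_db attenuation depth in dB (>= 0).
#' @param segments optional integer vector of segment indices; `NULL` means
#'   the full radial span.
#' @param trajectory,boundaries the trajectory model and track boundaries
#'   the defect is aligned to.
#' @return A defect specification list.
#' @export
defect_spec <- function(tracks, depth_db, segments = NULL,
                        trajectory = trajectory_model(),
                        boundaries = equal_flux_track_boundaries(default_flux_profile())) {
  stopifnot(depth_db >= 0, all(tracks >= 1))
  list(tracks = as.integer(tracks), depth_db = depth_db,
       segments = if (!is.null(segments)) as.integer(segments),
       trajectory = trajectory, boundaries = boundaries)
}

#' Apply a defect to an existing intensity-map pair
#'
#' Multiplies the NFL intensity by `10^(-depth/10)` inside the defect
#' region and returns the ground-truth mask of superpixels with at least
#' half their area affected.
#'
#' @param maps list with `nfl`/`ppec` from [make_normal_map()].
#' @param defect a [defect_spec()].
#' @param grid a [superpixel_grid()] for the ground-truth mask.
#' @return `maps` with attenuated NFL plus element `truth_mask` (logical,
#'   length `n_tracks * n_segments`).
#' @export
inject_defect <- function(maps, defect, grid) {
  pc <- map_polar_coords(maps$nfl)
  depth <- defect_depth_field(defect, pc$r, pc$theta)
  maps$nfl$values <- maps$nfl$values * 10^(-depth / 10)
  affected <- depth > 0 & !is.na(grid$membership)
  n_sp <- grid$n_tracks * grid$n_segments
  frac <- tabulate(grid$membership[affected], nbins = n_sp) / grid$counts
  maps$truth_mask <- frac >= 0.5
  maps$intrinsic$defects <- c(maps$intrinsic$defects, list(defect))
  maps
}

#' Repeat scans of the same eye
#'
#' Re-images a synthetic eye: the intrinsic reflectance (template, noise
#' field, defects, vessels) is held fixed while each repeat draws a fresh
#' incidence bias `(A, phi)` and fresh repeat measurement noise. This is the
#' substrate for the repeatability analysis (pooled between-repeat SD).
#'
#' @param config a [sim_config()].
#' @param intrinsic eye state from [make_normal_map()].
#' @param n_repeats number of scans.
#' @param bias optional list of fixed `c(A, phi)` per repeat.
#' @param noise logical; `FALSE` disables all per-scan noise (with fixed
#'   bias the repeats are then identical).
#' @return List of map pairs as from [make_normal_map()].
#' @export
make_repeat_scans <- function(config, intrinsic, n_repeats = 2, bias = NULL,
                              noise = TRUE) {
  lapply(seq_len(n_repeats), function(i)
    make_normal_map(config, intrinsic = intrinsic,
                    bias = if (!is.null(bias)) bias[[i]],
                    noise = noise))
}

# vessel mask: radially oriented curvilinear structures, denser toward the
# arcades, ~2-3 px wide
gen_vessel_mask <- function(config, vessel_seed) {
  npx <- config$npx; px <- config$pixel_size_mm
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(vessel_seed %% .Machine$integer.max))
  mask <- matrix(FALSE, npx, npx)
  n_v <- stats::rpois(1, config$vessel_density)
  flux <- default_flux_profile()
  half <- (npx + 1) / 2
  for (v in seq_len(n_v)) {
    repeat {                              # rejection-sample start angle
      th <- stats::runif(1, 0, 2 * pi)
      if (stats::runif(1) < flux(th) / 1.4) break
    }
    w <- sample(1:2, 1)
    rs <- seq(config$disc_radius_mm * 0.9, npx * px / 2 * 1.4, by = px / 2)
    drift <- stats::rnorm(1, 0, 0.15)
    thr <- th + drift * (rs - rs[1]) + 0.04 * sin(rs * 7 + v)
    ci <- round(half + rs * cos(thr) / px)
    ri <- round(half - rs * sin(thr) / px)
    for (dx in -w:w) for (dy in -w:w) {
      cj <- ci + dx; rj <- ri + dy
      ok <- cj >= 1 & cj <= npx & rj >= 1 & rj <= npx
      mask[cbind(rj[ok], cj[ok])] <- TRUE
    }
  }
  mask
}
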