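#' Generate a synthetic study cohort
#'
#' Draws a cohort with the study's group structure (normal / preperimetric
#' / perimetric glaucoma), covariates matching the study population, and
#' glaucomatous defects assigned so the pattern mix echoes the observed
#' taxonomy (PPG mostly wedge and diffuse with some minor patterns; PG only
#' wedge and diffuse, deeper and wider). Normal eyes receive no injected
#' defect; their low-reflectance superpixels arise from noise alone.
#'
#' `level = "superpixel"` draws superpixel vectors directly from the same
#' statistical model the map generator implements (template + covariate
#' shift + eye offset + angularly correlated field + white noise - defect),
#' which is orders of magnitude faster and is used for statistical
#' calibration experiments. `level = "map"` generates full intensity-map
#' pairs per eye to exercise the whole image pipeline; process them with
#' [process_cohort()].
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (required; the generator is a pure function of
#'   (config, seed)).
#' @param level `"superpixel"` or `"map"`.
#' @param grid optional [build_grid()] result (map level); defaults are
#'   built from the default flux profile and trajectory model.
#' @return For `"superpixel"`: a list with `cohort` (an [nfl_cohort()]) and
#'   `truth` (per-eye defect ground truth). For `"map"`: a list with `eyes`
#'   (list of map pairs + truth) and `info`.
#' @export
make_cohort <- function(config, seed, level = c("superpixel", "map"),
                        grid = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)

  boundaries <- equal_flux_track_boundaries(default_flux_profile())
  trajectory <- trajectory_model()
  groups <- c(rep("normal", config$n_normal), rep("PPG", config$n_ppg),
              rep("PG", config$n_pg))
  n <- length(groups)
  age_par <- list(normal = c(60.0, 10.8), PPG = c(65.1, 8.7), PG = c(66.9, 8.8))
  axl_par <- list(normal = c(23.6, 0.9), PPG = c(24.7, 1.0), PG = c(24.6, 1.3))
  male_p <- c(normal = 8 / 35, PPG = 12 / 30, PG = 21 / 35)

  info <- data.frame(eye_id = sprintf("eye%03d", seq_len(n)), group = groups,
                     stringsAsFactors = FALSE)
  info$age <- vapply(groups, function(g)
    rtrunc_norm(age_par[[g]][1], age_par[[g]][2], 40, 80), 0)
  info$axial_length <- vapply(groups, function(g)
    rtrunc_norm(axl_par[[g]][1], axl_par[[g]][2], 21, 28), 0)
  info$gender <- ifelse(stats::runif(n) < male_p[groups], "M", "F")
  info$laterality <- sample(c("OD", "OS"), n, replace = TRUE)

  truth <- lapply(seq_len(n), function(i)
    draw_defects(groups[i], boundaries, trajectory))
  burden <- vapply(truth, function(tr)
    sum(vapply(tr$defects, function(d)
      d$depth_db * length(d$tracks) *
        length(if (is.null(d$segments)) 1:5 else d$segments), 0)) / 160, 0)
  info$vf_md <- ifelse(groups == "normal",
                       stats::rnorm(n, 0.23, 1.24),
                       pmin(0.5, 0.4 - 1.05 * burden +
                              stats::rnorm(n, 0, 1.4)))
  info$thickness_profile_avg <- ifelse(groups == "normal", 102.1, 102.1) -
    3.6 * burden + stats::rnorm(n, 0, 6.5)
  info$thickness_map_avg <- 141.6 - 5.5 * burden + stats::rnorm(n, 0, 8)

  if (level == "superpixel") {
    centers <- superpixel_centers(boundaries, trajectory)
    mu_t <- template_db(centers$azimuth)
    vals <- matrix(NA_real_, n, length(mu_t))
    for (i in seq_len(n)) {
      eye <- gen_eye_intrinsic(config, info$age[i], info$axial_length[i])
      scan_field <- angular_noise_field(config$scan_noise_db)
      v <- mu_t + eye$cov_shift + eye$eye_offset +
        eye$ang_field(centers$azimuth, centers$radius) +
        scan_field(centers$azimuth)
      for (d in truth[[i]]$defects) {
        cells <- defect_cells(d)
        v[cells] <- v[cells] - d$depth_db
      }
      vals[i, ] <- v
    }
    list(cohort = nfl_cohort(vals, info), truth = truth,
         boundaries = boundaries, trajectory = trajectory)
  } else {
    if (is.null(grid))
      grid <- build_grid(boundaries, trajectory, npx = config$npx,
                         pixel_size_mm = config$pixel_size_mm)
    eyes <- vector("list", n)
    for (i in seq_len(n)) {
      m <- make_normal_map(config, info$age[i], info$axial_length[i],
                           defects = truth[[i]]$defects,
                           laterality = info$laterality[i])
      truth[[i]]$truth_mask <- defect_truth_mask(truth[[i]]$defects, grid)
      eyes[[i]] <- m
    }
    list(eyes = eyes, info = info, truth = truth, grid = grid,
         boundaries = boundaries, trajectory = trajectory)
  }
}

rtrunc_norm <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  mean
}

# superpixel centroid azimuths/radii under a boundary/trajectory pair
superpixel_centers <- function(boundaries, trajectory, n_segments = 5,
                               r_in = 1.1, r_out = 2.0) {
  nt <- length(boundaries)
  b2 <- c(boundaries, boundaries[1] + 2 * pi)
  track_mid <- (boundaries + diff(b2) / 2) %% (2 * pi)
  seg_r <- r_in + (r_out - r_in) * (seq_len(n_segments) - 0.5) / n_segments
  track <- rep(seq_len(nt), each = n_segments)
  seg <- rep(seq_len(n_segments), times = nt)
  list(track = track, segment = seg, radius = seg_r[seg],
       azimuth = trajectory$azimuth(seg_r[seg], track_mid[track]))
}

# linear superpixel indices covered by a defect (segment fastest)
defect_cells <- function(d, n_segments = 5) {
  segs <- if (is.null(d$segments)) seq_len(n_segments) else d$segments
  as.vector(outer(segs, (d$tracks - 1L) * n_segments, "+"))
}

# ground-truth low mask: superpixels with >= 50% of area inside a defect;
# with track-aligned defects this is exact membership
defect_truth_mask <- function(defects, grid) {
  n_sp <- grid$n_tracks * grid$n_segments
  mask <- rep(FALSE, n_sp)
  for (d in defects) mask[defect_cells(d, grid$n_segments)] <- TRUE
  mask
}

# defect draw per diagnostic group, echoing the observed pattern taxonomy
draw_defects <- function(group, boundaries, trajectory) {
  mk <- function(tracks, depth, segments = NULL)
    defect_spec(((tracks - 1L) %% length(boundaries)) + 1L, depth, segments,
                trajectory, boundaries)
  arcade_track <- function() {
    repeat {
      th <- stats::runif(1, 0, 2 * pi)
      if (stats::runif(1) < default_flux_profile()(th) / 1.4) break
    }
    b1 <- boundaries[1]
    findInterval((th - b1) %% (2 * pi), boundaries - b1)
  }
  pattern <- if (group == "normal") "none"
  else if (group == "PPG")
    sample(c("diffuse", "wedge", "other_grouping", "isolated", "none"), 1,
           prob = c(10, 12, 4, 3, 1))
  else sample(c("diffuse", "wedge"), 1, prob = c(24, 11))
  depth <- if (group == "PG") stats::runif(1, 4.5, 8) else stats::runif(1, 3.5, 5.5)
  if (group == "PG" && pattern == "diffuse") depth <- stats::runif(1, 6, 10)
  t0 <- arcade_track()
  defects <- switch(pattern,
    none = list(),
    diffuse = list(mk(t0 + seq_len(sample(10:14, 1)), depth)),
    wedge = list(mk(t0 + seq_len(sample(2:4, 1)), depth)),
    other_grouping = list(mk(t0 + 1:2, depth, segments = 2:3)),
    isolated = list(mk(t0, depth, segments = 3)))
  list(pattern = pattern, defects = defects)
}
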