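#' Map normalization constant from a normal cohort
#'
#' The linear-scale constant dividing every eye's NFL/PPEC ratio map before
#' the dB transform: the average over training normal eyes of the per-eye
#' mean ratio in the 1.1-2.0 mm analytic zone. Per-eye maps never
#' self-normalize; the constant is estimated once on normals and carried in
#' the fitted normative model.
#'
#' @param annulus_means numeric vector of per-eye annulus-mean ratios
#'   (linear scale).
#' @return Positive scalar.
#' @export
normalization_constant <- function(annulus_means) {
  if (any(!is.finite(annulus_means)) || any(annulus_means <= 0))
    stop("annulus means must be positive and finite")
  mean(annulus_means)
}

#' Process one eye's intensity maps into a superpixel vector
#'
#' The full per-eye image chain: NFL/PPEC ratio, vessel inpainting,
#' population normalization and dB transform, right-eye orientation,
#' azimuthal first-harmonic filtering, and aggregation onto the superpixel
#' grid.
#'
#' @param nfl,ppec [intensity_map()]s for the two bands.
#' @param grid a [build_grid()] result (defined in right-eye orientation).
#' @param norm_constant linear-scale normalization constant.
#' @param filter apply the azimuthal filter (default `TRUE`).
#' @param db_factor dB convention passed to [normalize_to_db()].
#' @return List with `map` (the filtered `reflectance_map`) and
#'   `superpixels` (numeric vector of per-superpixel mean dB).
#' @export
process_eye <- function(nfl, ppec, grid, norm_constant, filter = TRUE,
                        db_factor = 10) {
  rat <- compute_ratio_map(nfl, ppec)
  rat$ratio <- inpaint_vessels(rat$ratio, rat$vessel_mask & !rat$disc_mask)
  map <- normalize_to_db(rat, norm_constant, db_factor = db_factor)
  map <- orient_right_eye(map)
  if (filter) map <- azimuthal_filter(map)
  list(map = map, superpixels = aggregate_superpixels(map, grid))
}

# per-eye annulus-mean ratio after inpainting and orientation (linear scale)
eye_annulus_ratio <- function(nfl, ppec) {
  rat <- compute_ratio_map(nfl, ppec)
  rat$ratio <- inpaint_vessels(rat$ratio, rat$vessel_mask & !rat$disc_mask)
  annulus_mean(rat)
}

#' Process a map-level synthetic cohort
#'
#' Two-pass pipeline over the eyes of a [make_cohort()] `level = "map"`
#' result: first the normalization constant is estimated from the normal
#' eyes' annulus-mean ratios, then every eye is processed into its
#' superpixel vector.
#'
#' @param sim result of `make_cohort(..., level = "map")`.
#' @param filter apply the azimuthal filter.
#' @param norm_constant optional externally supplied constant; by default it
#'   is estimated from this cohort's normal eyes.
#' @return List with `cohort` (an [nfl_cohort()]), `norm_constant`, and
#'   `grid`.
#' @export
process_cohort <- function(sim, filter = TRUE, norm_constant = NULL) {
  if (is.null(norm_constant)) {
    nrm <- which(sim$info$group == "normal")
    am <- vapply(nrm, function(i)
      eye_annulus_ratio(sim$eyes[[i]]$nfl, sim$eyes[[i]]$ppec), 0)
    norm_constant <- normalization_constant(am)
  }
  vals <- t(vapply(sim$eyes, function(e)
    process_eye(e$nfl, e$ppec, sim$grid, norm_constant,
                filter = filter)$superpixels,
    numeric(sim$grid$n_tracks * sim$grid$n_segments)))
  list(cohort = nfl_cohort(vals, sim$info), norm_constant = norm_constant,
       grid = sim$grid)
}

#' Diagnostic evaluation tables for a scored cohort
#'
#' Builds the group-statistics, diagnostic-accuracy, sensitivity,
#' correlation, pattern-count, cluster and piecewise-regression tables for
#' a cohort of per-eye diagnostic results. Reflectance parameters come from
#' `results`; thickness columns (`thickness_profile_avg`,
#' `thickness_map_avg`) and `vf_md` are taken from `info` when present.
#'
#' @param results data frame from [predict.nfl_normative()] or
#'   [bootstrap_632()].
#' @param info cohort covariate table aligned by `eye_id`.
#' @param seed RNG seed for the clustering and bootstrap comparisons.
#' @param specificity target specificity for the sensitivity table.
#' @return Named list of data frames: `group_stats`, `roc`, `sensitivity`,
#'   `correlation`, `pattern_counts`, `clusters`, `piecewise`.
#' @export
evaluate_cohort <- function(results, info, seed = 1, specificity = 0.99) {
  info <- info[match(results$eye_id, info$eye_id), , drop = FALSE]
  is_normal <- results$group == "normal"
  params <- list(
    average_reflectance = list(x = results$average_reflectance, dir = "lower"),
    low_count_5 = list(x = results$low_count_5, dir = "higher"),
    focal_loss = list(x = results$focal_loss, dir = "lower"))
  for (th in c("thickness_profile_avg", "thickness_map_avg"))
    if (!is.null(info[[th]])) params[[th]] <- list(x = info[[th]], dir = "lower")

  fmt <- function(x) sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  group_stats <- do.call(rbind, lapply(names(params), function(p) {
    x <- params[[p]]$x
    data.frame(parameter = p, normal = fmt(x[is_normal]),
               glaucoma = fmt(x[!is_normal]),
               p_wilcoxon = wilcoxon_ranksum(x[is_normal], x[!is_normal]),
               stringsAsFactors = FALSE)
  }))

  roc <- do.call(rbind, lapply(names(params), function(p) {
    sc <- oriented_score(params[[p]])
    r <- auc_clustered(sc, !is_normal, results$eye_id)
    data.frame(parameter = p, auc = r$auc, se = r$se,
               ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               stringsAsFactors = FALSE)
  }))

  sens <- do.call(rbind, lapply(names(params), function(p) {
    sc <- oriented_score(params[[p]])
    row <- data.frame(parameter = p, stringsAsFactors = FALSE)
    for (g in c("PPG", "PG")) {
      sel <- results$group == g
      row[[paste0("sens_", g)]] <- if (any(sel))
        sensitivity_at_specificity(sc[is_normal], sc[sel],
                                   specificity = specificity,
                                   direction = "higher")
      else NA_real_
    }
    row$sens_all <- sensitivity_at_specificity(sc[is_normal], sc[!is_normal],
                                               specificity = specificity,
                                               direction = "higher")
    row
  }))

  correlation <- if (!is.null(info$vf_md)) {
    do.call(rbind, lapply(names(params), function(p)
      data.frame(parameter = p,
                 r_vf_md = stats::cor(params[[p]]$x, info$vf_md,
                                      use = "complete.obs"),
                 stringsAsFactors = FALSE)))
  } else NULL

  pattern_counts <- as.data.frame.matrix(
    table(factor(results$pattern,
                 levels = c("diffuse", "wedge", "other_grouping",
                            "isolated", "none")),
          factor(results$group, levels = c("normal", "PPG", "PG"))))
  pattern_counts <- cbind(pattern = rownames(pattern_counts), pattern_counts,
                          stringsAsFactors = FALSE)
  rownames(pattern_counts) <- NULL

  cl <- gmm_cluster(cbind(focal_loss = results$focal_loss,
                          average_reflectance = results$average_reflectance),
                    k = 3, seed = seed)
  clusters <- data.frame(eye_id = results$eye_id, group = results$group,
                         cluster = cl$labels, stringsAsFactors = FALSE)

  piecewise <- if (!is.null(info$vf_md)) {
    do.call(rbind, lapply(names(params), function(p) {
      pw <- piecewise_fit(info$vf_md, params[[p]]$x)
      data.frame(parameter = p, slope_hi_md = pw$slope_hi, r_hi = pw$r_hi,
                 p_hi = pw$p_hi, slope_lo_md = pw$slope_lo, r_lo = pw$r_lo,
                 p_lo = pw$p_lo, stringsAsFactors = FALSE)
    }))
  } else NULL

  list(group_stats = group_stats, roc = roc, sensitivity = sens,
       correlation = correlation, pattern_counts = pattern_counts,
       clusters = clusters, piecewise = piecewise)
}

oriented_score <- function(p) if (p$dir == "lower") -p$x else p$x

#' Wedge-plus-diffuse pattern fractions
#'
#' Summarises a pattern-count table (patterns as rows, groups as columns)
#' into the glaucomatous-pattern statistics used for the taxonomy analysis:
#' the percentage of glaucoma (PPG + PG) eyes with a wedge or diffuse
#' pattern, the percentage of normal eyes with one, and the count of PPG
#' eyes exhibiting any glaucomatous (wedge or diffuse) pattern.
#'
#' @param counts data frame with columns `pattern`, `normal`, `PPG`, `PG`.
#' @return List with `pct_glaucoma`, `pct_normal`, `n_ppg`, `n_ppg_total`
#'   (percentages rounded to integer as conventionally reported).
#' @export
glaucomatous_pattern_stats <- function(counts) {
  stopifnot(all(c("pattern", "normal", "PPG", "PG") %in% names(counts)))
  wd <- counts$pattern %in% c("wedge", "diffuse")
  n_gla <- sum(counts$PPG) + sum(counts$PG)
  list(pct_glaucoma = round(100 * sum(counts$PPG[wd] + counts$PG[wd]) / n_gla),
       pct_normal = round(100 * sum(counts$normal[wd]) / sum(counts$normal)),
       n_ppg = sum(counts$PPG[wd]), n_ppg_total = sum(counts$PPG))
}

#' Clinical reference pattern counts
#'
#' Loads the defect-pattern frequency table observed in the 35/30/35
#' normal/PPG/PG clinical study population that motivated the pattern
#' taxonomy, distributed with the package as a plain CSV. Used to check the
#' pattern-fraction arithmetic against the published values.
#'
#' @return Data frame with columns `pattern`, `normal`, `PPG`, `PG`.
#' @export
reported_pattern_counts <- function() {
  utils::read.csv(system.file("extdata", "reported_pattern_counts.csv",
                              package = "nflreflect"),
                  stringsAsFactors = FALSE)
}
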