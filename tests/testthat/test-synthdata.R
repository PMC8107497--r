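# Synthetic-eye generator: pipeline identity, calibration, defects,
# repeat scans, cohort structure.

test_that("noise-free, bias-free eye reproduces the template exactly", {
  m <- clean_map()
  pc <- nflreflect:::map_polar_coords(m)
  sel <- m$valid_mask & pc$r >= 1.1 & pc$r <= 2.0
  err <- m$values_db[sel] - nflreflect:::template_db(pc$theta[sel])
  expect_lt(max(abs(err)), 1e-9)
  # template is normalized: annulus mean ~ 0 dB by construction
  expect_lt(abs(annulus_mean(m)), 1e-3)
})

test_that("cohort mean approaches the template at the LLN rate", {
  sc <- make_cohort(sim_config(n_normal = 35, n_ppg = 0, n_pg = 0,
                               beta_age = 0, beta_axl = 0), seed = 41)
  centers <- nflreflect:::superpixel_centers(
    sc$boundaries, sc$trajectory)
  mu_t <- nflreflect:::template_db(centers$azimuth)
  rms <- sqrt(mean((colMeans(sc$cohort$values) - mu_t)^2))
  # per-superpixel SE is 1.8/sqrt(35) ~ 0.30 dB; allow 2x
  expect_lt(rms, 2 * 1.8 / sqrt(35))
})

test_that("per-superpixel population SD sits near the configured 1.8 dB", {
  sc <- make_cohort(sim_config(n_normal = 100, n_ppg = 0, n_pg = 0,
                               beta_age = 0, beta_axl = 0), seed = 42)
  sds <- apply(sc$cohort$values, 2, sd)
  expect_lt(abs(mean(sds) - 1.8) / 1.8, 0.15)
})

test_that("map-level superpixel SD is also within 15% of the target", {
  cfg <- small_config(vessel_density = 0)
  g <- small_grid()
  set.seed(43)
  vals <- t(vapply(1:25, function(i) {
    m <- make_normal_map(cfg, age = 50, axial_length = 23.6)
    process_eye(m$nfl, m$ppec, g, 1)$superpixels
  }, numeric(160)))
  expect_lt(abs(mean(apply(vals, 2, sd)) - 1.8) / 1.8, 0.15)
})

test_that("defect injection attenuates NFL intensity and reports truth", {
  cfg <- small_config(vessel_density = 0)
  g <- small_grid()
  m0 <- make_normal_map(cfg, bias = c(0, 0), noise = FALSE)
  d0 <- inject_defect(m0, defect_spec(5:7, 0), g)       # zero depth
  expect_equal(d0$nfl$values, m0$nfl$values)
  expect_false(any(d0$truth_mask))

  d <- inject_defect(m0, defect_spec(5:7, 6), g)
  expect_equal(sum(d$truth_mask), 15)                   # 3 tracks x 5 segs
  expect_equal(classify_pattern(d$truth_mask), "wedge")
  pe <- process_eye(d$nfl, d$ppec, g, 1, filter = FALSE)
  pe0 <- process_eye(m0$nfl, m0$ppec, g, 1, filter = FALSE)
  expect_equal(pe$superpixels[d$truth_mask] + 6,
               pe0$superpixels[d$truth_mask], tolerance = 1e-6)
  expect_equal(pe$superpixels[!d$truth_mask],
               pe0$superpixels[!d$truth_mask], tolerance = 1e-6)

  dd <- inject_defect(m0, defect_spec(10:21, 7), g)
  expect_equal(classify_pattern(dd$truth_mask), "diffuse")
})

test_that("every pattern branch is reachable from a defect configuration", {
  labs <- c(
    classify_pattern(nflreflect:::defect_truth_mask(
      list(defect_spec(1:12, 5)), small_grid())),
    classify_pattern(nflreflect:::defect_truth_mask(
      list(defect_spec(4:6, 5)), small_grid())),
    classify_pattern(nflreflect:::defect_truth_mask(
      list(defect_spec(4:5, 5, segments = 2:3)), small_grid())),
    classify_pattern(nflreflect:::defect_truth_mask(
      list(defect_spec(4, 5, segments = 3)), small_grid())),
    classify_pattern(nflreflect:::defect_truth_mask(list(), small_grid())))
  expect_equal(labs, c("diffuse", "wedge", "other_grouping", "isolated",
                       "none"))
})

test_that("repeat scans share intrinsics; zero noise + fixed bias repeats", {
  cfg <- small_config(vessel_density = 0)
  m <- make_normal_map(cfg, noise = FALSE, bias = c(0.8, 1.2))
  reps <- make_repeat_scans(cfg, m$intrinsic, 2,
                            bias = list(c(0.8, 1.2), c(0.8, 1.2)),
                            noise = FALSE)
  expect_identical(reps[[1]]$nfl$values, reps[[2]]$nfl$values)
})

test_that("pooled repeat SD scales with the scan noise level", {
  g <- small_grid()
  sd_at <- function(noise_db, seed) {
    cfg <- small_config(vessel_density = 0, scan_noise_db = noise_db,
                        bias_sd_db = 0)
    set.seed(seed)
    reps <- lapply(1:4, function(e) {
      m <- make_normal_map(cfg)
      scans <- make_repeat_scans(cfg, m$intrinsic, 2)
      t(vapply(scans, function(s)
        process_eye(s$nfl, s$ppec, g, 1, filter = FALSE)$superpixels,
        numeric(160)))
    })
    pooled_sd(reps)
  }
  r <- sd_at(1.0, 51) / sd_at(0.5, 52)
  expect_lt(abs(r - 2), 0.5)
})

test_that("cohorts are bit-reproducible given (config, seed)", {
  a <- make_cohort(sim_config(n_normal = 20, n_ppg = 3, n_pg = 3), seed = 44)
  b <- make_cohort(sim_config(n_normal = 20, n_ppg = 3, n_pg = 3), seed = 44)
  expect_identical(a$cohort$values, b$cohort$values)
  expect_identical(a$cohort$info, b$cohort$info)
  c2 <- make_cohort(sim_config(n_normal = 20, n_ppg = 3, n_pg = 3), seed = 45)
  expect_false(identical(a$cohort$values, c2$cohort$values))
})

test_that("covariates and defects follow the configured group structure", {
  sc <- make_cohort(sim_config(), seed = 46)
  info <- sc$cohort$info
  expect_equal(table(info$group)[c("normal", "PPG", "PG")],
               c(normal = 35, PPG = 30, PG = 35), ignore_attr = TRUE)
  expect_true(all(info$age >= 40 & info$age <= 80))
  ppat <- vapply(sc$truth, `[[`, "", "pattern")
  expect_true(all(ppat[info$group == "normal"] == "none"))
  expect_true(all(ppat[info$group == "PG"] %in% c("diffuse", "wedge")))
})

test_that("computed focal loss tracks the injected defect burden", {
  sc <- make_cohort(sim_config(), seed = 47)
  fit <- fit_normative(sc$cohort, method = "fast")
  pr <- predict(fit, sc$cohort)
  burden <- vapply(seq_along(sc$truth), function(i)
    sum(vapply(sc$truth[[i]]$defects, function(d)
      d$depth_db * length(nflreflect:::defect_cells(d)), 0)) / 160, 0)
  expect_gt(cor(-burden, pr$focal_loss), 0.9)
})
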