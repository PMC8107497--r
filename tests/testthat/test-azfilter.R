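# Polar resampling and azimuthal first-harmonic suppression.

test_that("polar resampling preserves constants and analytic angular fields", {
  pol <- to_polar(flat_map(2.5))
  expect_true(all(abs(pol$values_db[pol$valid_mask] - 2.5) < 1e-12))

  m <- field_map(function(r, th) cos(th))
  pol <- to_polar(m, n_theta = 256)
  for (i in c(1, 32, 64))
    expect_lt(max(abs(pol$values_db[i, ] - cos(pol$theta_centers)),
                  na.rm = TRUE), 0.02)
})

test_that("to_polar -> from_polar round trip is accurate on a smooth map", {
  m <- field_map(function(r, th) 2 * sin(2 * th) + 0.5 * r)
  pol <- to_polar(m)
  back <- from_polar(pol, m, r_in = 1.1, r_out = 2.0)
  pc <- nflreflect:::map_polar_coords(m)
  sel <- m$valid_mask & pc$r >= 1.1 & pc$r <= 2.0
  expect_lt(max(abs(back$values_db[sel] - m$values_db[sel])), 0.05)
})

test_that("harmonic fit recovers coefficients on full and masked rows", {
  th <- 2 * pi * (0:255) / 256
  cf <- fit_azimuthal_harmonics(3 + 2 * cos(th), th)
  expect_equal(unname(cf), c(3, 2, 0), tolerance = 1e-9)

  set.seed(4)
  mask <- runif(256) > 0.25
  cf <- fit_azimuthal_harmonics(5 * sin(th), th, mask)
  expect_equal(unname(cf), c(0, 0, 5), tolerance = 1e-3)

  cf <- fit_azimuthal_harmonics(cos(2 * th), th)
  expect_equal(unname(cf), c(0, 0, 0), tolerance = 1e-9)
})

test_that("harmonic fit refuses rows with insufficient angular support", {
  th <- 2 * pi * (0:255) / 256
  mask <- th < 0.9 * pi                      # spans less than half circle
  expect_warning(cf <- fit_azimuthal_harmonics(cos(th), th, mask),
                 "insufficient")
  expect_null(cf)
})

polar_of <- function(f) to_polar(field_map(f))

test_that("bandstop annihilates any first harmonic and passes the rest", {
  c0 <- 1.3
  for (case in list(c(A = 2.0, phi = 0.7), c(A = 0.01, phi = 4.1))) {
    pol <- polar_of(function(r, th) c0 + case["A"] * cos(th - case["phi"]))
    out <- azimuthal_bandstop(pol)
    for (i in seq_along(out$r_centers)) {
      ok <- out$valid_mask[i, ]
      if (!any(ok)) next
      cf <- fit_azimuthal_harmonics(out$values_db[i, ], out$theta_centers, ok)
      expect_lt(sqrt(cf["a1"]^2 + cf["b1"]^2) / case["A"], 1e-9)
      expect_equal(mean(out$values_db[i, ok]),
                   mean(pol$values_db[i, ok]), tolerance = 1e-9)
    }
  }
  pol2 <- polar_of(function(r, th) 1 + 0.8 * cos(2 * th))
  out2 <- azimuthal_bandstop(pol2)
  expect_lt(max(abs(out2$values_db - pol2$values_db), na.rm = TRUE), 1e-9)
})

test_that("radius-varying bias is removed while a wedge survives", {
  wedge <- function(r, th) -4 * (th > 1 & th < 1.4)
  biasf <- function(r, th) (0.5 + r) * cos(th - 0.2 * r)
  pol_all <- polar_of(function(r, th) wedge(r, th) + biasf(r, th))
  pol_wedge <- polar_of(wedge)
  out <- azimuthal_bandstop(pol_all)
  # compare to the wedge alone, also bandstop-filtered (the wedge itself
  # carries a small first harmonic that any azimuthal filter removes)
  ref <- azimuthal_bandstop(pol_wedge)
  ok <- out$valid_mask & ref$valid_mask
  expect_lt(sqrt(mean((out$values_db[ok] - ref$values_db[ok])^2)), 0.05)
})

test_that("cartesian filter: constants pass, projection is idempotent", {
  m <- flat_map(1.7)
  f1 <- azimuthal_filter(m)
  pc <- nflreflect:::map_polar_coords(m)
  ann <- m$valid_mask & pc$r >= 1.1 & pc$r <= 2.0
  expect_lt(max(abs(f1$values_db[ann] - 1.7)), 1e-9)

  m2 <- clean_map()
  g1 <- azimuthal_filter(m2)
  g2 <- azimuthal_filter(g1)
  expect_lt(max(abs(g2$values_db - g1$values_db), na.rm = TRUE), 1e-6)
})

test_that("cartesian filter is linear and preserves ring means", {
  mx <- field_map(function(r, th) 1.5 * cos(th) + sin(3 * th))
  my <- field_map(function(r, th) 0.3 * r + cos(th - 2))
  a <- 0.7; b <- -1.3
  mz <- mx; mz$values_db <- a * mx$values_db + b * my$values_db
  fz <- azimuthal_filter(mz)
  fx <- azimuthal_filter(mx); fy <- azimuthal_filter(my)
  expect_lt(max(abs(fz$values_db - (a * fx$values_db + b * fy$values_db)),
                na.rm = TRUE), 1e-9)

  pc <- nflreflect:::map_polar_coords(mx)
  sel <- mx$valid_mask & pc$r >= 1.0 & pc$r <= 2.1
  bin <- findInterval(pc$r[sel], seq(0.9, 2.2, length.out = 65))
  for (k in unique(bin)) {
    ii <- which(sel)[bin == k]
    expect_equal(mean(fx$values_db[ii]), mean(mx$values_db[ii]),
                 tolerance = 1e-9)
  }
})

test_that("filtering repeat scans with random bias lowers the pooled SD", {
  cfg <- small_config(vessel_density = 0)
  g <- small_grid()
  set.seed(77)
  unf <- list(); fil <- list()
  for (e in 1:6) {
    m <- make_normal_map(cfg)
    scans <- make_repeat_scans(cfg, m$intrinsic, 2)
    vu <- vf <- matrix(NA_real_, 2, 160)
    for (s in 1:2) {
      pe <- process_eye(scans[[s]]$nfl, scans[[s]]$ppec, g, 1, filter = FALSE)
      vu[s, ] <- pe$superpixels
      vf[s, ] <- aggregate_superpixels(azimuthal_filter(pe$map), g)
    }
    unf[[e]] <- vu; fil[[e]] <- vf
  }
  expect_lt(pooled_sd(fil), pooled_sd(unf))
})
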