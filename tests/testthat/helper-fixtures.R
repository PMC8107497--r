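# Shared fixtures, built once per test run. Map-level tests use a reduced
# 200-px raster (2.25 mm half-width, same physical extent) so the whole
# suite stays fast; physical-space behaviour is resolution-independent.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_npx <- 200
small_px_mm <- 4.5 / small_npx

small_config <- function(...) {
  sim_config(npx = small_npx, pixel_size_mm = small_px_mm, ...)
}

small_grid <- function() {
  fx("small_grid", function()
    build_grid(equal_flux_track_boundaries(default_flux_profile()),
               trajectory_model(), npx = small_npx,
               pixel_size_mm = small_px_mm))
}

radial_grid <- function() {
  fx("radial_grid", function()
    build_grid(equal_flux_track_boundaries(function(th) rep(1, length(th))),
               trajectory_model("radial"), npx = small_npx,
               pixel_size_mm = small_px_mm))
}

# a clean (noise-free, bias-free) reflectance map carrying the template
clean_map <- function() {
  fx("clean_map", function() {
    m <- make_normal_map(small_config(), age = 50, axial_length = 23.6,
                         bias = c(0, 0), noise = FALSE)
    process_eye(m$nfl, m$ppec, small_grid(), norm_constant = 1,
                filter = FALSE)$map
  })
}

# constant-valued reflectance map over the full raster minus a small disc
flat_map <- function(value = 0, npx = small_npx) {
  vals <- matrix(value, npx, npx)
  cc <- map_coords(npx, 4.5 / npx, c(0, 0))
  disc <- sqrt(cc$x^2 + cc$y^2) <= 0.75
  vals[disc] <- NA_real_
  nflreflect:::new_reflectance_map(vals, !disc, 4.5 / npx, c(0, 0), "OD", 1)
}

# reflectance map holding an arbitrary function of (r, theta)
field_map <- function(f, npx = small_npx) {
  cc <- map_coords(npx, 4.5 / npx, c(0, 0))
  r <- sqrt(cc$x^2 + cc$y^2); th <- atan2(cc$y, cc$x) %% (2 * pi)
  vals <- f(r, th)
  disc <- r <= 0.75
  vals[disc] <- NA_real_
  nflreflect:::new_reflectance_map(vals, !disc, 4.5 / npx, c(0, 0), "OD", 1)
}

map_coords <- nflreflect:::map_coords
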