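# Small in-code fixtures shared across test files.

# Regular grid with uniform bathymetry (all wet unless bathy = 0 somewhere).
toy_grid <- function(nlon = 8, nlat = 6, ndep = 5,
                     lon_range = c(-180, 180), lat_range = c(-78, -60),
                     depth_max = 2500, bathy_m = 2500) {
  lon_b <- seq(lon_range[1], lon_range[2], length.out = nlon + 1)
  lat_b <- seq(lat_range[1], lat_range[2], length.out = nlat + 1)
  dep_b <- seq(0, depth_max, length.out = ndep + 1)
  bathy <- matrix(bathy_m, nlon, nlat)
  ocean_grid(lon_b, lat_b, dep_b, bathy)
}

# Spatially constant annual/monthly field set on a grid.
constant_fields <- function(grid, theta = 0, sp = 34.5, o2 = 300,
                            time_axis = "annual") {
  shape <- if (time_axis == "monthly") c(grid$nlon, grid$nlat, grid$ndepth, 12L)
           else c(grid$nlon, grid$nlat, grid$ndepth)
  fs <- field_set(grid, array(theta, shape), array(sp, shape),
                  array(o2, shape), time_axis = time_axis)
  derive_insitu_fields(fs)
}

# Brute-force weighted percentile: for each candidate value compute the
# normalised weight of samples at or below it with a double loop, and take
# the smallest value reaching q.  Independent of the package's sorted
# cumulative-sum implementation.
brute_weighted_percentile <- function(values, weights, q) {
  tot <- sum(weights)
  best <- Inf
  for (i in seq_along(values)) {
    acc <- 0
    for (j in seq_along(values)) if (values[j] <= values[i]) acc <- acc + weights[j]
    if (acc / tot >= q - 1e-12 && values[i] < best) best <- values[i]
  }
  best
}

# Default synthetic study, built once per test run and memoised.
default_study <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) cache <<- build_synthetic_study(synth_config(seed = seed))
    cache
  }
})
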