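#' Configuration of the synthetic ocean
#'
#' Frozen study conditions for the fully synthetic, seeded inputs that
#' stand in for the ocean-model output.  The defaults emulate the
#' statistical structure of the Southern Ocean fields the analysis assumes:
#' a cold surface with a seasonal cycle confined to the upper ~200 m, a
#' warm oxygen-poor subsurface (Circumpolar Deep Water-like) temperature
#' maximum near 500 m, oxygen decreasing from the surface to a mid-depth
#' minimum, scenario forcing with surface-intensified warming (local
#' maximum ~1.3 deg C at full scale) and an oxygen perturbation that is
#' positive in the upper ocean and negative below with the loss peaking
#' near 700 m, a slow linear control drift, and quasi-circumpolar species
#' bands with distinct depth ranges.
#'
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param n_lon,n_lat,n_depth Grid sizes.
#' @param lat_range Latitude span, degrees (default -78 to -45).
#' @param depth_max Maximum depth, metres.
#' @param seasonal_amp_t Seasonal surface temperature amplitude, deg C.
#' @param scenario_scales Named forcing scale per scenario in `[0, 1]`.
#' @param warming_surface Maximum surface warming at full scale, deg C.
#' @param warming_subsurface Deep warming bump amplitude, deg C.
#' @param o2_gain_surface Upper-ocean O2 gain at full scale, mmol m-3.
#' @param deox_peak Subsurface O2 loss peak at full scale, mmol m-3.
#' @param deox_peak_depth Depth of peak O2 loss, metres.
#' @param drift_t,drift_o2 Control-run drift over the projection interval
#'   (deg C, mmol m-3).
#' @param noise_sd Named vector of field noise standard deviations
#'   (`t` deg C, `s`, `o2` mmol m-3).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_lon = 90, n_lat = 16, n_depth = 20,
                         lat_range = c(-78, -45), depth_max = 3500,
                         seasonal_amp_t = 1.5,
                         scenario_scales = c(ssp126 = 0.25, ssp245 = 0.5,
                                             ssp370 = 0.75, ssp585 = 1.0),
                         warming_surface = 1.3,
                         warming_subsurface = 0.2,
                         o2_gain_surface = 12,
                         deox_peak = 18, deox_peak_depth = 700,
                         drift_t = 0.05, drift_o2 = -2,
                         noise_sd = c(t = 0.15, s = 0.02, o2 = 6)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_lon >= 2, n_lat >= 2, n_depth >= 2,
            all(scenario_scales >= 0), all(scenario_scales <= 1))
  structure(as.list(environment()), class = "synth_config")
}

#' Synthetic grid with a coastal shelf and a deep basin
#'
#' Regular lon-lat grid with depth levels thickening with depth
#' (layer edges at `depth_max * f^1.7`) and an analytic bathymetry: a
#' shallow (~600 m) shelf band along the southern boundary, a continental
#' slope, and a deep basin, with a seeded longitudinal modulation of the
#' shelf break.
#'
#' @param config A [synth_config()].
#' @return An `ocean_grid`.
#' @export
make_grid <- function(config) {
  withr::with_seed(config$seed, {
    lon_b <- seq(-180, 180, length.out = config$n_lon + 1)
    lat_b <- seq(config$lat_range[1], config$lat_range[2],
                 length.out = config$n_lat + 1)
    dep_b <- config$depth_max * seq(0, 1, length.out = config$n_depth + 1)^1.7
    lat_c <- (lat_b[-1] + lat_b[-length(lat_b)]) / 2
    lon_c <- (lon_b[-1] + lon_b[-length(lon_b)]) / 2
    # shelf break latitude wobbles with longitude
    break_lat <- -73 + 1.5 * sin(2 * lon_c * pi / 180 + stats::runif(1, 0, 2 * pi))
    bathy <- matrix(0, config$n_lon, config$n_lat)
    for (i in seq_len(config$n_lon)) {
      s <- (lat_c - break_lat[i]) / 4      # slope width ~4 deg
      frac <- pmin(pmax(s, 0), 1)
      bathy[i, ] <- 600 + frac * (0.97 * config$depth_max - 600)
    }
    bathy <- bathy + matrix(stats::rnorm(length(bathy), 0, 25), nrow(bathy))
    bathy <- pmin(pmax(bathy, 400), config$depth_max)
    ocean_grid(lon_b, lat_b, dep_b, bathy)
  })
}

# Analytic mean-state profiles shared by climatology and scenarios.
# All take depth z (m) and latitude (deg) vectors of equal length.
synth_theta_mean <- function(z, lat, config) {
  nlat <- (lat + 78) / 33                       # 0 at 78S, 1 at 45S
  t_surf <- -1.5 + 6.5 * pmax(nlat, 0)^2
  cdw <- 1.6 * (0.5 + 0.5 * pmax(nlat, 0))
  t_surf * exp(-z / 180) + cdw * exp(-((z - 500) / 400)^2) + 0.1
}

synth_salinity_mean <- function(z, lat) {
  33.9 + 0.8 * (1 - exp(-z / 300))
}

synth_o2_mean <- function(z, lat, config) {
  nlat <- (lat + 78) / 33
  220 + 110 * exp(-z / 120) - 25 * exp(-((z - 600) / 400)^2) - 5 * nlat
}

# Scenario perturbations at full scale (added to theta / o2_conc).
synth_delta_theta <- function(z, lat, config) {
  nlat <- pmax((lat + 78) / 33, 0)
  shape_lat <- 0.3 + 0.7 * nlat^1.5             # weak under-ice warming south
  config$warming_surface * shape_lat * exp(-z / 300) +
    config$warming_subsurface * exp(-((z - 700) / 700)^2)
}

synth_delta_o2 <- function(z, lat, config) {
  config$o2_gain_surface * exp(-(z / 350)^2) -
    config$deox_peak * exp(-((z - config$deox_peak_depth) / 350)^2)
}

# Evaluate f(z, lat) on the grid as a [lon, lat, depth] array.
profile_array <- function(grid, f) {
  m <- outer(grid$lat, grid$depth, function(la, z) f(z, la))   # [lat, depth]
  aperm(array(m, dim = c(grid$nlat, grid$ndepth, grid$nlon)), c(3, 1, 2))
}

#' Synthetic monthly climatology
#'
#' Analytic temperature, salinity and oxygen fields on the grid for 12
#' climatological months plus derived in situ temperature and pO2.  The
#' seasonal temperature cycle decays by ~200 m depth; the seeded noise is
#' spatial texture (mesoscale anomalies of a long-term climatology) drawn
#' once per cell and shared by all months, so month-to-month variation is
#' carried by the seasonal cycle alone and a zero-amplitude seasonal cycle
#' makes every month identical to the annual mean.  With the defaults the
#' derived in-habitat mean pO2 decreases from roughly 190 mbar at the
#' surface to below 150 mbar near 500 m.
#'
#' @param grid An `ocean_grid` from [make_grid()].
#' @param config The same [synth_config()].
#' @return A monthly `field_set` with derived fields.
#' @export
make_climatology <- function(grid, config) {
  withr::with_seed(config$seed + 1L, {
    n3 <- c(grid$nlon, grid$nlat, grid$ndepth)
    nm <- c(n3, 12L)
    theta0 <- profile_array(grid, function(z, la) synth_theta_mean(z, la, config)) +
      array(stats::rnorm(prod(n3), 0, config$noise_sd[["t"]]), n3)
    s0 <- profile_array(grid, synth_salinity_mean) +
      array(stats::rnorm(prod(n3), 0, config$noise_sd[["s"]]), n3)
    o20 <- pmax(profile_array(grid, function(z, la) synth_o2_mean(z, la, config)) +
      array(stats::rnorm(prod(n3), 0, config$noise_sd[["o2"]]), n3), 1)
    seas_shape <- profile_array(grid, function(z, la) exp(-(z / 80)^2))
    theta <- array(0, nm); sp <- array(0, nm); o2 <- array(0, nm)
    for (m in 1:12) {
      seas <- config$seasonal_amp_t * cos(2 * pi * (m - 1) / 12) * seas_shape
      theta[, , , m] <- theta0 + seas
      sp[, , , m] <- s0
      o2[, , , m] <- o20
    }
    theta <- pmax(theta, -1.9)   # above the freezing point of seawater
    fs <- field_set(grid, theta, sp, o2, time_axis = "monthly",
                    period_label = "1995-2014", scenario_label = "historical")
    derive_insitu_fields(fs)
  })
}

#' Synthetic scenario set
#'
#' Annual-mean future fields per scenario: the historical annual mean plus
#' the scaled analytic perturbation (surface-intensified warming; O2 gain
#' above ~350 m and loss peaking near `deox_peak_depth`) plus the control
#' drift; control fields carry the drift only.  Monotone scenario scales
#' give monotone forcing.  All field sets carry derived in situ
#' temperature and pO2.
#'
#' @param clim Monthly climatology from [make_climatology()].
#' @param config The same [synth_config()].
#' @return A list of class `scenario_set`: `historical` (monthly),
#'   `historical_annual`, `control_hist`, `control_future`, and
#'   `scenarios` (named list of annual `field_set`s).
#' @export
make_scenarios <- function(clim, config) {
  grid <- clim$grid
  hist_annual <- annual_mean(clim)
  dtheta <- profile_array(grid, function(z, la) synth_delta_theta(z, la, config))
  do2 <- profile_array(grid, function(z, la) synth_delta_o2(z, la, config))
  mk <- function(theta, o2, period, scen) {
    fs <- field_set(grid, theta, hist_annual$sp, pmax(o2, 0),
                    time_axis = "annual", period_label = period,
                    scenario_label = scen)
    derive_insitu_fields(fs)
  }
  control_hist <- mk(hist_annual$theta, hist_annual$o2_conc,
                     "1995-2014", "control")
  control_future <- mk(hist_annual$theta + config$drift_t,
                       hist_annual$o2_conc + config$drift_o2,
                       "2091-2100", "control")
  scenarios <- lapply(names(config$scenario_scales), function(sc) {
    a <- config$scenario_scales[[sc]]
    mk(hist_annual$theta + a * dtheta + config$drift_t,
       hist_annual$o2_conc + a * do2 + config$drift_o2,
       "2091-2100", sc)
  })
  names(scenarios) <- names(config$scenario_scales)
  structure(list(historical = clim, historical_annual = hist_annual,
                 control_hist = control_hist, control_future = control_future,
                 scenarios = scenarios, future_period = "2091-2100"),
            class = "scenario_set")
}

#' Synthetic species set
#'
#' One domain-spanning predator (0-2210 m) and seven prey archetypes with
#' the lateral/vertical structure of a toothfish-like food web: shallow-shelf
#' (0-30 m), mid-shelf (0-1000 m), circumpolar krill-like (0-600 m),
#' subsurface open-ocean (200-800 m), sector-restricted mid-depth
#' (100-600 m), deep (500-2000 m), and a suitability-thresholded
#' squid-like species (200-2500 m).  Probability maps are smooth
#' latitude bumps (optionally windowed in longitude) with small seeded
#' noise; the predator map is positive over every wet column so its
#' habitat contains every prey footprint.
#'
#' @param grid An `ocean_grid`.
#' @param config A [synth_config()].
#' @param probability_threshold Occurrence-probability threshold for the
#'   probability-based species (default 0).
#' @return A `species_registry`.
#' @export
make_species_set <- function(grid, config, probability_threshold = 0) {
  withr::with_seed(config$seed + 2L, {
    lat <- grid$lat; lon <- grid$lon
    bump <- function(center, width, floor = 0, lon_sector = NULL) {
      p <- outer(rep(1, grid$nlon), exp(-((lat - center) / width)^2))
      if (!is.null(lon_sector))
        p <- p * outer(lon >= lon_sector[1] & lon < lon_sector[2],
                       rep(1, grid$nlat))
      p <- pmax(p, floor)
      p <- p + matrix(stats::rnorm(length(p), 0, 0.01), nrow(p))
      pmin(pmax(p, 0), 1)
    }
    shelf_lat <- -75.5
    tab <- data.frame(
      species_id = 1:8,
      name = c("predator (toothfish-like)", "shallow shelf prey",
               "mid shelf prey", "krill-like prey", "subsurface open-ocean prey",
               "sector-restricted prey", "deep prey", "squid-like prey"),
      common_name = c("predator", "shallow", "midshelf", "krill",
                      "subsurface", "sector", "deep", "squid"),
      min_depth_m = c(0, 0, 0, 0, 200, 100, 500, 200),
      max_depth_m = c(2210, 30, 1000, 600, 800, 600, 2000, 2500),
      suitability_threshold = c(NA, NA, NA, NA, NA, NA, NA, 0.228),
      stringsAsFactors = FALSE)
    maps <- list(
      `1` = list(map = pmax(bump(-66, 14), 0.2) * 0.9 + 0.05),
      `2` = list(map = bump(shelf_lat, 2.5)),
      `3` = list(map = bump(shelf_lat, 4)),
      `4` = list(map = bump(-62, 9, floor = 0.05)),
      `5` = list(map = bump(-60, 6)),
      `6` = list(map = bump(-68, 5, lon_sector = c(0, 120))),
      `7` = list(map = bump(-66, 10, floor = 0.02)),
      `8` = list(map = bump(-64, 11, floor = 0.1)))
    load_registry(tab, maps, grid, probability_threshold)
  })
}

#' Build the whole synthetic study
#'
#' Convenience wrapper: grid, monthly climatology, scenario set and species
#' registry from one config.
#'
#' @param config A [synth_config()].
#' @param probability_threshold Occurrence-probability threshold.
#' @return List of class `synthetic_study` with `grid`, `clim`, `scenarios`,
#'   `registry`, `masks`, `config`.
#' @export
build_synthetic_study <- function(config, probability_threshold = 0) {
  grid <- make_grid(config)
  clim <- make_climatology(grid, config)
  scen <- make_scenarios(clim, config)
  registry <- make_species_set(grid, config, probability_threshold)
  structure(list(grid = grid, clim = clim, scenarios = scen,
                 registry = registry, masks = ccamlr_masks(grid),
                 config = config),
            class = "synthetic_study")
}
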