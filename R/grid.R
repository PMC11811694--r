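#' Regular lon-lat-depth ocean grid
#'
#' Builds the geometry on which all fields and masks live: cell centres and
#' bounds, spherical cell areas, bathymetry, and wet cell volumes.  The wet
#' thickness of a layer is clipped to the bathymetry (partial bottom cells),
#' so a layer entirely below the seafloor has zero volume.  Depths are
#' positive down throughout the package.
#'
#' @param lon_bounds Strictly increasing longitude cell edges, degrees east,
#'   in `[-180, 180]`.
#' @param lat_bounds Strictly increasing latitude cell edges, degrees north.
#' @param depth_bounds Strictly increasing depth layer edges, metres,
#'   starting at 0.
#' @param bathymetry Matrix `[lon, lat]` of seafloor depth in metres
#'   (positive; 0 means land).
#' @return An object of class `ocean_grid`: a list with `lon`, `lat`,
#'   `depth` (centres), the three `*_bounds`, `cell_area` (km^2, `[lon,lat]`),
#'   `bathymetry` (m), `cell_volume` (km^3, `[lon,lat,depth]`), `wet`
#'   (logical `[lon,lat,depth]`), and the dimension sizes.
#' @export
ocean_grid <- function(lon_bounds, lat_bounds, depth_bounds, bathymetry) {
  stopifnot(all(diff(lon_bounds) > 0), all(diff(lat_bounds) > 0),
            all(diff(depth_bounds) > 0), depth_bounds[1] >= 0)
  nlon <- length(lon_bounds) - 1L
  nlat <- length(lat_bounds) - 1L
  ndep <- length(depth_bounds) - 1L
  bathymetry <- as.matrix(bathymetry)
  if (!all(dim(bathymetry) == c(nlon, nlat)))
    stop("bathymetry must be a [lon, lat] matrix matching the bounds")
  if (any(bathymetry < 0)) stop("bathymetry must be non-negative (positive down)")

  r_earth <- 6371  # km
  dlam <- diff(lon_bounds) * pi / 180
  dsin <- diff(sin(lat_bounds * pi / 180))
  cell_area <- r_earth^2 * outer(dlam, dsin)  # km^2, [lon, lat]

  # wet thickness per layer, clipped to bathymetry
  thick <- array(0, dim = c(nlon, nlat, ndep))
  for (k in seq_len(ndep)) {
    tk <- pmin(bathymetry, depth_bounds[k + 1]) - depth_bounds[k]
    thick[, , k] <- pmax(tk, 0)
  }
  cell_volume <- sweep(thick, c(1, 2), cell_area, "*") / 1000  # m -> km
  structure(list(
    lon = (lon_bounds[-1] + lon_bounds[-(nlon + 1)]) / 2,
    lat = (lat_bounds[-1] + lat_bounds[-(nlat + 1)]) / 2,
    depth = (depth_bounds[-1] + depth_bounds[-(ndep + 1)]) / 2,
    lon_bounds = lon_bounds, lat_bounds = lat_bounds,
    depth_bounds = depth_bounds,
    cell_area = cell_area, bathymetry = bathymetry,
    cell_volume = cell_volume, wet = cell_volume > 0,
    nlon = nlon, nlat = nlat, ndepth = ndep
  ), class = "ocean_grid")
}

#' @export
print.ocean_grid <- function(x, ...) {
  cat(sprintf("<ocean_grid> %d lon x %d lat x %d depth (0-%g m)\n",
              x$nlon, x$nlat, x$ndepth, max(x$depth_bounds)))
  cat(sprintf("  lat %g..%g, total wet volume %.4g km^3\n",
              min(x$lat_bounds), max(x$lat_bounds), total_volume(x)))
  invisible(x)
}

#' Total wet ocean volume of a grid
#' @param grid An `ocean_grid`.
#' @return Volume in km^3.
#' @export
total_volume <- function(grid) sum(grid$cell_volume)

#' Clip a grid to the analysis domain
#'
#' Retains latitude cells with centre south of `lat_max` and depth levels
#' with centre at or above `depth_max` (the toothfish analysis uses 45 deg S
#' and 3185 m).  Idempotent.
#'
#' @param grid An `ocean_grid`.
#' @param lat_max Northern limit, degrees (cells with centre `< lat_max` kept).
#' @param depth_max Deepest level centre retained, metres.
#' @return A clipped `ocean_grid`.
#' @export
clip_grid <- function(grid, lat_max = -45, depth_max = 3185) {
  jj <- which(grid$lat < lat_max)
  kk <- which(grid$depth <= depth_max)
  if (!length(jj) || !length(kk)) stop("clipping removes the whole grid")
  ocean_grid(grid$lon_bounds,
             grid$lat_bounds[c(jj, max(jj) + 1L)],
             grid$depth_bounds[c(kk, max(kk) + 1L)],
             grid$bathymetry[, jj, drop = FALSE])
}

#' Antarctic continental shelf mask
#'
#' The shelf is the connected region of wet cells with bathymetry at or above
#' the isobath (shallower than `isobath` metres) that touches the
#' southernmost grid row: a flood fill from the southern boundary through
#' shallow cells, with longitude wrap-around.  Isolated offshore banks
#' shallower than the isobath are excluded.
#'
#' @param grid An `ocean_grid`.
#' @param isobath Depth in metres defining the shelf (default 1000).
#' @return Logical `[lon, lat]` matrix.
#' @export
shelf_mask <- function(grid, isobath = 1000) {
  wet2d <- grid$bathymetry > 0
  if (!any(wet2d[, 1])) stop("no wet cell in the southernmost row")
  shallow <- wet2d & grid$bathymetry <= isobath
  nlon <- grid$nlon; nlat <- grid$nlat
  visited <- matrix(FALSE, nlon, nlat)
  # seeds: shallow cells touching the southern boundary
  queue <- which(shallow[, 1])
  visited[cbind(queue, 1L)] <- TRUE
  queue <- cbind(queue, rep(1L, length(queue)))
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    i <- cur[1]; j <- cur[2]
    nb <- rbind(c(ifelse(i == 1L, nlon, i - 1L), j),
                c(ifelse(i == nlon, 1L, i + 1L), j),
                c(i, j - 1L), c(i, j + 1L))
    nb <- nb[nb[, 2] >= 1L & nb[, 2] <= nlat, , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      ii <- nb[r, 1]; jj <- nb[r, 2]
      if (!visited[ii, jj] && shallow[ii, jj]) {
        visited[ii, jj] <- TRUE
        queue <- rbind(queue, c(ii, jj))
      }
    }
  }
  visited
}

#' CCAMLR Convention Area and domain masks
#'
#' Longitude-sector masks for the three Southern Ocean management areas:
#' Area 48 (Weddell Sea; 70 deg W - 30 deg E), Area 58 (East Antarctica;
#' 30 deg E - 150 deg E) and Area 88 (Ross/Amundsen/Bellingshausen;
#' 150 deg E - 70 deg W across the dateline), plus the south-of-45 deg S
#' analysis domain and the continental shelf.  The three areas partition
#' the domain.
#'
#' @param grid An `ocean_grid` with longitudes in `[-180, 180)`.
#' @return A list of logical `[lon, lat]` matrices: `domain`, `shelf`,
#'   `area48`, `area58`, `area88`.
#' @export
ccamlr_masks <- function(grid) {
  domain <- outer(rep(TRUE, grid$nlon), grid$lat < -45) & grid$bathymetry > 0
  lon <- grid$lon
  in48 <- lon >= -70 & lon < 30
  in58 <- lon >= 30 & lon < 150
  in88 <- lon >= 150 | lon < -70
  band <- function(sel) domain & outer(sel, rep(TRUE, grid$nlat))
  list(domain = domain,
       shelf = shelf_mask(grid) & domain,
       area48 = band(in48), area58 = band(in58), area88 = band(in88))
}

#' Wet volume per region and depth level
#'
#' @param grid An `ocean_grid`.
#' @param masks Named list of logical `[lon, lat]` matrices (e.g. from
#'   [ccamlr_masks()]).
#' @return A data frame with columns `region`, `depth_level_m`, `volume_km3`.
#' @export
region_volume_table <- function(grid, masks) {
  out <- lapply(names(masks), function(nm) {
    m3 <- array(masks[[nm]], dim = dim(grid$cell_volume))
    data.frame(region = nm, depth_level_m = grid$depth,
               volume_km3 = apply(grid$cell_volume * m3, 3, sum))
  })
  do.call(rbind, out)
}

# Expand a [lon,lat] mask to [lon,lat,depth] (recycling along depth).
expand_mask3d <- function(mask2d, grid) {
  array(mask2d, dim = c(grid$nlon, grid$nlat, grid$ndepth))
}

# Volume of the cells of a 3-D logical mask, total.
mask_volume <- function(mask3d, grid) sum(grid$cell_volume[mask3d])

# Volume per depth level of a 3-D logical mask.
mask_volume_by_level <- function(mask3d, grid) {
  apply(grid$cell_volume * mask3d, 3, sum)
}
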