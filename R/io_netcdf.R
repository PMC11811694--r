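#' Write a field set to CF-style NetCDF
#'
#' Writes the state and derived variables with dimensions
#' (lon, lat, depth[, time]), coordinate bounds, bathymetry and global
#' attributes recording period/scenario labels, so that [load_fields()]
#' can reconstruct both the grid and the fields bit-for-bit.
#'
#' @param fs A `field_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fields <- function(fs, path) {
  g <- fs$grid
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dim_dep <- ncdf4::ncdim_def("depth", "m", g$depth)
  dim_bnd <- ncdf4::ncdim_def("bnds", "", 1:2, create_dimvar = FALSE)
  dims <- list(dim_lon, dim_lat, dim_dep)
  if (fs$time_axis == "monthly") {
    dim_time <- ncdf4::ncdim_def("time", "month of climatology", 1:12)
    dims <- c(dims, list(dim_time))
  }
  mv <- 1e30
  vdef <- function(name, units) ncdf4::ncvar_def(name, units, dims, missval = mv, prec = "double")
  bdef <- function(name, d) ncdf4::ncvar_def(name, "", list(dim_bnd, d), prec = "double")
  vars <- list(thetao = vdef("thetao", "degC"),
               so = vdef("so", "1"),
               o2 = vdef("o2", "mmol m-3"))
  if (!is.null(fs$t_insitu)) vars$to_insitu <- vdef("to_insitu", "degC")
  if (!is.null(fs$po2)) vars$po2 <- vdef("po2", "mbar")
  vars$deptho <- ncdf4::ncvar_def("deptho", "m", list(dim_lon, dim_lat),
                                  missval = mv, prec = "double")
  vars$lon_bnds <- bdef("lon_bnds", dim_lon)
  vars$lat_bnds <- bdef("lat_bnds", dim_lat)
  vars$depth_bnds <- bdef("depth_bnds", dim_dep)
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  put <- function(name, x) {
    x[is.na(x)] <- mv
    ncdf4::ncvar_put(nc, vars[[name]], x)
  }
  put("thetao", fs$theta); put("so", fs$sp); put("o2", fs$o2_conc)
  if (!is.null(fs$t_insitu)) put("to_insitu", fs$t_insitu)
  if (!is.null(fs$po2)) put("po2", fs$po2)
  put("deptho", g$bathymetry)
  edges <- function(b) rbind(b[-length(b)], b[-1])
  ncdf4::ncvar_put(nc, vars$lon_bnds, edges(g$lon_bounds))
  ncdf4::ncvar_put(nc, vars$lat_bnds, edges(g$lat_bounds))
  ncdf4::ncvar_put(nc, vars$depth_bnds, edges(g$depth_bounds))
  ncdf4::ncatt_put(nc, 0, "period_label", fs$period_label)
  ncdf4::ncatt_put(nc, 0, "scenario_label", fs$scenario_label)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8 (subset)")
  invisible(path)
}

#' Read a field set from NetCDF
#'
#' Reconstructs the grid from the stored coordinate bounds and bathymetry
#' and returns the fields on it.  Depth axes stored negative-up are
#' converted to positive-down.  A missing mapped variable is a descriptive
#' error.
#'
#' @param path NetCDF file written by [write_fields()] (or any file with
#'   compatible structure).
#' @param variable_map Named character vector mapping internal names
#'   (`theta`, `sp`, `o2_conc`) to file variable names.
#' @return A `field_set`.
#' @export
load_fields <- function(path,
                        variable_map = c(theta = "thetao", sp = "so",
                                         o2_conc = "o2")) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  have <- names(nc$var)
  for (nm in c("theta", "sp", "o2_conc")) {
    if (!variable_map[[nm]] %in% have)
      stop(sprintf("file '%s' lacks variable '%s' (mapped to '%s')",
                   basename(path), variable_map[[nm]], nm))
  }
  getb <- function(v) {
    b <- ncdf4::ncvar_get(nc, v)
    c(b[1, ], b[2, ncol(b)])
  }
  lon_b <- getb("lon_bnds"); lat_b <- getb("lat_bnds"); dep_b <- getb("depth_bnds")
  flipped <- FALSE
  if (all(dep_b <= 0)) {  # negative-up convention: convert to positive-down
    dep_b <- rev(-dep_b)
    flipped <- TRUE
  }
  bathy <- ncdf4::ncvar_get(nc, "deptho")
  bathy[is.na(bathy)] <- 0
  grid <- ocean_grid(lon_b, lat_b, dep_b, bathy)
  getv <- function(v) {
    x <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
    if (flipped) {
      idx <- rev(seq_len(dim(x)[3]))
      x <- if (length(dim(x)) == 4L) x[, , idx, , drop = FALSE] else x[, , idx, drop = FALSE]
    }
    x
  }
  theta <- getv(variable_map[["theta"]])
  time_axis <- if (length(dim(theta)) == 4L) "monthly" else "annual"
  att <- function(a) {
    r <- ncdf4::ncatt_get(nc, 0, a)
    if (r$hasatt) r$value else ""
  }
  fs <- field_set(grid, theta, getv(variable_map[["sp"]]),
                  getv(variable_map[["o2_conc"]]), time_axis = time_axis,
                  period_label = att("period_label"),
                  scenario_label = att("scenario_label"))
  if ("to_insitu" %in% have) fs$t_insitu <- getv("to_insitu")
  if ("po2" %in% have) fs$po2 <- getv("po2")
  fs
}

#' Write a 3-D habitat mask to NetCDF
#'
#' Masks are stored as byte arrays with `flag_values` 0/1 on the
#' (lon, lat, depth) grid.
#'
#' @param mask3d Logical `[lon, lat, depth]` array.
#' @param grid The `ocean_grid` the mask lives on.
#' @param path Output file path.
#' @param name Variable name (default `"habitat"`).
#' @param attrs Named list of global attributes (e.g.
#'   `probability_threshold`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask3d, grid, path, name = "habitat", attrs = list()) {
  dims <- list(ncdf4::ncdim_def("lon", "degrees_east", grid$lon),
               ncdf4::ncdim_def("lat", "degrees_north", grid$lat),
               ncdf4::ncdim_def("depth", "m", grid$depth))
  v <- ncdf4::ncvar_def(name, "1", dims, prec = "byte")
  nc <- ncdf4::nc_create(path, list(v))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, array(as.integer(mask3d), dim = dim(mask3d)))
  ncdf4::ncatt_put(nc, name, "flag_values", "0, 1")
  for (a in names(attrs)) ncdf4::ncatt_put(nc, 0, a, attrs[[a]])
  invisible(path)
}

#' Read a 3-D habitat mask written by [write_mask()]
#' @param path NetCDF file path.
#' @param name Variable name.
#' @return Logical array.
#' @export
load_mask <- function(path, name = "habitat") {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_get(nc, name, collapse_degen = FALSE) != 0
}
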