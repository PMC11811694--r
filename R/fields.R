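#' Gridded ocean state for one period/scenario
#'
#' A `field_set` bundles potential temperature, practical salinity and
#' oxygen concentration (plus, once derived, in situ temperature and pO2)
#' on an [ocean_grid()], either as a 12-month climatology
#' (`[lon,lat,depth,12]`) or as a single annual mean (`[lon,lat,depth]`).
#' Land and below-seafloor cells are `NA`, never zero.
#'
#' @param grid An `ocean_grid`.
#' @param theta Potential temperature, deg C.
#' @param sp Practical salinity.
#' @param o2_conc Dissolved oxygen, mmol m-3.
#' @param time_axis `"monthly"` or `"annual"`.
#' @param period_label,scenario_label Free-text labels recorded in output.
#' @return An object of class `field_set`.
#' @export
field_set <- function(grid, theta, sp, o2_conc, time_axis = c("monthly", "annual"),
                      period_label = "", scenario_label = "") {
  time_axis <- match.arg(time_axis)
  want <- if (time_axis == "monthly") c(grid$nlon, grid$nlat, grid$ndepth, 12L)
          else c(grid$nlon, grid$nlat, grid$ndepth)
  for (nm in c("theta", "sp", "o2_conc")) {
    x <- get(nm)
    if (!all(dim(x) == want))
      stop(sprintf("field '%s' has dims [%s]; expected [%s]", nm,
                   paste(dim(x), collapse = ","), paste(want, collapse = ",")))
  }
  dry <- !grid$wet
  if (time_axis == "monthly") dry <- array(dry, dim = want)
  for (nm in c("theta", "sp", "o2_conc")) {
    x <- get(nm); x[dry] <- NA_real_; assign(nm, x)
  }
  if (any(o2_conc < 0, na.rm = TRUE)) stop("negative oxygen concentration")
  structure(list(grid = grid, theta = theta, sp = sp, o2_conc = o2_conc,
                 t_insitu = NULL, po2 = NULL, time_axis = time_axis,
                 period_label = period_label, scenario_label = scenario_label),
            class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("<field_set> %s %s [%s], derived: %s\n",
              x$period_label, x$scenario_label, x$time_axis,
              if (is.null(x$po2)) "no" else "t_insitu, po2"))
  invisible(x)
}

# depth/lat-dependent arrays broadcast to field shape
broadcast_depth_lat <- function(fun2d, fs) {
  g <- fs$grid
  m <- outer(g$lat, g$depth, fun2d)              # [lat, depth]
  a <- aperm(array(m, dim = c(g$nlat, g$ndepth, g$nlon)), c(3, 1, 2))
  if (fs$time_axis == "monthly") array(a, dim = c(dim(a), 12L)) else a
}

#' Derive in situ temperature and pO2 for a field set
#'
#' Computes in situ temperature from potential temperature and salinity,
#' in situ density, converts oxygen to mol kg-1, and derives pO2.  Fills
#' the `t_insitu` and `po2` slots.
#'
#' @param fs A `field_set`.
#' @return The `field_set` with derived fields populated.
#' @export
derive_insitu_fields <- function(fs) {
  depth_arr <- broadcast_depth_lat(function(la, de) de, fs)
  lat_arr <- broadcast_depth_lat(function(la, de) la, fs)
  ok <- !is.na(fs$theta)
  t_in <- fs$theta
  t_in[ok] <- insitu_temperature(fs$theta[ok], fs$sp[ok], depth_arr[ok], lat_arr[ok])
  rho <- fs$theta
  rho[ok] <- insitu_density(t_in[ok], fs$sp[ok], depth_arr[ok], lat_arr[ok])
  po2 <- fs$theta
  po2[ok] <- compute_po2(o2_molal(fs$o2_conc[ok], rho[ok]), t_in[ok], fs$sp[ok])
  fs$t_insitu <- t_in
  fs$po2 <- po2
  fs
}

#' Annual mean of a monthly field set
#'
#' Averages the 12 climatological months (equal month weights) of the state
#' variables, then re-derives in situ temperature and pO2 from the
#' annual-mean state so that derived fields are self-consistent.
#'
#' @param fs A monthly `field_set`.
#' @return An annual `field_set` with derived fields populated.
#' @export
annual_mean <- function(fs) {
  stopifnot(fs$time_axis == "monthly")
  mn <- function(x) apply(x, 1:3, mean)
  out <- field_set(fs$grid, mn(fs$theta), mn(fs$sp), mn(fs$o2_conc),
                   time_axis = "annual", period_label = fs$period_label,
                   scenario_label = fs$scenario_label)
  derive_insitu_fields(out)
}

#' Clip a field set to the analysis domain
#'
#' Subsets to cells south of `lat_max` and depth levels with centre at or
#' above `depth_max`.  Idempotent.
#'
#' @param fs A `field_set`.
#' @inheritParams clip_grid
#' @return A clipped `field_set` (derived fields are subset too).
#' @export
clip_domain <- function(fs, lat_max = -45, depth_max = 3185) {
  g <- fs$grid
  jj <- which(g$lat < lat_max)
  kk <- which(g$depth <= depth_max)
  newg <- clip_grid(g, lat_max, depth_max)
  sub <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(dim(x)) == 4L) x[, jj, kk, , drop = FALSE]
    else x[, jj, kk, drop = FALSE]
  }
  out <- fs
  out$grid <- newg
  for (nm in c("theta", "sp", "o2_conc", "t_insitu", "po2"))
    out[[nm]] <- sub(fs[[nm]])
  out
}
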