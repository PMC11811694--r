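#' Drift correction of a scenario field
#'
#' Removes the control simulation's drift over the same interval:
#' `X_corrected = X_scenario - (X_control_future - X_control_hist)`.
#' Applied to in situ temperature and oxygen concentration before pO2 is
#' recomputed.  Linear, and the control corrects to its own historical
#' state exactly.
#'
#' @param scenario_future,control_future,control_hist Arrays of identical
#'   shape.
#' @return Corrected array.
#' @export
drift_correct <- function(scenario_future, control_future, control_hist) {
  if (!identical(dim(scenario_future), dim(control_future)) ||
      !identical(dim(scenario_future), dim(control_hist)))
    stop("field shapes differ")
  scenario_future - (control_future - control_hist)
}

#' Drift-correct a future field set against the control run
#'
#' Applies [drift_correct()] to the in situ temperature and oxygen
#' concentration of an annual future `field_set`, then recomputes pO2 from
#' the corrected fields (density from the corrected temperature and the
#' scenario salinity).
#'
#' @param future,control_future,control_hist Annual `field_set`s with
#'   derived fields.
#' @return The corrected annual `field_set`.
#' @export
drift_correct_fields <- function(future, control_future, control_hist) {
  fs <- future
  fs$t_insitu <- drift_correct(future$t_insitu, control_future$t_insitu,
                               control_hist$t_insitu)
  fs$o2_conc <- drift_correct(future$o2_conc, control_future$o2_conc,
                              control_hist$o2_conc)
  fs$o2_conc <- pmax(fs$o2_conc, 0)
  fs$po2 <- recompute_po2(fs$o2_conc, fs$t_insitu, fs$sp, fs$grid)
  fs
}

# pO2 from volumetric O2, in situ T and salinity on a grid (annual arrays).
recompute_po2 <- function(o2_conc, t_insitu, sp, grid) {
  depth_arr <- aperm(array(grid$depth, dim = c(grid$ndepth, grid$nlon, grid$nlat)),
                     c(2, 3, 1))
  lat_arr <- aperm(array(grid$lat, dim = c(grid$nlat, grid$nlon, grid$ndepth)),
                   c(2, 1, 3))
  ok <- !is.na(t_insitu) & !is.na(o2_conc) & !is.na(sp)
  out <- t_insitu
  out[!ok] <- NA_real_
  rho <- insitu_density(t_insitu[ok], sp[ok], depth_arr[ok], lat_arr[ok])
  out[ok] <- compute_po2(o2_molal(o2_conc[ok], rho), t_insitu[ok], sp[ok])
  out
}

#' Attribute AGI change to temperature or oxygen
#'
#' Builds the (in situ temperature, pO2) pair entering the AGI computation
#' for an attribution mode: `temperature_only` keeps pO2 at historical
#' levels while using future temperature; `oxygen_only` keeps temperature
#' at historical levels and recomputes pO2 from the (drift-corrected)
#' future oxygen concentration with historical temperature and salinity;
#' `both` uses the future fields as they are.
#'
#' @param hist Annual historical `field_set` with derived fields.
#' @param future Annual (drift-corrected) future `field_set` with derived
#'   fields.
#' @param mode One of `"temperature_only"`, `"oxygen_only"`, `"both"`.
#' @return List with `t_insitu` and `po2` arrays.
#' @export
attribute_change <- function(hist, future,
                             mode = c("both", "temperature_only", "oxygen_only")) {
  mode <- match.arg(mode)
  switch(mode,
    both = list(t_insitu = future$t_insitu, po2 = future$po2),
    temperature_only = list(t_insitu = future$t_insitu, po2 = hist$po2),
    oxygen_only = list(
      t_insitu = hist$t_insitu,
      po2 = recompute_po2(future$o2_conc, hist$t_insitu, hist$sp, hist$grid)
    ))
}

#' Volume-weighted in-habitat profile of a field
#'
#' Per depth level, the volume-weighted mean of a 3-D field over the cells
#' of a habitat mask; levels with no habitat cells are `NA`.
#'
#' @param field Numeric `[lon, lat, depth]` array.
#' @param habitat3d Logical habitat mask.
#' @param grid The `ocean_grid`.
#' @return Numeric vector of length `ndepth`.
#' @export
habitat_profile <- function(field, habitat3d, grid) {
  vapply(seq_len(grid$ndepth), function(k) {
    sel <- habitat3d[, , k] & grid$wet[, , k] & !is.na(field[, , k])
    if (!any(sel)) return(NA_real_)
    w <- grid$cell_volume[, , k][sel]
    sum(field[, , k][sel] * w) / sum(w)
  }, numeric(1))
}

pct_change <- function(future, hist) {
  ifelse(is.na(hist) | hist == 0, NA_real_, 100 * (future - hist) / hist)
}

#' Per-species viable habitat change report
#'
#' Percent change of Omega between the historical baseline and a future
#' period, total (the vertically averaged change, with the whole historical
#' 3-D habitat volume as denominator) and per depth level.  Species with
#' zero historical Omega are flagged `NA`, never divided.
#'
#' @param registry A `species_registry`.
#' @param hist_viability,future_viability Named lists (by species id) of
#'   `viability_result`s.
#' @return A data frame with one row per species (`species_id`, `name`,
#'   `omega_hist_km3`, `omega_future_km3`, `omega_change_pct`) and an
#'   attribute `by_level` (matrix species x depth of percent changes).
#' @export
omega_change_report <- function(registry, hist_viability, future_viability) {
  ids <- names(registry$records)
  rows <- lapply(ids, function(id) {
    h <- hist_viability[[id]]; f <- future_viability[[id]]
    data.frame(species_id = registry$records[[id]]$species_id,
               name = registry$records[[id]]$name,
               omega_hist_km3 = h$omega_total,
               omega_future_km3 = f$omega_total,
               omega_change_pct = pct_change(f$omega_total, h$omega_total))
  })
  out <- do.call(rbind, rows)
  by_level <- t(vapply(ids, function(id)
    pct_change(future_viability[[id]]$omega_by_level,
               hist_viability[[id]]$omega_by_level),
    numeric(length(hist_viability[[ids[1]]]$omega_by_level))))
  attr(out, "by_level") <- by_level
  out
}

#' Per-prey overlap change report
#'
#' Phi between the predator and each prey, historical and future, for the
#' whole habitat, the continental shelf, each depth interval and each
#' region mask, with percent changes (`NA` where the historical overlap in
#' a stratum is zero) and the historical overlap as percent of the
#' historical predator viable volume.
#'
#' @param registry A `species_registry`.
#' @param hist_viability,future_viability Named lists of
#'   `viability_result`s (must include the predator).
#' @param grid The `ocean_grid`.
#' @param masks Region masks from [ccamlr_masks()].
#' @param breaks Depth interval edges, metres.
#' @return A data frame with one row per prey species.
#' @export
phi_change_report <- function(registry, hist_viability, future_viability,
                              grid, masks, breaks = c(0, 400, 700, 1000, 3500)) {
  pid <- as.character(registry$predator_id)
  prey_ids <- setdiff(names(registry$records), pid)
  region_names <- intersect(c("area48", "area58", "area88"), names(masks))
  rows <- lapply(prey_ids, function(id) {
    oh <- overlap_volume(hist_viability[[pid]], hist_viability[[id]], grid,
                         shelf = masks$shelf, breaks = breaks)
    of <- overlap_volume(future_viability[[pid]], future_viability[[id]], grid,
                         shelf = masks$shelf, breaks = breaks)
    row <- data.frame(
      species_id = registry$records[[id]]$species_id,
      name = registry$records[[id]]$name,
      phi_hist_km3 = oh$phi, phi_future_km3 = of$phi,
      phi_change_pct = pct_change(of$phi, oh$phi),
      phi_pct_of_predator = oh$phi_pct_of_predator,
      phi_shelf_hist_km3 = oh$phi_shelf,
      phi_shelf_change_pct = pct_change(of$phi_shelf, oh$phi_shelf))
    for (iv in names(oh$phi_by_interval)) {
      row[[paste0("phi_hist_", iv)]] <- oh$phi_by_interval[[iv]]
      row[[paste0("phi_change_pct_", iv)]] <-
        pct_change(of$phi_by_interval[[iv]], oh$phi_by_interval[[iv]])
    }
    for (rn in region_names) {
      bh <- hist_viability[[pid]]$viable & hist_viability[[id]]$viable &
        expand_mask3d(masks[[rn]], grid)
      bf <- future_viability[[pid]]$viable & future_viability[[id]]$viable &
        expand_mask3d(masks[[rn]], grid)
      vh <- mask_volume(bh, grid); vf <- mask_volume(bf, grid)
      row[[paste0("phi_hist_", rn)]] <- vh
      row[[paste0("phi_change_pct_", rn)]] <- pct_change(vf, vh)
    }
    row
  })
  do.call(rbind, rows)
}

#' Prey richness in the predator's viable habitat
#'
#' At each cell of the predator's viable mask, counts the prey species
#' whose viable mask includes the cell.  Reports the richness field, the
#' area-weighted mean per depth level for the whole habitat and per region,
#' and a top-1000 m column average map.
#'
#' @param registry A `species_registry`.
#' @param viability Named list of `viability_result`s including the
#'   predator.
#' @param grid The `ocean_grid`.
#' @param masks Region masks ([ccamlr_masks()]).
#' @param top_depth Cap in metres for the column-average map (default 1000).
#' @param within Optional fixed logical reference mask over which to count
#'   and average (defaults to the predator's viable mask in `viability`).
#'   Passing the historical viable mask when evaluating a future period
#'   compares prey numbers over one and the same region.
#' @return List with `richness` (array, `NA` outside the reference mask),
#'   `profile` (matrix level x region incl. `all`), `column_map`
#'   (`[lon, lat]` thickness-weighted mean over the top `top_depth` m).
#' @export
prey_richness <- function(registry, viability, grid, masks, top_depth = 1000,
                          within = NULL) {
  pid <- as.character(registry$predator_id)
  prey_ids <- setdiff(names(registry$records), pid)
  pv <- if (is.null(within)) viability[[pid]]$viable else within
  counts <- array(0L, dim = dim(pv))
  for (id in prey_ids) counts <- counts + viability[[id]]$viable
  richness <- array(NA_real_, dim = dim(pv))
  richness[pv] <- counts[pv]

  regions <- c(list(all = matrix(TRUE, grid$nlon, grid$nlat)),
               masks[intersect(c("area48", "area58", "area88"), names(masks))])
  profile <- vapply(regions, function(m) {
    vapply(seq_len(grid$ndepth), function(k) {
      sel <- pv[, , k] & m
      if (!any(sel)) return(NA_real_)
      w <- grid$cell_area[sel]
      sum(richness[, , k][sel] * w) / sum(w)
    }, numeric(1))
  }, numeric(grid$ndepth))
  profile <- matrix(profile, nrow = grid$ndepth,
                    dimnames = list(NULL, names(regions)))

  kk <- which(grid$depth <= top_depth)
  thick <- diff(grid$depth_bounds)[kk]
  column_map <- matrix(NA_real_, grid$nlon, grid$nlat)
  for (i in seq_len(grid$nlon)) for (j in seq_len(grid$nlat)) {
    sel <- pv[i, j, kk]
    if (!any(sel)) next
    column_map[i, j] <- sum(richness[i, j, kk][sel] * thick[sel]) / sum(thick[sel])
  }
  list(richness = richness, profile = profile, column_map = column_map)
}
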