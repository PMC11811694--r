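#' AGI model parameters
#'
#' Constants of the extended aerobic growth index: `j1` and `j2` are the
#' anabolism and catabolism activation energies divided by the Boltzmann
#' constant (Kelvin), `d` the metabolic scaling coefficient, and
#' `mass_ratio_base` the base of the demand mass factor
#' `mass_ratio_base^(1 - d)`.  Defaults are the published constants.
#'
#' @param j1,j2 Activation temperatures in Kelvin, `j2 > j1`.
#' @param d Metabolic scaling coefficient in (0, 1).
#' @param mass_ratio_base Positive dimensionless base (default 1/3).
#' @return A list of class `agi_params`.
#' @export
agi_params <- function(j1 = 4500, j2 = 8000, d = 0.7, mass_ratio_base = 1 / 3) {
  stopifnot(j2 > j1, d > 0, d < 1, mass_ratio_base > 0)
  structure(list(j1 = j1, j2 = j2, d = d, mass_ratio_base = mass_ratio_base),
            class = "agi_params")
}

#' Volume-weighted percentile (weighted empirical CDF, lower-value rule)
#'
#' Returns the smallest value `v` such that the normalised cumulative weight
#' of all samples `<= v` reaches at least `q`.  With `q = 0` this is the
#' minimum, with `q = 1` the maximum; no interpolation is performed, so the
#' result is always one of the input values and the rule is exact on ties.
#'
#' @param values Numeric vector (finite).
#' @param weights Non-negative weights (cell volumes), at least one positive.
#' @param q Probability in `[0, 1]`.
#' @return A single value from `values`.
#' @export
weighted_percentile <- function(values, weights, q) {
  stopifnot(length(q) == 1, q >= 0, q <= 1)
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]; weights <- weights[keep]
  if (!length(values)) stop("no samples")
  if (any(weights < 0)) stop("negative weights")
  tot <- sum(weights)
  if (tot <= 0) stop("all weights are zero")
  o <- order(values)
  cw <- cumsum(weights[o]) / tot
  values[o][which(cw >= q - 1e-12)[1]]
}

#' Species thresholds from the monthly climatology
#'
#' The preferred temperature is the volume-weighted in-habitat median (50th
#' percentile) of monthly climatological in situ temperature; the pO2
#' threshold is the volume-weighted 10th percentile of monthly
#' climatological in-habitat pO2.  Each of the 12 months contributes one
#' sample per habitat cell, weighted by the cell volume (months equally
#' weighted).
#'
#' @param clim A monthly `field_set` with derived `t_insitu` and `po2`.
#' @param habitat3d Logical `[lon, lat, depth]` habitat mask.
#' @param grid The `ocean_grid`.
#' @return A list of class `species_thresholds` with `t_pref` (deg C) and
#'   `po2_thr` (mbar); `agi_crit` is `NA` until set by [agi_crit()].
#' @export
species_thresholds <- function(clim, habitat3d, grid) {
  stopifnot(clim$time_axis == "monthly")
  if (is.null(clim$t_insitu) || is.null(clim$po2))
    stop("climatology lacks derived fields; call derive_insitu_fields() first")
  if (!any(habitat3d & grid$wet)) stop("empty habitat")
  sel <- which(habitat3d & grid$wet)
  w <- rep(grid$cell_volume[sel], times = 12L)
  ncell <- prod(dim(grid$cell_volume))
  idx <- as.vector(outer(sel, (0:11) * ncell, "+"))
  structure(list(
    t_pref = weighted_percentile(clim$t_insitu[idx], w, 0.5),
    po2_thr = weighted_percentile(clim$po2[idx], w, 0.1),
    agi_crit = NA_real_
  ), class = "species_thresholds")
}

#' Aerobic growth index
#'
#' Ratio of environmental pO2 supply to the species-specific,
#' temperature-dependent pO2 demand:
#' `AGI = pO2 / (pO2_thr * b^(1-d) * exp((j2-j1)/Tpref_K - (j2-j1)/T_K))`
#' with `b = mass_ratio_base` and temperatures in Kelvin (conversion
#' happens here; thresholds are stored in deg C).  At the preferred
#' temperature and threshold pO2 the index equals
#' `mass_ratio_base^-(1-d)` (about 1.3904 for the defaults), for every
#' species.  AGI is linear in pO2 and strictly decreasing in temperature:
#' warming raises the demand.
#'
#' @param t_insitu In situ temperature, deg C (scalar or array).
#' @param po2 Oxygen partial pressure, mbar (non-negative).
#' @param thresholds A `species_thresholds` (or list with `t_pref`,
#'   `po2_thr`).
#' @param params An [agi_params()].
#' @return AGI, dimensionless, same shape as the inputs.
#' @export
agi <- function(t_insitu, po2, thresholds, params = agi_params()) {
  if (is.null(thresholds$po2_thr) || thresholds$po2_thr <= 0)
    stop("po2_thr must be positive")
  if (any(po2 < 0, na.rm = TRUE)) stop("negative pO2")
  dj <- params$j2 - params$j1
  tk <- t_insitu + 273.15
  tprefk <- thresholds$t_pref + 273.15
  demand <- thresholds$po2_thr * params$mass_ratio_base^(1 - params$d) *
    exp(dj / tprefk - dj / tk)
  po2 / demand
}

#' Critical AGI of a species
#'
#' The 10th volume-weighted percentile of monthly climatological in-habitat
#' AGI, evaluated per cell-month with the species' thresholds.
#'
#' @inheritParams species_thresholds
#' @param thresholds A `species_thresholds` from [species_thresholds()].
#' @param params An [agi_params()].
#' @return The `species_thresholds` with `agi_crit` filled in.
#' @export
agi_crit <- function(clim, habitat3d, thresholds, grid, params = agi_params()) {
  stopifnot(clim$time_axis == "monthly")
  if (!any(habitat3d & grid$wet)) stop("empty habitat")
  sel <- which(habitat3d & grid$wet)
  ncell <- prod(dim(grid$cell_volume))
  idx <- as.vector(outer(sel, (0:11) * ncell, "+"))
  a <- agi(clim$t_insitu[idx], clim$po2[idx], thresholds, params)
  w <- rep(grid$cell_volume[sel], times = 12L)
  thresholds$agi_crit <- weighted_percentile(a, w, 0.1)
  thresholds
}

#' Viable habitat volume
#'
#' A habitat cell is viable when its AGI strictly exceeds the species'
#' critical AGI.  Omega is the summed volume of viable cells, reported in
#' total, per depth level, and per region mask.
#'
#' @param agi_field AGI array `[lon, lat, depth]` (annual evaluation).
#' @param crit Critical AGI (scalar), or a `species_thresholds` with
#'   `agi_crit` set.
#' @param habitat3d Logical habitat mask.
#' @param grid The `ocean_grid`.
#' @param masks Optional named list of `[lon, lat]` region masks.
#' @return List of class `viability_result`: `viable` (logical array),
#'   `omega_total` (km^3), `omega_by_level` (km^3 per depth level),
#'   `omega_by_region` (named vector, if masks given).
#' @export
viable_volume <- function(agi_field, crit, habitat3d, grid, masks = NULL) {
  if (inherits(crit, "species_thresholds")) crit <- crit$agi_crit
  viable <- habitat3d & grid$wet & !is.na(agi_field) & (agi_field > crit)
  by_region <- NULL
  if (!is.null(masks))
    by_region <- vapply(masks, function(m)
      mask_volume(viable & expand_mask3d(m, grid), grid), numeric(1))
  structure(list(viable = viable,
                 omega_total = mask_volume(viable, grid),
                 omega_by_level = mask_volume_by_level(viable, grid),
                 omega_by_region = by_region),
            class = "viability_result")
}

#' Depth-interval membership of grid levels
#'
#' Assigns each depth level (by its centre) to the analysis intervals
#' 0-400, 400-700, 700-1000 and 1000-3500 m.
#'
#' @param grid An `ocean_grid`.
#' @param breaks Interval edges in metres.
#' @return Factor of length `ndepth` with interval labels.
#' @export
depth_intervals <- function(grid, breaks = c(0, 400, 700, 1000, 3500)) {
  cut(grid$depth, breaks = breaks, right = TRUE, include.lowest = TRUE,
      labels = paste0(breaks[-length(breaks)], "-", breaks[-1], "m"))
}

#' Viable habitat overlap of predator and prey
#'
#' Phi is the volume where both viable masks are true, reported in total,
#' per depth interval, and on the continental shelf.  Phi is symmetric and
#' bounded by both Omegas.
#'
#' @param pred,prey `viability_result`s on the same grid.
#' @param grid The `ocean_grid`.
#' @param shelf Optional logical `[lon, lat]` shelf mask.
#' @param breaks Depth interval edges (metres).
#' @return List of class `overlap_value`: `phi` (km^3),
#'   `phi_pct_of_predator`, `phi_by_interval` (named vector), `phi_shelf`.
#' @export
overlap_volume <- function(pred, prey, grid, shelf = NULL,
                           breaks = c(0, 400, 700, 1000, 3500)) {
  both <- pred$viable & prey$viable
  lev <- mask_volume_by_level(both, grid)
  iv <- depth_intervals(grid, breaks)
  phi_by_interval <- tapply(lev, iv, sum, default = 0)
  phi <- sum(lev)
  structure(list(
    phi = phi,
    phi_pct_of_predator = if (pred$omega_total > 0) 100 * phi / pred$omega_total else NA_real_,
    phi_by_interval = phi_by_interval,
    phi_shelf = if (!is.null(shelf)) mask_volume(both & expand_mask3d(shelf, grid), grid) else NA_real_
  ), class = "overlap_value")
}

#' Relative AGI change
#'
#' Percent change of AGI between a future field and the historical
#' baseline, `100 * (future / historical - 1)`.  Because the
#' species-specific demand cancels in the ratio, the result is species
#' independent: it reflects only the change in temperature and oxygen.
#'
#' @param agi_future,agi_hist AGI arrays on the same support.
#' @return Percent-change array; `NA` where the historical AGI is 0 or
#'   missing.
#' @export
agi_rel <- function(agi_future, agi_hist) {
  out <- 100 * (agi_future / agi_hist - 1)
  out[!is.finite(out)] <- NA_real_
  out
}
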