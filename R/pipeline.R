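#' Species thresholds table for a study
#'
#' Computes preferred temperature, pO2 threshold and critical AGI for every
#' species in a registry from the monthly climatology, in the layout of the
#' study's reference table.
#'
#' @param clim Monthly `field_set` with derived fields.
#' @param registry A `species_registry`.
#' @param grid The `ocean_grid`.
#' @param params An [agi_params()].
#' @return Data frame: `species_id`, `name`, `t_pref_c`, `po2_thr_mbar`,
#'   `agi_crit`, `probability_threshold`; plus attribute `thresholds`
#'   (named list of `species_thresholds`).
#' @export
thresholds_table <- function(clim, registry, grid, params = agi_params()) {
  th <- lapply(registry$records, function(rec) {
    t0 <- species_thresholds(clim, rec$habitat3d, grid)
    agi_crit(clim, rec$habitat3d, t0, grid, params)
  })
  out <- data.frame(
    species_id = vapply(registry$records, `[[`, numeric(1), "species_id"),
    name = vapply(registry$records, `[[`, character(1), "name"),
    t_pref_c = vapply(th, `[[`, numeric(1), "t_pref"),
    po2_thr_mbar = vapply(th, `[[`, numeric(1), "po2_thr"),
    agi_crit = vapply(th, `[[`, numeric(1), "agi_crit"),
    probability_threshold = registry$probability_threshold,
    row.names = NULL)
  attr(out, "thresholds") <- th
  out
}

# Viability of every species on an annual (t_insitu, po2) pair.
viability_all <- function(fields, thresholds, registry, grid, masks,
                          params = agi_params()) {
  out <- lapply(names(registry$records), function(id) {
    a <- agi(fields$t_insitu, fields$po2, thresholds[[id]], params)
    viable_volume(a, thresholds[[id]], registry$records[[id]]$habitat3d,
                  grid, masks = masks[c("shelf", "area48", "area58", "area88")])
  })
  names(out) <- names(registry$records)
  out
}

#' Run the full change analysis on a study
#'
#' The complete pipeline for one occurrence-probability threshold: species
#' thresholds from the monthly historical climatology; historical viability
#' on the annual-mean historical fields; per scenario, drift-corrected
#' future fields, attribution, viability, and the change reports (per-depth
#' profiles of dT, dpO2 and relative AGI change in the predator habitat,
#' per-species viable-volume change, per-prey overlap change, prey
#' richness).
#'
#' @param study A `synthetic_study` (or a list with the same elements
#'   built from real inputs).
#' @param scenarios Character vector of scenario names to analyse.
#' @param params An [agi_params()].
#' @param attribution_modes Attribution modes to evaluate for the AGIrel
#'   profile (the change reports always use `"both"`).
#' @return List of class `change_report` with `thresholds`, `hist_viability`,
#'   and per scenario: `fields` (drift-corrected), `viability`,
#'   `profiles` (data frame), `omega_change`, `phi_change`, `richness`,
#'   `richness_hist`.
#' @export
run_change_analysis <- function(study, scenarios = names(study$scenarios$scenarios),
                                params = agi_params(),
                                attribution_modes = c("both", "temperature_only",
                                                      "oxygen_only")) {
  grid <- study$grid
  masks <- study$masks
  registry <- study$registry
  ttab <- thresholds_table(study$clim, registry, grid, params)
  th <- attr(ttab, "thresholds")
  hist_annual <- study$scenarios$historical_annual
  hist_v <- viability_all(hist_annual, th, registry, grid, masks, params)
  pid <- as.character(registry$predator_id)
  pred_hab <- registry$records[[pid]]$habitat3d
  rich_hist <- prey_richness(registry, hist_v, grid, masks)

  per_scen <- lapply(scenarios, function(sc) {
    fut <- drift_correct_fields(study$scenarios$scenarios[[sc]],
                                study$scenarios$control_future,
                                study$scenarios$control_hist)
    pair_both <- attribute_change(hist_annual, fut, "both")
    agirel_profiles <- lapply(attribution_modes, function(md) {
      pair <- attribute_change(hist_annual, fut, md)
      af <- agi(pair$t_insitu, pair$po2, th[[pid]], params)
      ah <- agi(hist_annual$t_insitu, hist_annual$po2, th[[pid]], params)
      habitat_profile(agi_rel(af, ah), pred_hab, grid)
    })
    names(agirel_profiles) <- attribution_modes
    profiles <- data.frame(
      depth_m = grid$depth,
      dt_c = habitat_profile(pair_both$t_insitu - hist_annual$t_insitu,
                             pred_hab, grid),
      dpo2_mbar = habitat_profile(pair_both$po2 - hist_annual$po2,
                                  pred_hab, grid))
    for (md in attribution_modes)
      profiles[[paste0("agirel_pct_", md)]] <- agirel_profiles[[md]]
    fut_v <- viability_all(fut, th, registry, grid, masks, params)
    list(fields = fut,
         viability = fut_v,
         profiles = profiles,
         omega_change = omega_change_report(registry, hist_v, fut_v),
         phi_change = phi_change_report(registry, hist_v, fut_v, grid, masks),
         richness = prey_richness(registry, fut_v, grid, masks))
  })
  names(per_scen) <- scenarios
  structure(list(thresholds = ttab, hist_viability = hist_v,
                 richness_hist = rich_hist, scenarios = per_scen,
                 grid = grid, masks = masks, registry = registry),
            class = "change_report")
}

#' Fraction of prey losing viable habitat
#'
#' Counts the prey species whose total viable-habitat change is a decline
#' of at least `loss_pct` percent.
#'
#' @param omega_change Data frame from [omega_change_report()].
#' @param predator_id Species id of the predator (excluded).
#' @param loss_pct Loss threshold in percent (positive).
#' @return Fraction in `[0, 1]`.
#' @export
prey_loss_fraction <- function(omega_change, predator_id, loss_pct) {
  prey <- omega_change[omega_change$species_id != predator_id, ]
  mean(prey$omega_change_pct <= -loss_pct, na.rm = TRUE)
}
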