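#!/usr/bin/env Rscript
# Stage 3: scenario projections -- drift-corrected change profiles of in
# situ temperature, pO2 and relative AGI in the predator habitat
# (including the temperature-only / oxygen-only attribution), and the
# per-species viable-habitat and per-prey overlap change tables for all
# four emission scenarios.

suppressPackageStartupMessages(library(agihabitat))

seed <- 1
dir.create("results", showWarnings = FALSE)

study <- build_synthetic_study(synth_config(seed = seed))
rep_all <- run_change_analysis(study)

profiles <- do.call(rbind, lapply(names(rep_all$scenarios), function(sc) {
  cbind(scenario = sc, rep_all$scenarios[[sc]]$profiles)
}))
write.csv(profiles, "results/change_profiles.csv", row.names = FALSE)

omega <- do.call(rbind, lapply(names(rep_all$scenarios), function(sc) {
  cbind(scenario = sc, rep_all$scenarios[[sc]]$omega_change)
}))
write.csv(omega, "results/omega_change.csv", row.names = FALSE)

phi <- do.call(rbind, lapply(names(rep_all$scenarios), function(sc) {
  cbind(scenario = sc, rep_all$scenarios[[sc]]$phi_change)
}))
write.csv(phi, "results/phi_change.csv", row.names = FALSE)

p585 <- rep_all$scenarios$ssp585$profiles
k_cross <- with(p585, depth_m[which(agirel_pct_both < 0)[1]])
message("SSP5-8.5: relative AGI change turns negative at the level centred ",
        round(k_cross), " m; the oxygen-only attribution explains most of ",
        "the subsurface decline (compare agirel_pct_oxygen_only).")
oc5 <- rep_all$scenarios$ssp585$omega_change
worst <- oc5[which.min(oc5$omega_change_pct), ]
message("Largest viable-habitat loss: ", worst$name, " (",
        round(worst$omega_change_pct, 1), "%).")
message("Fraction of prey losing >= 10% viable habitat (SSP5-8.5): ",
        round(100 * prey_loss_fraction(oc5, study$registry$predator_id, 10)),
        "%")
message("Wrote results/change_profiles.csv, omega_change.csv, phi_change.csv")
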