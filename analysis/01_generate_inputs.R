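#!/usr/bin/env Rscript
# Stage 1: generate the seeded synthetic study inputs -- grid, monthly
# climatology, scenario fields, and the species set -- and write them to
# results/inputs as the same NetCDF/CSV artifacts a real-data run would
# consume.

suppressPackageStartupMessages(library(agihabitat))

seed <- 1
out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
study <- build_synthetic_study(cfg)

message("Grid: ", study$grid$nlon, " x ", study$grid$nlat, " x ",
        study$grid$ndepth, ", total wet volume ",
        format(total_volume(study$grid), big.mark = ","), " km^3")

write_fields(study$clim, file.path(out_dir, "climatology_monthly.nc"))
write_fields(study$scenarios$historical_annual,
             file.path(out_dir, "historical_annual.nc"))
write_fields(study$scenarios$control_hist, file.path(out_dir, "control_hist.nc"))
write_fields(study$scenarios$control_future,
             file.path(out_dir, "control_future.nc"))
for (sc in names(study$scenarios$scenarios))
  write_fields(study$scenarios$scenarios[[sc]],
               file.path(out_dir, paste0(sc, "_2091-2100.nc")))

for (id in names(study$registry$records))
  write_mask(study$registry$records[[id]]$habitat3d, study$grid,
             file.path(out_dir, paste0("habitat_species_", id, ".nc")),
             attrs = list(probability_threshold =
                            study$registry$probability_threshold))

vol_tab <- region_volume_table(study$grid, study$masks)
write.csv(vol_tab, file.path(out_dir, "region_volumes.csv"), row.names = FALSE)

# run manifest: everything needed to reproduce this stage
manifest <- list(seed = seed, config = study$config[setdiff(names(study$config),
                                                            "")],
                 package_version = as.character(packageVersion("agihabitat")),
                 r_version = R.version.string,
                 files = list.files(out_dir))
if (requireNamespace("jsonlite", quietly = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

message("Shelf fraction of domain area: ",
        round(100 * sum(study$grid$cell_area[study$masks$shelf]) /
                sum(study$grid$cell_area[study$masks$domain]), 1), "%")
message("Wrote inputs to ", out_dir)
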