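test_that("drift correction is exact arithmetic with the expected identities", {
  x <- array(5, c(2, 2, 2)); cf <- array(4, c(2, 2, 2)); ch <- array(3, c(2, 2, 2))
  expect_equal(drift_correct(x, cf, ch), array(4, c(2, 2, 2)))
  # zero drift: identity
  expect_equal(drift_correct(x, ch, ch), x)
  # the control corrects to its own historical state
  expect_equal(drift_correct(cf, cf, ch), ch)
  # linear in the (scenario, control) triple: correcting a sum of fields
  # against summed controls equals the sum of corrected fields
  y <- array(runif(8), c(2, 2, 2))
  expect_equal(drift_correct(x + y, cf + cf, ch + ch),
               drift_correct(x, cf, ch) + drift_correct(y, cf, ch),
               tolerance = 1e-12)
  expect_error(drift_correct(x, cf[, , 1, drop = FALSE], ch), "shape")
})

test_that("attribution isolates the perturbed driver", {
  g <- toy_grid(nlon = 3, nlat = 2, ndep = 3)
  hist <- constant_fields(g, theta = 0, o2 = 280)
  # temperature-only perturbation of the world
  fut_t <- constant_fields(g, theta = 1, o2 = 280)
  # oxygen-only attribution must see no change at all
  pair <- attribute_change(hist, fut_t, "oxygen_only")
  expect_equal(pair$t_insitu, hist$t_insitu)
  expect_equal(pair$po2, hist$po2, tolerance = 1e-12)
  # and the temperature-only attribution reproduces the full fields here
  pair_t <- attribute_change(hist, fut_t, "temperature_only")
  expect_equal(pair_t$t_insitu, fut_t$t_insitu)
  expect_equal(pair_t$po2, hist$po2)
  # oxygen-only perturbation: temperature attribution sees nothing
  fut_o <- constant_fields(g, theta = 0, o2 = 240)
  pair_o <- attribute_change(hist, fut_o, "temperature_only")
  th <- list(t_pref = 0, po2_thr = 120)
  rel <- agi_rel(agi(pair_o$t_insitu, pair_o$po2, th),
                 agi(hist$t_insitu, hist$po2, th))
  expect_equal(max(abs(rel), na.rm = TRUE), 0)
  expect_error(attribute_change(hist, fut_o, "bogus"))
})

test_that("attribution ratios multiply to the combined ratio when pO2 is supplied directly", {
  set.seed(21)
  th <- list(t_pref = 0.5, po2_thr = 125)
  t_h <- runif(30, -1.5, 4); t_f <- t_h + runif(30, 0, 1.5)
  p_h <- runif(30, 100, 200); p_f <- p_h * runif(30, 0.8, 1.1)
  a_h <- agi(t_h, p_h, th)
  r_t <- agi(t_f, p_h, th) / a_h
  r_o <- agi(t_h, p_f, th) / a_h
  r_b <- agi(t_f, p_f, th) / a_h
  expect_equal(r_t * r_o, r_b, tolerance = 1e-12)
})

test_that("habitat profiles are volume-weighted level means", {
  g <- ocean_grid(c(0, 10, 20), c(-70, -65), c(0, 100), matrix(100, 2, 1))
  hab <- array(TRUE, c(2, 1, 1))
  f <- array(c(0, 2), c(2, 1, 1))
  # equal volumes: plain mean
  expect_equal(habitat_profile(f, hab, g), 1)
  # weights 1:3 via bathymetry, values 0 and 4 -> 3
  g2 <- ocean_grid(c(0, 10, 20), c(-70, -65), c(0, 100),
                   matrix(c(25, 75), 2, 1))
  f2 <- array(c(0, 4), c(2, 1, 1))
  expect_equal(habitat_profile(f2, array(TRUE, c(2, 1, 1)), g2), 3)
  # constant field: profile is the constant; empty level is NA
  g3 <- toy_grid(nlon = 2, nlat = 2, ndep = 3)
  f3 <- array(7, c(2, 2, 3))
  hab3 <- array(TRUE, c(2, 2, 3)); hab3[, , 3] <- FALSE
  expect_equal(habitat_profile(f3, hab3, g3), c(7, 7, NA))
})

test_that("omega and phi change reports divide by the historical value only when positive", {
  g <- ocean_grid(c(0, 10), c(-70, -65), c(0, 300, 600, 900), matrix(900, 1, 1))
  hab <- array(TRUE, c(1, 1, 3))
  tab <- data.frame(species_id = 1:2, name = c("pred", "prey"),
                    common_name = c("p", "q"), min_depth_m = c(0, 0),
                    max_depth_m = c(900, 900),
                    suitability_threshold = c(NA, NA))
  maps <- list(`1` = list(map = matrix(1, 1, 1)), `2` = list(map = matrix(1, 1, 1)))
  reg <- load_registry(tab, maps, g)
  mk <- function(vals) viable_volume(array(vals, c(1, 1, 3)), 1, hab, g)
  hist_v <- list(`1` = mk(c(2, 2, 2)), `2` = mk(c(2, 2, 0)))
  fut_v <- list(`1` = mk(c(2, 2, 2)), `2` = mk(c(2, 0, 0)))
  oc <- omega_change_report(reg, hist_v, fut_v)
  v <- g$cell_volume[1, 1, ]
  expect_equal(oc$omega_change_pct[1], 0)
  expect_equal(oc$omega_change_pct[2], 100 * (v[1] - v[1] - v[2]) / (v[1] + v[2]))
  # halving omega reads -50%
  hv <- list(`1` = mk(c(2, 2, 0)), `2` = mk(c(2, 2, 0)))
  fv <- list(`1` = mk(c(2, 0, 0)), `2` = mk(c(2, 0, 0)))
  oc2 <- omega_change_report(reg, hv, fv)
  expect_equal(oc2$omega_change_pct[1], 100 * (v[1] / (v[1] + v[2]) - 1))
  # zero historical volume is NA, not a division
  hz <- list(`1` = mk(c(0, 0, 0)), `2` = mk(c(0, 0, 0)))
  expect_true(all(is.na(omega_change_report(reg, hz, hz)$omega_change_pct)))
})

test_that("phi change tracks the predator for an identical prey and dies with disjoint habitats", {
  study <- default_study()
  rep_all <- run_change_analysis(study, scenarios = "ssp585")
  pid <- as.character(study$registry$predator_id)
  hv <- rep_all$hist_viability
  fv <- rep_all$scenarios$ssp585$viability
  # prey identical to predator: phi == omega on both sides
  ovh <- overlap_volume(hv[[pid]], hv[[pid]], study$grid)
  expect_equal(ovh$phi, hv[[pid]]$omega_total)
  ovf <- overlap_volume(fv[[pid]], fv[[pid]], study$grid)
  expect_equal(100 * (ovf$phi / ovh$phi - 1),
               rep_all$scenarios$ssp585$omega_change$omega_change_pct[1],
               tolerance = 1e-10)
  # disjoint viable masks: zero overlap in all periods
  empty <- hv[[pid]]
  empty$viable <- array(FALSE, dim(empty$viable))
  expect_equal(overlap_volume(hv[[pid]], empty, study$grid)$phi, 0)
})

test_that("prey richness counts viable prey inside the predator mask only", {
  g <- ocean_grid(c(0, 10, 20), c(-70, -65), c(0, 500), matrix(500, 2, 1))
  hab <- array(TRUE, c(2, 1, 1))
  tab <- data.frame(species_id = 1:3, name = c("pred", "a", "b"),
                    common_name = tolower(c("pred", "a", "b")),
                    min_depth_m = 0, max_depth_m = 500,
                    suitability_threshold = NA)
  maps <- lapply(1:3, function(i) list(map = matrix(1, 2, 1)))
  names(maps) <- as.character(1:3)
  reg <- load_registry(tab, maps, g)
  mk <- function(vals) viable_volume(array(vals, c(2, 1, 1)), 1, hab, g)
  viab <- list(`1` = mk(c(2, 0)),   # predator viable only in cell 1
               `2` = mk(c(2, 2)), `3` = mk(c(2, 2)))
  masks <- list(shelf = matrix(TRUE, 2, 1))
  rich <- prey_richness(reg, viab, g, masks)
  expect_equal(rich$richness[1, 1, 1], 2)
  expect_true(is.na(rich$richness[2, 1, 1]))       # outside predator mask
  expect_equal(rich$profile[1, "all"], 2, ignore_attr = TRUE)
  expect_equal(rich$column_map[1, 1], 2)
  expect_true(is.na(rich$column_map[2, 1]))
})

test_that("richness is invariant under permutation of prey order and bounded by depth availability", {
  study <- default_study()
  rep_all <- run_change_analysis(study, scenarios = "ssp126")
  v <- rep_all$hist_viability
  g <- study$grid
  r1 <- prey_richness(study$registry, v, g, study$masks)
  v_perm <- v[c("1", rev(setdiff(names(v), "1")))]
  r2 <- prey_richness(study$registry, v_perm, g, study$masks)
  expect_equal(r1$richness, r2$richness)
  # bound: at each level, count <= number of prey whose depth range covers it
  prey <- study$registry$records[setdiff(names(study$registry$records), "1")]
  for (k in seq_len(g$ndepth)) {
    vals <- r1$richness[, , k]
    if (all(is.na(vals))) next
    avail <- sum(vapply(prey, function(r) any(r$habitat3d[, , k]), logical(1)))
    expect_lte(max(vals, na.rm = TRUE), avail)
  }
})
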