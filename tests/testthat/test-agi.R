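test_that("weighted percentile follows the lower-value weighted ECDF rule", {
  expect_equal(weighted_percentile(c(1, 2, 3, 4), c(1, 1, 1, 7), 0.5), 4)
  # equal weights, odd n: the middle order statistic
  expect_equal(weighted_percentile(c(5, 1, 9, 3, 7), rep(1, 5), 0.5), 5)
  # two equal-volume samples: lower-value rule at the median
  expect_equal(weighted_percentile(c(0, 2), c(1, 1), 0.5), 0)
  # boundaries
  x <- c(4, -2, 7, 0)
  expect_equal(weighted_percentile(x, c(1, 2, 3, 4), 0), -2)
  expect_equal(weighted_percentile(x, c(1, 2, 3, 4), 1), 7)
  expect_error(weighted_percentile(numeric(0), numeric(0), 0.5), "no samples")
  expect_error(weighted_percentile(c(1, 2), c(0, 0), 0.5), "zero")
  expect_error(weighted_percentile(c(1, 2), c(-1, 2), 0.5), "negative")
})

test_that("weighted percentile matches the brute-force oracle on enumerated instances", {
  qs <- c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 1)
  weight_patterns <- list(c(1), c(2, 1), c(1, 1), c(1, 2, 7), c(5, 5, 5),
                          c(1, 1, 1, 7), c(3, 1, 4, 1, 5), c(1, 0, 2, 0, 3),
                          rep(1, 8), c(8, 4, 2, 1, 1, 2, 4, 8))
  set.seed(101)
  for (w in weight_patterns) {
    n <- length(w)
    vals_list <- list(seq_len(n), rev(seq_len(n)), rep(1, n),
                      round(rnorm(n), 2), sample(c(0, 1), n, replace = TRUE))
    for (v in vals_list) for (q in qs) {
      expect_equal(weighted_percentile(v, w, q),
                   brute_weighted_percentile(v, w, q),
                   info = sprintf("n=%d q=%g", n, q))
    }
  }
})

test_that("the AGI closed-form anchor holds at preferred conditions for any species", {
  set.seed(4)
  for (i in 1:10) {
    th <- list(t_pref = runif(1, -2, 10), po2_thr = runif(1, 100, 170))
    expect_equal(agi(th$t_pref, th$po2_thr, th), 3^0.3, tolerance = 1e-13)
  }
  # non-default mass ratio base
  p2 <- agi_params(mass_ratio_base = 0.5)
  expect_equal(agi(1, 120, list(t_pref = 1, po2_thr = 120), p2),
               0.5^(-0.3), tolerance = 1e-13)
})

test_that("AGI reproduces the independent scalar evaluation for toothfish thresholds", {
  # published toothfish thresholds: Tpref +0.06 degC, pO2thr 120.2 mbar;
  # warmed by 1 K at unchanged pO2 the index drops to ~1.327
  th <- list(t_pref = 0.06, po2_thr = 120.2)
  # independent evaluation written out term by term
  dj <- 8000 - 4500
  demand <- 120.2 * (1 / 3)^(0.3) * exp(dj / (0.06 + 273.15) - dj / (1.06 + 273.15))
  expect_equal(agi(1.06, 120.2, th), 120.2 / demand, tolerance = 1e-14)
  expect_equal(agi(1.06, 120.2, th), 1.327, tolerance = 5e-4)
})

test_that("AGI is linear in pO2 and strictly decreasing in temperature", {
  th <- list(t_pref = 0, po2_thr = 120)
  expect_equal(agi(2, 240, th), 2 * agi(2, 120, th), tolerance = 1e-13)
  tt <- seq(-2, 8, 0.5)
  expect_true(all(diff(agi(tt, 150, th)) < 0))
  expect_error(agi(0, -5, th), "negative")
  expect_error(agi(0, 120, list(t_pref = 0, po2_thr = 0)), "po2_thr")
})

test_that("the AGI ratio identity cancels species parameters", {
  set.seed(12)
  for (i in 1:20) {
    th <- list(t_pref = runif(1, -2, 10), po2_thr = runif(1, 100, 170))
    t_h <- runif(1, -2, 5); t_f <- t_h + runif(1, -1, 2)
    p_h <- runif(1, 80, 220); p_f <- p_h * runif(1, 0.7, 1.3)
    ratio <- agi(t_f, p_f, th) / agi(t_h, p_h, th)
    ref <- (p_f / p_h) * exp(3500 * (1 / (t_f + 273.15) - 1 / (t_h + 273.15)))
    expect_equal(ratio, ref, tolerance = 1e-12)
  }
})

test_that("species thresholds come from the volume-weighted monthly ECDF", {
  g <- toy_grid(nlon = 2, nlat = 1, ndep = 1, lat_range = c(-70, -65),
                depth_max = 100, bathy_m = 100)
  # constant climatology: thresholds equal the constants
  clim <- constant_fields(g, theta = -1, sp = 34.5, o2 = 250, time_axis = "monthly")
  hab <- array(TRUE, dim = c(2, 1, 1))
  th <- species_thresholds(clim, hab, g)
  expect_equal(th$t_pref, clim$t_insitu[1, 1, 1, 1], tolerance = 1e-9)
  expect_equal(th$po2_thr, clim$po2[1, 1, 1, 1], tolerance = 1e-9)
  # two equal-volume cells at 0 and 2 degC: lower-value rule gives 0
  clim2 <- clim
  clim2$t_insitu[2, 1, 1, ] <- clim2$t_insitu[1, 1, 1, ] + 2
  th2 <- species_thresholds(clim2, hab, g)
  expect_equal(th2$t_pref, clim2$t_insitu[1, 1, 1, 1])
  expect_error(species_thresholds(clim, array(FALSE, c(2, 1, 1)), g), "empty")
})

test_that("critical AGI of a constant climatology equals the anchor", {
  g <- toy_grid(nlon = 3, nlat = 2, ndep = 2)
  clim <- constant_fields(g, theta = 0.5, sp = 34.5, o2 = 260, time_axis = "monthly")
  hab <- array(TRUE, dim = c(3, 2, 2))
  th <- species_thresholds(clim, hab, g)
  th <- agi_crit(clim, hab, th, g)
  # constant fields: Tpref/pO2thr equal the field values level by level?
  # no -- with depth structure from pressure they differ slightly, so only
  # check the percentile ordering property and the exact single-level case
  gl <- toy_grid(nlon = 3, nlat = 2, ndep = 1, depth_max = 50, bathy_m = 50)
  cl <- constant_fields(gl, theta = 0.5, sp = 34.5, o2 = 260, time_axis = "monthly")
  hl <- array(TRUE, dim = c(3, 2, 1))
  tl <- agi_crit(cl, hl, species_thresholds(cl, hl, gl), gl)
  # cells differ at ~1e-8 through the latitude dependence of pressure
  expect_equal(tl$agi_crit, 3^0.3, tolerance = 1e-6)
  # percentile ordering: crit no larger than the in-habitat median AGI
  sel <- which(hab)
  a_med <- weighted_percentile(
    agi(clim$t_insitu[sel], clim$po2[sel], th), g$cell_volume[sel], 0.5)
  expect_lte(th$agi_crit, a_med)
})

test_that("viable volume sums volumes above the strict critical threshold", {
  g <- ocean_grid(c(0, 10), c(-70, -65), c(0, 1, 3, 6),
                  matrix(6, 1, 1))
  # volumes proportional to 10, 20, 30
  v <- g$cell_volume[1, 1, ]
  expect_equal(v / v[1], c(1, 2, 3))
  hab <- array(TRUE, c(1, 1, 3))
  a <- array(c(1.5, 1.1, 1.3), c(1, 1, 3))
  res <- viable_volume(a, 1.2, hab, g)
  expect_equal(res$omega_total, v[1] + v[3])
  expect_equal(res$omega_by_level, c(v[1], 0, v[3]))
  expect_equal(sum(res$omega_by_level), res$omega_total)
  # boundary cells are excluded (strict inequality)
  res_b <- viable_volume(array(1.2, c(1, 1, 3)), 1.2, hab, g)
  expect_equal(res_b$omega_total, 0)
  # everything below crit
  expect_equal(viable_volume(a, 2, hab, g)$omega_total, 0)
})

test_that("overlap volume is a symmetric bounded intersection that sums over intervals", {
  g <- ocean_grid(c(0, 10), c(-70, -65), c(0, 300, 600, 900), matrix(900, 1, 1))
  hab <- array(TRUE, c(1, 1, 3))
  mk <- function(vals) viable_volume(array(vals, c(1, 1, 3)), 1, hab, g)
  pred <- mk(c(2, 2, 0.5))   # viable at levels 1, 2
  prey <- mk(c(0.5, 2, 2))   # viable at levels 2, 3
  ov <- overlap_volume(pred, prey, g, breaks = c(0, 400, 700, 1000, 3500))
  v <- g$cell_volume[1, 1, ]
  expect_equal(ov$phi, v[2])
  expect_lte(ov$phi, min(pred$omega_total, prey$omega_total))
  expect_equal(sum(ov$phi_by_interval), ov$phi)
  # symmetry and idempotence
  expect_equal(overlap_volume(prey, pred, g)$phi, ov$phi)
  expect_equal(overlap_volume(pred, pred, g)$phi, pred$omega_total)
})

test_that("relative AGI change is a percent ratio, zero on identity", {
  a <- array(runif(24, 0.5, 2), c(2, 3, 4))
  expect_equal(agi_rel(a, a), array(0, dim(a)))
  expect_equal(agi_rel(2 * a, a), array(100, dim(a)))
  h <- a; h[1, 1, 1] <- 0
  expect_true(is.na(agi_rel(a, h)[1, 1, 1]))
})
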