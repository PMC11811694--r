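#' Seawater pressure from depth
#'
#' Hydrostatic pressure at a given depth and latitude using the Saunders
#' (1981) fit, which accounts for the latitude dependence of gravity and for
#' seawater compressibility.
#'
#' @param depth Depth in metres, positive down.
#' @param lat Latitude in degrees.
#' @return Pressure in decibar.
#' @export
pressure_dbar <- function(depth, lat) {
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative (positive down)")
  x <- sin(lat * pi / 180)^2
  c1 <- 5.92e-3 + 5.25e-3 * x
  ((1 - c1) - sqrt((1 - c1)^2 - 8.84e-6 * depth)) / 4.42e-6
}

# Adiabatic temperature gradient (deg C per dbar), Fofonoff & Millard (1983).
# t in deg C (IPTS-68 scale differences are ignored), s practical salinity,
# p pressure in dbar.
adiabatic_gradient <- function(s, t, p) {
  ds <- s - 35
  (((-2.1687e-16 * t + 1.8676e-14) * t - 4.6206e-13) * p +
     ((2.7759e-12 * t - 1.1351e-10) * ds +
        ((-5.4481e-14 * t + 8.733e-12) * t - 6.7795e-10) * t + 1.8741e-8)) * p +
    (-4.2393e-8 * t + 1.8932e-6) * ds +
    ((6.6228e-10 * t - 6.836e-8) * t + 8.5258e-6) * t + 3.5803e-5
}

#' Potential temperature of seawater
#'
#' Temperature a water parcel would have if moved adiabatically from pressure
#' `p` to reference pressure `p_ref` (UNESCO Runge-Kutta integration of the
#' adiabatic lapse rate; Fofonoff & Millard 1983).  Published check value:
#' `potential_temperature(40, 40, 10000, 0) == 36.89073` to 5 decimals.
#'
#' @param s Practical salinity.
#' @param t In situ temperature, deg C, at pressure `p`.
#' @param p,p_ref Pressure and reference pressure, dbar.
#' @return Temperature in deg C at `p_ref`.
#' @export
potential_temperature <- function(s, t, p, p_ref = 0) {
  h <- p_ref - p
  xk <- h * adiabatic_gradient(s, t, p)
  t <- t + 0.5 * xk
  q <- xk
  p <- p + 0.5 * h
  xk <- h * adiabatic_gradient(s, t, p)
  t <- t + 0.29289322 * (xk - q)
  q <- 0.58578644 * xk + 0.121320344 * q
  xk <- h * adiabatic_gradient(s, t, p)
  t <- t + 1.707106781 * (xk - q)
  q <- 3.414213562 * xk - 4.121320344 * q
  p <- p + 0.5 * h
  xk <- h * adiabatic_gradient(s, t, p)
  t + (xk - 2 * q) / 6
}

check_ts_range <- function(theta, sp) {
  bad_t <- !is.na(theta) & (theta < -3 | theta > 40)
  bad_s <- !is.na(sp) & (sp < 0 | sp > 42)
  if (any(bad_t)) stop("temperature outside plausible range [-3, 40] degC")
  if (any(bad_s)) stop("salinity outside plausible range [0, 42]")
  invisible(TRUE)
}

#' In situ temperature from potential temperature
#'
#' Inverts the potential-temperature computation: integrates the adiabatic
#' lapse rate from the surface down to the local pressure.  At depth 0 the
#' result equals the potential temperature.
#'
#' @param theta Potential temperature, deg C (reference pressure 0 dbar).
#' @param sp Practical salinity.
#' @param depth Depth in metres, positive down.
#' @param lat Latitude, degrees.
#' @return In situ temperature, deg C.
#' @export
insitu_temperature <- function(theta, sp, depth, lat) {
  check_ts_range(theta, sp)
  p <- pressure_dbar(depth, lat)
  potential_temperature(sp, theta, 0, p)
}

# Density of seawater at atmospheric pressure (EOS-80 one-atmosphere term).
rho_atm <- function(s, t) {
  smow <- 999.842594 + (6.793952e-2 + (-9.095290e-3 +
    (1.001685e-4 + (-1.120083e-6 + 6.536332e-9 * t) * t) * t) * t) * t
  b <- 8.24493e-1 + (-4.0899e-3 + (7.6438e-5 +
    (-8.2467e-7 + 5.3875e-9 * t) * t) * t) * t
  cc <- -5.72466e-3 + (1.0227e-4 - 1.6546e-6 * t) * t
  smow + b * s + cc * s^1.5 + 4.8314e-4 * s^2
}

# Secant bulk modulus K(s, t, p) of EOS-80; p in bar.
bulk_modulus <- function(s, t, pb) {
  kw <- 19652.21 + (148.4206 + (-2.327105 +
    (1.360477e-2 - 5.155288e-5 * t) * t) * t) * t
  k0 <- kw + s * (54.6746 + (-0.603459 + (1.09987e-2 - 6.1670e-5 * t) * t) * t) +
    s^1.5 * (7.944e-2 + (1.6483e-2 - 5.3009e-4 * t) * t)
  aw <- 3.239908 + (1.43713e-3 + (1.16092e-4 - 5.77905e-7 * t) * t) * t
  a <- aw + s * (2.2838e-3 + (-1.0981e-5 - 1.6078e-6 * t) * t) + 1.91075e-4 * s^1.5
  bw <- 8.50935e-5 + (-6.12293e-6 + 5.2787e-8 * t) * t
  b <- bw + s * (-9.9348e-7 + (2.0816e-8 + 9.1697e-10 * t) * t)
  k0 + (a + b * pb) * pb
}

#' In situ density of seawater
#'
#' International equation of state of seawater (EOS-80, UNESCO 1983) with the
#' pressure effect through the secant bulk modulus.  Check values:
#' rho(S=0, t=5, p=0) = 999.96675, rho(35, 5, 0) = 1027.67547,
#' rho(35, 25, 10000 dbar) = 1062.53817 kg m-3.
#'
#' @param t_insitu In situ temperature, deg C.
#' @param sp Practical salinity.
#' @param depth Depth in metres, positive down.
#' @param lat Latitude, degrees.
#' @return Density in kg m-3.
#' @export
insitu_density <- function(t_insitu, sp, depth, lat) {
  check_ts_range(t_insitu, sp)
  pb <- pressure_dbar(depth, lat) / 10  # bar
  r0 <- rho_atm(sp, t_insitu)
  r0 / (1 - pb / bulk_modulus(sp, t_insitu, pb))
}

#' Oxygen saturation concentration
#'
#' Equilibrium O2 concentration of seawater with moist air at 1 atm total
#' pressure, Garcia & Gordon (1992) fit to the Benson & Krause data, in
#' umol kg-1.  Check value: 274.610 umol kg-1 at t = 10 degC, S = 35.
#'
#' @param t_insitu In situ temperature, deg C.
#' @param sp Practical salinity.
#' @return Saturation concentration, umol kg-1.
#' @export
o2_saturation <- function(t_insitu, sp) {
  ts <- log((298.15 - t_insitu) / (273.15 + t_insitu))
  a <- 5.80871 + (3.20291 + (4.17887 + (5.10006 +
    (-9.86643e-2 + 3.80369 * ts) * ts) * ts) * ts) * ts
  b <- -7.01577e-3 + (-7.70028e-3 + (-1.13864e-2 - 9.51519e-3 * ts) * ts) * ts
  exp(a + sp * b - 2.75915e-7 * sp^2)
}

#' Vapour pressure of water over seawater
#'
#' Weiss & Price (1980) fit, converted from atm to mbar.
#'
#' @inheritParams o2_saturation
#' @return Vapour pressure in mbar.
#' @export
water_vapour_pressure <- function(t_insitu, sp) {
  tk <- t_insitu + 273.15
  1013.25 * exp(24.4543 - 67.4509 * (100 / tk) - 4.8489 * log(tk / 100) -
                  0.000544 * sp)
}

#' Oxygen concentration unit conversion
#'
#' Volumetric model units (mmol m-3) to mass-specific units (mol kg-1) using
#' in situ density, and back.
#'
#' @param o2_conc O2 concentration, mmol m-3.
#' @param rho In situ density, kg m-3.
#' @return `o2_molal()`: mol kg-1; `o2_volumetric()`: mmol m-3.
#' @export
o2_molal <- function(o2_conc, rho) o2_conc / rho * 1e-3

#' @rdname o2_molal
#' @param o2_mol O2 concentration, mol kg-1.
#' @export
o2_volumetric <- function(o2_mol, rho) o2_mol * rho * 1e3

#' Partial pressure of oxygen
#'
#' Saturation-fraction formulation: the oxygen partial pressure is the
#' saturation fraction times the equilibrium pO2 of moist air,
#' `pO2 = (C / Csat) * x_O2 * (P_atm - p_H2O)`, with the dry-air O2 mole
#' fraction x_O2 = 0.20946 and P_atm = 1013.25 mbar.  Hydrostatic pressure is
#' ignored, as conventional for metabolic indices.
#'
#' @param o2_mol O2 concentration, mol kg-1 (must be non-negative).
#' @param t_insitu In situ temperature, deg C.
#' @param sp Practical salinity.
#' @return pO2 in mbar.
#' @export
compute_po2 <- function(o2_mol, t_insitu, sp) {
  if (any(o2_mol < 0, na.rm = TRUE)) stop("negative oxygen concentration")
  sat <- o2_saturation(t_insitu, sp)          # umol kg-1
  frac <- (o2_mol * 1e6) / sat
  frac * 0.20946 * (1013.25 - water_vapour_pressure(t_insitu, sp))
}
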