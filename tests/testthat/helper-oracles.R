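# Independent oracles and small fixture builders shared across tests.

# Solar elevation oracle: Meeus-style ephemeris (geometric mean longitude,
# equation of center, apparent obliquity), evaluated for the year 2015 and
# compared in true solar time (hour angle = 15 * (t - 12) degrees), which is
# the same time convention the package uses, so the equation of time cancels
# in the comparison. Independent of the package's Spencer-series declination.
oracle_solar_elevation <- function(lat, doy, hour) {
  jd <- 2457023.5 + (doy - 1) + hour / 24          # 2015-01-01 00:00 UT
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * T) %% 360
  M <- (357.52911 + 35999.05029 * T) * pi / 180
  C <- (1.914602 - 0.004817 * T) * sin(M) +
    (0.019993 - 0.000101 * T) * sin(2 * M) + 0.000289 * sin(3 * M)
  lam <- L0 + C
  omega <- (125.04 - 1934.136 * T) * pi / 180
  lam_app <- (lam - 0.00569 - 0.00478 * sin(omega)) * pi / 180
  eps0 <- 23 + 26 / 60 + 21.448 / 3600 - 46.815 * T / 3600
  eps <- (eps0 + 0.00256 * cos(omega)) * pi / 180
  delta <- asin(sin(eps) * sin(lam_app))
  H <- (hour - 12) * 15 * pi / 180
  latr <- lat * pi / 180
  asin(pmin(pmax(sin(latr) * sin(delta) + cos(latr) * cos(delta) * cos(H),
                 -1), 1)) * 180 / pi
}

# Closed-form diffuse light index for a sky open only within a cap of
# half-angle theta_h (radians) around the zenith, under SOC with b = 1:
# analytic integral of (1 + cos z) cos z sin z over the cap / full dome.
dli_cap_closed_form <- function(theta_h) {
  1 - (3 * cos(theta_h)^2 + 2 * cos(theta_h)^3) / 5
}

# Hemispherical image whose macro-terrain channel obscures all directions
# below `elev_deg` elevation (a uniform artificial horizon).
uniform_horizon_image <- function(side, elev_deg, camera = NULL) {
  g <- canopylight:::.pixel_grid(side)
  mask <- (pi / 2 - g$zen) < (elev_deg * pi / 180) & g$valid
  hemi_image(side, macro_terrain = mask, camera = camera)
}

# Small random vegetation-over-flat-ground cloud for rendering tests.
random_veg_cloud <- function(n_veg, n_ground = 200, rmax = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ang <- runif(n_veg, 0, 2 * pi)
  rad <- sqrt(runif(n_veg)) * rmax
  gx <- runif(n_ground, -rmax, rmax)
  gy <- runif(n_ground, -rmax, rmax)
  point_cloud(c(rad * sin(ang), gx), c(rad * cos(ang), gy),
              c(runif(n_veg, 2, 25), rep(0, n_ground)),
              class_label = rep(c("vegetation", "ground"),
                                c(n_veg, n_ground)))
}

flat_camera <- function(latitude = 47, altitude = 800) {
  camera_position(0, 0, z_ground = 0, height_above_ground = 1,
                  latitude = latitude, altitude = altitude)
}

# fast radiation config for bulk tests: coarser sun tracking only
fast_rad <- function() radiation_config(time_step = 60)
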