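#' Radiation model configuration
#'
#' Defaults follow common hemispherical-photograph light-climate settings:
#' atmospheric transmission split into 40% direct beam plus 20% diffuse of
#' the extraterrestrial flux, with barometric correction for altitude; the
#' standard overcast sky (SOC) gradation parameter `b = 1`; and sun tracking
#' across the growing season (May 1 - September 30) in 10-minute steps of
#' true solar time.
#'
#' @param b_soc SOC gradation parameter (0 = isotropic sky).
#' @param tau_direct Direct-beam atmospheric transmission at sea level per
#'   unit air mass.
#' @param frac_diffuse Diffuse fraction of extraterrestrial radiation. Does
#'   not affect the (ratio-valued) diffuse light index; retained for absolute
#'   irradiance output.
#' @param season_start,season_end First and last day of year of the
#'   integration window (defaults: 121 and 273, i.e. May 1 - Sep 30).
#' @param time_step Sun-tracking step in minutes.
#' @param sun_disk_radius Angular radius of the solar disk, degrees.
#' @param pressure_scale_height Barometric scale height in meters.
#' @return A `radiation_config` object.
#' @export
radiation_config <- function(b_soc = 1, tau_direct = 0.40, frac_diffuse = 0.20,
                             season_start = 121, season_end = 273,
                             time_step = 10, sun_disk_radius = 0.266,
                             pressure_scale_height = 8434) {
  stopifnot(tau_direct > 0, tau_direct < 1, frac_diffuse >= 0,
            frac_diffuse < 1, time_step > 0, b_soc >= 0,
            sun_disk_radius > 0, pressure_scale_height > 0,
            season_start >= 1, season_end <= 366, season_start <= season_end)
  structure(list(b_soc = b_soc, tau_direct = tau_direct,
                 frac_diffuse = frac_diffuse, season_start = season_start,
                 season_end = season_end, time_step = time_step,
                 sun_disk_radius = sun_disk_radius,
                 pressure_scale_height = pressure_scale_height),
            class = "radiation_config")
}

#' Solar position from latitude, day of year and true solar time
#'
#' Declination from the Spencer (1971) Fourier series; hour angle
#' `15 * (hour - 12)` degrees (true solar time, so no equation-of-time or
#' longitude correction is needed). Azimuth is measured from North,
#' clockwise through East.
#'
#' @param latitude Degrees (-90 to 90).
#' @param day_of_year Integer 1-366 (vectorized).
#' @param solar_time Hours 0-24 (vectorized).
#' @return A data frame with `elevation` and `azimuth` in degrees.
#' @export
solar_position <- function(latitude, day_of_year, solar_time) {
  stopifnot(latitude >= -90, latitude <= 90,
            all(day_of_year >= 1), all(day_of_year <= 366),
            all(solar_time >= 0), all(solar_time <= 24))
  g <- 2 * pi * (day_of_year - 1 + (solar_time - 12) / 24) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lat <- latitude * pi / 180
  H <- (solar_time - 12) * 15 * pi / 180
  sin_e <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(H)
  elev <- asin(pmin(pmax(sin_e, -1), 1))
  az <- atan2(-cos(decl) * sin(H),
              cos(lat) * sin(decl) - sin(lat) * cos(decl) * cos(H))
  data.frame(elevation = elev * 180 / pi,
             azimuth = (az * 180 / pi) %% 360)
}

#' Relative optical air mass with barometric altitude correction
#'
#' Kasten-Young (1989) air mass scaled by the barometric pressure ratio
#' `exp(-altitude / scale_height)`.
#'
#' @param elevation Solar elevation in degrees (> 0).
#' @param altitude Site altitude in meters a.s.l.
#' @param cfg A [radiation_config()].
#' @return Dimensionless relative air mass.
#' @export
air_mass <- function(elevation, altitude = 0, cfg = radiation_config()) {
  if (any(elevation <= 0)) stop("air mass is undefined for elevation <= 0")
  p_ratio <- exp(-altitude / cfg$pressure_scale_height)
  p_ratio / (sin(elevation * pi / 180) +
             0.50572 * (elevation + 6.07995)^(-1.6364))
}

#' Standard overcast sky relative radiance
#'
#' `L(zenith) / L(zenith = 0) = (1 + b * cos(zenith)) / (1 + b)`: radiance
#' increases toward the zenith for `b > 0`; `b = 0` is an isotropic sky.
#'
#' @param zenith Zenith angle(s), radians in `[0, pi/2]`.
#' @param b Gradation parameter.
#' @return Relative radiance in `(0, 1]`.
#' @export
soc_radiance <- function(zenith, b = 1) {
  (1 + b * cos(zenith)) / (1 + b)
}

#' Canopy closure of a hemispherical image
#'
#' The solid-angle proportion of the sky vault obscured by canopy or terrain:
#' pixel occupancy weighted by the equiangular pixel solid angle
#' (proportional to `sin(zen)/zen`) over all valid pixels. Rendered images
#' carry an anti-aliased marker coverage channel that is used here;
#' images built from hard masks use the boolean obscured mask.
#'
#' @param img A [hemi_image()].
#' @return Fraction in `[0, 1]`.
#' @export
canopy_closure <- function(img) {
  g <- .pixel_grid(img$side)
  occ <- .occupancy(img)
  sum(g$w * occ) / sum(g$w[g$valid])
}

#' Diffuse light index
#'
#' The ratio of SOC diffuse irradiance received on a horizontal sensor
#' through the unobscured part of the sky to that under a fully open sky:
#' `sum_visible L(zen) cos(zen) w / sum_all L(zen) cos(zen) w`. Because the
#' SOC angular shape is time-invariant, the seasonal ratio reduces to this
#' single spatial integral.
#'
#' @param img A [hemi_image()].
#' @param cfg A [radiation_config()] (supplies `b_soc`).
#' @return Fraction in `[0, 1]`; 1 for an open sky.
#' @export
diffuse_index <- function(img, cfg = radiation_config()) {
  g <- .pixel_grid(img$side)
  occ <- .occupancy(img)
  lc <- soc_radiance(g$zen, cfg$b_soc) * cos(g$zen) * g$w
  sum(lc[g$valid] * (1 - occ[g$valid])) / sum(lc[g$valid])
}

# growing-season sun track with horizontal-beam weights, cached
.solar_track <- function(latitude, altitude, cfg) {
  key <- sprintf("track_%.5f_%.1f_%d_%d_%g_%g", latitude, altitude,
                 cfg$season_start, cfg$season_end, cfg$time_step,
                 cfg$tau_direct)
  if (!is.null(.cl_cache[[key]])) return(.cl_cache[[key]])
  days <- seq(cfg$season_start, cfg$season_end)
  hours <- seq(0, 24 - cfg$time_step / 60, by = cfg$time_step / 60)
  grid <- expand.grid(day = days, hour = hours)
  pos <- solar_position(latitude, grid$day, grid$hour)
  up <- pos$elevation > 0
  track <- data.frame(day = grid$day[up], hour = grid$hour[up],
                      elevation = pos$elevation[up],
                      azimuth = pos$azimuth[up])
  m <- air_mass(track$elevation, altitude, cfg)
  # horizontal-surface beam irradiance, extraterrestrial constant cancels
  track$weight <- cfg$tau_direct^m * sin(track$elevation * pi / 180)
  .cl_cache[[key]] <- track
  track
}

# fixed quasi-uniform sample pattern over the unit disk (19 points)
.disk_offsets <- function() {
  ring <- function(n, r) {
    t <- 2 * pi * (seq_len(n) - 0.5) / n
    cbind(r * sin(t), r * cos(t))
  }
  rbind(c(0, 0), ring(6, 0.45), ring(12, 0.85))
}

#' Direct (beam) light index
#'
#' Tracks the solar disk across the configured season and reports the
#' beam-weighted visible fraction: `sum_t w(t) v(t) / sum_t w(t)` where
#' `w(t) = tau^m(t) * sin(elevation)` is the horizontal-surface beam
#' irradiance (relative units) and `v(t)` the unobscured fraction of the sun
#' disk's projected pixels (sampled with a fixed 19-point pattern so that
#' even sub-pixel disks are supersampled; rendered images contribute their
#' fractional marker coverage per sampled pixel).
#'
#' @param img A [hemi_image()].
#' @param camera A [camera_position()] with `latitude` (and `altitude`) set.
#' @param cfg A [radiation_config()].
#' @return Fraction in `[0, 1]`; 1 for an open sky.
#' @export
direct_index <- function(img, camera, cfg = radiation_config()) {
  if (is.null(camera) || is.na(camera$latitude))
    stop("direct_index requires a camera latitude")
  altitude <- if (is.null(camera$altitude) || is.na(camera$altitude)) 0
              else camera$altitude
  track <- .solar_track(camera$latitude, altitude, cfg)
  if (nrow(track) == 0) return(0)
  side <- img$side
  R <- side / 2
  occ <- .occupancy(img)
  g <- .pixel_grid(side)
  centre <- project_equiangular(track$elevation * pi / 180,
                                track$azimuth * pi / 180, side)
  rad_px <- cfg$sun_disk_radius / 90 * R
  offs <- .disk_offsets()
  ns <- nrow(offs)
  nt <- nrow(track)
  cols <- rep(centre[, 1], each = ns) + rep(offs[, 1], nt) * rad_px
  rows <- rep(centre[, 2], each = ns) + rep(offs[, 2], nt) * rad_px
  pc <- floor(cols) + 1L
  pr <- floor(rows) + 1L
  ok <- pc >= 1L & pc <= side & pr >= 1L & pr <= side
  lin <- (pc - 1L) * side + pr
  inside <- ok
  inside[ok] <- g$valid[lin[ok]]
  vis <- numeric(length(inside))
  vis[inside] <- 1 - occ[lin[inside]]
  vis_m <- matrix(vis, nrow = ns)
  in_m <- matrix(inside, nrow = ns)
  nvalid <- colSums(in_m)
  v <- ifelse(nvalid > 0, colSums(vis_m) / nvalid, 0)
  sum(track$weight * v) / sum(track$weight)
}

#' All three light metrics of a hemispherical image
#'
#' @param img A [hemi_image()].
#' @param camera A [camera_position()] (latitude needed for the direct
#'   index); defaults to the camera stored in `img`.
#' @param cfg A [radiation_config()].
#' @return A one-row data frame with `diffuse_index`, `direct_index`,
#'   `canopy_closure`.
#' @export
compute_indices <- function(img, camera = img$camera,
                            cfg = radiation_config()) {
  data.frame(diffuse_index = diffuse_index(img, cfg),
             direct_index = direct_index(img, camera, cfg),
             canopy_closure = canopy_closure(img))
}
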