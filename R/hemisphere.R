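#' Camera position for hemispherical rendering
#'
#' @param x,y Planimetric position in meters (projected CRS).
#' @param z_ground Terrain elevation at (x, y), meters a.s.l.
#' @param height_above_ground Camera height above ground, meters (default 1,
#'   the standard understory viewpoint).
#' @param latitude Site latitude in degrees (needed for the direct light
#'   index).
#' @param altitude Site altitude in meters a.s.l. (air-mass correction);
#'   defaults to `z_ground`.
#' @return A `camera_position` object.
#' @export
camera_position <- function(x, y, z_ground = 0, height_above_ground = 1,
                            latitude = NA_real_, altitude = z_ground) {
  stopifnot(height_above_ground >= 0)
  if (!is.na(latitude) && (latitude < -90 || latitude > 90))
    stop("latitude must be in [-90, 90]")
  structure(list(x = x, y = y, z_ground = z_ground,
                 height_above_ground = height_above_ground,
                 latitude = latitude, altitude = altitude),
            class = "camera_position")
}

#' Rendering configuration
#'
#' Controls the synthetic hemispherical image: the point-inclusion radius,
#' the distance-scaled marker sizes, the image resolution and the horizon
#' discretization. Marker sizes are anchored at the 1200-px reference side
#' (7 px for the nearest return, 0.5 px at `max_radius`) and scale
#' proportionally with `image_side_px`, so the angular footprint of a marker
#' is resolution-independent.
#'
#' @param max_radius Point inclusion radius around the camera, meters.
#' @param marker_near_px Marker diameter (px at the reference side) for a
#'   return at distance 0.
#' @param marker_far_px Marker diameter (px at the reference side) for a
#'   return at `max_radius`.
#' @param image_side_px Side of the square image in pixels.
#' @param horizon_bins Number of azimuth bins of the terrain horizon profile.
#' @param marker_reference_side Image side at which the marker anchors are
#'   defined.
#' @return A `render_config` object.
#' @export
render_config <- function(max_radius = 100, marker_near_px = 7,
                          marker_far_px = 0.5, image_side_px = 1200,
                          horizon_bins = 360, marker_reference_side = 1200) {
  stopifnot(max_radius > 0, marker_near_px >= marker_far_px,
            marker_far_px > 0, image_side_px >= 16, horizon_bins >= 72)
  structure(list(max_radius = max_radius, marker_near_px = marker_near_px,
                 marker_far_px = marker_far_px, image_side_px = image_side_px,
                 horizon_bins = horizon_bins,
                 marker_reference_side = marker_reference_side),
            class = "render_config")
}

#' Transform returns into the camera-centered spherical frame
#'
#' Returns are expressed as distance `r` from the camera eye point, elevation
#' angle `theta` above the horizontal (radians, `asin(dz/r)`), and azimuth
#' `phi` (radians, 0 = North, increasing clockwise so East = pi/2). Points at
#' zero distance or beyond `max_radius` are dropped.
#'
#' @param cloud A [point_cloud()] (or any data frame with `x`, `y`, `z`).
#' @param camera A [camera_position()].
#' @param max_radius Inclusion radius in meters.
#' @return A data frame with columns `r`, `theta`, `phi` and the surviving
#'   row indices of `cloud` in `idx`.
#' @export
to_spherical <- function(cloud, camera, max_radius = 100) {
  if (nrow(cloud) == 0) stop("empty point cloud")
  dx <- cloud$x - camera$x
  dy <- cloud$y - camera$y
  dz <- cloud$z - (camera$z_ground + camera$height_above_ground)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  keep <- r > 0 & r <= max_radius
  r <- r[keep]; dx <- dx[keep]; dy <- dy[keep]; dz <- dz[keep]
  theta <- asin(pmin(pmax(dz / r, -1), 1))
  phi <- atan2(dx, dy) %% (2 * pi)
  data.frame(r = r, theta = theta, phi = phi, idx = which(keep))
}

#' Distance-scaled marker diameter
#'
#' Marker diameter in pixels (at the reference image side) decreases linearly
#' with distance, from `marker_near_px` at r = 0 to `marker_far_px` at
#' `max_radius`.
#'
#' @param r Distances in meters, `0 <= r <= max_radius`.
#' @param cfg A [render_config()].
#' @return Diameters in pixels.
#' @export
marker_size <- function(r, cfg = render_config()) {
  if (any(r < 0 | r > cfg$max_radius))
    stop("r must lie in [0, max_radius]")
  cfg$marker_near_px +
    (cfg$marker_far_px - cfg$marker_near_px) * r / cfg$max_radius
}

#' Equiangular fisheye projection
#'
#' Maps a viewing direction to continuous image coordinates of an
#' upward-looking fisheye with equiangular (polar) projection: radial pixel
#' distance is proportional to zenith angle. North is up and East is to the
#' left, as seen looking up. Continuous coordinates run from 0 (top/left
#' edge) to `side`; the image center is at (side/2, side/2).
#'
#' @param theta Elevation angle(s) above horizontal, radians.
#' @param phi Azimuth(s), radians (0 = North, clockwise).
#' @param side Image side in pixels.
#' @return A two-column matrix of (col, row) continuous coordinates.
#' @export
project_equiangular <- function(theta, phi, side) {
  R <- side / 2
  rho <- R * (pi / 2 - theta) / (pi / 2)
  cbind(col = R - rho * sin(phi), row = R - rho * cos(phi))
}

#' Inverse equiangular projection
#'
#' @param col,row Continuous image coordinates.
#' @param side Image side in pixels.
#' @return A data frame with `theta` (elevation, radians) and `phi`
#'   (azimuth, radians in `[0, 2*pi)`).
#' @export
unproject_equiangular <- function(col, row, side) {
  R <- side / 2
  dx <- R - col; dy <- R - row
  rho <- sqrt(dx^2 + dy^2)
  data.frame(theta = pi / 2 * (1 - rho / R),
             phi = ifelse(rho == 0, 0, atan2(dx, dy) %% (2 * pi)))
}

# cached per-pixel zenith/azimuth/solid-angle grids for a given image side
.pixel_grid <- function(side) {
  key <- paste0("px", side)
  if (!is.null(.cl_cache[[key]])) return(.cl_cache[[key]])
  R <- side / 2
  d <- (seq_len(side) - 0.5) - R           # offset of pixel centers
  dxc <- -d                                 # dx = R - col_center
  dyr <- -d                                 # dy = R - row_center
  rho <- sqrt(outer(dyr^2, dxc^2, "+"))
  zen <- rho / R * (pi / 2)
  valid <- rho <= R + 1e-9
  az <- outer(dyr, dxc, function(yy, xx) atan2(xx, yy)) %% (2 * pi)
  # equiangular pixel solid angle is proportional to sin(zen)/zen
  w <- ifelse(zen > 0, sin(zen) / zen, 1)
  w[!valid] <- 0
  g <- list(zen = zen, az = az, valid = valid, w = w)
  .cl_cache[[key]] <- g
  g
}

#' Terrain horizon profile around a camera
#'
#' For each azimuth bin, the horizon elevation is the maximum terrain
#' elevation angle along the outgoing ray, sampled at half-cell steps out to
#' the grid edge, floored at zero (terrain below the eye casts no macro
#' shadow).
#'
#' @param grid A [terrain_grid()].
#' @param camera A [camera_position()]; must lie inside the grid extent.
#' @param bins Number of azimuth bins (>= 72; default 360, i.e. 1 degree).
#' @return A `horizon_profile`: list with `azimuth` (bin centers, radians)
#'   and `elevation` (radians, >= 0).
#' @export
horizon_line <- function(grid, camera, bins = 360) {
  stopifnot(bins >= 72)
  nr <- nrow(grid$elevation); nc <- ncol(grid$elevation)
  ext <- c(grid$origin[1], grid$origin[1] + nc * grid$cell_size,
           grid$origin[2], grid$origin[2] + nr * grid$cell_size)
  if (camera$x < ext[1] || camera$x > ext[2] ||
      camera$y < ext[3] || camera$y > ext[4])
    stop("camera lies outside the terrain grid")
  cam_z <- camera$z_ground + camera$height_above_ground
  step <- grid$cell_size / 2
  dmax <- sqrt(max((camera$x - ext[1:2])^2) + max((camera$y - ext[3:4])^2))
  dist <- seq(step, dmax, by = step)
  az <- (seq_len(bins) - 1) * 2 * pi / bins
  # all bins x all distances in one vectorized lookup
  px <- camera$x + outer(sin(az), dist)
  py <- camera$y + outer(cos(az), dist)
  ez <- matrix(terrain_elevation(grid, as.vector(px), as.vector(py)),
               nrow = bins)
  ang <- atan2(ez - cam_z, matrix(dist, nrow = bins, ncol = length(dist),
                                  byrow = TRUE))
  ang[is.na(ang)] <- -Inf
  elev <- pmax(apply(ang, 1, max), 0)
  structure(list(azimuth = az, elevation = elev, bins = bins),
            class = "horizon_profile")
}

#' Construct a hemispherical occupancy image
#'
#' The square raster has three boolean channels (canopy, macro-terrain,
#' micro-terrain); a pixel is "obscured" if any channel is set. Pixels outside
#' the circumscribed circle are invalid.
#'
#' @param side Image side in pixels.
#' @param canopy,macro_terrain,micro_terrain Optional logical `side x side`
#'   matrices; missing channels start empty.
#' @param coverage Optional numeric `side x side` matrix in `[0, 1]`:
#'   anti-aliased occupancy of the point markers (canopy and micro-terrain),
#'   produced by [render_hemisphere()]. When present, the radiometric
#'   integrals ([canopy_closure()], [diffuse_index()], [direct_index()]) use
#'   it instead of the hard boolean marker channels, which makes them
#'   resolution-convergent; the boolean channels remain the masks for
#'   export and set-level properties.
#' @param camera,cfg Optional provenance ([camera_position()],
#'   [render_config()]) carried along for the light model.
#' @return A `hemi_image` object.
#' @export
hemi_image <- function(side, canopy = NULL, macro_terrain = NULL,
                       micro_terrain = NULL, coverage = NULL, camera = NULL,
                       cfg = NULL) {
  empty <- function(m) {
    if (is.null(m)) return(matrix(FALSE, side, side))
    stopifnot(is.logical(m), nrow(m) == side, ncol(m) == side)
    m
  }
  if (!is.null(coverage))
    stopifnot(is.numeric(coverage), nrow(coverage) == side,
              ncol(coverage) == side, all(coverage >= 0 & coverage <= 1))
  structure(list(side = side, canopy = empty(canopy),
                 macro_terrain = empty(macro_terrain),
                 micro_terrain = empty(micro_terrain),
                 coverage = coverage, camera = camera, cfg = cfg),
            class = "hemi_image")
}

# fractional sky occupancy in [0, 1] per pixel, used by the light integrals:
# the anti-aliased marker coverage (if rendered) combined with the analytic
# macro-terrain mask, else the hard obscured mask
.occupancy <- function(img) {
  g <- .pixel_grid(img$side)
  if (is.null(img$coverage)) return(obscured_mask(img) * 1)
  occ <- pmax(img$coverage, img$macro_terrain * 1)
  occ[!g$valid] <- 0
  occ
}

#' Composite obscured mask of a hemispherical image
#'
#' @param img A [hemi_image()].
#' @return Logical matrix: pixel obscured by any channel (invalid pixels are
#'   `FALSE`).
#' @export
obscured_mask <- function(img) {
  g <- .pixel_grid(img$side)
  (img$canopy | img$macro_terrain | img$micro_terrain) & g$valid
}

#' @export
print.hemi_image <- function(x, ...) {
  g <- .pixel_grid(x$side)
  obs <- obscured_mask(x)
  cat(sprintf("<hemi_image> %d x %d px; obscured pixel fraction %.3f\n",
              x$side, x$side, sum(obs) / sum(g$valid)))
  invisible(x)
}

#' Render a synthetic hemispherical image from a point cloud
#'
#' Vegetation returns within `max_radius` and at or above the horizontal are
#' stamped into the canopy channel as filled disks whose diameter shrinks
#' linearly with distance; ground returns above the camera go into the
#' micro-terrain channel with the same marker rule; all pixels below the
#' terrain horizon (from the DTM) are set in the macro-terrain channel.
#' True (non-normalized) coordinates are used throughout, so canopy on an
#' uphill slope plots nearer the image center.
#'
#' @param cloud A [point_cloud()].
#' @param camera A [camera_position()].
#' @param cfg A [render_config()].
#' @param terrain Optional [terrain_grid()] for the macro horizon.
#' @param horizon Optional precomputed [horizon_line()] profile (overrides
#'   `terrain`).
#' @return A [hemi_image()].
#' @export
render_hemisphere <- function(cloud, camera, cfg = render_config(),
                              terrain = NULL, horizon = NULL) {
  side <- cfg$image_side_px
  img <- hemi_image(side, camera = camera, cfg = cfg)
  scale <- side / cfg$marker_reference_side
  cov <- matrix(0, side, side)

  stamp_channel <- function(canvas, sub) {
    if (nrow(sub) == 0) return(canvas)
    pc <- project_equiangular(sub$theta, sub$phi, side)
    diam <- marker_size(sub$r, cfg) * scale
    cov <<- stamp_disks_cov_cpp(cov, pc[, 1], pc[, 2], diam)
    stamp_disks_cpp(canvas, pc[, 1], pc[, 2], diam)
  }

  if (nrow(cloud) > 0) {
    sph <- to_spherical(cloud, camera, cfg$max_radius)
    lab <- cloud$class_label[sph$idx]
    veg <- sph[lab == "vegetation" & sph$theta >= 0, , drop = FALSE]
    img$canopy <- stamp_channel(img$canopy, veg)
    gnd <- sph[lab == "ground" & sph$theta > 0, , drop = FALSE]
    img$micro_terrain <- stamp_channel(img$micro_terrain, gnd)
  }
  img$coverage <- cov

  if (is.null(horizon) && !is.null(terrain))
    horizon <- horizon_line(terrain, camera, cfg$horizon_bins)
  if (!is.null(horizon) && any(horizon$elevation > 0)) {
    g <- .pixel_grid(side)
    width <- 2 * pi / horizon$bins
    bin <- (round(g$az / width) %% horizon$bins) + 1L
    helev <- matrix(horizon$elevation[bin], side, side)
    img$macro_terrain <- (pi / 2 - g$zen) < helev & g$valid
  }
  img$horizon <- horizon
  img
}

#' Export a hemispherical image as PNG
#'
#' Sky is white, canopy black, macro-terrain red, micro-terrain green;
#' the area outside the image circle is light gray.
#'
#' @param img A [hemi_image()].
#' @param path Output `.png` path.
#' @param mirror_ew Flip East/West to obtain map orientation (the default
#'   `FALSE` is the view looking up: North up, East left).
#' @return `path`, invisibly.
#' @export
write_hemi_png <- function(img, path, mirror_ew = FALSE) {
  g <- .pixel_grid(img$side)
  r <- gmat <- b <- matrix(1, img$side, img$side)
  set <- function(mask, rgb) {
    r[mask] <<- rgb[1]; gmat[mask] <<- rgb[2]; b[mask] <<- rgb[3]
  }
  set(!g$valid, c(0.85, 0.85, 0.85))
  set(img$macro_terrain & g$valid, c(0.85, 0.15, 0.15))
  set(img$micro_terrain & g$valid, c(0.15, 0.65, 0.15))
  set(img$canopy & g$valid, c(0, 0, 0))
  arr <- array(c(r, gmat, b), dim = c(img$side, img$side, 3))
  if (mirror_ew) arr <- arr[, rev(seq_len(img$side)), , drop = FALSE]
  png::writePNG(arr, path)
  invisible(path)
}
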