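#' Specification of a synthetic conifer stand
#'
#' Describes the ground plane, the stem population and the per-return
#' densities used by [generate_stand()] and [generate_terrain()]. Defaults
#' emulate the study conditions the pipeline targets: conifer stands scanned
#' at 10 or more returns per square meter on sloping terrain.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in meters.
#' @param stem_density Stems per hectare.
#' @param tree_height_range `c(min, max)` total tree height, meters.
#' @param crown_base_frac Crown base height as a fraction of tree height.
#' @param crown_radius_frac Crown base radius as a fraction of crown length.
#' @param crown_point_density Returns per cubic meter of crown volume.
#' @param ground_point_density Ground returns per square meter. With the
#'   default crown density a moderately stocked stand exceeds 10 total
#'   returns per square meter.
#' @param slope_deg Terrain slope in degrees (0-60).
#' @param aspect_deg Downslope azimuth in degrees (0 = N, clockwise).
#' @param z0 Terrain elevation at the extent center, meters.
#' @param ridges Optional list of ridges for the macro terrain, each a list
#'   with `azimuth_deg`, `distance` (m from the extent center), `height` (m)
#'   and `width` (Gaussian sigma, m).
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A `stand_spec` object.
#' @export
stand_spec <- function(extent = c(-120, 120, -120, 120), stem_density = 300,
                       tree_height_range = c(12, 30), crown_base_frac = 0.25,
                       crown_radius_frac = 0.22,
                       crown_point_density = 1.5, ground_point_density = 4,
                       slope_deg = 0, aspect_deg = 180, z0 = 0,
                       ridges = list(), seed = 1L) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            stem_density >= 0, crown_point_density > 0,
            ground_point_density > 0, slope_deg >= 0, slope_deg <= 60)
  structure(list(extent = extent, stem_density = stem_density,
                 tree_height_range = tree_height_range,
                 crown_base_frac = crown_base_frac,
                 crown_radius_frac = crown_radius_frac,
                 crown_point_density = crown_point_density,
                 ground_point_density = ground_point_density,
                 slope_deg = slope_deg, aspect_deg = aspect_deg, z0 = z0,
                 ridges = ridges, seed = as.integer(seed)),
            class = "stand_spec")
}

# ground plane elevation of a stand spec
.plane_z <- function(spec, x, y) {
  cx <- mean(spec$extent[1:2]); cy <- mean(spec$extent[3:4])
  asp <- spec$aspect_deg * pi / 180
  # elevation decreases in the downslope (aspect) direction
  spec$z0 - tan(spec$slope_deg * pi / 180) *
    (sin(asp) * (x - cx) + cos(asp) * (y - cy))
}

#' Generate a terrain grid from a stand specification
#'
#' A planar slope plus optional Gaussian ridges: each ridge raises the
#' terrain by `height * exp(-(t - distance)^2 / (2 width^2))` where `t` is
#' the position along the ridge's azimuth from the extent center, producing
#' a linear crest perpendicular to that azimuth.
#'
#' @param spec A [stand_spec()].
#' @param cell_size Grid cell size in meters (default 100, the macro DTM
#'   resolution).
#' @param pad Margin added around the stand extent in meters, so distant
#'   ridges are inside the grid.
#' @return A [terrain_grid()].
#' @export
generate_terrain <- function(spec, cell_size = 100, pad = 3000) {
  ext <- spec$extent + c(-pad, pad, -pad, pad)
  nc <- ceiling((ext[2] - ext[1]) / cell_size)
  nr <- ceiling((ext[4] - ext[3]) / cell_size)
  xs <- ext[1] + (seq_len(nc) - 0.5) * cell_size
  ys <- ext[3] + (nr - seq_len(nr) + 0.5) * cell_size  # row 1 = north
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  Z <- .plane_z(spec, X, Y)
  cx <- mean(spec$extent[1:2]); cy <- mean(spec$extent[3:4])
  for (rg in spec$ridges) {
    az <- rg$azimuth_deg * pi / 180
    t <- sin(az) * (X - cx) + cos(az) * (Y - cy)
    Z <- Z + rg$height * exp(-(t - rg$distance)^2 / (2 * rg$width^2))
  }
  terrain_grid(Z, origin = c(ext[1], ext[3]), cell_size = cell_size)
}

# uniform samples inside a cone crown: apex at the tree top, base radius at
# the crown base; point density weighted by the squared local radius
.cone_points <- function(n, x0, y0, z_base, z_top, base_radius) {
  if (n == 0) return(NULL)
  u <- runif(n)
  # height fraction above crown base; radius shrinks linearly toward the top
  f <- 1 - u^(1 / 3)                      # density ~ (1 - f)^2
  zz <- z_base + f * (z_top - z_base)
  rr <- base_radius * (1 - f) * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  cbind(x0 + rr * sin(ang), y0 + rr * cos(ang), zz)
}

#' Generate a classified ALS point cloud for a synthetic stand
#'
#' Stems are Poisson-placed over the extent; each crown is a cone filled
#' with uniformly distributed vegetation returns; ground returns are uniform
#' over the ground plane. First-return flags are assigned per 0.5-m
#' planimetric column, topmost return first (a simplification of pulse
#' geometry adequate for count-ratio metrics).
#'
#' @param spec A [stand_spec()].
#' @return A [point_cloud()], seed-deterministic.
#' @export
generate_stand <- function(spec) {
  set.seed(spec$seed)
  ext <- spec$extent
  area <- (ext[2] - ext[1]) * (ext[4] - ext[3])
  n_gnd <- rpois(1, spec$ground_point_density * area)
  gx <- runif(n_gnd, ext[1], ext[2])
  gy <- runif(n_gnd, ext[3], ext[4])
  gz <- .plane_z(spec, gx, gy)
  pts <- list(cbind(gx, gy, gz))
  lab <- list(rep("ground", n_gnd))

  n_stem <- rpois(1, spec$stem_density * area / 1e4)
  if (n_stem > 0) {
    sx <- runif(n_stem, ext[1], ext[2])
    sy <- runif(n_stem, ext[3], ext[4])
    hh <- runif(n_stem, spec$tree_height_range[1], spec$tree_height_range[2])
    zb <- .plane_z(spec, sx, sy) + spec$crown_base_frac * hh
    zt <- .plane_z(spec, sx, sy) + hh
    cl <- zt - zb
    br <- spec$crown_radius_frac * cl
    vol <- pi * br^2 * cl / 3
    nv <- rpois(n_stem, spec$crown_point_density * vol)
    for (i in seq_len(n_stem)) {
      p <- .cone_points(nv[i], sx[i], sy[i], zb[i], zt[i], br[i])
      if (!is.null(p)) {
        pts[[length(pts) + 1]] <- p
        lab[[length(lab) + 1]] <- rep("vegetation", nrow(p))
      }
    }
  }
  m <- do.call(rbind, pts)
  label <- unlist(lab)

  # first-return assignment: highest return within each 0.5-m column
  colw <- 0.5
  ix <- floor((m[, 1] - ext[1]) / colw)
  iy <- floor((m[, 2] - ext[3]) / colw)
  key <- ix * (ceiling((ext[4] - ext[3]) / colw) + 1) + iy
  ord <- order(key, -m[, 3])
  first_of_col <- !duplicated(key[ord])
  rn <- integer(nrow(m))
  rn[ord] <- stats::ave(seq_along(ord), key[ord], FUN = seq_along)
  is_first <- logical(nrow(m))
  is_first[ord] <- first_of_col
  point_cloud(m[, 1], m[, 2], m[, 3], class_label = label,
              return_number = pmin(rn, 7L), is_first = is_first)
}

#' Specification of a synthetic plant community
#'
#' Species respond to a light gradient through Gaussian niches; their light
#' indicator values increase with the niche optimum.
#'
#' @param n_species Species pool size.
#' @param niche_breadth Gaussian niche breadth on the (0, 1] light gradient.
#' @param noise_sigma Lognormal abundance noise (sd on the log scale).
#' @param max_cover Percent cover of a species at its optimum.
#' @param detection_floor Percent cover below which a species is absent.
#' @param seed Integer seed.
#' @return A `community_spec` object.
#' @export
community_spec <- function(n_species = 30, niche_breadth = 0.15,
                           noise_sigma = 0.3, max_cover = 60,
                           detection_floor = 0.05, seed = 1L) {
  stopifnot(n_species >= 1, niche_breadth > 0, noise_sigma >= 0,
            max_cover > 0, max_cover <= 100)
  structure(list(n_species = n_species, niche_breadth = niche_breadth,
                 noise_sigma = noise_sigma, max_cover = max_cover,
                 detection_floor = detection_floor, seed = as.integer(seed)),
            class = "community_spec")
}

#' Generate a plot x species community along a light gradient
#'
#' Expected percent cover of species `s` in a plot with true light `l` is
#' `max_cover * exp(-(l - optimum_s)^2 / (2 * breadth^2))`, multiplied by
#' lognormal noise and truncated at the detection floor. Species optima are
#' evenly spread over the gradient and the light indicator value `L`
#' (1-5) increases with the optimum. Abundances are also quantized through
#' the Braun-Blanquet scale and back to midpoints, as field covers would be.
#'
#' @param spec A [community_spec()].
#' @param light Numeric vector of per-plot true light values in (0, 1].
#' @return A list with `abundance` (plot x species percent cover, exact),
#'   `abundance_bb` (midpoints after Braun-Blanquet quantization),
#'   `bb_class` (character matrix of classes), `L` (per-species indicator
#'   values), `optima`.
#' @export
generate_community <- function(spec, light) {
  stopifnot(all(light > 0 & light <= 1))
  set.seed(spec$seed)
  S <- spec$n_species
  optima <- (seq_len(S) - 0.5) / S
  L <- pmin(pmax(ceiling(optima * 5), 1), 5)
  n <- length(light)
  mu <- outer(light, optima, function(l, o)
    spec$max_cover * exp(-(l - o)^2 / (2 * spec$niche_breadth^2)))
  noise <- matrix(rlnorm(n * S, meanlog = -spec$noise_sigma^2 / 2,
                         sdlog = spec$noise_sigma), n, S)
  ab <- pmin(mu * noise, 100)
  ab[ab < spec$detection_floor] <- 0
  bb <- matrix(cover_to_braun_blanquet(ab), n, S)
  ab_bb <- matrix(0, n, S)
  pres <- !is.na(bb)
  ab_bb[pres] <- braun_blanquet_to_cover(bb[pres])
  rn <- paste0("plot", seq_len(n)); sn <- paste0("sp", seq_len(S))
  dimnames(ab) <- dimnames(ab_bb) <- dimnames(bb) <- list(rn, sn)
  list(abundance = ab, abundance_bb = ab_bb, bb_class = bb,
       L = L, optima = optima)
}

#' Generate covariate tables for the three predictor groups
#'
#' Emulates the explanatory data of a variation-partitioning analysis: the
#' light group holds noisy measurements of the true per-plot light (log and
#' linear scale), the climate group holds two macroclimate covariates that
#' can be correlated with light at a chosen level, and the soil group holds
#' three independent topography/soil covariates.
#'
#' @param light Per-plot true light values in (0, 1].
#' @param r_climate Correlation between the climate covariates and the light
#'   gradient (0 = independent).
#' @param measurement_noise Standard deviation of the noise added to the
#'   light measurements.
#' @param seed Integer seed.
#' @return A list of data frames `light`, `climate`, `soil`.
#' @export
generate_covariates <- function(light, r_climate = 0,
                                measurement_noise = 0.05, seed = 1L) {
  stopifnot(r_climate >= -1, r_climate <= 1)
  set.seed(seed)
  n <- length(light)
  lz <- as.numeric(scale(light))
  mix <- function() r_climate * lz + sqrt(1 - r_climate^2) * rnorm(n)
  list(light = data.frame(log_light = log(light) + rnorm(n, 0, measurement_noise),
                          light_lin = light + rnorm(n, 0, measurement_noise)),
       climate = data.frame(degree_days = mix(), precip = mix()),
       soil = data.frame(twi = rnorm(n), tpi = rnorm(n), ph = rnorm(n)))
}
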