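#' Construct a classified point cloud
#'
#' A point cloud is a data frame of laser returns in a projected, metric
#' coordinate system, with a classification (`ground`, `vegetation`, `other`),
#' a return number and a first-return flag.
#'
#' @param x,y,z Numeric coordinate vectors in meters (projected CRS).
#' @param class_label Character or factor; one of `"ground"`, `"vegetation"`,
#'   `"other"` per return (recycled).
#' @param return_number Positive integer per return (recycled).
#' @param is_first Logical; defaults to `return_number == 1`.
#' @return A `point_cloud` (also a `data.frame`) with columns `x`, `y`, `z`,
#'   `class_label`, `return_number`, `is_first`.
#' @export
point_cloud <- function(x, y, z, class_label = "other",
                        return_number = 1L,
                        is_first = return_number == 1L) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length")
  if (n > 0 && !all(is.finite(x) & is.finite(y) & is.finite(z)))
    stop("coordinates must be finite")
  class_label <- rep_len(as.character(class_label), n)
  bad <- setdiff(unique(class_label), c("ground", "vegetation", "other"))
  if (length(bad))
    stop("unknown class_label(s): ", paste(bad, collapse = ", "))
  return_number <- rep_len(as.integer(return_number), n)
  if (n > 0 && any(return_number < 1L))
    stop("return_number must be positive")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   class_label = class_label,
                   return_number = return_number,
                   is_first = rep_len(as.logical(is_first), n))
  class(df) <- c("point_cloud", "data.frame")
  df
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d returns (%d ground, %d vegetation, %d other)\n",
              nrow(x), sum(x$class_label == "ground"),
              sum(x$class_label == "vegetation"),
              sum(x$class_label == "other")))
  if (nrow(x)) {
    cat(sprintf("  extent: x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
                min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  }
  invisible(x)
}

# ---- LAS 1.2 (point data record format 0) ------------------------------
# Minimal reader/writer for the standard ASPRS LAS exchange format.
# Classification dialect: 2 = ground; 3,4,5 = vegetation; everything else
# retained as "other".

.las_class_to_label <- function(code) {
  out <- rep("other", length(code))
  out[code == 2L] <- "ground"
  out[code %in% c(3L, 4L, 5L)] <- "vegetation"
  out
}

.label_to_las_class <- function(label) {
  out <- rep(1L, length(label))           # 1 = unclassified
  out[label == "ground"] <- 2L
  out[label == "vegetation"] <- 4L        # medium vegetation
  out
}

#' Write a point cloud to a LAS file
#'
#' Writes LAS 1.2, point data record format 0, with coordinates quantized at
#' `scale` (default 1 mm).
#'
#' @param cloud A [point_cloud()].
#' @param path Output file path (`.las`).
#' @param scale Coordinate quantization step in meters.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, scale = 0.001) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud)
  if (n == 0) stop("refusing to write an empty point cloud")
  off <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  X <- as.integer(round((cloud$x - off[1]) / scale))
  Y <- as.integer(round((cloud$y - off[2]) / scale))
  Z <- as.integer(round((cloud$z - off[3]) / scale))
  rn <- pmin(pmax(cloud$return_number, 1L), 7L)
  nret <- pmax(rn, ifelse(cloud$is_first & rn > 1L, rn, 1L))
  flags <- as.integer(bitwAnd(rn, 7L) + bitwShiftL(bitwAnd(nret, 7L), 3L))
  cls <- .label_to_las_class(cloud$class_label)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("LASF"), con)
  writeBin(rep(0L, 2), con, size = 2, endian = "little")   # source id, encoding
  writeBin(raw(16), con)                                   # GUID
  writeBin(c(1L, 2L), con, size = 1)                       # version 1.2
  sysid <- charToRaw("canopylight"); writeBin(c(sysid, raw(32 - length(sysid))), con)
  gen <- charToRaw("canopylight R package"); writeBin(c(gen, raw(32 - length(gen))), con)
  writeBin(c(1L, 2024L), con, size = 2, endian = "little") # day, year
  writeBin(227L, con, size = 2, endian = "little")         # header size
  writeBin(227L, con, size = 4, endian = "little")         # offset to points
  writeBin(0L, con, size = 4, endian = "little")           # number of VLRs
  writeBin(0L, con, size = 1)                              # point format 0
  writeBin(20L, con, size = 2, endian = "little")          # record length
  writeBin(n, con, size = 4, endian = "little")            # n points
  by_ret <- as.integer(tabulate(pmin(rn, 5L), nbins = 5))
  writeBin(by_ret, con, size = 4, endian = "little")
  writeBin(rep(scale, 3), con, size = 8, endian = "little")
  writeBin(off, con, size = 8, endian = "little")
  writeBin(c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
             max(cloud$z), min(cloud$z)), con, size = 8, endian = "little")

  rec <- matrix(as.raw(0), nrow = 20, ncol = n)
  rec[1:4, ]   <- matrix(writeBin(X, raw(), size = 4, endian = "little"), nrow = 4)
  rec[5:8, ]   <- matrix(writeBin(Y, raw(), size = 4, endian = "little"), nrow = 4)
  rec[9:12, ]  <- matrix(writeBin(Z, raw(), size = 4, endian = "little"), nrow = 4)
  # intensity (13:14) left zero
  rec[15, ] <- as.raw(flags)
  rec[16, ] <- as.raw(cls)
  # scan angle, user data (17:18) zero; point source id (19:20) zero
  writeBin(as.vector(rec), con)
  invisible(path)
}

.read_u16 <- function(raw, at) readBin(raw[at:(at + 1)], "integer", size = 2,
                                       endian = "little", signed = FALSE)
.read_u32 <- function(raw, at) readBin(raw[at:(at + 3)], "integer", size = 4,
                                       endian = "little")
.read_f64 <- function(raw, at, n = 1) readBin(raw[at:(at + 8 * n - 1)], "double",
                                              n = n, size = 8, endian = "little")

#' Read a classified point cloud from a LAS file
#'
#' Supports LAS 1.1-1.4 with point data record formats 0-5 (the leading 20
#' bytes common to those formats are parsed; extra attributes are skipped).
#' ASPRS class 2 maps to `ground`, classes 3/4/5 to `vegetation`, everything
#' else to `other`. Coordinates must be in metric units; files whose extents
#' and quantization look like geographic (degree) coordinates are refused.
#'
#' @param path Path to a `.las` file.
#' @param bounds Optional numeric `c(xmin, xmax, ymin, ymax)` rectangle;
#'   only points inside (inclusive) are returned.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, bounds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readBin(path, "raw", n = 375)
  if (length(hdr) < 227 || rawToChar(hdr[1:4]) != "LASF")
    stop("not a LAS file (missing LASF signature): ", path)
  pt_offset <- .read_u32(hdr, 97)
  pdrf <- as.integer(hdr[105]) %% 128L     # high bits flag LAZ compression
  if (as.integer(hdr[105]) >= 128L) stop("LAZ (compressed) input is not supported")
  if (pdrf > 5L) stop("unsupported point data record format: ", pdrf)
  reclen <- .read_u16(hdr, 106)
  if (reclen < 20L) stop("corrupt LAS header: record length ", reclen)
  npts <- .read_u32(hdr, 108)
  scale <- .read_f64(hdr, 132, 3)
  offset <- .read_f64(hdr, 156, 3)
  mm <- .read_f64(hdr, 180, 6)  # maxx minx maxy miny maxz minz
  if (all(scale[1:2] <= 1e-6) && abs(mm[1]) <= 360 && abs(mm[2]) <= 360 &&
      abs(mm[3]) <= 90 && abs(mm[4]) <= 90)
    stop("coordinates appear to be geographic (degrees); metric CRS required")
  if (npts <= 0) stop("LAS file contains no points: ", path)

  sz <- file.size(path)
  body <- readBin(path, "raw", n = sz)
  need <- pt_offset + as.numeric(npts) * reclen
  if (sz < need) stop("corrupt LAS file: truncated point data")
  rec <- matrix(body[(pt_offset + 1):(pt_offset + npts * reclen)],
                nrow = reclen)
  X <- readBin(as.vector(rec[1:4, ]), "integer", n = npts, size = 4,
               endian = "little")
  Y <- readBin(as.vector(rec[5:8, ]), "integer", n = npts, size = 4,
               endian = "little")
  Z <- readBin(as.vector(rec[9:12, ]), "integer", n = npts, size = 4,
               endian = "little")
  flags <- as.integer(rec[15, ])
  cls <- bitwAnd(as.integer(rec[16, ]), 31L)  # strip synthetic/keypoint bits
  x <- X * scale[1] + offset[1]
  y <- Y * scale[2] + offset[2]
  z <- Z * scale[3] + offset[3]
  rn <- pmax(bitwAnd(flags, 7L), 1L)
  keep <- rep(TRUE, npts)
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 4)
    keep <- x >= bounds[1] & x <= bounds[2] & y >= bounds[3] & y <= bounds[4]
    if (!any(keep)) stop("no points inside the requested bounds")
  }
  point_cloud(x[keep], y[keep], z[keep],
              class_label = .las_class_to_label(cls[keep]),
              return_number = rn[keep],
              is_first = rn[keep] == 1L)
}

# ---- Terrain rasters (ESRI ASCII grid) ---------------------------------

#' Construct a terrain grid
#'
#' A single-band elevation raster. Row 1 of the matrix is the northernmost
#' row (map orientation); `origin` is the lower-left corner of the grid.
#'
#' @param elevation Numeric matrix of cell elevations in meters; `NA` = nodata.
#' @param origin Numeric `c(x, y)` of the lower-left grid corner.
#' @param cell_size Cell size in meters (> 0).
#' @return A `terrain_grid` object.
#' @export
terrain_grid <- function(elevation, origin = c(0, 0), cell_size = 100) {
  stopifnot(is.matrix(elevation), cell_size > 0, length(origin) == 2)
  if (any(!is.finite(elevation) & !is.na(elevation)))
    stop("elevations must be finite or NA (nodata)")
  structure(list(elevation = elevation, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size)),
            class = "terrain_grid")
}

#' @export
print.terrain_grid <- function(x, ...) {
  cat(sprintf("<terrain_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(x$elevation), ncol(x$elevation), x$cell_size,
              x$origin[1], x$origin[2]))
  rng <- range(x$elevation, na.rm = TRUE)
  cat(sprintf("  elevation: [%.1f, %.1f] m, %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$elevation))))
  invisible(x)
}

#' Read a terrain grid from an ESRI ASCII grid file
#'
#' @param path Path to a `.asc` raster with a complete 6-line header
#'   (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#'   `NODATA_value`).
#' @return A [terrain_grid()]; nodata cells are `NA`.
#' @export
read_terrain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  kv <- lapply(strsplit(trimws(lines), "\\s+"), function(p) p)
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys) || any(!is.finite(vals[need])))
    stop("missing or malformed ASCII grid header (geotransform) in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  vv <- scan(path, skip = 6, quiet = TRUE)
  if (length(vv) != nc * nr)
    stop("ASCII grid body has ", length(vv), " values, expected ", nc * nr)
  m <- matrix(vv, nrow = nr, ncol = nc, byrow = TRUE)  # row 1 = north
  m[m == nodata] <- NA
  terrain_grid(m, origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
               cell_size = vals[["cellsize"]])
}

#' Write a terrain grid to an ESRI ASCII grid file
#'
#' @param grid A [terrain_grid()].
#' @param path Output path (`.asc`).
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_terrain <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "terrain_grid"))
  m <- grid$elevation
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(grid$origin[1], scientific = FALSE)),
           paste("yllcorner", format(grid$origin[2], scientific = FALSE)),
           paste("cellsize", format(grid$cell_size, scientific = FALSE)),
           paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bilinear elevation lookup on a terrain grid
#'
#' Interpolates between the four surrounding cell centers; queries within the
#' half-cell margin of the grid edge are clamped to the edge centers. Queries
#' outside the grid extent return `NA`.
#'
#' @param grid A [terrain_grid()].
#' @param x,y Query coordinates (vectors of equal length).
#' @return Numeric vector of elevations.
#' @export
terrain_elevation <- function(grid, x, y) {
  m <- grid$elevation
  nr <- nrow(m); nc <- ncol(m); cs <- grid$cell_size
  # continuous cell-center coordinates (1-based column/row-from-south index)
  u <- (x - grid$origin[1]) / cs + 0.5          # column index of center
  v <- (y - grid$origin[2]) / cs + 0.5          # row index from south
  inside <- x >= grid$origin[1] & x <= grid$origin[1] + nc * cs &
            y >= grid$origin[2] & y <= grid$origin[2] + nr * cs
  u <- pmin(pmax(u, 1), nc)
  v <- pmin(pmax(v, 1), nr)
  j0 <- pmin(pmax(floor(u), 1), nc - 1L); j1 <- j0 + 1L
  i0s <- pmin(pmax(floor(v), 1), nr - 1L); i1s <- i0s + 1L
  fu <- u - j0; fv <- v - i0s
  if (nc == 1L) { j0 <- j1 <- 1L; fu <- 0 }
  if (nr == 1L) { i0s <- i1s <- 1L; fv <- 0 }
  # convert south-based row index to matrix row (row 1 = north)
  r0 <- nr - i0s + 1L; r1 <- nr - i1s + 1L
  z00 <- m[cbind(r0, j0)]; z10 <- m[cbind(r0, j1)]
  z01 <- m[cbind(r1, j0)]; z11 <- m[cbind(r1, j1)]
  out <- (1 - fu) * (1 - fv) * z00 + fu * (1 - fv) * z10 +
         (1 - fu) * fv * z01 + fu * fv * z11
  out[!inside] <- NA_real_
  out
}

# ---- Height normalization ----------------------------------------------

.ground_surface <- function(cloud, qx, qy, k = 12L) {
  g <- cloud$class_label == "ground"
  if (sum(g) < 3)
    stop("height normalization needs at least 3 ground returns")
  gx <- cloud$x[g]; gy <- cloud$y[g]; gz <- cloud$z[g]
  # collinearity check on ground-return planimetric positions
  cc <- cbind(gx - mean(gx), gy - mean(gy))
  sv <- svd(cc, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("ground returns are collinear; cannot fit a ground surface")
  k <- min(k, length(gx))
  nn <- RANN::nn2(cbind(gx, gy), cbind(qx, qy), k = k)
  idx <- nn$nn.idx
  nx <- matrix(gx[idx], nrow(idx)); ny <- matrix(gy[idx], nrow(idx))
  nz <- matrix(gz[idx], nrow(idx))
  # least-squares plane through each query's neighborhood, coordinates
  # centered per neighborhood for numerical stability
  mx <- rowMeans(nx); my <- rowMeans(ny); mz <- rowMeans(nz)
  dx <- nx - mx; dy <- ny - my; dz <- nz - mz
  sxx <- rowSums(dx * dx); syy <- rowSums(dy * dy); sxy <- rowSums(dx * dy)
  sxz <- rowSums(dx * dz); syz <- rowSums(dy * dz)
  det <- sxx * syy - sxy^2
  ok <- det > 1e-9 * (sxx + syy + 1e-12)^2
  a <- ifelse(ok, (sxz * syy - syz * sxy) / det, 0)
  b <- ifelse(ok, (syz * sxx - sxz * sxy) / det, 0)
  res <- mz + a * (qx - mx) + b * (qy - my)
  # degenerate (collinear) neighborhood: nearest ground return's elevation
  res[!ok] <- nz[!ok, 1]
  # queries coinciding with a ground return take its elevation exactly
  exact <- nn$nn.dists[, 1] < 1e-9
  res[exact] <- nz[exact, 1]
  res
}

#' Interpolated ground elevation at arbitrary positions
#'
#' Moving-plane interpolation: a least-squares plane through the k = 12
#' nearest ground returns of each query position (exact at ground-return
#' positions and on planar ground).
#'
#' @param cloud A [point_cloud()] containing ground returns.
#' @param x,y Query coordinates.
#' @return Ground surface elevation (m) at each query position.
#' @export
ground_elevation <- function(cloud, x, y) {
  .ground_surface(cloud, x, y)
}

#' Normalize return heights above ground
#'
#' Computes `height_above_ground = z - ground surface` where the ground
#' surface is a moving plane fitted through the nearest ground returns of
#' each position (see [ground_elevation()]). Ground returns themselves come
#' out at height 0.
#'
#' @param cloud A [point_cloud()] with at least 3 non-collinear ground returns.
#' @return A `normalized_cloud`: the input plus a `height_above_ground`
#'   column.
#' @export
normalize_heights <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  zg <- .ground_surface(cloud, cloud$x, cloud$y)
  cloud$height_above_ground <- cloud$z - zg
  class(cloud) <- c("normalized_cloud", class(cloud))
  cloud
}
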