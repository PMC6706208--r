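test_that("spherical transform matches hand geometry", {
  cam <- flat_camera()
  # 10 m due North at eye height
  s <- to_spherical(point_cloud(0, 10, 1, "vegetation"), cam)
  expect_equal(s$r, 10)
  expect_equal(s$theta, 0)
  expect_equal(s$phi, 0)
  # directly overhead: phi defaults to 0 at the pole
  s2 <- to_spherical(point_cloud(0, 0, 6, "vegetation"), cam)
  expect_equal(s2$r, 5)
  expect_equal(s2$theta, pi / 2)
  expect_equal(s2$phi, 0)
  # 10 m East, 10 m up -> r = sqrt(200), theta = pi/4, phi = pi/2
  s3 <- to_spherical(point_cloud(10, 0, 11, "vegetation"), cam)
  expect_equal(s3$r, sqrt(200))
  expect_equal(s3$theta, pi / 4)
  expect_equal(s3$phi, pi / 2)
  # out-of-radius and zero-distance points are dropped
  s4 <- to_spherical(point_cloud(c(0, 0), c(150, 0), c(1, 1), "vegetation"),
                     cam, max_radius = 100)
  expect_equal(nrow(s4), 0)
  expect_error(to_spherical(point_cloud(numeric(0), numeric(0), numeric(0)),
                            cam), "empty")
})

test_that("marker size is linear in distance with the published anchors", {
  cfg <- render_config()
  expect_equal(marker_size(100, cfg), 0.5)   # farthest canopy element
  expect_equal(marker_size(0, cfg), 7)       # nearest canopy element
  expect_equal(marker_size(50, cfg), 3.75)   # linear midpoint
  expect_error(marker_size(101, cfg), "max_radius")
})

test_that("equiangular projection maps the reference directions", {
  side <- 1200
  expect_equal(project_equiangular(pi / 2, 0, side)[1, ],
               c(col = 600, row = 600))
  expect_equal(project_equiangular(0, 0, side)[1, ],
               c(col = 600, row = 0))
  expect_equal(project_equiangular(pi / 4, pi / 2, side)[1, ],
               c(col = 300, row = 600))
})

test_that("projection round trip recovers direction within half a pixel", {
  set.seed(21)
  side <- 1200
  n <- 10000
  theta <- runif(n, 0, pi / 2)
  phi <- runif(n, 0, 2 * pi)
  pc <- project_equiangular(theta, phi, side)
  back <- unproject_equiangular(pc[, 1], pc[, 2], side)
  # angular equivalent of half a pixel
  tol <- (pi / 2) / (side / 2) * 0.5
  expect_lt(max(abs(back$theta - theta)), tol)
  dphi <- pmin(abs(back$phi - phi), 2 * pi - abs(back$phi - phi))
  # azimuth error scaled by the radial distance from center
  expect_lt(max(dphi * (pi / 2 - theta)), tol * pi / 2)
})

test_that("terrain horizon: flat, single ridge, and summit cases", {
  spec <- stand_spec(slope_deg = 0)
  flat <- generate_terrain(spec, cell_size = 100, pad = 2000)
  cam <- flat_camera()
  h <- horizon_line(flat, cam)
  expect_length(h$elevation, 360)
  expect_true(all(h$elevation == 0))

  # 100-m ridge 1,000 m North: horizon ~ atan(0.1) = 5.71 deg in the North
  spec2 <- stand_spec(ridges = list(list(azimuth_deg = 0, distance = 1000,
                                         height = 100, width = 150)))
  ridge <- generate_terrain(spec2, cell_size = 100, pad = 2500)
  h2 <- horizon_line(ridge, cam)
  north <- h2$elevation[1] * 180 / pi
  south <- h2$elevation[181] * 180 / pi
  expect_equal(north, 5.71, tolerance = 0.3)
  expect_equal(south, 0)

  # camera on a summit: everything below eye level, all bins floored at 0
  summit <- terrain_grid(matrix(0, 40, 40), origin = c(-2000, -2000),
                         cell_size = 100)
  cam_high <- camera_position(0, 0, z_ground = 50, height_above_ground = 1)
  h3 <- horizon_line(summit, cam_high)
  expect_true(all(h3$elevation == 0))
  expect_error(horizon_line(flat, camera_position(1e6, 1e6)), "outside")
})

test_that("rendering an empty scene gives an empty image", {
  cl <- point_cloud(runif(100, -50, 50), runif(100, -50, 50), rep(0, 100),
                    class_label = "ground")
  img <- render_hemisphere(cl, flat_camera(), render_config(image_side_px = 400))
  expect_equal(sum(img$canopy), 0)
  expect_equal(sum(img$micro_terrain), 0)
  expect_equal(sum(img$macro_terrain), 0)
  expect_equal(canopy_closure(img), 0)
})

test_that("a single vegetation point stamps one disk of the predicted size", {
  # r = 10, theta = pi/4, phi = 0: diameter 6.35 px at (cx, cy - R/2)
  cam <- flat_camera()
  d <- 10 / sqrt(2)
  cl <- point_cloud(0, d, 1 + d, class_label = "vegetation")
  img <- render_hemisphere(cl, cam, render_config(image_side_px = 1200))
  npx <- sum(img$canopy)
  expect_gt(npx, pi / 4 * 6.35^2 * 0.8)
  expect_lt(npx, pi / 4 * 6.35^2 * 1.3)
  w <- which(img$canopy, arr.ind = TRUE)
  expect_equal(unname(colMeans(w)), c(300.5, 600.5), tolerance = 1e-6)
})

test_that("uphill ground returns appear as micro-terrain, vegetation below eye is ignored", {
  cam <- flat_camera()
  cl <- point_cloud(c(0, 0), c(20, -20), c(5, 0.2),
                    class_label = c("ground", "vegetation"))
  img <- render_hemisphere(cl, cam, render_config(image_side_px = 400))
  expect_gt(sum(img$micro_terrain), 0)   # ground above camera plots
  expect_equal(sum(img$canopy), 0)       # vegetation below eye level ignored
})

test_that("macro-terrain masking fills the annulus below a uniform 30-deg horizon", {
  spec <- stand_spec(slope_deg = 0)
  cl <- point_cloud(runif(200, -50, 50), runif(200, -50, 50), rep(0, 200),
                    class_label = "ground")
  horizon <- structure(list(azimuth = (0:359) * pi / 180,
                            elevation = rep(30 * pi / 180, 360), bins = 360),
                       class = "horizon_profile")
  img <- render_hemisphere(cl, flat_camera(), render_config(image_side_px = 1200),
                           horizon = horizon)
  expect_equal(canopy_closure(img), 0.5, tolerance = 0.005)
})

test_that("rotating the cloud by 90 degrees rotates the canopy channel", {
  cl <- random_veg_cloud(2000, seed = 22)
  cam <- flat_camera()
  cfg <- render_config(image_side_px = 1200)
  img <- render_hemisphere(cl, cam, cfg)
  # azimuth + 90 degrees: (x, y) -> (y, -x)
  cl_rot <- cl; cl_rot$x <- cl$y; cl_rot$y <- -cl$x
  img_rot <- render_hemisphere(cl_rot, cam, cfg)
  side <- cfg$image_side_px
  expected <- t(img$canopy)[seq(side, 1), ]   # image-space 90-deg rotation
  expect_gte(mean(img_rot$canopy == expected), 0.99)
})

test_that("adding vegetation returns only ever adds canopy pixels", {
  set.seed(23)
  cam <- flat_camera()
  cfg <- render_config(image_side_px = 400)
  base <- random_veg_cloud(400, seed = 24)
  extra <- random_veg_cloud(150, n_ground = 0, seed = 25)
  both <- point_cloud(c(base$x, extra$x), c(base$y, extra$y),
                      c(base$z, extra$z),
                      class_label = c(base$class_label, extra$class_label))
  img_a <- render_hemisphere(base, cam, cfg)
  img_b <- render_hemisphere(both, cam, cfg)
  expect_true(all(img_b$canopy[img_a$canopy]))
  expect_true(all(img_b$coverage >= img_a$coverage - 1e-12))
})

test_that("marker footprint shrinks with distance", {
  cam <- flat_camera()
  cfg <- render_config(image_side_px = 1200)
  mk <- function(r) {
    cl <- point_cloud(0, r / sqrt(2), 1 + r / sqrt(2), "vegetation")
    sum(render_hemisphere(cl, cam, cfg)$canopy)
  }
  expect_gt(mk(10), mk(90))
})

test_that("PNG export writes a decodable image", {
  cl <- random_veg_cloud(200, seed = 26)
  img <- render_hemisphere(cl, flat_camera(), render_config(image_side_px = 200))
  path <- withr::local_tempfile(fileext = ".png")
  write_hemi_png(img, path)
  arr <- png::readPNG(path)
  expect_equal(dim(arr)[1:2], c(200, 200))
})
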