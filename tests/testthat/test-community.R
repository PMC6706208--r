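test_that("Braun-Blanquet conversion uses the midpoint table both ways", {
  expect_equal(braun_blanquet_to_cover("3"), 37.5)
  expect_equal(braun_blanquet_to_cover("r"), 0.1)
  expect_equal(braun_blanquet_to_cover(c("+", "2a", "2b", "5")),
               c(0.5, 10, 20.5, 87.5))
  expect_error(braun_blanquet_to_cover("6"), "unknown")
  expect_equal(cover_to_braun_blanquet(c(0.1, 37.5, 87.5)),
               c("r", "3", "5"))
  expect_true(is.na(cover_to_braun_blanquet(0)))
  # midpoints are fixed points of the quantization
  mids <- braun_blanquet_to_cover(c("r", "+", "1", "2a", "2b", "3", "4", "5"))
  expect_equal(braun_blanquet_to_cover(cover_to_braun_blanquet(mids)), mids)
})

test_that("weighted indicator mean excludes species without values", {
  expect_equal(weighted_indicator_mean(10, 3), 3)
  expect_equal(weighted_indicator_mean(c(5, 5), c(2, 4)), 3)
  expect_equal(weighted_indicator_mean(c(75, 25), c(2, 4)), 2.5)
  expect_equal(weighted_indicator_mean(c(75, 25, 40), c(2, 4, NA)), 2.5)
  expect_error(weighted_indicator_mean(c(0, 10), c(3, NA)), "no species")
})

test_that("proxy regression recovers exact, null and known-noise relations", {
  x <- seq(-2, 2, length.out = 43)
  fit <- suppressWarnings(proxy_regression(2 * x + 1, x))  # perfect fit
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  set.seed(51)
  fit0 <- proxy_regression(rnorm(400), rnorm(400))
  expect_lt(fit0$r_squared, 0.05)
  # y = 2x + N(0, 1), x ~ N(0, 1): population R2 = 4 / (4 + 1) = 0.8
  set.seed(52)
  xs <- rnorm(43); ys <- 2 * xs + rnorm(43)
  fit2 <- proxy_regression(ys, xs)
  expect_equal(fit2$r_squared, 0.8, tolerance = 0.1)
  expect_error(proxy_regression(rnorm(10), rep(1, 10)), "constant")
})

test_that("Simpson dissimilarity has its defining values", {
  m <- rbind(p1 = c(1, 1, 1, 0), p2 = c(1, 1, 1, 0))
  expect_equal(simpson_dissimilarity(m)["p1", "p2"], 0)   # identical
  m2 <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(simpson_dissimilarity(m2)["a", "b"], 1)    # disjoint
  m3 <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1))       # a=2, b=c=1
  expect_equal(simpson_dissimilarity(m3)["a", "b"], 1 / 3)
  m4 <- rbind(a = c(1, 1, 0), b = c(1, 1, 1))             # nested
  expect_equal(simpson_dissimilarity(m4)["a", "b"], 0)
  expect_error(simpson_dissimilarity(m[1, , drop = FALSE]), "2 plots")
})

test_that("Simpson dissimilarity is symmetric, bounded, label-invariant and matches vegan", {
  set.seed(53)
  for (rep in 1:5) {
    m <- matrix(rbinom(20 * 15, 1, 0.4), 20, 15)
    m[rowSums(m) == 0, 1] <- 1       # avoid empty plots for the vegan check
    d <- simpson_dissimilarity(m)
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(diag(d), rep(0, 20))
    perm <- sample(ncol(m))
    expect_equal(simpson_dissimilarity(m[, perm]), d)
    ref <- as.matrix(vegan::betadiver(m, "sim"))
    dimnames(ref) <- NULL
    expect_equal(unname(d), ref, tolerance = 1e-12)
  }
})

test_that("db-RDA explains its own principal coordinates completely", {
  set.seed(54)
  pts <- matrix(rnorm(7 * 3), 7)
  D <- as.matrix(dist(pts))
  ax <- cmdscale(D, k = 3, eig = TRUE)   # 7 points in 3-D: rank 3
  keep <- ax$eig[1:3] > 1e-8 * max(ax$eig)
  X <- as.data.frame(ax$points[, which(keep), drop = FALSE])
  res <- db_rda(D, X)
  expect_equal(res$r_squared, 1, tolerance = 1e-8)
})

test_that("db-RDA matches a from-scratch PCoA + least-squares oracle", {
  set.seed(55)
  comm <- matrix(rbinom(25 * 18, 1, 0.4), 25, 18)
  comm[rowSums(comm) == 0, 1] <- 1
  D <- simpson_dissimilarity(comm)
  X <- data.frame(u = rnorm(25), v = rnorm(25))
  res <- db_rda(D, X)
  # oracle: Gower-centered -D^2/2, eigen-decomposition, project positive
  # axes on the covariates
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G)); G <- sweep(G, 2, colMeans(G)); G <- G + mean(-0.5 * D^2)
  ee <- eigen(G, symmetric = TRUE)
  pos <- ee$values > 1e-8 * max(ee$values)
  Y <- ee$vectors[, pos] %*% diag(sqrt(ee$values[pos]))
  fit <- lm(Y ~ u + v, data = X)
  r2_oracle <- sum(fitted(fit)^2) / sum(Y^2)
  expect_equal(res$r_squared, r2_oracle, tolerance = 1e-6)
})

test_that("db-RDA is null-calibrated and invariant to covariate rescaling", {
  set.seed(56)
  adj <- replicate(100, {
    pts <- matrix(rnorm(100 * 2), 100)
    D <- as.matrix(dist(pts))
    db_rda(D, data.frame(x = rnorm(100)))$adj_r_squared
  })
  expect_lte(abs(mean(adj)), 0.03)
  # affine rescaling of a covariate column leaves R2 unchanged
  pts <- matrix(rnorm(30 * 2), 30)
  D <- as.matrix(dist(pts))
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  r1 <- db_rda(D, X)$r_squared
  X2 <- data.frame(a = 100 * X$a - 7, b = X$b / 3 + 2)
  expect_equal(db_rda(D, X2)$r_squared, r1, tolerance = 1e-10)
})

test_that("db-RDA separates a two-cluster dissimilarity structure", {
  n <- 20
  D <- matrix(0.9, n, n)
  cluster <- rep(c(0, 1), each = n / 2)
  D[outer(cluster, cluster, "==")] <- 0.1
  diag(D) <- 0
  res <- db_rda(D, data.frame(cl = cluster))
  expect_gt(res$r_squared, 0.8)
})

test_that("collinear covariates are dropped with a warning", {
  set.seed(57)
  pts <- matrix(rnorm(20 * 2), 20)
  D <- as.matrix(dist(pts))
  X <- data.frame(a = rnorm(20))
  X$b <- 2 * X$a
  expect_warning(res <- db_rda(D, X), "collinear")
  expect_equal(res$p, 1)
})

test_that("adjusted R-squared follows the Ezekiel formula", {
  expect_equal(adjusted_r2(1, 43, 2), 1)
  expect_equal(adjusted_r2(0, 43, 2), -0.05)
  expect_equal(adjusted_r2(0.37, 50, 0), 0.37)
  expect_error(adjusted_r2(0.5, 4, 3), "n > p")
})

test_that("variation partitioning satisfies its exact identities", {
  set.seed(58)
  light <- runif(43, 0.05, 0.95)
  com <- generate_community(community_spec(seed = 59), light)
  D <- simpson_dissimilarity(com$abundance_bb)
  cv <- generate_covariates(light, seed = 60)
  vp <- variation_partition(D, cv$light, cv$climate, cv$soil)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
  expect_true(all(vp$fractions_display[1:7] >= 0))
  expect_equal(vp$fractions[["residual"]], 1 - vp$adj_r2[["ABC"]])

  # duplicated group: no independent contribution remains on either copy
  vp2 <- suppressWarnings(
    variation_partition(D, cv$light, cv$light, cv$soil))
  expect_lt(abs(vp2$fractions[["light"]]), 1e-10)
  expect_lt(abs(vp2$fractions[["climate"]]), 1e-10)
  # the duplicated groups share (almost) their whole marginal effect
  expect_equal(vp2$fractions[["light_climate"]] +
                 vp2$fractions[["all_shared"]] +
                 vp2$fractions[["light_soil"]],
               vp2$adj_r2[["A"]], tolerance = 1e-10)
})

test_that("orthogonal predictor groups yield near-zero shared fractions", {
  set.seed(61)
  n <- 150
  base <- matrix(rnorm(n * 3), n)
  D <- as.matrix(dist(base))
  X1 <- data.frame(a = base[, 1] + rnorm(n, 0, 0.1))
  X2 <- data.frame(b = base[, 2] + rnorm(n, 0, 0.1))
  X3 <- data.frame(c = base[, 3] + rnorm(n, 0, 0.1))
  vp <- variation_partition(D, X1, X2, X3)
  shared <- vp$fractions[c("light_climate", "climate_soil", "light_soil",
                           "all_shared")]
  expect_true(all(abs(shared) <= 0.02))
  expect_equal(vp$fractions[["light"]], vp$adj_r2[["A"]], tolerance = 0.02)
  expect_equal(vp$fractions[["climate"]], vp$adj_r2[["B"]], tolerance = 0.02)
})

test_that("variation partitioning agrees with vegan::varpart on metric data", {
  # Euclidean-embeddable dissimilarities: no negative eigenvalues, so the
  # capscale-based route and vegan's dbrda-based varpart coincide
  set.seed(62)
  n <- 30
  pts <- matrix(rnorm(n * 2), n)
  D <- as.matrix(dist(pts))
  X1 <- data.frame(a1 = rnorm(n), a2 = rnorm(n))
  X2 <- data.frame(b1 = rnorm(n))
  X3 <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  vp <- variation_partition(D, X1, X2, X3)
  ref <- vegan::varpart(stats::as.dist(D), X1, X2, X3)
  ind <- ref$part$indfract$Adj.R.square
  expect_equal(unname(vp$fractions[c("light", "climate", "soil",
                                     "light_climate", "climate_soil",
                                     "light_soil", "all_shared",
                                     "residual")]),
               ind[1:8], tolerance = 1e-8)
})
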