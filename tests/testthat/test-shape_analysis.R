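test_that("centroid size matches hand computation and scales homogeneously", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(square), sqrt(2))
  set.seed(1)
  shp <- rand_config(25L)
  # independent two-pass oracle: centroid first, then deviations
  ctr <- colMeans(shp)
  oracle <- sqrt(sum((shp[, 1] - ctr[1])^2 + (shp[, 2] - ctr[2])^2))
  expect_equal(centroid_size(shp), oracle, tolerance = 1e-12)
  for (c_scale in c(0.3, 2, 117)) {
    expect_equal(centroid_size(shp * c_scale), c_scale * centroid_size(shp),
                 tolerance = 1e-12)
  }
  expect_error(centroid_size(matrix(1, 5L, 2L)), "degenerate")
})

test_that("alignment removes rotation, translation and scale", {
  set.seed(2)
  shp <- rand_config(10L)
  d <- landmark_dataset(list(shp,
                             transform_config(shp, angle = pi / 2,
                                              scale = 3, shift = c(5, -2))))
  fit <- gpa(d)
  expect_true(fit$converged)
  expect_lt(dist(fit$tangent)[1], 1e-10)
})

test_that("identical shapes are a fixed point of the alignment", {
  set.seed(3)
  shp <- rand_config(8L)
  d <- landmark_dataset(replicate(5L, shp, simplify = FALSE))
  fit <- gpa(d)
  norm_shape <- sweep(shp, 2L, colMeans(shp))
  norm_shape <- norm_shape / sqrt(sum(norm_shape^2))
  # consensus equals the normalized shape up to rotation; residuals vanish
  expect_lt(max(dist(fit$tangent)), 1e-10)
  expect_equal(sqrt(sum(matrix(fit$mean_shape, ncol = 2L)^2)), 1,
               tolerance = 1e-10)
  expect_equal(max(abs(colMeans(fit$tangent) - fit$mean_shape)), 0,
               tolerance = 1e-8)
  expect_error(gpa(landmark_dataset(list(shp))), "at least 2")
})

test_that("two-shape alignment matches an exhaustive rotation search", {
  set.seed(4)
  tri1 <- rand_config(3L)
  tri2 <- rand_config(3L)
  d <- landmark_dataset(list(tri1, tri2))
  fit <- gpa(d)
  aligned_dist <- sqrt(sum((fit$aligned[, , 1L] - fit$aligned[, , 2L])^2))
  # brute-force grid over rotation angle at 1e-4 rad resolution
  norm <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm(tri1); b <- norm(tri2)
  angles <- seq(0, 2 * pi, by = 1e-4)
  ca <- cos(angles); sa <- sin(angles)
  ss <- vapply(seq_along(angles), function(i) {
    R <- matrix(c(ca[i], sa[i], -sa[i], ca[i]), 2L, 2L)
    sum((a - b %*% R)^2)
  }, 0)
  expect_equal(aligned_dist, sqrt(min(ss)), tolerance = 1e-6)
})

test_that("Procrustes distances are invariant to input similarity transforms", {
  set.seed(5)
  for (rep in 1:5) {
    d <- make_noisy_dataset(n = 8L, k = 12L, noise = 0.1)
    ref <- as.vector(procrustes_distances(gpa(d)))
    coords2 <- d$coords
    idx <- sample(8L, 4L)
    for (i in idx)
      coords2[, , i] <- transform_config(coords2[, , i],
                                         angle = runif(1, 0, 2 * pi),
                                         scale = runif(1, 0.2, 5),
                                         shift = runif(2, -10, 10))
    d2 <- landmark_dataset(coords2, specimen_ids = d$specimen_ids)
    expect_lt(max(abs(as.vector(procrustes_distances(gpa(d2))) - ref)), 1e-8)
  }
})

test_that("relative warps capture rank-1 variation on a single axis", {
  set.seed(6)
  d <- make_noisy_dataset(n = 20L, k = 10L, noise = 1e-9)
  fit <- gpa(d)
  # overwrite tangent coords with exact rank-1 structure
  dir <- rnorm(ncol(fit$tangent))
  dir <- dir - mean(dir)
  fit$tangent <- outer(seq(-1, 1, length.out = 20L), dir) +
    matrix(fit$mean_shape, 20L, length(fit$mean_shape), byrow = TRUE)
  rownames(fit$tangent) <- fit$specimen_ids
  sp <- relative_warps(fit)
  expect_equal(sp$variance_fraction[[1L]], 1, tolerance = 1e-10)
})

test_that("variance decomposes completely and scores preserve geometry", {
  set.seed(7)
  d <- make_noisy_dataset(n = 15L, k = 9L, noise = 0.08)
  fit <- gpa(d)
  sp <- relative_warps(fit)
  expect_equal(sum(sp$variance_fraction), 1, tolerance = 1e-10)
  expect_true(all(sp$variance_fraction >= 0))
  # axes orthonormal, score columns centered
  expect_equal(crossprod(sp$axes), diag(ncol(sp$axes)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(sp$scores))), 1e-12)
  # full-rank reconstruction of the centered tangent coordinates
  rec <- sp$scores %*% t(sp$axes)
  ctr <- sweep(fit$tangent, 2L, sp$center)
  expect_lt(max(abs(rec - ctr)), 1e-10)
  # pairwise tangent distances reproduced by the scores
  expect_equal(as.vector(dist(sp$scores)), as.vector(dist(fit$tangent)),
               tolerance = 1e-10)
  expect_error(relative_warps(structure(list(tangent = fit$tangent[1:2, ]),
                                        class = "gpa_fit")), "at least 3")
})

test_that("allometry residuals behave at the zero-slope and perfect-fit poles", {
  set.seed(8)
  n <- 60L
  cs <- runif(n, 100, 400)
  raw <- matrix(rnorm(n * 3L), n, 3L)
  # orthogonalize scores against size and the constant
  ortho <- apply(raw, 2L, function(y) residuals(lm(y ~ cs)))
  sp <- structure(list(scores = ortho, specimen_ids = as.character(1:n),
                       groups = NULL), class = "shape_space")
  colnames(sp$scores) <- paste0("RW", 1:3)
  corr <- allometry_residuals(sp, cs)
  expect_equal(corr$residuals, sweep(ortho, 2L, colMeans(ortho)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(corr$r_squared), 1e-20)

  sp$scores <- cbind(RW1 = 0.2 * cs, RW2 = -3 * cs)
  corr2 <- allometry_residuals(sp, cs)
  expect_lt(max(abs(corr2$residuals)), 1e-9)
  expect_equal(unname(corr2$r_squared), c(1, 1), tolerance = 1e-10)

  expect_error(allometry_residuals(sp, rep(5, n)), "all equal")
})

test_that("an allometric slope of 0.3 is recovered from noisy scores", {
  set.seed(9)
  n <- 150L
  cs <- rnorm(n, 10, 2)
  sp <- structure(list(scores = cbind(RW1 = 0.3 * cs + rnorm(n, 0, 0.1)),
                       specimen_ids = as.character(1:n), groups = NULL),
                  class = "shape_space")
  corr <- allometry_residuals(sp, cs)
  expect_lt(abs(corr$slopes[["RW1"]] - 0.3), 0.05)
  # residuals orthogonal to size
  expect_lt(abs(cor(corr$residuals[, 1L], cs)), 1e-10)
})
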