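# Geometry: segmentation, 3D morphology from a 2D slice, centrosome.

test_that("segment_field returns one region per nucleus, nuclei contained", {
  d <- c(120L, 60L)
  tub <- matrix(0, d[1], d[2])
  nuc <- matrix(0, d[1], d[2])
  tub[disk_mask(d, c(30, 30), 22)] <- 0.6
  tub[disk_mask(d, c(90, 30), 22)] <- 0.6
  nuc[disk_mask(d, c(30, 30), 8)] <- 1
  nuc[disk_mask(d, c(90, 30), 8)] <- 1
  segs <- segment_field(image2d(tub), image2d(nuc))
  expect_length(segs, 2L)
  for (s in segs)
    expect_true(all(s$cell$voxels[s$nucleus$voxels]))
  # regions pairwise disjoint
  expect_false(any(segs[[1]]$cell$voxels & segs[[2]]$cell$voxels))

  # single-object case
  one <- segment_field(image2d(tub * disk_mask(d, c(30, 30), 25)),
                       image2d(nuc * disk_mask(d, c(30, 30), 25)))
  expect_length(one, 1L)
  expect_true(all(one[[1]]$cell$voxels[one[[1]]$nucleus$voxels]))

  # no nuclei -> empty list plus warning
  expect_warning(empty <- segment_field(image2d(tub),
                                        image2d(matrix(0, d[1], d[2]))),
                 "no nuclei")
  expect_length(empty, 0L)
})

test_that("bottom_shape keeps the largest component and fills holes", {
  d <- c(64L, 64L)
  disk <- disk_mask(d, c(32, 32), 20)
  img <- matrix(0, d[1], d[2]); img[disk] <- 1
  expect_equal(bottom_shape(image2d(img))$voxels, disk)

  holey <- img
  holey[disk_mask(d, c(32, 32), 5)] <- 0
  expect_equal(bottom_shape(image2d(holey))$voxels, disk)

  two <- img
  two[disk_mask(d, c(8, 8), 4)] <- 1
  expect_equal(bottom_shape(image2d(two))$voxels, disk)

  expect_error(bottom_shape(image2d(matrix(0, 8, 8))), "empty cell")

  # idempotence on its own indicator image
  m1 <- bottom_shape(image2d(img))
  m2 <- bottom_shape(image2d(m1$voxels * 1))
  expect_equal(m1$voxels, m2$voxels)
})

test_that("area profile halves per micrometre of height", {
  expect_equal(area_profile(1000, 0), 1000)
  expect_equal(area_profile(1000, 1.0), 500)
  expect_equal(area_profile(1000, 2.0), 250)
  expect_error(area_profile(1000, -0.5), "nonnegative")
})

test_that("interpolate_shape hits target areas and is monotone", {
  d <- c(100L, 100L)
  bottom <- mask2d(disk_mask(d, c(50, 50), 40))
  top <- mask2d(disk_mask(d, c(50, 50), 10))
  expect_equal(interpolate_shape(bottom, top, mask_area(bottom))$voxels,
               bottom$voxels)
  expect_equal(interpolate_shape(bottom, top, mask_area(top))$voxels,
               top$voxels)
  target <- pi * 25^2
  mid <- interpolate_shape(bottom, top, target)
  expect_lt(abs(mask_area(mid) - target) / target, 0.01)
  expect_error(interpolate_shape(bottom, top, 1e6), "outside")

  # area monotone in the mixing weight on random blob pairs
  set.seed(11)
  for (i in 1:5) {
    big <- random_blob()
    small <- big & disk_mask(dim(big), dim(big) / 2, 12)
    sb <- mtubesim:::signed_distance(big)
    st <- mtubesim:::signed_distance(small)
    areas <- vapply(seq(0, 1, by = 0.1),
                    function(t) sum(((1 - t) * sb + t * st) < 0), 0)
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("build_volume slice count and area decay follow the model", {
  bottom <- mask2d(disk_mask(c(120L, 120L), c(60, 60), 50))
  vol <- build_volume(bottom, 1.6, 0.2, "cell")
  expect_identical(dim(vol$voxels)[3], 8L)

  one <- build_volume(bottom, 0.2, 0.2, "cell")
  expect_identical(dim(one$voxels)[3], 1L)
  expect_equal(one$voxels[, , 1], bottom$voxels)

  areas <- apply(vol$voxels, 3, sum)
  expect_true(all(diff(areas) <= 0))
  rel <- areas / mask_area(bottom)
  z <- (0:7) * 0.2
  expect_true(all(abs(rel - 2^(-z)) / 2^(-z) < 0.05))

  expect_error(build_volume(bottom, 0.5, 0.2), "multiple")
})

test_that("centrosome XY is the smoothed in-vicinity intensity argmax", {
  d <- c(100L, 100L)
  nuc <- mask2d(disk_mask(d, c(50, 50), 12))
  gx <- outer((seq_len(d[1]) - 68)^2, rep(1, d[2]))
  gy <- outer(rep(1, d[1]), (seq_len(d[2]) - 50)^2)
  spot <- exp(-(gx + gy) / (2 * 4^2))   # centre (68, 50), 1-based
  xy <- detect_centrosome_xy(image2d(spot), nuc)
  expect_lte(max(abs(xy - c(67, 49))), 1)  # 0-based

  # brighter spot far outside the vicinity loses
  far <- spot + 5 * exp(-((outer((seq_len(d[1]) - 5)^2, rep(1, d[2])) +
                            outer(rep(1, d[1]), (seq_len(d[2]) - 5)^2)) /
                           (2 * 3^2)))
  xy2 <- detect_centrosome_xy(image2d(far), nuc)
  expect_lte(max(abs(xy2 - c(67, 49))), 1)

  # uniform image: deterministic first-in-array-order tie-break
  u1 <- detect_centrosome_xy(image2d(matrix(1, d[1], d[2])), nuc)
  u2 <- detect_centrosome_xy(image2d(matrix(1, d[1], d[2])), nuc)
  expect_identical(u1, u2)
})

test_that("centrosome z regression predicts and clips; fallback is central", {
  img <- image2d(matrix(runif(400), 20, 20))
  expect_identical(estimate_centrosome_z(img, c(3, 3), NULL, 8L), 4L)
  m <- centrosome_z_model(c(2, 0, 0, 0))
  expect_identical(estimate_centrosome_z(img, c(3, 3), m, 8L), 2L)
  mbig <- centrosome_z_model(c(100, 0, 0, 0))
  expect_identical(estimate_centrosome_z(img, c(3, 3), mbig, 8L), 7L)

  # least squares on noiseless synthetic pairs recovers a planted relation
  set.seed(3)
  beta <- c(1.5, 0.8, -2.0, 0.5)
  preds <- t(replicate(30, {
    px <- matrix(runif(100, 0, 4), 10, 10)
    c(max(px), mean(px), px[4, 4])
  }))
  z <- beta[1] + preds %*% beta[2:4] + rnorm(30, sd = 1e-4)
  fit <- lm(z ~ preds)
  expect_gt(summary(fit)$r.squared, 0.99)
  mfit <- centrosome_z_model(coef(fit))
  expect_identical(mfit$coefficients, unname(coef(fit)))
})

test_that("assemble_geometry validates and relocates the centrosome", {
  d <- c(30L, 30L, 6L)
  cell <- array(FALSE, d); cell[5:26, 5:26, ] <- TRUE
  nuc <- array(FALSE, d); nuc[12:19, 12:19, ] <- TRUE
  g <- assemble_geometry(mask3d(cell), mask3d(nuc), c(6, 6, 2))
  expect_s3_class(g, "cell_geometry")
  expect_equal(g$height_um, 1.2)

  # centrosome inside the nucleus: relocated to nearest cytosolic voxel
  expect_message(g2 <- assemble_geometry(mask3d(cell), mask3d(nuc),
                                         c(15, 15, 2)),
                 "relocated")
  idx <- which(g2$cytosol, arr.ind = TRUE) - 1L
  d2 <- (idx[, 1] - 15)^2 + (idx[, 2] - 15)^2 + (idx[, 3] - 2)^2
  best <- min(d2)
  got <- sum((g2$centrosome - c(15, 15, 2))^2 *
               c(1, 1, 1))
  expect_equal(got, best)

  # nucleus not inside cell is an error
  nuc2 <- array(FALSE, d); nuc2[1:10, 1:10, ] <- TRUE
  expect_error(assemble_geometry(mask3d(cell), mask3d(nuc2), c(6, 6, 2)),
               "not contained")
})
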