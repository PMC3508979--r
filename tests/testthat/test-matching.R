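# Features and nearest-library matching.

test_that("feature vector is finite and handles degenerate images", {
  d <- c(60L, 60L)
  mask <- mask2d(disk_mask(d, c(30, 30), 25))
  const <- image2d(matrix(5, d[1], d[2]))
  f <- compute_features(const, mask, c(30, 30))
  expect_length(f, 35L)
  expect_named(f, feature_names())
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["grad_total"]), 0)
  expect_equal(unname(f["grad_mag_h1"]), 1)
  expect_true(all(f[paste0("grad_dir_h", 1:8)] == 0))
  expect_equal(unname(f["int_mean"]), 5)
})

test_that("a vertical step edge loads the two horizontal-gradient sectors", {
  d <- c(60L, 60L)
  mask <- mask2d(matrix(TRUE, d[1], d[2]))
  img <- matrix(0, d[1], d[2]); img[31:60, ] <- 1  # step along x
  f <- compute_features(image2d(img), mask, c(30, 30))
  hdir <- f[paste0("grad_dir_h", 1:8)]
  # gradient along +/- x: sectors containing 0 and 180 degrees
  expect_gt(unname(hdir[1] + hdir[5]), 0.99)
})

test_that("checkerboard exceeds constant in Haralick contrast, per a brute-force GLCM", {
  d <- c(32L, 32L)
  mask <- mask2d(matrix(TRUE, d[1], d[2]))
  board <- outer(1:d[1], 1:d[2], function(i, j) (i + j) %% 2)
  f_board <- compute_features(image2d(board), mask, c(16, 16))
  f_const <- compute_features(image2d(board * 0 + 1), mask, c(16, 16))
  expect_gt(f_board["har_contrast"], f_const["har_contrast"])

  # independent co-occurrence oracle: horizontal neighbours of a
  # checkerboard always differ by one quantization step, so the
  # contrast (expected squared level difference) is positive
  glcm_contrast <- function(m, levels = 2) {
    q <- m - min(m)
    q <- floor(q / max(q, 1) * (levels - 1))
    pairs <- cbind(as.vector(q[-nrow(q), ]), as.vector(q[-1, ]))
    mean((pairs[, 1] - pairs[, 2])^2)
  }
  expect_gt(glcm_contrast(board), 0)
  expect_equal(glcm_contrast(board * 0 + 1), 0)
})

test_that("normalized distance matches explicit z-scoring", {
  ns <- list(mean = c(a = 0, b = 0), sd = c(a = 2, b = 1))
  x <- c(a = 1, b = 3); y <- c(a = 5, b = 3)
  expect_equal(normalized_distance(x, x, ns), 0)
  expect_equal(normalized_distance(x, y, ns), 2)

  set.seed(31)
  nm <- paste0("f", 1:10)
  ns2 <- list(mean = setNames(rnorm(10), nm),
              sd = setNames(runif(10, 0.5, 3), nm))
  a <- setNames(rnorm(10), nm); b <- setNames(rnorm(10), nm)
  oracle <- sqrt(sum(((a - b) / ns2$sd)^2))
  expect_equal(normalized_distance(a, b, ns2), oracle)

  names(b)[3] <- "zz"
  expect_error(normalized_distance(a, b, ns2), "mismatched")
})

test_that("matching is an exact argmin with deterministic ties", {
  g <- small_cell_geometry()
  b <- fixture_bottom_shapes(small_cell_spec())
  grid <- parameter_grid(c(10L, 40L), c(2, 4), 0.97, 1.6)
  lib <- build_library(b$cell, b$nucleus, grid, base_seed = 100L)
  expect_identical(nrow(lib$entries), 4L)
  expect_true(all(is.finite(lib$features)))

  # self-match: every entry recovers itself at distance exactly 0
  for (i in seq_len(nrow(lib$entries))) {
    m <- match_library(lib$features[i, ], lib)
    expect_identical(m$entry_id, lib$entries$entry_id[i])
    expect_identical(m$distance, 0)
  }

  # tiny perturbation keeps the match
  q <- lib$features[2, ]
  keep <- lib$norm_stats$sd > 0
  q[keep] <- q[keep] + 1e-6 * lib$norm_stats$sd[keep]
  expect_identical(match_library(q, lib)$entry_id, lib$entries$entry_id[2])

  # equals a brute-force linear scan
  set.seed(32)
  q2 <- lib$features[3, ] * (1 + 0.05 * rnorm(35))
  dists <- vapply(seq_len(nrow(lib$entries)), function(i)
    normalized_distance(q2, lib$features[i, ], lib$norm_stats), 0)
  m2 <- match_library(q2, lib)
  expect_identical(m2$entry_id, lib$entries$entry_id[which.min(dists)])
  expect_equal(m2$distance, min(dists))

  empty <- lib; empty$entries <- lib$entries[0, ]
  expect_error(match_library(q2, empty), "empty library")
})

test_that("libraries are deterministic under a fixed seed and round-trip to disk", {
  b <- fixture_bottom_shapes(small_cell_spec())
  grid <- parameter_grid(c(10L, 40L), c(2, 4), 0.97, 1.6)
  lib1 <- build_library(b$cell, b$nucleus, grid, base_seed = 100L)
  lib2 <- build_library(b$cell, b$nucleus, grid, base_seed = 100L)
  expect_identical(lib1$features, lib2$features)

  dir <- withr::local_tempdir()
  save_library(lib1, dir)
  back <- load_library(dir)
  expect_equal(back$entries$n, lib1$entries$n)
  expect_equal(back$features, lib1$features)
  expect_equal(back$norm_stats$sd, lib1$norm_stats$sd)
  expect_identical(nrow(read.csv(file.path(dir, "features.csv"))),
                   nrow(lib1$entries))

  file.remove(file.path(dir, "images", "entry_0001.tif"))
  expect_error(load_library(dir), "missing library image")

  # schema version mismatch is detected
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  idx$schema_version <- 99
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_library(dir), "schema version")
})

test_that("estimate_cell runs the full pipeline on a synthetic field", {
  # build a realistic single-cell field from the generative model itself
  spec <- small_cell_spec()
  g <- make_geometry(spec)
  set.seed(41)
  mts <- generate_distribution(g, growth_params(40, 4, 0.97))
  vol <- apply_optics(render(mts, g), make_psf(), 20, pad = TRUE,
                      quantize_8bit = TRUE)
  tub <- central_slice(vol)
  nucmask <- central_slice(g$nucleus)
  nuc <- image2d(nucmask$voxels * 200)
  grid <- parameter_grid(c(10L, 40L), c(2, 4), 0.97, 1.6)
  res <- estimate_cell(tub, nuc, grid, base_seed = 7L)
  expect_s3_class(res, "match_result")
  expect_true(res$n %in% grid$n_values)
  expect_true(res$mu_um %in% grid$mu_values)
  res2 <- estimate_cell(tub, nuc, grid, base_seed = 7L)
  expect_identical(res$entry_id, res2$entry_id)
  expect_identical(res$distance, res2$distance)

  # blank nuclei channel: the geometry stage fails
  blank <- image2d(matrix(0, nrow(tub$pixels), ncol(tub$pixels)))
  expect_warning(expect_error(estimate_cell(tub, blank, grid), "no cells"))
})
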