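# Shared fixtures, built in code.  Expensive geometries are memoised
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# large open geometry: growth is effectively unconstrained
open_geometry <- function() {
  cached("open_geometry", {
    d <- c(120L, 120L, 120L)
    cell <- array(TRUE, d)
    nuc <- array(FALSE, d)
    nuc[1:2, 1:2, 1:2] <- TRUE
    suppressMessages(
      assemble_geometry(mask3d(cell), mask3d(nuc), c(60, 60, 60)))
  })
}

# small realistic cell (16 x 12 um footprint, 8 slices): fast to grow in
small_cell_spec <- function()
  fixture_spec(cell_semiaxes_um = c(8, 6), nucleus_semiaxes_um = c(3, 2.5),
               nucleus_offset_um = c(1.5, 0), height_um = 1.6)

small_cell_geometry <- function() {
  cached("small_cell_geometry", make_geometry(small_cell_spec()))
}

disk_mask <- function(dims, centre, r) {
  gx <- seq_len(dims[1]) - centre[1]
  gy <- seq_len(dims[2]) - centre[2]
  outer(gx^2, rep(1, dims[2])) + outer(rep(1, dims[1]), gy^2) <= r^2
}

# a blobby random mask: union of a few disks (always connected)
random_blob <- function(dims = c(80L, 80L), n_disks = 4L) {
  m <- disk_mask(dims, dims / 2, 18)
  for (i in seq_len(n_disks)) {
    c0 <- dims / 2 + round(runif(2, -10, 10))
    m <- m | disk_mask(dims, c0, round(runif(1, 6, 14)))
  }
  m
}

# straight microtubule along +x starting at a voxel centre, in um
straight_mt <- function(start_voxel, n_steps, step_um = 0.2) {
  p0 <- (start_voxel + 0.5) * step_um
  pts <- cbind(p0[1] + (0:n_steps) * step_um, p0[2], p0[3])
  structure(list(points = pts, length_um = n_steps * step_um,
                 step_um = step_um), class = "microtubule")
}
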