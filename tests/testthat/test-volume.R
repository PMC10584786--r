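test_that("zero-irregularity lesion is a digital ellipsoid with constant interior", {
  v <- gen_volume(-1, size = c(48, 48, 48), shape_irregularity = 0,
                  texture_heterogeneity = 0, seed = 1)
  expect_true(all(abs(v$image[v$tumor_mask] - v$image[v$tumor_mask][1]) < 1e-12))
  # ellipsoid: recover axes from the mask and compare occupancy exactly
  idx <- which(v$tumor_mask, arr.ind = TRUE)
  ctr <- (dim(v$tumor_mask) + 1) / 2
  # an ellipsoid mask must be symmetric under point reflection at center
  reflected <- sweep(-sweep(idx, 2, ctr), 2, -ctr)
  expect_true(all(v$tumor_mask[round(reflected)]))
})

test_that("same seed and parameters give bit-identical samples", {
  a <- gen_volume(1, seed = 11)
  b <- gen_volume(1, seed = 11)
  expect_identical(a, b)
  c <- gen_volume(1, seed = 12)
  expect_false(identical(a$tumor_mask, c$tumor_mask))
})

test_that("generation does not disturb the caller's RNG state", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(gen_volume(-1, seed = 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("volumes too small for lesion plus ring are rejected", {
  expect_error(gen_volume(1, size = c(32, 32, 32), seed = 1), "too small")
  expect_error(gen_volume(1, size = c(20, 40, 40), seed = 1), ">= 32")
})

test_that("metastasis-like lesions are more spherical and have higher run entropy", {
  n_draws <- 10
  stats_for <- function(label) {
    vapply(seq_len(n_draws), function(s) {
      v <- gen_volume(label, seed = 100 + s)
      lab <- discretize_fbn(v$image, v$tumor_mask, 32)
      c(sph = sphericity(v$tumor_mask, v$spacing),
        re = texture_stats(lab, v$tumor_mask, 32)$glrlm_run_entropy)
    }, numeric(2))
  }
  met <- stats_for(-1)
  gli <- stats_for(1)
  expect_gt(mean(met["sph", ]), mean(gli["sph", ]))
  expect_gt(mean(met["re", ]), mean(gli["re", ]))
})

test_that("ring of a single voxel at radius 1 is the unit ball shell", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  ring <- make_ring(m, radius = 1, spacing = c(1, 1, 1))
  # |ball(1)| = 7 lattice points; minus the center leaves the 6 neighbors
  expect_equal(sum(ring), 6)
  expect_false(ring[5, 5, 5])
})

test_that("ring around a cube is 5 voxels thick along the axes", {
  m <- array(FALSE, c(32, 32, 32)); m[14:19, 14:19, 14:19] <- TRUE
  ring <- make_ring(m, radius = 5, spacing = c(1, 1, 1))
  expect_true(all(ring[14, 14, 9:13]))   # 5 voxels below the face
  expect_false(ring[14, 14, 8])
  expect_false(any(ring & m))
})

test_that("ring geometry invariants hold for generated lesions", {
  v <- gen_volume(1, seed = 3)
  expect_false(any(v$tumor_mask & v$ring_mask))
  expect_gt(sum(v$ring_mask), 0)
  # every ring voxel is within 5 mm of some tumor voxel
  idx_r <- which(v$ring_mask, arr.ind = TRUE)
  idx_t <- which(v$tumor_mask, arr.ind = TRUE)
  pick <- idx_r[seq(1, nrow(idx_r), length.out = 25), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    d2 <- colSums((t(idx_t) - pick[i, ])^2)
    expect_lte(sqrt(min(d2)), 5 + 1e-9)
  }
  expect_error(make_ring(array(FALSE, c(5, 5, 5))), "empty")
})

test_that("anisotropic spacing uses per-axis voxel radii", {
  m <- array(FALSE, c(15, 15, 15)); m[8, 8, 8] <- TRUE
  ring <- make_ring(m, radius = 4, spacing = c(1, 1, 2))
  expect_true(ring[4, 8, 8])    # 4 voxels = 4 mm along x
  expect_true(ring[8, 8, 6])    # 2 voxels = 4 mm along z
  expect_false(ring[8, 8, 5])   # 3 voxels = 6 mm exceeds the radius
})

test_that("NIfTI round trip preserves image, masks and spacing", {
  v <- gen_volume(-1, seed = 2, spacing = c(1, 1, 1.5))
  tmp <- file.path(tempdir(), "vol_rt")
  write_volume_sample(v, tmp)
  r <- read_volume_sample(tmp, label = v$label)
  expect_equal(r$image, v$image, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(which(r$tumor_mask), which(v$tumor_mask))
  expect_equal(which(r$ring_mask), which(v$ring_mask))
  expect_equal(as.numeric(r$spacing), v$spacing, tolerance = 1e-6)
  unlink(paste0(tmp, "*"))
})
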