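# axis-aligned FIB correlation: view along y so the lamella plane is z = const
fib_corr_z <- function() make_correlation(rotation = rotmat(c(1, 0, 0), -90))

test_that("lamella_spec validates its geometry", {
  poly <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_s3_class(lamella_spec(poly, c(5, 5), c(0, 0), 300), "lamella_spec")
  expect_fibclem_error(lamella_spec(poly, c(20, 20), c(0, 0), 300), "param_error")
  expect_fibclem_error(lamella_spec(poly, c(5, 5), c(0, 0), -1), "param_error")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_fibclem_error(lamella_spec(bowtie, c(5, 5), c(0, 0), 300), "param_error")
})

test_that("axis-aligned lamella mask matches the counting oracle", {
  sem <- make_correlation()
  fib <- fib_corr_z()
  poly <- rbind(c(5, 5), c(25, 5), c(25, 25), c(5, 25))
  anchor_y <- as.numeric(fib$rotation[2, ] %*% c(0, 0, 10))
  sp <- lamella_spec(poly, c(15, 15), c(0, anchor_y), thickness = 210)
  m <- build_lamella_mask(sp, sem, fib, c(32, 32, 32), pixel_grid(100, 100, 100))
  # voxels with z in {9, 10, 11} (|z - 10| * 100 nm <= 105) and x, y in [5, 25]
  expect_equal(sum(m), 21 * 21 * 3)
  expect_equal(sum(m[, , 10:12]), sum(m))
})

test_that("mask membership equals the brute-force per-voxel oracle", {
  set.seed(21)
  sem <- make_correlation(rotation = rotmat(c(0.2, 0.1, 1), 14), scale = 1.1,
                          translation = c(1, -2, 0))
  fib <- make_correlation(rotation = rotmat(c(1, 0.1, 0), -75), scale = 0.9,
                          translation = c(0, 3, 0))
  poly <- rbind(c(2, 2), c(20, 4), c(22, 20), c(3, 18))
  sp <- lamella_spec(poly, c(12, 10), c(5, 8), thickness = 400)
  dims <- c(20, 22, 18)
  grid <- pixel_grid(110, 110, 340)
  m <- build_lamella_mask(sp, sem, fib, dims, grid)
  # brute force: scalar loop over every voxel
  a <- fib$scale * fib$rotation[2, ]
  grad <- a / c(110, 110, 340)
  norm_g <- sqrt(sum(grad^2))
  mismatch <- 0
  for (z in 0:(dims[3] - 1)) for (x in 0:(dims[2] - 1)) for (y in 0:(dims[1] - 1)) {
    p <- c(x, y, z)
    q <- sem$scale * (sem$rotation %*% p) + sem$translation
    inside <- fibclem:::point_in_polygon(q[1], q[2], poly)
    yf <- sum(a * p) + fib$translation[2]
    slab <- abs((yf - sp$fib_anchor[2]) / norm_g) <= 200 + 1e-9
    if ((inside && slab) != m[y + 1, x + 1, z + 1]) mismatch <- mismatch + 1
  }
  expect_equal(mismatch, 0)
})

test_that("a plane missing the prism yields an empty mask with a warning", {
  sem <- make_correlation()
  fib <- fib_corr_z()
  poly <- rbind(c(2, 2), c(12, 2), c(12, 12), c(2, 12))
  anchor_y <- as.numeric(fib$rotation[2, ] %*% c(0, 0, 500))
  sp <- lamella_spec(poly, c(7, 7), c(0, anchor_y), thickness = 100)
  expect_warning(
    m <- build_lamella_mask(sp, sem, fib, c(16, 16, 16), pixel_grid(100, 100, 100)),
    class = "fibclem_empty_mask")
  expect_equal(sum(m), 0)
})

test_that("a thick slab over the full field selects the whole prism", {
  sem <- make_correlation()
  fib <- fib_corr_z()
  poly <- rbind(c(-1, -1), c(16, -1), c(16, 16), c(-1, 16))
  anchor_y <- as.numeric(fib$rotation[2, ] %*% c(0, 0, 8))
  sp <- lamella_spec(poly, c(8, 8), c(0, anchor_y), thickness = 1e7)
  m <- build_lamella_mask(sp, sem, fib, c(16, 16, 16), pixel_grid(100, 100, 100))
  expect_true(all(m))
})

test_that("identity masked projection equals the brute-force z-maximum", {
  set.seed(22)
  vol <- array(runif(24 * 20 * 16), c(24, 20, 16))
  p <- masked_projection(vol, NULL, affine_identity(), c(24, 20))
  expect_equal(p, apply(vol, c(1, 2), max), tolerance = 1e-12)
})

test_that("a single bright voxel projects to its transformed position", {
  vol <- array(0, c(24, 24, 24))
  vol[13, 9, 5] <- 1  # (x, y, z) = (8, 12, 4)
  view <- compose_affine(affine_translate(c(3, -2, 0)),
                         affine_rotate(c(0, 0, 1), 90, center = c(11.5, 11.5, 0)))
  p <- masked_projection(vol, NULL, view, c(28, 28))
  tp <- apply_affine(view, points_tbl(8, 12, 4))
  pk <- which(p == max(p), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(c(pk[2] - 1, pk[1] - 1) - c(tp$x, tp$y))), 1)
})

test_that("projection is invariant to the patch partition and monotone in the mask", {
  set.seed(23)
  vol <- array(runif(30 * 30 * 20), c(30, 30, 20))
  view <- compose_affine(affine_rotate(c(1, 0, 0), 30, center = c(15, 15, 10)),
                         affine_scale(1.2))
  p_small <- masked_projection(vol, NULL, view, c(40, 40), patch_size = 32)
  p_large <- masked_projection(vol, NULL, view, c(40, 40), patch_size = 257)
  expect_identical(p_small, p_large)

  mask <- array(runif(30 * 30 * 20) > 0.5, c(30, 30, 20))
  p_masked <- masked_projection(vol, mask, view, c(40, 40))
  expect_true(all(p_masked <= p_small + 1e-12))
})

test_that("projection is equivariant to integer in-plane view translations", {
  set.seed(24)
  vol <- array(runif(20 * 20 * 12), c(20, 20, 12))
  base <- affine_rotate(c(0, 1, 0), 20, center = c(10, 10, 6))
  p0 <- masked_projection(vol, NULL, base, c(36, 36))
  shifted <- compose_affine(affine_translate(c(4, 3, 0)), base)
  p1 <- masked_projection(vol, NULL, shifted, c(36, 36))
  expect_equal(p1[(3 + 1):36, (4 + 1):36], p0[1:33, 1:32], tolerance = 1e-12)
})

test_that("masked projection rejects singular views", {
  vol <- array(0, c(8, 8, 8))
  bad <- affine3d(matrix(c(1, 0, 0, 0, 1, 0, 1, 0, 0), 3, 3))
  expect_fibclem_error(masked_projection(vol, NULL, bad, c(8, 8)),
                       "singular_transform")
})

test_that("virtual slice series scans heights and brightest member matches the blob", {
  sem <- make_correlation()
  fib <- fib_corr_z()
  grid <- pixel_grid(100, 100, 100)
  poly <- rbind(c(1, 1), c(30, 1), c(30, 30), c(1, 30))
  # blob on the plane z = 13; anchor corresponds to z = 10, so height +3
  # FIB pixels (at scale 1 and this view, 1 px height = 1 z-voxel)
  gen <- synth_flm_volume(tibble::tibble(x = 16, y = 16, z = 13),
                          psf_xyz = c(1.5, 1.5, 1), seed = 2,
                          vol_dim = c(32, 32, 24))
  anchor_y <- as.numeric(fib$rotation[2, ] %*% c(0, 0, 10))
  sp <- lamella_spec(poly, c(15, 15), c(0, anchor_y), thickness = 150)
  heights <- -5:5
  dyfib <- sign(as.numeric(fib$rotation[2, ] %*% c(0, 0, 1)))
  series <- virtual_slice_series(gen$volume, sp, sem, fib,
                                 heights = heights * dyfib, grid = grid,
                                 output_shape = c(32, 32),
                                 view = affine_identity())
  expect_length(series, 11)
  peak <- vapply(series, max, numeric(1))
  expect_equal(unname(which.max(peak)), which(heights == 3))
  # heights [0] reduces to the single build+project path
  single <- masked_projection(gen$volume,
                              build_lamella_mask(sp, sem, fib, dim(gen$volume), grid),
                              affine_identity(), c(32, 32))
  series0 <- virtual_slice_series(gen$volume, sp, sem, fib, 0, grid, c(32, 32),
                                  view = affine_identity())
  expect_identical(series0[[1]], single)
})
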