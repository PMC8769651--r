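test_that("decurtain removes planted vertical stripes and preserves structure", {
  g <- expand.grid(y = 0:255, x = 0:255)
  clean <- matrix(0.5 + 0.2 * exp(-((g$x - 120)^2 + (g$y - 100)^2) / (2 * 30^2)),
                  256, 256)
  gen <- synth_curtain(clean, period = 8, amplitude = 0.1, seed = 5)
  colvar <- function(m) var(colMeans(m))
  out <- decurtain(gen$image, postprocess_config(decurtain_sigma = 6))
  v_before <- colvar(gen$image); v_after <- colvar(out); v_clean <- colvar(clean)
  reduction <- 1 - (v_after - v_clean) / (v_before - v_clean)
  expect_gte(reduction, 0.9)
  expect_equal(dim(out), dim(gen$image))
  # stripe removal is zero-mean at DC
  expect_lt(abs(mean(out) - mean(gen$image)) / abs(mean(gen$image)), 0.001)
})

test_that("decurtain is the identity in the sigma-to-zero limit and on constants", {
  set.seed(41)
  m <- matrix(rnorm(96 * 80, 1, 0.3), 96, 80)
  out <- decurtain(m, postprocess_config(decurtain_sigma = 0))
  expect_lt(max(abs(out - m)), 1e-6)
  const <- matrix(0.7, 64, 64)
  expect_lt(max(abs(decurtain(const, postprocess_config()) - 0.7)), 1e-9)
  expect_fibclem_error(decurtain(matrix(0, 8, 8),
                                 postprocess_config(levels = 4)),
                       "image_too_small")
})

test_that("stripe suppression holds across generator seeds", {
  g <- expand.grid(y = 0:191, x = 0:191)
  clean <- matrix(0.5 + 0.15 * sin(g$y / 17) * cos(g$x / 23), 192, 192)
  colvar <- function(m) var(colMeans(m))
  for (seed in 1:10) {
    gen <- synth_curtain(clean, period = 8, amplitude = 0.1, seed = seed)
    out <- decurtain(gen$image, postprocess_config())
    red <- 1 - (colvar(out) - colvar(clean)) / (colvar(gen$image) - colvar(clean))
    expect_gte(red, 0.9)
  }
})

test_that("charging compensation attenuates a broad hill and keeps detail", {
  set.seed(42)
  texture <- matrix(runif(400 * 400, 0.3, 0.7), 400, 400)
  gen <- synth_charge(texture, sigma = 60, amplitude = 0.5)
  out <- remove_charging(gen$image, postprocess_config())
  # low-pass amplitude oracle: residual hill height over its far baseline
  lo <- lowpass(out, 60)
  base <- median(lo[c(1:40, 361:400), ])
  expect_lte(max(lo) - base, 0.2 * 0.5)
  # texture-only image passes through nearly unchanged (detail preserved)
  out_tex <- remove_charging(texture, postprocess_config())
  expect_gte(cor(as.numeric(out_tex), as.numeric(texture)), 0.95)
  # constant image maps to a constant (zero after the min shift)
  const_out <- remove_charging(matrix(0.4, 128, 128), postprocess_config())
  expect_lt(diff(range(const_out)), 1e-9)
})

test_that("CLAHE is shape-preserving, monotone per tile and expands flat ramps", {
  const <- matrix(0.5, 96, 96)
  expect_equal(enhance_local_contrast(const, postprocess_config()), const)
  # two-level step image: level ordering preserved
  step <- matrix(0.3, 96, 96); step[, 49:96] <- 0.6
  out <- enhance_local_contrast(step, postprocess_config(clahe_tile = 48))
  expect_true(mean(out[, 49:96]) > mean(out[, 1:48]))
  # low-contrast ramp gains dynamic range
  ramp <- matrix(rep(seq(0.45, 0.55, length.out = 96), each = 96), 96, 96)
  out_r <- enhance_local_contrast(ramp, postprocess_config(clahe_tile = 32))
  expect_gte(diff(range(out_r)), diff(range(ramp)))
})

test_that("phase correlation recovers integer shifts exactly and subpixel within 0.1 px", {
  base <- textured_slice(seed = 6)
  for (s in list(c(2, -1), c(-3, 4))) {
    mov <- shift_image(base, s[1], s[2], wrap = TRUE)
    est <- phase_correlate(base, mov)
    expect_equal(as.numeric(est), s, tolerance = 1e-9)
  }
  mov <- shift_image(base, 0.3, -0.7, wrap = TRUE)
  est <- phase_correlate(base, mov, upsample = 10)
  expect_lt(max(abs(est - c(0.3, -0.7))), 0.1 + 1e-9)
  expect_warning(z <- phase_correlate(matrix(0, 32, 32), matrix(0, 32, 32)),
                 class = "fibclem_zero_confidence")
  expect_equal(as.numeric(z), c(0, 0))
})

test_that("stack alignment recovers planted drifts", {
  base <- textured_slice(seed = 7)
  gen <- synth_drift_stack(base, c(2, -1), n_slices = 6, seed = 8)
  al <- align_stack(gen$stack)
  expect_equal(al$offsets$cum_dy, gen$truth$dy, tolerance = 1e-9)
  expect_equal(al$offsets$cum_dx, gen$truth$dx, tolerance = 1e-9)
  # aligned stack matches the first slice away from the exposed border
  expect_lt(max(abs(al$stack[20:76, 20:76, 6] - base[20:76, 20:76])), 1e-6)

  # identical slices: offsets all zero
  ident <- array(rep(base, 4), c(dim(base), 4))
  expect_true(all(align_stack(ident)$offsets[, c("dy", "dx")] == 0))

  # subpixel drift within 0.1 px/slice
  gen_sp <- synth_drift_stack(base, c(0.3, 0.2), n_slices = 5, seed = 9)
  al_sp <- align_stack(gen_sp$stack)
  expect_lt(max(abs(al_sp$offsets$dy[-1] - 0.3)), 0.1 + 1e-9)
  expect_lt(max(abs(al_sp$offsets$dx[-1] - 0.2)), 0.1 + 1e-9)
})

test_that("foreshortening correction stretches heights deterministically", {
  img <- matrix(runif(100 * 40), 100, 40)
  out90 <- correct_foreshortening(img, beam_geometry(89.99999))
  expect_equal(dim(out90), dim(img))
  img1000 <- matrix(runif(1000 * 20), 1000, 20)
  out52 <- correct_foreshortening(img1000, beam_geometry(52))
  expect_equal(nrow(out52), 1269)
  # a disk squashed by sin(52) becomes circular within 1% eccentricity
  th <- 52 * pi / 180
  g <- expand.grid(y = 0:199, x = 0:199)
  disk <- matrix(as.numeric(((g$x - 100)^2 / 40^2 +
                               (g$y - 100)^2 / (40 * sin(th))^2) <= 1), 200, 200)
  fixed <- correct_foreshortening(disk, beam_geometry(52))
  yr <- range(which(rowSums(fixed > 0.5) > 0))
  xr <- range(which(colSums(fixed > 0.5) > 0))
  ry <- diff(yr) / 2; rx <- diff(xr) / 2
  expect_lt(abs(ry - rx) / rx, 0.02)
})

test_that("the full pipeline restores a corrupted stack and is idempotent in alignment", {
  base <- textured_slice(dim = c(128, 128), seed = 10)
  cfg <- postprocess_config(levels = 3, charge_sigma = 20, clahe_tile = 64)
  corrupt <- array(0, c(128, 128, 4))
  clean <- array(0, c(128, 128, 4))
  for (i in 1:4) {
    sl <- shift_image(base, (i - 1) * 2, -(i - 1), wrap = TRUE)
    clean[, , i] <- sl
    cc <- synth_curtain(sl, period = 8, amplitude = 0.15, seed = i)$image
    corrupt[, , i] <- synth_charge(cc, sigma = 30, amplitude = 0.3)$image
  }
  grid <- pixel_grid(10, 10, 100)
  st <- slice_stack(corrupt, grid, beam_geometry(52))
  res <- postprocess_stack(st, cfg, stages = c("decurtain", "decharge"))
  al <- align_stack(res$stack, wrap = TRUE)
  expect_equal(res$log, c("decurtain", "decharge"))
  # restored slices are structurally close to the clean ground truth
  ref <- clean[, , 1]
  norm01 <- function(m) (m - min(m)) / diff(range(m))
  ssim_before <- ssim(norm01(corrupt[, , 4]), norm01(ref), L = 1)
  ssim_after <- ssim(norm01(al$stack$data[, , 4]), norm01(ref), L = 1)
  expect_gte(ssim_after, 0.8)
  expect_lte(ssim_before, 0.5)
  res <- c(res, list(offsets = al$offsets))
  res$stack <- al$stack
  # re-aligning the aligned stack finds essentially no residual drift
  re <- align_stack(res$stack)
  expect_lte(max(abs(as.matrix(re$offsets[, c("dy", "dx")]))), 0.1)
  # disabling every stage returns the input unchanged
  none <- postprocess_stack(st, cfg, stages = character(0))
  expect_identical(none$stack$data, st$data)
})

test_that("all operations preserve raster shape except the foreshortening stretch", {
  img <- matrix(runif(64 * 64, 0.2, 0.8), 64, 64)
  cfg <- postprocess_config(levels = 2, charge_sigma = 10, clahe_tile = 32)
  expect_equal(dim(decurtain(img, cfg)), dim(img))
  expect_equal(dim(remove_charging(img, cfg)), dim(img))
  expect_equal(dim(enhance_local_contrast(img, cfg)), dim(img))
  f <- foreshortening_factor(52)
  expect_equal(nrow(correct_foreshortening(img, beam_geometry(52))),
               round(64 * f))
})

test_that("multi-page TIFF stacks round-trip through disk", {
  set.seed(44)
  arr <- array(runif(16 * 16 * 3), c(16, 16, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(arr, path)
  back <- read_stack_tiff(path)
  expect_equal(back, arr, tolerance = 1e-6)
  img <- arr[, , 1]
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, p2)
  expect_equal(read_image_tiff(p2), img, tolerance = 1e-6)
})
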