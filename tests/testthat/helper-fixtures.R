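# Shared fixture builders. Everything is generated in code at test time.

# identity-like correlation objects for geometric toys
make_correlation <- function(rotation = diag(3), scale = 1,
                             translation = c(0, 0, 0)) {
  structure(list(rotation = rotation,
                 quaternion = fibclem:::quat_from_matrix(rotation),
                 scale = scale, translation = translation,
                 residuals = tibble::tibble(), rms = 0, n = 0),
            class = "clem_correlation")
}

rotmat <- function(axis, angle_deg) {
  fibclem:::rotation_matrix(axis / sqrt(sum(axis^2)), angle_deg * pi / 180)
}

# random invertible affine with bounded anisotropy/shear
random_affine <- function(scale_range = c(0.7, 1.5), shear = 0.2,
                          trans_scale = 50) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- rotmat(ax, runif(1, 0, 180))
  S <- diag(runif(3, scale_range[1], scale_range[2]))
  Sh <- diag(3); Sh[1, 2] <- runif(1, -shear, shear); Sh[2, 3] <- runif(1, -shear, shear)
  affine3d(R %*% S %*% Sh, rnorm(3, 0, trans_scale))
}

# disk image with known centers; amplitude 1, optional noise sd
disk_image <- function(centers_xy, radius, dim = c(120, 140), noise_sd = 0) {
  ny <- dim[1]; nx <- dim[2]
  g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1))
  img <- matrix(0, ny, nx)
  for (i in seq_len(nrow(centers_xy))) {
    d <- sqrt((g$x - centers_xy[i, 1])^2 + (g$y - centers_xy[i, 2])^2)
    img <- img + matrix(pmin(pmax(radius + 0.5 - d, 0), 1), ny, nx)
  }
  img <- pmin(img, 1)
  if (noise_sd > 0) img <- img + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
  img
}

# isotropic gaussian blob image
blob_image <- function(cx, cy, sigma = 2.5, dim = c(60, 60), offset = 0.1) {
  g <- expand.grid(y = 0:(dim[1] - 1), x = 0:(dim[2] - 1))
  matrix(offset + exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * sigma^2)),
         dim[1], dim[2])
}

# textured base slice for alignment tests: blobs plus fine grain so the
# content has broadband spectral power
textured_slice <- function(dim = c(96, 96), seed = 1) {
  fibclem:::with_seed(seed, {
    g <- expand.grid(y = 0:(dim[1] - 1), x = 0:(dim[2] - 1))
    img <- matrix(0.3, dim[1], dim[2])
    for (i in 1:15) {
      cx <- runif(1, 10, dim[2] - 10); cy <- runif(1, 10, dim[1] - 10)
      img <- img + matrix(0.5 * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * 9)),
                          dim[1], dim[2])
    }
    grain <- matrix(runif(prod(dim), -1, 1), dim[1], dim[2])
    k <- fibclem:::gaussian_kernel1d(1)
    img + 0.12 * fibclem:::convolve1d(fibclem:::convolve1d(grain, k, 1), k, 2)
  })
}

# structural similarity (Gaussian-windowed, standard constants) used as
# restoration oracle
ssim <- function(a, b, sigma = 1.5, L = NULL) {
  L <- L %||% max(diff(range(a)), diff(range(b)))
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  blur <- function(m) lowpass(m, sigma)
  mu_a <- blur(a); mu_b <- blur(b)
  va <- blur(a^2) - mu_a^2; vb <- blur(b^2) - mu_b^2
  cab <- blur(a * b) - mu_a * mu_b
  mean(((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
         ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# separable gaussian low-pass used as measurement filter in oracles
lowpass <- function(m, sigma) {
  k <- fibclem:::gaussian_kernel1d(sigma)
  fibclem:::convolve1d(fibclem:::convolve1d(m, k, 1), k, 2)
}

expect_fibclem_error <- function(expr, class) {
  expect_error(expr, class = paste0("fibclem_", class))
}
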