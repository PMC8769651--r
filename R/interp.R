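# Resampling cores shared by the projection, registration and stack modules.
# Images are matrices indexed [row = y + 1, col = x + 1]; volumes are arrays
# indexed [y + 1, x + 1, z + 1]. Query coordinates are 0-based pixel centers.

# Bilinear interpolation of img at (y, x) vectors; out-of-bounds -> fill.
interp2 <- function(img, y, x, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  val <- numeric(length(y))
  ok <- y >= -0.5 & y <= ny - 0.5 & x >= -0.5 & x <= nx - 0.5
  get <- function(yy, xx) {
    yy <- pmin(pmax(yy, 0), ny - 1); xx <- pmin(pmax(xx, 0), nx - 1)
    img[cbind(yy + 1, xx + 1)]
  }
  if (any(ok)) {
    y0k <- y0[ok]; x0k <- x0[ok]; fyk <- fy[ok]; fxk <- fx[ok]
    v00 <- get(y0k, x0k);     v01 <- get(y0k, x0k + 1)
    v10 <- get(y0k + 1, x0k); v11 <- get(y0k + 1, x0k + 1)
    val[ok] <- v00 * (1 - fyk) * (1 - fxk) + v01 * (1 - fyk) * fxk +
      v10 * fyk * (1 - fxk) + v11 * fyk * fxk
  }
  val[!ok] <- fill
  val
}

# Trilinear interpolation of vol at (y, x, z) vectors; out-of-bounds -> fill.
# Queries outside [0, n-1] in any axis return fill (no clamped extrapolation
# beyond half a voxel).
interp3 <- function(vol, y, x, z, fill = 0) {
  d <- dim(vol); ny <- d[1]; nx <- d[2]; nz <- d[3]
  val <- rep(fill, length(y))
  ok <- y >= 0 & y <= ny - 1 & x >= 0 & x <= nx - 1 & z >= 0 & z <= nz - 1
  if (!any(ok)) return(val)
  y <- y[ok]; x <- x[ok]; z <- z[ok]
  y0 <- floor(y); x0 <- floor(x); z0 <- floor(z)
  y0 <- pmin(y0, ny - 2); x0 <- pmin(x0, nx - 2); z0 <- pmin(z0, nz - 2)
  y0 <- pmax(y0, 0); x0 <- pmax(x0, 0); z0 <- pmax(z0, 0)
  fy <- y - y0; fx <- x - x0; fz <- z - z0
  idx <- function(dy, dx, dz) {
    (y0 + dy) + ny * (x0 + dx) + ny * nx * (z0 + dz) + 1
  }
  v <- vol[idx(0, 0, 0)] * (1 - fy) * (1 - fx) * (1 - fz) +
    vol[idx(1, 0, 0)] * fy * (1 - fx) * (1 - fz) +
    vol[idx(0, 1, 0)] * (1 - fy) * fx * (1 - fz) +
    vol[idx(1, 1, 0)] * fy * fx * (1 - fz) +
    vol[idx(0, 0, 1)] * (1 - fy) * (1 - fx) * fz +
    vol[idx(1, 0, 1)] * fy * (1 - fx) * fz +
    vol[idx(0, 1, 1)] * (1 - fy) * fx * fz +
    vol[idx(1, 1, 1)] * fy * fx * fz
  val[ok] <- v
  val
}

# Translate an image by (dy, dx) pixels (possibly subpixel); the content
# moves by +dy/+dx, i.e. out[y, x] = img[y - dy, x - dx]. With wrap = TRUE
# coordinates wrap periodically (a moving window over a statistically
# uniform larger field) instead of exposing a fill border.
shift_image <- function(img, dy, dx, fill = 0, wrap = FALSE) {
  ny <- nrow(img); nx <- ncol(img)
  g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1))
  ys <- g$y - dy; xs <- g$x - dx
  if (wrap) {
    # cyclic bilinear interpolation (seamless across the period)
    ys <- ys %% ny; xs <- xs %% nx
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    y0 <- y0 %% ny; x0 <- x0 %% nx
    y1 <- (y0 + 1) %% ny; x1 <- (x0 + 1) %% nx
    v <- img[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
      img[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
      img[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
      img[cbind(y1 + 1, x1 + 1)] * fy * fx
    return(matrix(v, ny, nx))
  }
  matrix(interp2(img, ys, xs, fill = fill), ny, nx)
}

# 1-D Gaussian kernel; sigma <= ~0 degenerates to a delta (identity blur).
gaussian_kernel1d <- function(sigma) {
  if (sigma < 1e-6) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 1-D convolution along rows (dim = 1 blurs along y) or columns
# (dim = 2 blurs along x), replicate-padded at the borders.
convolve1d <- function(m, kernel, dim = 1) {
  if (length(kernel) == 1L) return(m * kernel)
  r <- (length(kernel) - 1L) / 2L
  if (dim == 2) return(t(convolve1d(t(m), kernel, dim = 1)))
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(kernel)) {
    out <- out + kernel[i] * pad[i:(i + n - 1L), , drop = FALSE]
  }
  out
}
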