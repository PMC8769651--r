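# Fiducial detection and subpixel localization. Fluorescent microbeads
# (~1 um) are visible in fluorescence, SEM and FIB imaging and anchor all
# cross-modality transforms; lipid droplets and similar stained organelles
# serve the same role inside FIB-SEM volumes.

#' Bead detection parameters
#'
#' @param radius Expected bead radius in pixels.
#' @param radius_multiplier Scale applied to `radius` for the circle-Hough
#'   accumulator.
#' @param threshold_method One of `"otsu"`, `"mean"`, `"fixed"` for the soft
#'   mask threshold.
#' @param fixed_threshold Threshold value when `threshold_method = "fixed"`.
#' @param n_peaks Maximum number of detections returned.
#' @param min_separation Non-maximum-suppression radius in pixels
#'   (defaults to `radius`).
#' @param min_score Absolute floor on the combined score (the product of
#'   three maps each normalized to `[0, 1]`); suppresses numerical-noise
#'   peaks.
#' @return A list of class `bead_params`.
#' @export
bead_params <- function(radius, radius_multiplier = 1,
                        threshold_method = c("otsu", "mean", "fixed"),
                        fixed_threshold = 0.5, n_peaks = 10L,
                        min_separation = radius, min_score = 1e-6) {
  threshold_method <- match.arg(threshold_method)
  if (!is_scalar_number(radius) || radius < 1)
    stop_fibclem("param_error", "bead radius must be >= 1 pixel")
  if (n_peaks < 1) stop_fibclem("param_error", "n_peaks must be >= 1")
  structure(list(radius = radius, radius_multiplier = radius_multiplier,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 n_peaks = as.integer(n_peaks),
                 min_separation = min_separation, min_score = min_score),
            class = "bead_params")
}

# zero-padded linear filtering (odd-sized kernel)
filter2_zero <- function(img, kern) {
  ry <- (nrow(kern) - 1L) %/% 2L
  rx <- (ncol(kern) - 1L) %/% 2L
  pad <- matrix(0, nrow(img) + 2 * ry, ncol(img) + 2 * rx)
  pad[ry + seq_len(nrow(img)), rx + seq_len(ncol(img))] <- img
  out <- EBImage::filter2(pad, kern, boundary = 0)
  out[ry + seq_len(nrow(img)), rx + seq_len(ncol(img))]
}

gaussian_kernel2d <- function(sigma) {
  k <- gaussian_kernel1d(sigma)
  outer(k, k)
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, orientation-
# quantized non-maximum suppression, double-threshold hysteresis.
canny_edges <- function(image, sigma = 1, low_q = 0.7, high_q = 0.9) {
  sm <- convolve1d(convolve1d(image, gaussian_kernel1d(sigma), 1),
                   gaussian_kernel1d(sigma), 2)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
  # replicate-padded gradients: zero padding would fabricate border edges
  gy <- EBImage::filter2(sm, t(sx), boundary = "replicate")
  gx <- EBImage::filter2(sm, sx, boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) < 1e-12) return(matrix(FALSE, nrow(image), ncol(image)))
  ang <- atan2(gy, gx)  # quantize to 4 directions
  sector <- (round(ang / (pi / 4)) %% 4)
  ny <- nrow(mag); nx <- ncol(mag)
  shift_m <- function(m, dy, dx) {
    out <- matrix(0, ny, nx)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))  # (dy,dx) per sector
  nms <- matrix(FALSE, ny, nx)
  for (s in 0:3) {
    d <- dirs[[s + 1]]
    keep <- sector == s & mag >= shift_m(mag, d[1], d[2]) &
      mag >= shift_m(mag, -d[1], -d[2])
    nms <- nms | keep
  }
  mag_nms <- mag * nms
  pos <- mag_nms[mag_nms > 0]
  if (length(pos) == 0) return(matrix(FALSE, ny, nx))
  hi <- quantile(pos, high_q, names = FALSE)
  lo <- quantile(pos, low_q, names = FALSE)
  strong <- mag_nms >= hi
  weak <- mag_nms >= lo
  # hysteresis: grow strong into weak
  repeat {
    grown <- EBImage::dilate(strong * 1, EBImage::makeBrush(3, "box")) > 0 & weak
    if (identical(grown, strong)) break
    if (all(grown == strong)) break
    strong <- grown
  }
  strong
}

# ring kernel for circle-center accumulation
ring_kernel <- function(radius) {
  r <- ceiling(radius) + 1L
  n <- 2L * r + 1L
  g <- expand.grid(y = -r:r, x = -r:r)
  d <- sqrt(g$y^2 + g$x^2)
  k <- matrix(as.numeric(abs(d - radius) <= 0.5), n, n)
  if (sum(k) > 0) k / sum(k) else k
}

#' Per-pixel bead likelihood score maps
#'
#' Computes the three score maps whose product drives bead detection in SEM
#' images: normalized cross-correlation with a Gaussian kernel
#' (`sigma = radius`), a circle-Hough center accumulator built from Canny
#' edges over radii `radius * radius_multiplier * c(0.8 .. 1.2)` (5 steps,
#' max-pooled), and a soft mask obtained by thresholding, dilation with a
#' disk of the bead radius, and Gaussian blurring (`sigma = radius`).
#'
#' @param image Numeric image matrix (`[y, x]`).
#' @param params A [bead_params()] list.
#' @return A list with matrices `gauss_score`, `hough_score`, `soft_mask`,
#'   all the same shape as `image`.
#' @export
bead_score_maps <- function(image, params) {
  stopifnot(inherits(params, "bead_params"))
  r <- params$radius
  if (nrow(image) < 3 * r || ncol(image) < 3 * r)
    stop_fibclem("image_too_small",
                 sprintf("image must be at least 3*radius (= %g) in each dimension", 3 * r))
  storage.mode(image) <- "double"

  # (1) normalized cross-correlation with a Gaussian template
  K <- gaussian_kernel2d(r)
  K0 <- K - mean(K)
  W <- matrix(1, nrow(K), ncol(K))
  n <- sum(W)
  s1 <- filter2_zero(image, W)
  s2 <- filter2_zero(image^2, W)
  num <- filter2_zero(image, K0)
  den <- sqrt(sum(K0^2)) * sqrt(pmax(s2 - s1^2 / n, 0))
  gauss_score <- ifelse(den > 1e-12, num / den, 0)
  gauss_score <- pmin(pmax(gauss_score, -1), 1)

  # (2) Canny edges + circle-Hough accumulator, max-pooled over radii
  edges <- canny_edges(image, sigma = max(1, r / 3))
  hough <- matrix(0, nrow(image), ncol(image))
  if (any(edges)) {
    radii <- params$radius * params$radius_multiplier * seq(0.8, 1.2, length.out = 5)
    em <- edges * 1
    for (rr in radii) hough <- pmax(hough, filter2_zero(em, ring_kernel(rr)))
  }

  # (3) soft mask: threshold -> dilate -> blur
  rng <- range(image)
  img01 <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  thr <- switch(params$threshold_method,
    otsu = EBImage::otsu(EBImage::Image(img01)),
    mean = mean(img01),
    fixed = params$fixed_threshold
  )
  fg <- (img01 > thr) * 1
  if (any(fg > 0)) {
    fg <- EBImage::dilate(fg, EBImage::makeBrush(2L * ceiling(r) + 1L, "disc"))
    fg <- EBImage::gblur(fg, sigma = r)
  }
  soft_mask <- pmin(pmax(unclass(fg), 0), 1)

  list(gauss_score = unclass(gauss_score), hough_score = unclass(hough),
       soft_mask = soft_mask)
}

minmax01 <- function(m) {
  rng <- range(m)
  if (diff(rng) <= 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

#' Detect beads in an image
#'
#' Multiplies the three min-max-normalized score maps of
#' [bead_score_maps()], finds local maxima with non-maximum suppression at
#' `min_separation`, excludes a border of width `radius`, and returns the
#' top `n_peaks` detections in deterministic order (score descending, then
#' y, then x ascending).
#'
#' @inheritParams bead_score_maps
#' @return A tibble with columns `x`, `y` (0-based pixel coordinates) and
#'   `score`; the binary peak map is attached as attribute `peak_map` and
#'   the final score map as `score_map`.
#' @export
detect_beads <- function(image, params) {
  maps <- bead_score_maps(image, params)
  score <- minmax01(maps$gauss_score) * minmax01(maps$hough_score) *
    minmax01(maps$soft_mask)
  sep <- max(1L, round(params$min_separation))
  local_max <- unclass(EBImage::dilate(score, EBImage::makeBrush(2L * sep + 1L, "box")))
  peaks <- score >= params$min_score & score >= local_max - 1e-12
  border <- ceiling(params$radius)
  ny <- nrow(score); nx <- ncol(score)
  if (border > 0) {
    keep <- matrix(FALSE, ny, nx)
    if (ny > 2 * border && nx > 2 * border)
      keep[(border + 1):(ny - border), (border + 1):(nx - border)] <- TRUE
    peaks <- peaks & keep
  }
  idx <- which(peaks, arr.ind = TRUE)
  det <- tibble::tibble(x = as.numeric(idx[, 2] - 1),
                        y = as.numeric(idx[, 1] - 1),
                        score = score[idx])
  det <- det[order(-det$score, det$y, det$x), , drop = FALSE]
  # greedy suppression: enforce min_separation among returned peaks
  if (nrow(det) > 1) {
    keep <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
      if (i == 1) { keep[1] <- TRUE; next }
      prev <- det[keep, , drop = FALSE]
      dmin <- min(sqrt((prev$x - det$x[i])^2 + (prev$y - det$y[i])^2))
      keep[i] <- dmin >= params$min_separation
    }
    det <- det[keep, , drop = FALSE]
  }
  det <- head(det, params$n_peaks)
  peak_map <- matrix(0L, ny, nx)
  if (nrow(det) > 0) peak_map[cbind(det$y + 1, det$x + 1)] <- 1L
  attr(det, "peak_map") <- peak_map
  attr(det, "score_map") <- score
  det
}

# 1-D Gaussian-with-offset least-squares fit; returns c(A, mu, sigma, offset)
# or NULL on failure.
fit_gauss1d <- function(v, xs = seq_along(v) - 1) {
  off0 <- min(v); A0 <- max(v) - off0
  if (!is.finite(A0) || A0 <= 1e-12) return(NULL)
  w <- pmax(v - off0, 0)
  mu0 <- sum(xs * w) / sum(w)
  s0 <- sqrt(max(sum((xs - mu0)^2 * w) / sum(w), 0.25))
  obj <- function(p) {
    pred <- p[4] + p[1] * exp(-(xs - p[2])^2 / (2 * p[3]^2))
    sum((pred - v)^2)
  }
  fit <- tryCatch(
    optim(c(A0, mu0, s0, off0), obj, method = "L-BFGS-B",
          lower = c(1e-9, min(xs) - 1, 0.3, -Inf),
          upper = c(Inf, max(xs) + 1, diff(range(xs)) + 1, Inf)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  p <- fit$par
  if (p[1] <= 1e-9) return(NULL)
  p
}

# 2-D elliptical Gaussian-with-offset fit on a patch; returns
# c(A, cy, cx, sy, sx, offset) in patch coordinates, or NULL.
fit_gauss2d <- function(patch) {
  ny <- nrow(patch); nx <- ncol(patch)
  off0 <- min(patch); A0 <- max(patch) - off0
  if (!is.finite(A0) || A0 <= 1e-12) return(NULL)
  w <- pmax(patch - off0, 0)
  ys <- rep(0:(ny - 1), nx); xs <- rep(0:(nx - 1), each = ny)
  sw <- sum(w)
  cy0 <- sum(ys * w) / sw; cx0 <- sum(xs * w) / sw
  sy0 <- sqrt(max(sum((ys - cy0)^2 * w) / sw, 0.25))
  sx0 <- sqrt(max(sum((xs - cx0)^2 * w) / sw, 0.25))
  v <- as.numeric(patch)
  obj <- function(p) {
    pred <- p[6] + p[1] * exp(-((ys - p[2])^2 / (2 * p[4]^2) +
                                  (xs - p[3])^2 / (2 * p[5]^2)))
    sum((pred - v)^2)
  }
  fit <- tryCatch(
    optim(c(A0, cy0, cx0, sy0, sx0, off0), obj, method = "L-BFGS-B",
          lower = c(1e-9, -1, -1, 0.3, 0.3, -Inf),
          upper = c(Inf, ny, nx, ny, nx, Inf)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  p <- fit$par
  if (p[1] <= 1e-9) return(NULL)
  p
}

extract_window1d <- function(data, center, axis, fix, window) {
  r <- (window - 1L) %/% 2L
  d <- dim(data)
  lo <- max(0L, round(center) - r); hi <- min(d[axis] - 1L, round(center) + r)
  xs <- lo:hi
  v <- switch(length(d) - 1L,
    # 2D data: axis 1 = y, axis 2 = x; fix = c(y, x) rounded complement
    {
      if (axis == 1L) data[xs + 1L, fix[2] + 1L] else data[fix[1] + 1L, xs + 1L]
    },
    # 3D data
    {
      if (axis == 1L) data[xs + 1L, fix[2] + 1L, fix[3] + 1L]
      else if (axis == 2L) data[fix[1] + 1L, xs + 1L, fix[3] + 1L]
      else data[fix[1] + 1L, fix[2] + 1L, xs + 1L]
    })
  list(values = v, xs = xs)
}

#' Subpixel fiducial center by iterative Gaussian fitting
#'
#' Alternates 1-D Gaussian fits (with a jointly fitted constant background)
#' along each axis through the current center estimate with a 2-D in-plane
#' elliptical Gaussian fit, until the center moves less than 0.01 px or 20
#' iterations are reached. For 3-D input the z-center comes from the 1-D fit
#' along z.
#'
#' @param data 2-D matrix or 3-D array of intensities.
#' @param seed Approximate center, `c(x, y)` or `c(x, y, z)` (0-based).
#' @param window Odd fitting window size in pixels (>= 5).
#' @return Numeric subpixel center, same length/ordering as `seed`.
#' @export
fit_center_gaussian <- function(data, seed, window = 11L) {
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L)
    stop_fibclem("param_error", "window must be odd and >= 5")
  d <- dim(data)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  seed <- as.numeric(seed)
  stopifnot(length(seed) == nd)
  # seed comes as (x, y[, z]); internal order (y, x[, z])
  ctr <- if (nd == 2L) c(seed[2], seed[1]) else c(seed[2], seed[1], seed[3])
  if (any(ctr < 0) || any(ctr > d[seq_len(nd)] - 1))
    stop_fibclem("param_error", "seed lies outside the data")
  r <- (window - 1L) %/% 2L
  for (iter in seq_len(20L)) {
    prev <- ctr
    fix <- pmin(pmax(round(ctr), 0), d - 1)
    new <- ctr
    for (axis in seq_len(nd)) {
      w1 <- extract_window1d(data, ctr[axis], axis, fix, window)
      p <- fit_gauss1d(w1$values, w1$xs)
      if (is.null(p)) stop_fibclem("fit_failed", "1-D Gaussian fit failed (flat or diverging profile)")
      new[axis] <- min(max(p[2], 0), d[axis] - 1)
    }
    ctr <- new
    # in-plane 2-D refinement
    ylo <- max(0L, round(ctr[1]) - r); yhi <- min(d[1] - 1L, round(ctr[1]) + r)
    xlo <- max(0L, round(ctr[2]) - r); xhi <- min(d[2] - 1L, round(ctr[2]) + r)
    patch <- if (nd == 2L) data[(ylo:yhi) + 1L, (xlo:xhi) + 1L, drop = FALSE]
    else data[(ylo:yhi) + 1L, (xlo:xhi) + 1L, pmin(pmax(round(ctr[3]), 0), d[3] - 1) + 1L]
    p2 <- fit_gauss2d(patch)
    if (is.null(p2)) stop_fibclem("fit_failed", "2-D Gaussian fit failed (flat or diverging patch)")
    ctr[1] <- min(max(ylo + p2[2], 0), d[1] - 1)
    ctr[2] <- min(max(xlo + p2[3], 0), d[2] - 1)
    if (sqrt(sum((ctr - prev)^2)) < 0.01) break
  }
  if (nd == 2L) c(x = ctr[2], y = ctr[1]) else c(x = ctr[2], y = ctr[1], z = ctr[3])
}

# 3-D connected components, 26-connectivity, on a logical array.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  todo <- which(mask)
  visited <- array(FALSE, d)
  cur <- 0L
  for (s in todo) {
    if (visited[s]) next
    cur <- cur + 1L
    frontier <- s
    visited[s] <- TRUE
    lab[s] <- cur
    while (length(frontier) > 0) {
      ai <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        cand <- cbind(ai[, 1] + offs$dy[k], ai[, 2] + offs$dx[k], ai[, 3] + offs$dz[k])
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
        if (!any(ok)) next
        lin <- cand[ok, 1] + d[1] * (cand[ok, 2] - 1) + d[1] * d[2] * (cand[ok, 3] - 1)
        lin <- lin[mask[lin] & !visited[lin]]
        if (length(lin) > 0) {
          visited[lin] <- TRUE
          lab[lin] <- cur
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Centroids of labeled 3-D features
#'
#' One centroid per 26-connected component within each label value
#' (0 = background), as the unweighted mean of member voxel coordinates.
#' Ordering is deterministic: by label value, then component scan order.
#'
#' @param label_volume 3-D integer array (`[y, x, z]`), labels >= 0.
#' @return A tibble with `label`, `component`, `x`, `y`, `z` (0-based voxel
#'   coordinates) and `n_voxels`; zero rows if the volume is all background.
#' @export
extract_centroids <- function(label_volume) {
  d <- dim(label_volume)
  stopifnot(length(d) == 3L)
  if (any(label_volume < 0)) stop_fibclem("param_error", "labels must be >= 0")
  labels <- sort(unique(as.integer(label_volume[label_volume > 0])))
  out <- list()
  for (lv in labels) {
    comp <- label_components_3d(label_volume == lv)
    for (ci in seq_len(max(comp))) {
      vox <- arrayInd(which(comp == ci), d)
      out[[length(out) + 1]] <- tibble::tibble(
        label = lv, component = ci,
        x = mean(vox[, 2] - 1), y = mean(vox[, 1] - 1), z = mean(vox[, 3] - 1),
        n_voxels = nrow(vox))
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(label = integer(), component = integer(),
                          x = numeric(), y = numeric(), z = numeric(),
                          n_voxels = integer()))
  dplyr::bind_rows(out)
}
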