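# Lamella volume masks and masked maximum-intensity "virtual slice"
# projections. A lamella drawn on the SEM image, together with its position
# in the FIB image, defines a slab in the 3-D fluorescence frame; masking
# the fluorescence volume with that slab and projecting shows exactly the
# signal retained in the milled lamella.

#' Lamella geometry annotation
#'
#' @param polygon_sem Tibble/matrix of >= 3 polygon vertices (`x`, `y`) in
#'   the SEM image marking the lamella boundary; must be simple
#'   (non-self-intersecting).
#' @param interior_point_sem Point `c(x, y)` inside the polygon.
#' @param fib_anchor Point `c(x, y)` on the lamella in the FIB image; its y
#'   coordinate anchors the lamella plane.
#' @param thickness Lamella thickness in nm.
#' @return A list of class `lamella_spec`.
#' @export
lamella_spec <- function(polygon_sem, interior_point_sem, fib_anchor, thickness) {
  poly <- as_point_matrix(polygon_sem, 2)
  if (nrow(poly) < 3) stop_fibclem("param_error", "polygon needs >= 3 vertices")
  if (polygon_self_intersects(poly))
    stop_fibclem("param_error", "lamella polygon is self-intersecting")
  if (!is_scalar_number(thickness) || thickness <= 0)
    stop_fibclem("param_error", "thickness must be positive (nm)")
  ip <- as.numeric(interior_point_sem)
  if (!point_in_polygon(ip[1], ip[2], poly))
    stop_fibclem("param_error", "interior point lies outside the polygon")
  structure(list(polygon_sem = poly, interior_point_sem = ip,
                 fib_anchor = as.numeric(fib_anchor), thickness = thickness),
            class = "lamella_spec")
}

# even-odd point-in-polygon; points on the boundary count as inside
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary test: point within 1e-9 of segment
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      t <- pmin(pmax(((px - xi) * dx + (py - yi) * dy) / len2, 0), 1)
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      on_edge <- on_edge | d2 < 1e-18
    }
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + ((yj - yi) == 0) * 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside | on_edge
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[i %% n + 1, ])
  inter <- function(a, b) {
    d1 <- a[2, ] - a[1, ]; d2 <- b[2, ] - b[1, ]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1, 1] - a[1, 1]) * d2[2] - (b[1, 2] - a[1, 2]) * d2[1]) / den
    u <- ((b[1, 1] - a[1, 1]) * d1[2] - (b[1, 2] - a[1, 2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through wrap
      if (inter(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# linear map p -> FIB image y for a correlation transform: a . p + b
fib_y_plane <- function(fib_corr) {
  a <- fib_corr$scale * fib_corr$rotation[2, ]
  b <- fib_corr$translation[2]
  list(a = a, b = b)
}

#' Build the 3-D lamella mask in the fluorescence frame
#'
#' A voxel belongs to the mask iff (a) its projection through the SEM
#' correlation falls inside the lamella polygon (even-odd rule, boundary
#' inclusive) and (b) its physical distance to the lamella plane -- the set
#' of fluorescence-frame points whose FIB-image y equals the anchor's y --
#' is at most half the lamella thickness.
#'
#' @param spec A [lamella_spec()].
#' @param sem_corr,fib_corr Fitted `clem_correlation` objects for the SEM
#'   and FIB views.
#' @param dim Fluorescence volume dimensions `c(ny, nx, nz)`.
#' @param grid [pixel_grid()] of the fluorescence volume (needs
#'   `slice_thickness`).
#' @return Logical 3-D array (`[y, x, z]`); all-`FALSE` with an
#'   `fibclem_empty_mask` warning when the plane misses the polygon prism.
#' @export
build_lamella_mask <- function(spec, sem_corr, fib_corr, dim, grid) {
  stopifnot(inherits(spec, "lamella_spec"), inherits(grid, "pixel_grid"))
  ny <- dim[1]; nx <- dim[2]; nz <- dim[3]
  vx <- rep(rep(0:(nx - 1), each = ny), nz)
  vy <- rep(rep(0:(ny - 1), nx), nz)
  vz <- rep(0:(nz - 1), each = ny * nx)
  P <- cbind(vx, vy, vz)
  proj <- apply_correlation(sem_corr, P)
  inside <- point_in_polygon(proj$x, proj$y, spec$polygon_sem)
  pl <- fib_y_plane(fib_corr)
  yfib <- P %*% pl$a + pl$b
  vox <- c(grid$pixel_size_x, grid$pixel_size_y, grid$slice_thickness)
  if (anyNA(vox)) stop_fibclem("bad_grid", "volume grid needs slice_thickness")
  grad_phys <- pl$a / vox  # d(yfib)/d(nm)
  dist_nm <- (yfib - spec$fib_anchor[2]) / sqrt(sum(grad_phys^2))
  # boundary-inclusive slab test with a sub-picometer guard against
  # round-off in the transform arithmetic
  mask <- array(inside & abs(dist_nm) <= spec$thickness / 2 + 1e-9,
                dim = c(ny, nx, nz))
  if (!any(mask))
    warn_fibclem("empty_mask", "lamella plane does not intersect the polygon prism; mask is empty")
  mask
}

as_view_affine <- function(view) {
  if (inherits(view, "clem_correlation")) correlation_as_affine(view)
  else if (inherits(view, "affine3d")) view
  else stop_fibclem("param_error", "view must be an affine3d or clem_correlation")
}

#' Masked maximum-intensity projection through an affine view
#'
#' Transforms the masked volume by inverse mapping with trilinear
#' interpolation and takes the maximum along the viewing (z) axis of the
#' output frame. Only the z-range covered by the transformed volume is
#' evaluated; the computation proceeds in output-raster patches whose size
#' never changes the result.
#'
#' @param volume 3-D numeric array (`[y, x, z]`).
#' @param mask Logical/numeric array of the same shape (use `NULL` or an
#'   all-ones array for an unmasked projection).
#' @param view An [affine3d()] or `clem_correlation` mapping volume
#'   coordinates to output coordinates.
#' @param output_shape `c(ny, nx)` of the projection.
#' @param patch_size Output tile edge in pixels (cost knob only).
#' @param workers Kept for interface compatibility; evaluation is
#'   sequential and deterministic regardless of its value.
#' @return Numeric matrix `output_shape`.
#' @export
masked_projection <- function(volume, mask, view, output_shape,
                              patch_size = 128L, workers = 1L) {
  a <- as_view_affine(view)
  if (abs(det(a$linear)) < 1e-12)
    stop_fibclem("singular_transform", "view transform is singular")
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(volume)))
    volume <- volume * mask
  }
  ai <- invert_affine(a)
  d <- dim(volume)
  corners <- as.matrix(expand.grid(x = c(0, d[2] - 1), y = c(0, d[1] - 1),
                                   z = c(0, d[3] - 1)))[, c("x", "y", "z")]
  cz <- apply_affine(a, corners)$z
  z_lo <- floor(min(cz)); z_hi <- ceiling(max(cz))
  ny <- output_shape[1]; nx <- output_shape[2]
  out <- matrix(-Inf, ny, nx)
  ps <- max(8L, as.integer(patch_size))
  for (y0 in seq(0L, ny - 1L, by = ps)) {
    y1 <- min(y0 + ps - 1L, ny - 1L)
    for (x0 in seq(0L, nx - 1L, by = ps)) {
      x1 <- min(x0 + ps - 1L, nx - 1L)
      gy <- rep(y0:y1, times = x1 - x0 + 1L)
      gx <- rep(x0:x1, each = y1 - y0 + 1L)
      acc <- rep(-Inf, length(gy))
      for (zq in z_lo:z_hi) {
        src <- apply_affine(ai, cbind(gx, gy, zq))
        acc <- pmax(acc, interp3(volume, src$y, src$x, src$z, fill = 0))
      }
      out[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- matrix(acc, y1 - y0 + 1L)
    }
  }
  out[!is.finite(out)] <- 0
  out
}

#' Virtual-slice series over FIB sample heights
#'
#' Builds one masked projection per height offset; height `h` (FIB-image
#' pixels) shifts the lamella plane anchor by `h` along the FIB y-axis
#' before mask construction, scanning candidate lamella planes above and
#' below the nominal position.
#'
#' @inheritParams build_lamella_mask
#' @param volume Fluorescence volume (`[y, x, z]`).
#' @param heights Numeric vector of FIB-y pixel offsets.
#' @param view Projection view (defaults to the FIB correlation).
#' @param output_shape Projection raster shape `c(ny, nx)`.
#' @param patch_size Passed to [masked_projection()].
#' @return A named list of projection matrices, one per height
#'   (names `h<offset>`).
#' @export
virtual_slice_series <- function(volume, spec, sem_corr, fib_corr, heights,
                                 grid, output_shape, view = fib_corr,
                                 patch_size = 128L) {
  out <- vector("list", length(heights))
  for (i in seq_along(heights)) {
    sp <- spec
    sp$fib_anchor[2] <- sp$fib_anchor[2] + heights[i]
    m <- build_lamella_mask(sp, sem_corr, fib_corr, dim(volume), grid)
    out[[i]] <- masked_projection(volume, m, view, output_shape, patch_size)
  }
  names(out) <- paste0("h", heights)
  out
}
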