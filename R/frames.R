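# Coordinate frames and geometric primitives.
#
# Conventions used package-wide: pixel coordinates are 0-based and refer to
# pixel centers; x runs right, y runs down, z is the slice index of a stack.
# Angles are degrees at every interface and radians internally. Physical
# (nm) conversions always go through a pixel_grid.

# points ------------------------------------------------------------------

#' Assemble a point table
#'
#' Points are carried as tibbles with columns `x`, `y` and optionally `z`,
#' in 0-based pixel-center coordinates.
#'
#' @param x,y,z Numeric coordinate vectors (`z` may be `NULL` for 2D points).
#' @return A tibble with columns `x`, `y` (and `z` for 3D points).
#' @export
points_tbl <- function(x, y, z = NULL) {
  if (is.null(z)) tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  else tibble::tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
}

# Accepts a tibble/data.frame with x,y(,z) columns or a numeric matrix and
# returns an n x d coordinate matrix.
as_point_matrix <- function(points, d = NULL) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    m <- as.matrix(points[cols])
  } else {
    m <- as.matrix(points)
    if (is.null(dim(m)) || ncol(m) == 1L) m <- matrix(as.numeric(points), nrow = 1L)
  }
  storage.mode(m) <- "double"
  if (!is.null(d)) {
    if (ncol(m) != d)
      stop_fibclem("bad_points", sprintf("expected %d-column point set, got %d", d, ncol(m)))
  }
  if (!all(is.finite(m))) stop_fibclem("bad_points", "point coordinates must be finite")
  m
}

# pixel grid --------------------------------------------------------------

#' Physical pixel/voxel calibration
#'
#' @param pixel_size_x,pixel_size_y Pixel pitch in nm (y defaults to x).
#' @param slice_thickness Slice (z) pitch in nm for stacks, or `NA` for 2D data.
#' @param origin_offset Numeric offset of the pixel (0,0[,0]) center in nm.
#' @return An object of class `pixel_grid`.
#' @export
pixel_grid <- function(pixel_size_x, pixel_size_y = pixel_size_x,
                       slice_thickness = NA_real_, origin_offset = c(0, 0, 0)) {
  sizes <- c(pixel_size_x, pixel_size_y)
  if (!all(vapply(sizes, is_scalar_number, logical(1))) || any(sizes <= 0))
    stop_fibclem("bad_grid", "pixel sizes must be positive finite scalars")
  if (!is.na(slice_thickness) && slice_thickness <= 0)
    stop_fibclem("bad_grid", "slice_thickness must be positive")
  structure(list(pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
                 slice_thickness = as.numeric(slice_thickness),
                 origin_offset = as.numeric(origin_offset)),
            class = "pixel_grid")
}

#' Convert pixel coordinates to physical nm
#'
#' @param points Point tibble or matrix (2 or 3 columns).
#' @param grid A [pixel_grid()].
#' @return A tibble of physical coordinates in nm.
#' @export
pixels_to_nm <- function(points, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  m <- as_point_matrix(points)
  sc <- c(grid$pixel_size_x, grid$pixel_size_y, grid$slice_thickness)[seq_len(ncol(m))]
  if (anyNA(sc)) stop_fibclem("bad_grid", "3D conversion requires slice_thickness")
  off <- grid$origin_offset[seq_len(ncol(m))]
  out <- sweep(sweep(m, 2, sc, `*`), 2, off, `+`)
  colnames(out) <- c("x", "y", "z")[seq_len(ncol(m))]
  tibble::as_tibble(out)
}

# beam geometry -----------------------------------------------------------

#' Ion/electron beam geometry
#'
#' @param inter_beam_angle Angle between the ion and electron beams in degrees
#'   (52 on the dual-beam systems this package models).
#' @param stage_tilt,pre_tilt Stage and shuttle pre-tilt in degrees (metadata).
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(inter_beam_angle = 52, stage_tilt = 0, pre_tilt = 0) {
  if (!is_scalar_number(inter_beam_angle) || inter_beam_angle <= 0 || inter_beam_angle >= 90)
    stop_fibclem("invalid_angle", "inter_beam_angle must lie in (0, 90) degrees")
  structure(list(inter_beam_angle = inter_beam_angle,
                 stage_tilt = stage_tilt, pre_tilt = pre_tilt),
            class = "beam_geometry")
}

# affine transforms -------------------------------------------------------

#' 3D affine transform
#'
#' @param linear 3x3 linear part.
#' @param translation Length-3 translation.
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (!all(is.finite(linear)) || !all(is.finite(translation)))
    stop_fibclem("bad_transform", "affine components must be finite")
  structure(list(linear = linear, translation = translation), class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d>\nlinear:\n")
  print(round(x$linear, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Identity, scaling, translation and rotation constructors
#'
#' `affine_rotate()` builds the rotation about a unit `axis` through `center`
#' by `angle` degrees (right-handed in the x-right / y-down / z-in frame).
#'
#' @param s Isotropic or per-axis scale factor(s).
#' @param v Length-3 translation vector.
#' @param axis Rotation axis (any nonzero 3-vector).
#' @param angle Rotation angle in degrees.
#' @param center Point the rotation axis passes through.
#' @return An `affine3d`.
#' @export
affine_identity <- function() affine3d()

#' @rdname affine_identity
#' @export
affine_scale <- function(s) affine3d(diag(rep(s, length.out = 3)))

#' @rdname affine_identity
#' @export
affine_translate <- function(v) affine3d(diag(3), v)

#' @rdname affine_identity
#' @export
affine_rotate <- function(axis, angle, center = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop_fibclem("degenerate_geometry", "rotation axis must be nonzero")
  R <- rotation_matrix(axis / n, deg2rad(angle))
  affine3d(R, as.numeric(center) - R %*% as.numeric(center))
}

# Rodrigues rotation about a unit axis, angle in radians.
rotation_matrix <- function(u, theta) {
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Apply an affine transform to points
#'
#' @param t An [affine3d()].
#' @param points 3D point tibble or n x 3 matrix.
#' @return A tibble with transformed `x`, `y`, `z`.
#' @export
apply_affine <- function(t, points) {
  stopifnot(inherits(t, "affine3d"))
  m <- as_point_matrix(points, 3)
  out <- m %*% t(t$linear)
  out <- sweep(out, 2, t$translation, `+`)
  colnames(out) <- c("x", "y", "z")
  tibble::as_tibble(out)
}

#' Invert / compose affine transforms
#'
#' @param t,a,b [affine3d()] objects.
#' @return An `affine3d`; `compose_affine(a, b)` applies `b` first, then `a`.
#' @export
invert_affine <- function(t) {
  stopifnot(inherits(t, "affine3d"))
  d <- det(t$linear)
  if (!is.finite(d) || abs(d) < 1e-300)
    stop_fibclem("singular_transform", "affine linear part is singular")
  Li <- solve(t$linear)
  affine3d(Li, -Li %*% t$translation)
}

#' @rdname invert_affine
#' @export
compose_affine <- function(a, b) {
  stopifnot(inherits(a, "affine3d"), inherits(b, "affine3d"))
  affine3d(a$linear %*% b$linear, a$linear %*% b$translation + a$translation)
}

# plane fitting -----------------------------------------------------------

#' Total-least-squares plane through a point set
#'
#' Fits the plane minimizing the sum of squared orthogonal point-plane
#' distances (smallest singular vector of the centered coordinates). The
#' normal is oriented with positive z-component (ties broken toward
#' positive y, then positive x) so the output is deterministic.
#'
#' @param points >= 3 non-collinear 3D points.
#' @return A list of class `plane3d` with unit `normal`, `point` (centroid)
#'   and `rms` orthogonal distance.
#' @export
fit_plane <- function(points) {
  m <- as_point_matrix(points, 3)
  if (nrow(m) < 3L)
    stop_fibclem("degenerate_geometry", "plane fit needs at least 3 points")
  ctr <- colMeans(m)
  X <- sweep(m, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop_fibclem("degenerate_geometry", "points are collinear; plane is undetermined")
  n <- sv$v[, 3]
  # deterministic orientation: +z, ties +y, then +x
  key <- c(n[3], n[2], n[1])
  first <- which(abs(key) > 1e-12)[1]
  if (!is.na(first) && key[first] < 0) n <- -n
  structure(list(normal = n / sqrt(sum(n^2)), point = ctr,
                 rms = sqrt(mean((X %*% n)^2))),
            class = "plane3d")
}

#' Signed distance from points to a plane
#'
#' @param plane A [fit_plane()] result or list with `point` and unit `normal`.
#' @param points 3D points.
#' @return Numeric vector of signed distances (positive along the normal).
#' @export
plane_distance <- function(plane, points) {
  m <- as_point_matrix(points, 3)
  drop(sweep(m, 2, plane$point) %*% plane$normal)
}

# optics / geometry scalars -----------------------------------------------

#' Foreshortening correction factor
#'
#' Images of the milled face acquired at the inter-beam angle are compressed
#' along y; stretching by `1/sin(angle)` restores isotropy (1.269 at the
#' 52 degree geometry of common dual-beam instruments).
#'
#' @param angle Angle in degrees, in (0, 90].
#' @return `1 / sin(angle)`.
#' @export
foreshortening_factor <- function(angle) {
  if (!is_scalar_number(angle) || angle <= 0 || angle > 90)
    stop_fibclem("invalid_angle", "angle must lie in (0, 90] degrees")
  1 / sin(deg2rad(angle))
}

#' Diffraction-limited confocal resolution
#'
#' Lateral FWHM-type bound `0.51 * lambda / NA` and axial bound
#' `0.88 * lambda / (n - sqrt(n^2 - NA^2))` for a confocal system at a
#' pinhole of 1 Airy unit. The default refractive index 1.31 is vitreous ice,
#' the specimen medium of cryo-fluorescence imaging.
#'
#' @param numerical_aperture Objective NA (must be < `refractive_index`).
#' @param wavelength_nm Wavelength in nm.
#' @param refractive_index Specimen refractive index.
#' @return A tibble with `lateral_nm` and `axial_nm`.
#' @export
confocal_resolution <- function(numerical_aperture, wavelength_nm,
                                refractive_index = 1.31) {
  if (!is_scalar_number(numerical_aperture) || numerical_aperture <= 0)
    stop_fibclem("invalid_optics", "numerical aperture must be positive")
  if (!is_scalar_number(wavelength_nm) || wavelength_nm <= 0)
    stop_fibclem("invalid_optics", "wavelength must be positive")
  if (numerical_aperture >= refractive_index)
    stop_fibclem("invalid_optics", "NA must be smaller than the specimen refractive index")
  lateral <- 0.51 * wavelength_nm / numerical_aperture
  axial <- 0.88 * wavelength_nm /
    (refractive_index - sqrt(refractive_index^2 - numerical_aperture^2))
  tibble::tibble(lateral_nm = lateral, axial_nm = axial)
}

# serialization -----------------------------------------------------------

#' Read / write affine transforms as JSON
#'
#' The on-disk form is `{"linear": [9 floats row-major], "translation": [3]}`.
#'
#' @param t An [affine3d()].
#' @param path File path.
#' @return `read_transform_json()` returns an `affine3d`;
#'   `write_transform_json()` returns `path` invisibly.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "affine3d"))
  obj <- list(linear = as.numeric(t(t$linear)), translation = t$translation)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine3d(matrix(obj$linear, 3, 3, byrow = TRUE), obj$translation)
}

#' Read / write point coordinate CSV
#'
#' Header `x,y[,z]`, one point per row, units pixels.
#'
#' @param points Point tibble.
#' @param path File path.
#' @return A point tibble (read) or `path` invisibly (write).
#' @export
write_points_csv <- function(points, path) {
  readr::write_csv(tibble::as_tibble(points), path)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
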