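# Fluorescence-to-SEM/FIB correlation. The transform model is a rigid
# rotation, isotropic scale and translation (7 d.o.f.); the image-plane
# prediction drops z after transforming, and the retained z is the depth of
# the point above/below the image plane. Only the x/y residuals constrain
# the fit, so the z-translation is fixed at 0 (depth gauge).

quat_from_matrix <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s, s / 4)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[i] <- s / 4
    q[j] <- (R[j, i] + R[i, j]) / s
    q[k] <- (R[k, i] + R[i, k]) / s
    q[4] <- (R[k, j] - R[j, k]) / s
  }
  q <- q / sqrt(sum(q^2))  # (x, y, z, w)
  if (q[4] < 0) q <- -q
  q
}

rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  rotation_matrix(v / th, th)
}

matrix_to_rotvec <- function(R) {
  q <- quat_from_matrix(R)
  w <- min(max(q[4], -1), 1)
  th <- 2 * acos(w)
  s <- sqrt(max(1 - w^2, 0))
  if (s < 1e-9) return(c(0, 0, 0))
  q[1:3] / s * th
}

# Closed-form 2-D similarity (rotation angle, scale, translation) mapping
# src (n x 2) onto dst (n x 2) in least squares (Umeyama).
similarity2d <- function(src, dst) {
  ms <- colMeans(src); md <- colMeans(dst)
  S <- sweep(src, 2, ms); D <- sweep(dst, 2, md)
  C <- t(D) %*% S / nrow(src)
  sv <- svd(C)
  sgn <- sign(det(sv$u %*% t(sv$v)))
  Sm <- diag(c(1, sgn))
  R <- sv$u %*% Sm %*% t(sv$v)
  varS <- mean(rowSums(S^2))
  s <- if (varS > 0) sum(diag(Sm) * sv$d) / varS else 1
  list(angle = atan2(R[2, 1], R[1, 1]), scale = max(s, 1e-6),
       translation = md - s * R %*% ms)
}

corr_predict <- function(par, P) {
  # par = (rotvec[3], log scale, tx, ty)
  R <- rotvec_to_matrix(par[1:3])
  s <- exp(par[4])
  Q <- s * (P %*% t(R))
  Q[, 1] <- Q[, 1] + par[5]
  Q[, 2] <- Q[, 2] + par[6]
  Q
}

corr_objective <- function(par, P, obs) {
  Q <- corr_predict(par, P)
  sum((Q[, 1] - obs[, 1])^2 + (Q[, 2] - obs[, 2])^2)
}

# fixed deterministic grid of starting rotations for the refinement
corr_start_rotations <- function() {
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0) / sqrt(2), c(1, -1, 0) / sqrt(2))
  angles <- c(45, 90, 135, 180, -45, -90, -135)
  starts <- list(diag(3))
  for (ax in axes) for (an in angles)
    starts[[length(starts) + 1]] <- rotation_matrix(ax, deg2rad(an))
  starts
}

#' Fit a 3D-fluorescence-to-2D-image correlation transform
#'
#' Least-squares estimate of rotation, isotropic scale and translation
#' minimizing the squared image-plane distance between projected 3-D
#' fiducials and their 2-D counterparts. Initialization combines a
#' closed-form in-plane similarity fit with a fixed grid of out-of-plane
#' starting rotations, each refined by quasi-Newton minimization; the result
#' is deterministic for given inputs.
#'
#' @param points3d 3-D fiducial positions (tibble with `x`, `y`, `z` or
#'   n x 3 matrix), fluorescence frame, pixels.
#' @param points2d Matched 2-D positions (tibble with `x`, `y` or n x 2
#'   matrix), SEM or FIB image frame, pixels. Row order pairs the sets.
#' @return An object of class `clem_correlation` with elements `rotation`
#'   (3x3), `quaternion` (x, y, z, w), `scale`, `translation` (z fixed at 0),
#'   `residuals` (per-point tibble), `rms` and `n`.
#' @export
fit_correlation <- function(points3d, points2d) {
  P <- as_point_matrix(points3d, 3)
  obs <- as_point_matrix(points2d, 2)
  if (nrow(P) != nrow(obs))
    stop_fibclem("param_error", "point sets must be paired (equal row counts)")
  if (nrow(P) < 4L)
    stop_fibclem("not_enough_fiducials", "at least 4 paired fiducials are required")
  spread <- svd(sweep(obs, 2, colMeans(obs)))$d
  if (spread[2] < 1e-9 * max(spread[1], 1))
    stop_fibclem("degenerate_geometry", "2-D points are collinear")

  best <- NULL
  for (R0 in corr_start_rotations()) {
    Pr <- P %*% t(R0)
    sim <- similarity2d(Pr[, 1:2, drop = FALSE], obs)
    Rz <- rotation_matrix(c(0, 0, 1), sim$angle)
    Rinit <- Rz %*% R0
    par0 <- c(matrix_to_rotvec(Rinit), log(sim$scale), sim$translation[1], sim$translation[2])
    fit <- tryCatch(
      optim(par0, corr_objective, P = P, obs = obs, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-16 * nrow(P)) break
  }
  if (is.null(best)) stop_fibclem("fit_failed", "correlation fit did not converge")
  # Levenberg-Marquardt polish to machine precision
  resid_fn <- function(par) {
    Q <- corr_predict(par, P)
    c(Q[, 1] - obs[, 1], Q[, 2] - obs[, 2])
  }
  lm <- minpack.lm::nls.lm(best$par, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  par <- lm$par
  R <- rotvec_to_matrix(par[1:3])
  s <- exp(par[4])
  pred <- corr_predict(par, P)
  res <- sqrt((pred[, 1] - obs[, 1])^2 + (pred[, 2] - obs[, 2])^2)
  out <- structure(list(
    rotation = R, quaternion = quat_from_matrix(R), scale = s,
    translation = c(par[5], par[6], 0),
    residuals = tibble::tibble(id = seq_len(nrow(P)),
                               x_obs = obs[, 1], y_obs = obs[, 2],
                               x_pred = pred[, 1], y_pred = pred[, 2],
                               residual_px = res),
    rms = sqrt(mean(res^2)), n = nrow(P)),
    class = "clem_correlation")
  out
}

#' @export
print.clem_correlation <- function(x, ...) {
  cat("<clem_correlation>", x$n, "fiducials, rms", signif(x$rms, 4), "px\n")
  cat("scale", signif(x$scale, 6), " quaternion (x,y,z,w):",
      paste(signif(x$quaternion, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.clem_correlation <- function(x, ...) x$residuals

#' @export
glance.clem_correlation <- function(x, ...) {
  tibble::tibble(n = x$n, rms_px = x$rms, scale = x$scale,
                 max_residual_px = max(x$residuals$residual_px))
}

#' Apply a correlation transform
#'
#' @param t A `clem_correlation` (or the transform element of one).
#' @param points3d 3-D points.
#' @return A tibble with `x`, `y` (image-plane position) and `depth`
#'   (retained third coordinate, same pixel units).
#' @export
apply_correlation <- function(t, points3d) {
  stopifnot(inherits(t, "clem_correlation"))
  P <- as_point_matrix(points3d, 3)
  Q <- t$scale * (P %*% t(t$rotation))
  Q <- sweep(Q, 2, t$translation, `+`)
  tibble::tibble(x = Q[, 1], y = Q[, 2], depth = Q[, 3])
}

# correlation as an affine3d (for volume resampling / projections)
correlation_as_affine <- function(t) {
  stopifnot(inherits(t, "clem_correlation"))
  affine3d(t$scale * t$rotation, t$translation)
}

#' Predict fiducial positions in the FIB image from the SEM correlation
#'
#' At coincidence height the SEM and FIB views are related by a rotation by
#' the inter-beam angle about an axis parallel to the image x-axis, plus a
#' beam-shift translation. The fiducials are mapped through the SEM
#' correlation, a total-least-squares plane is fit to their 3-D positions,
#' coordinates are rotated about the x-parallel axis through the reference
#' point (placed on that plane), projected, and translated so the reference
#' point lands on its user-matched FIB counterpart.
#'
#' @param fiducials3d 3-D fiducial positions in the fluorescence frame.
#' @param sem_ref Reference point `c(x, y)` in the SEM image, on (or near)
#'   the fiducial plane.
#' @param fib_match The same feature's position `c(x, y)` in the FIB image.
#' @param geom A [beam_geometry()].
#' @param sem_corr The fitted SEM `clem_correlation`.
#' @param rotation_sign +1 (default) rotates +y points away from the viewer
#'   for positive angles; -1 flips the convention.
#' @return A tibble of predicted FIB `x`, `y` in input order.
#' @export
predict_fib_positions <- function(fiducials3d, sem_ref, fib_match, geom,
                                  sem_corr, rotation_sign = 1) {
  stopifnot(inherits(geom, "beam_geometry"))
  mapped <- apply_correlation(sem_corr, fiducials3d)
  pts3 <- cbind(mapped$x, mapped$y, mapped$depth)
  pl <- fit_plane(pts3)
  if (abs(pl$normal[3]) < 1e-9)
    stop_fibclem("degenerate_geometry", "fiducial plane is parallel to the viewing axis")
  # put the reference point on the fiducial plane
  z_ref <- pl$point[3] - (pl$normal[1] * (sem_ref[1] - pl$point[1]) +
                            pl$normal[2] * (sem_ref[2] - pl$point[2])) / pl$normal[3]
  th <- deg2rad(geom$inter_beam_angle)
  y0 <- sem_ref[2]
  y_rot <- y0 + cos(th) * (pts3[, 2] - y0) -
    rotation_sign * sin(th) * (pts3[, 3] - z_ref)
  tibble::tibble(x = pts3[, 1] + (fib_match[1] - sem_ref[1]),
                 y = y_rot + (fib_match[2] - sem_ref[2]))
}

#' Root-mean-square residual between paired 2-D points
#'
#' @param a,b Paired point tibbles/matrices with `x`, `y`.
#' @param grid Optional [pixel_grid()]; if given, the value is also reported
#'   in nm (isotropic pixels assumed for the nm norm when x/y sizes differ;
#'   the geometric mean pitch is used).
#' @return The rms distance in pixels, with attribute `rms_nm` when a grid
#'   is supplied.
#' @export
rms_residual <- function(a, b, grid = NULL) {
  A <- as_point_matrix(a, 2); B <- as_point_matrix(b, 2)
  if (nrow(A) == 0) stop_fibclem("empty_input", "no point pairs")
  stopifnot(nrow(A) == nrow(B))
  rms <- sqrt(mean((A[, 1] - B[, 1])^2 + (A[, 2] - B[, 2])^2))
  if (!is.null(grid)) {
    px <- sqrt(grid$pixel_size_x * grid$pixel_size_y)
    attr(rms, "rms_nm") <- rms * px
  }
  rms
}
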