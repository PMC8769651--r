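# 3D <-> 3D affine registration between fluorescence volumes and FIB-SEM
# volumes from matched fiducial centroids. The affine (12 d.o.f.) absorbs
# the anisotropic axial compression of cryo-fluorescence stacks acquired
# with dry objectives as well as stage-drift shear in the FIB-SEM volume.
# Coordinates are expected in physical units (nm); residuals are reported
# in the same units.

#' Registration configuration
#'
#' @param strategy `"ransac"`, `"multistart_local"` or `"basinhopping"`.
#' @param ransac_iters RANSAC hypothesis count.
#' @param inlier_threshold Inlier distance threshold (same units as the
#'   points, typically nm).
#' @param n_starts Number of rigid-hypothesis starts for
#'   `multistart_local`.
#' @param hops Basin-hopping iterations.
#' @param seed Integer seed controlling all randomness of the fit.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(strategy = c("ransac", "multistart_local", "basinhopping"),
                                ransac_iters = 1000L, inlier_threshold = 100,
                                n_starts = 8L, hops = 50L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (ransac_iters < 1 || n_starts < 1 || hops < 1)
    stop_fibclem("param_error", "iteration counts must be >= 1")
  if (inlier_threshold <= 0)
    stop_fibclem("param_error", "inlier_threshold must be positive")
  structure(list(strategy = strategy, ransac_iters = as.integer(ransac_iters),
                 inlier_threshold = inlier_threshold,
                 n_starts = as.integer(n_starts), hops = as.integer(hops),
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' Mutual-nearest-neighbor fiducial matching
#'
#' Pairs each source point with its nearest destination point under the
#' (optionally pre-transformed) Euclidean distance, keeping only mutual
#' pairs closer than `max_dist`.
#'
#' @param src,dst 3-D point tibbles/matrices.
#' @param initial_guess Optional [affine3d()] applied to `src` before
#'   matching.
#' @param max_dist Maximum pairing distance (same units as the points).
#' @return A tibble with `src`, `dst` (row indices) and `dist`; zero rows
#'   with an `fibclem_empty_matching` warning when nothing pairs.
#' @export
match_fiducials <- function(src, dst, initial_guess = NULL, max_dist = Inf) {
  S <- as_point_matrix(src, 3); D <- as_point_matrix(dst, 3)
  if (nrow(S) == 0 || nrow(D) == 0)
    stop_fibclem("empty_input", "point sets must be non-empty")
  if (!is.null(initial_guess)) S <- as.matrix(apply_affine(initial_guess, S))
  d2 <- outer(rowSums(S^2), rep(1, nrow(D))) +
    outer(rep(1, nrow(S)), rowSums(D^2)) - 2 * S %*% t(D)
  d2 <- pmax(d2, 0)
  fwd <- apply(d2, 1, which.min)
  bwd <- apply(d2, 2, which.min)
  keep <- which(bwd[fwd] == seq_len(nrow(S)))
  dist <- sqrt(d2[cbind(keep, fwd[keep])])
  ok <- dist <= max_dist
  out <- tibble::tibble(src = keep[ok], dst = fwd[keep][ok], dist = dist[ok])
  if (nrow(out) == 0)
    warn_fibclem("empty_matching", "no mutual-nearest-neighbor pairs within max_dist")
  out
}

# exact least-squares affine: dst ~ A src + t
affine_lsq <- function(S, D) {
  X <- cbind(S, 1)
  B <- tryCatch(solve(crossprod(X), crossprod(X, D)), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  affine3d(t(B[1:3, , drop = FALSE]), B[4, ])
}

registration_residuals <- function(a, S, D) {
  P <- as.matrix(apply_affine(a, S))
  sqrt(rowSums((P - D)^2))
}

check_pairs_3d <- function(S, D) {
  if (nrow(S) != nrow(D))
    stop_fibclem("param_error", "paired point lists must have equal length")
  if (nrow(S) < 4)
    stop_fibclem("degenerate_geometry", "affine fit needs >= 4 point pairs")
  sv <- svd(sweep(S, 2, colMeans(S)))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop_fibclem("degenerate_geometry", "source points are coplanar; 3-D affine is undetermined")
}

par_to_affine <- function(p) affine3d(matrix(p[1:9], 3, 3), p[10:12])
affine_to_par <- function(a) c(as.numeric(a$linear), a$translation)

affine_objective <- function(p, S, D) {
  A <- matrix(p[1:9], 3, 3)
  P <- S %*% t(A)
  sum((sweep(P, 2, p[10:12], `+`) - D)^2)
}

# rigid + isotropic-scale hypothesis from a random point triple, in the
# spirit of certifiable correspondence-based initializers: the scale comes
# from pairwise-distance ratios, the rotation from aligning the triad
# frames, the translation from the centroids.
rigid_hypothesis <- function(S, D, idx) {
  s1 <- S[idx, ]; d1 <- D[idx, ]
  ls <- sqrt(sum((s1[2, ] - s1[1, ])^2)) + sqrt(sum((s1[3, ] - s1[1, ])^2))
  ld <- sqrt(sum((d1[2, ] - d1[1, ])^2)) + sqrt(sum((d1[3, ] - d1[1, ])^2))
  if (ls < 1e-9) return(NULL)
  sc <- ld / ls
  Sc <- sweep(s1, 2, colMeans(s1)) * sc
  Dc <- sweep(d1, 2, colMeans(d1))
  C <- t(Dc) %*% Sc
  sv <- svd(C)
  R <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  A <- sc * R
  affine3d(A, colMeans(d1) - A %*% colMeans(s1))
}

lbfgsb_refine <- function(par0, S, D) {
  fit <- tryCatch(
    optim(par0, affine_objective, S = S, D = D, method = "L-BFGS-B",
          control = list(maxit = 500, factr = 1e1)),
    error = function(e) NULL)
  fit
}

#' Fit a 3-D affine transform to matched point pairs
#'
#' Minimizes the sum of squared distances between transformed source points
#' and destination points. Three strategies are available: RANSAC over
#' 4-point minimal samples with inlier refitting (robust to gross outliers),
#' L-BFGS-B local minimization from multiple rigid-hypothesis starting
#' positions, and basin-hopping coupled with L-BFGS-B. All randomness is
#' driven by `cfg$seed`, making every strategy reproducible.
#'
#' @param src,dst Paired 3-D point tibbles/matrices (same row order), in
#'   physical units (nm recommended; see [pixels_to_nm()]).
#' @param cfg A [registration_config()].
#' @return An object of class `affine_registration` with `transform`
#'   ([affine3d()]), `rms` (over inliers, input units), `inliers` (logical
#'   mask), `residuals` tibble, `strategy` and `n`.
#' @export
fit_affine <- function(src, dst, cfg = registration_config()) {
  S <- as_point_matrix(src, 3); D <- as_point_matrix(dst, 3)
  check_pairs_3d(S, D)
  stopifnot(inherits(cfg, "registration_config"))
  n <- nrow(S)
  a <- switch(cfg$strategy,
    ransac = {
      best <- NULL; best_score <- c(-1, Inf)
      rng <- local({ set.seed(cfg$seed); lapply(seq_len(cfg$ransac_iters),
                                                function(i) sample.int(n, 4)) })
      for (idx in rng) {
        s4 <- S[idx, ]
        if (abs(det(cbind(s4[2, ] - s4[1, ], s4[3, ] - s4[1, ], s4[4, ] - s4[1, ]))) < 1e-9)
          next
        h <- affine_lsq(s4, D[idx, ])
        if (is.null(h)) next
        r <- registration_residuals(h, S, D)
        inl <- r < cfg$inlier_threshold
        if (sum(inl) < 4) next
        score <- c(sum(inl), sqrt(mean(r[inl]^2)))
        if (score[1] > best_score[1] ||
            (score[1] == best_score[1] && score[2] < best_score[2])) {
          best_score <- score; best <- inl
        }
      }
      if (is.null(best))
        stop_fibclem("fit_failed", "RANSAC found no consensus set")
      affine_lsq(S[best, ], D[best, ])
    },
    multistart_local = {
      set.seed(cfg$seed)
      starts <- list(affine_lsq(S, D))
      for (i in seq_len(cfg$n_starts - 1L)) {
        h <- rigid_hypothesis(S, D, sample.int(n, 3))
        if (!is.null(h)) starts[[length(starts) + 1]] <- h
      }
      best <- NULL
      for (st in starts) {
        fit <- lbfgsb_refine(affine_to_par(st), S, D)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
      }
      par_to_affine(best$par)
    },
    basinhopping = {
      set.seed(cfg$seed)
      extent <- max(apply(S, 2, function(v) diff(range(v))))
      step_t <- 0.1 * extent
      cur <- lbfgsb_refine(affine_to_par(affine_lsq(S, D)), S, D)
      best <- cur
      temp <- max(cur$value, 1e-12)
      for (hop in seq_len(cfg$hops)) {
        prop <- cur$par + c(rnorm(9, 0, 0.05), rnorm(3, 0, step_t))
        fit <- lbfgsb_refine(prop, S, D)
        if (is.null(fit)) next
        if (fit$value < cur$value ||
            runif(1) < exp(-(fit$value - cur$value) / temp)) cur <- fit
        if (fit$value < best$value) best <- fit
      }
      par_to_affine(best$par)
    })
  # final polish on the (inlier) least-squares solution
  inl <- rep(TRUE, n)
  if (cfg$strategy == "ransac") {
    r <- registration_residuals(a, S, D)
    inl <- r < cfg$inlier_threshold
    a <- affine_lsq(S[inl, , drop = FALSE], D[inl, , drop = FALSE])
  }
  r <- registration_residuals(a, S, D)
  structure(list(
    transform = a, rms = sqrt(mean(r[inl]^2)), inliers = inl,
    residuals = tibble::tibble(id = seq_len(n), residual = r, inlier = inl),
    strategy = cfg$strategy, n = n),
    class = "affine_registration")
}

#' Best-of-strategies affine registration
#'
#' Runs all three strategies of [fit_affine()] and returns the result with
#' the lowest inlier rms.
#'
#' @inheritParams fit_affine
#' @return An `affine_registration` with an extra `all_rms` element naming
#'   each strategy's rms.
#' @export
fit_affine_best <- function(src, dst, cfg = registration_config()) {
  fits <- lapply(c("ransac", "multistart_local", "basinhopping"), function(s) {
    cfg$strategy <- s
    fit_affine(src, dst, cfg)
  })
  rms <- vapply(fits, `[[`, numeric(1), "rms")
  out <- fits[[which.min(rms)]]
  out$all_rms <- setNames(rms, c("ransac", "multistart_local", "basinhopping"))
  out
}

#' @export
print.affine_registration <- function(x, ...) {
  cat("<affine_registration>", x$strategy, ":", x$n, "pairs,",
      sum(x$inliers), "inliers, rms", signif(x$rms, 4), "\n")
  invisible(x)
}

#' @export
tidy.affine_registration <- function(x, ...) x$residuals

#' @export
glance.affine_registration <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, n = x$n, n_inliers = sum(x$inliers),
                 rms = x$rms, det_linear = det(x$transform$linear))
}

#' Resample a volume through an affine transform
#'
#' Inverse-mapped trilinear resampling: output voxel `q` takes the
#' interpolated value of the source volume at `a^{-1}(q)`.
#'
#' @param volume 3-D numeric array (`[y, x, z]`).
#' @param a An [affine3d()] mapping source to output coordinates
#'   (`(x, y, z)` voxel units).
#' @param out_shape Output dimensions `c(ny, nx, nz)` (default: input shape).
#' @param fill Value outside the source volume.
#' @return 3-D numeric array of shape `out_shape`.
#' @export
transform_volume <- function(volume, a, out_shape = dim(volume), fill = 0) {
  stopifnot(inherits(a, "affine3d"))
  ai <- invert_affine(a)
  ny <- out_shape[1]; nx <- out_shape[2]; nz <- out_shape[3]
  out <- array(fill, dim = out_shape)
  # process z-slabs to bound memory
  gx <- rep(rep(0:(nx - 1), each = ny), 1)
  gy <- rep(0:(ny - 1), nx)
  for (z in 0:(nz - 1)) {
    src <- apply_affine(ai, cbind(gx, gy, z))
    out[, , z + 1] <- matrix(interp3(volume, src$y, src$x, src$z, fill = fill), ny, nx)
  }
  out
}
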