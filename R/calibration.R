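## Stereo camera calibration from checkerboard views: Zhang-style closed-form
## initialization of the intrinsics from inter-image homographies, followed by
## joint Levenberg-Marquardt refinement of intrinsics, two-coefficient radial
## distortion and poses (single camera), then of the full two-camera rig.

#' Checkerboard specification
#'
#' @param inner_rows,inner_cols number of *inner* corners per column/row of
#'   the board (a board of R x C squares has (R-1) x (C-1) inner corners).
#' @param square_size square side length in mm.
#' @return an object of class \code{"checkerboard_spec"}.
#' @export
checkerboard_spec <- function(inner_rows, inner_cols, square_size) {
  if (inner_rows < 2 || inner_cols < 2)
    stop("need at least 2x2 inner corners", call. = FALSE)
  if (square_size <= 0) stop("square_size must be positive", call. = FALSE)
  structure(list(inner_rows = as.integer(inner_rows),
                 inner_cols = as.integer(inner_cols),
                 square_size = square_size),
            class = "checkerboard_spec")
}

#' Board-frame coordinates of the inner corners, row-major
#'
#' @param spec a \code{checkerboard_spec}.
#' @return n x 2 matrix (X, Y) in mm; the board lies in its z = 0 plane.
#' @export
board_points <- function(spec) {
  g <- expand.grid(X = (seq_len(spec$inner_cols) - 1) * spec$square_size,
                   Y = (seq_len(spec$inner_rows) - 1) * spec$square_size)
  ## expand.grid varies X fastest -> row-major (row = Y, col = X)
  cbind(X = g$X, Y = g$Y)
}

## ---- homography and closed-form intrinsics (Zhang) ----

#' Plane-to-image homography by normalized DLT
#' @keywords internal
homography_dlt <- function(obj, img) {
  n <- nrow(obj)
  norm2d <- function(p) {
    m <- colMeans(p)
    d <- mean(sqrt(rowSums((p - matrix(m, n, 2, byrow = TRUE))^2)))
    s <- sqrt(2) / d
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * m[1], -s * m[2], 1), 3, 3)
    list(T = T, p = cbind(p[, 1] * s - s * m[1], p[, 2] * s - s * m[2]))
  }
  no <- norm2d(obj); ni <- norm2d(img)
  x <- no$p[, 1]; y <- no$p[, 2]; u <- ni$p[, 1]; v <- ni$p[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  h <- svd(A, nu = 0)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(ni$T) %*% H %*% no$T
  H / H[3, 3]
}

#' Closed-form zero-skew intrinsics from a set of homographies
#' @keywords internal
intrinsics_from_homographies <- function(Hs) {
  vrow <- function(H, i, j) {
    h1 <- H[, i]; h2 <- H[, j]
    c(h1[1] * h2[1],
      h1[2] * h2[2],
      h1[3] * h2[1] + h1[1] * h2[3],
      h1[3] * h2[2] + h1[2] * h2[3],
      h1[3] * h2[3])
  }
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(vrow(H, 1, 2), vrow(H, 1, 1) - vrow(H, 2, 2))
  }))
  b <- svd(V, nu = 0)$v[, 5]
  if (b[1] < 0) b <- -b
  B11 <- b[1]; B22 <- b[2]; B13 <- b[3]; B23 <- b[4]; B33 <- b[5]
  cx <- -B13 / B11
  cy <- -B23 / B22
  lam <- B33 - (B13^2 / B11 + B23^2 / B22)
  if (lam / B11 <= 0 || lam / B22 <= 0)
    stop("degenerate geometry: closed-form intrinsics are not positive; ",
         "use more varied board orientations", call. = FALSE)
  camera_intrinsics(fx = sqrt(lam / B11), fy = sqrt(lam / B22),
                    cx = cx, cy = cy)
}

#' Board pose from its homography and known intrinsics
#' @keywords internal
pose_from_homography <- function(H, intr) {
  Kinv <- matrix(c(1 / intr$fx, 0, 0,
                   0, 1 / intr$fy, 0,
                   -intr$cx / intr$fx, -intr$cy / intr$fy, 1), 3, 3)
  A <- Kinv %*% H
  lam <- 1 / sqrt(sum(A[, 1]^2))
  if (A[3, 3] * lam < 0) lam <- -lam  # board must be in front of the camera
  r1 <- A[, 1] * lam; r2 <- A[, 2] * lam; t <- A[, 3] * lam
  R <- nearest_rotation(cbind(r1, r2, cross3(r1, r2)))
  camera_extrinsics(R, t)
}

## ---- parameter packing for LM refinement ----

#' @keywords internal
pack_pose <- function(extr) c(rvec_from_rotation(extr$R), extr$t)

#' @keywords internal
unpack_pose <- function(p) camera_extrinsics(rotation_from_rvec(p[1:3]), p[4:6])

#' @keywords internal
intr_from_par <- function(p)
  camera_intrinsics(p[1], p[2], p[3], p[4], p[5], p[6])

#' @keywords internal
par_from_intr <- function(k) c(k$fx, k$fy, k$cx, k$cy, k$k1, k$k2)

## ---- single-camera calibration ----

#' Calibrate one camera from checkerboard views
#'
#' Closed-form initialization of fx, fy, cx, cy from the inter-image
#' homographies (zero skew, k1 = k2 = 0), then joint Levenberg-Marquardt
#' refinement of the intrinsics, the two radial distortion coefficients and
#' all board poses, minimizing the reprojection error.
#'
#' @param views list of n x 2 matrices of detected corner pixel coordinates,
#'   each ordered row-major to match \code{\link{board_points}}.
#' @param spec a \code{checkerboard_spec}.
#' @return list with \code{intrinsics}, \code{poses} (per-view
#'   \code{camera_extrinsics}), \code{mean_reprojection_error} and
#'   \code{per_view_errors} (px), class \code{"camera_calibration"}.
#' @export
calibrate_camera <- function(views, spec) {
  if (length(views) < 3)
    stop("degenerate geometry: need at least 3 checkerboard views",
         call. = FALSE)
  bp <- board_points(spec)
  n_corners <- nrow(bp)
  for (v in views) {
    if (nrow(v) != n_corners)
      stop("corner count does not match the board spec", call. = FALSE)
  }
  Hs <- lapply(views, function(v) homography_dlt(bp, v))
  intr0 <- intrinsics_from_homographies(Hs)
  poses0 <- lapply(Hs, pose_from_homography, intr = intr0)

  bp3 <- cbind(bp, 0)
  obs <- do.call(rbind, views)
  par0 <- c(par_from_intr(intr0), unlist(lapply(poses0, pack_pose)))
  resid_fn <- function(par) {
    intr <- intr_from_par(par[1:6])
    res <- lapply(seq_along(views), function(i) {
      pose <- unpack_pose(par[6 + (i - 1) * 6 + 1:6])
      project_points(bp3, intr, pose)
    })
    as.numeric(do.call(rbind, res) - obs)
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-10, ptol = 1e-10))
  par <- fit$par
  intr <- intr_from_par(par[1:6])
  poses <- lapply(seq_along(views), function(i)
    unpack_pose(par[6 + (i - 1) * 6 + 1:6]))
  res <- matrix(resid_fn(par), ncol = 2)
  d <- sqrt(rowSums(res^2))
  per_view <- vapply(seq_along(views), function(i)
    mean(d[(i - 1) * n_corners + seq_len(n_corners)]), 0)
  structure(list(intrinsics = intr, poses = poses,
                 mean_reprojection_error = mean(d),
                 per_view_errors = per_view, spec = spec),
            class = "camera_calibration")
}

## ---- stereo calibration ----

#' Calibrate a stereo rig from paired checkerboard views
#'
#' Each camera is calibrated individually, the inter-camera pose is
#' initialized by rotation-averaging the per-view pose compositions, and all
#' parameters (both cameras' intrinsics and distortion, the relative pose,
#' and every board pose) are then refined jointly by Levenberg-Marquardt
#' bundle adjustment over the reprojection error in both cameras.
#'
#' The returned rig lives in the camera-1 frame (camera 1 at the identity
#' pose) with rectification transforms populated.
#'
#' @param views list of paired views, each a list with elements \code{cam1}
#'   and \code{cam2} holding n x 2 corner matrices in identical board order.
#' @param spec a \code{checkerboard_spec}.
#' @param optics optional \code{optics_config} stored on the rig.
#' @return an object of class \code{"stereo_calibration"} with fields
#'   \code{rig}, \code{mean_reprojection_error}, \code{per_view_errors},
#'   \code{poses} (board poses in the camera-1 frame) and \code{theta}
#'   (recovered vergence half-angle, degrees).
#' @export
calibrate_stereo <- function(views, spec, optics = optics_config()) {
  for (v in views) {
    if (is.null(v$cam1) || is.null(v$cam2))
      stop("inconsistent pairing: every view needs cam1 and cam2 corners",
           call. = FALSE)
    if (nrow(v$cam1) != nrow(v$cam2))
      stop("inconsistent pairing: corner counts differ between cameras",
           call. = FALSE)
  }
  cal1 <- calibrate_camera(lapply(views, `[[`, "cam1"), spec)
  cal2 <- calibrate_camera(lapply(views, `[[`, "cam2"), spec)

  ## relative pose from per-view composition, chordal rotation average
  Rsum <- matrix(0, 3, 3); tacc <- matrix(0, length(views), 3)
  for (i in seq_along(views)) {
    R1 <- cal1$poses[[i]]$R; t1 <- cal1$poses[[i]]$t
    R2 <- cal2$poses[[i]]$R; t2 <- cal2$poses[[i]]$t
    Rrel <- R2 %*% t(R1)
    Rsum <- Rsum + Rrel
    tacc[i, ] <- t2 - Rrel %*% t1
  }
  Rrel0 <- nearest_rotation(Rsum)
  trel0 <- colMeans(tacc)

  bp3 <- cbind(board_points(spec), 0)
  n_corners <- nrow(bp3)
  obs <- do.call(rbind, lapply(views, function(v) rbind(v$cam1, v$cam2)))
  par0 <- c(par_from_intr(cal1$intrinsics), par_from_intr(cal2$intrinsics),
            rvec_from_rotation(Rrel0), trel0,
            unlist(lapply(cal1$poses, pack_pose)))
  resid_fn <- function(par) {
    i1 <- intr_from_par(par[1:6]); i2 <- intr_from_par(par[7:12])
    Rr <- rotation_from_rvec(par[13:15]); tr <- par[16:18]
    res <- lapply(seq_along(views), function(i) {
      pose1 <- unpack_pose(par[18 + (i - 1) * 6 + 1:6])
      pose2 <- camera_extrinsics(nearest_rotation(Rr %*% pose1$R),
                                 as.numeric(Rr %*% pose1$t + tr))
      rbind(project_points(bp3, i1, pose1),
            project_points(bp3, i2, pose2))
    })
    as.numeric(do.call(rbind, res) - obs)
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-10, ptol = 1e-10))
  par <- fit$par
  i1 <- intr_from_par(par[1:6]); i2 <- intr_from_par(par[7:12])
  Rr <- rotation_from_rvec(par[13:15]); tr <- par[16:18]
  poses <- lapply(seq_along(views), function(i)
    unpack_pose(par[18 + (i - 1) * 6 + 1:6]))
  res <- matrix(resid_fn(par), ncol = 2)
  d <- sqrt(rowSums(res^2))
  per_view <- vapply(seq_along(views), function(i)
    mean(d[(i - 1) * 2 * n_corners + seq_len(2 * n_corners)]), 0)

  rig <- stereo_rig(
    cam1 = list(intrinsics = i1,
                extrinsics = camera_extrinsics(diag(3), c(0, 0, 0))),
    cam2 = list(intrinsics = i2, extrinsics = camera_extrinsics(Rr, tr)),
    theta = NA_real_, optics = optics)
  ## vergence half-angle from the angle between the two optical axes
  ct <- min(1, max(-1, sum(c(0, 0, 1) * Rr[3, ])))
  theta <- acos(ct) / 2 * 180 / pi
  rig$theta <- theta
  structure(list(rig = rig, theta = theta,
                 mean_reprojection_error = mean(d),
                 per_view_errors = per_view,
                 poses = poses, spec = spec,
                 n_views = length(views), n_corners = n_corners,
                 residuals = res),
            class = "stereo_calibration")
}

#' Mean reprojection error of a calibration against corner observations
#'
#' @param result a \code{stereo_calibration}.
#' @param views the paired corner views (as given to
#'   \code{\link{calibrate_stereo}}).
#' @return mean Euclidean pixel residual over all corners, views, cameras.
#' @export
reprojection_error <- function(result, views) {
  bp3 <- cbind(board_points(result$spec), 0)
  rig <- result$rig
  Rr <- rig$cam2$extrinsics$R; tr <- rig$cam2$extrinsics$t
  total <- 0; n <- 0
  for (i in seq_along(views)) {
    pose1 <- result$poses[[i]]
    pose2 <- camera_extrinsics(nearest_rotation(Rr %*% pose1$R),
                               as.numeric(Rr %*% pose1$t + tr))
    p1 <- project_points(bp3, rig$cam1$intrinsics, pose1)
    p2 <- project_points(bp3, rig$cam2$intrinsics, pose2)
    total <- total + sum(sqrt(rowSums((p1 - views[[i]]$cam1)^2))) +
      sum(sqrt(rowSums((p2 - views[[i]]$cam2)^2)))
    n <- n + 2 * nrow(bp3)
  }
  total / n
}

#' @export
print.stereo_calibration <- function(x, ...) {
  cat("Stereo calibration:", x$n_views, "views,", x$n_corners,
      "corners per view\n")
  cat(sprintf("  mean reprojection error: %.4f px\n",
              x$mean_reprojection_error))
  cat(sprintf("  vergence half-angle: %.3f deg, baseline %.2f mm\n",
              x$theta, x$rig$baseline))
  invisible(x)
}

#' @export
summary.stereo_calibration <- function(object, ...) {
  print(object)
  cat("  per-view mean errors (px):\n")
  print(round(object$per_view_errors, 4))
  cat("  camera intrinsics:\n")
  print(round(rbind(cam1 = stats::coef(object)[1:6],
                    cam2 = stats::coef(object)[7:12]), 4))
  invisible(object)
}

#' @export
coef.stereo_calibration <- function(object, ...) {
  k1 <- object$rig$cam1$intrinsics; k2 <- object$rig$cam2$intrinsics
  c(fx1 = k1$fx, fy1 = k1$fy, cx1 = k1$cx, cy1 = k1$cy,
    k1_1 = k1$k1, k2_1 = k1$k2,
    fx2 = k2$fx, fy2 = k2$fy, cx2 = k2$cx, cy2 = k2$cy,
    k1_2 = k2$k1, k2_2 = k2$k2)
}

#' @export
residuals.stereo_calibration <- function(object, ...) object$residuals

## ---- checkerboard corner detection ----

#' Detect ordered sub-pixel checkerboard corners in an image
#'
#' Corners are found as local maxima of the saddle response
#' \code{Ixy^2 - Ixx Iyy} of the Gaussian-smoothed image, refined to
#' sub-pixel precision by iterating the gradient-orthogonality condition
#' (every image gradient in a window around a saddle point is orthogonal
#' to its offset from the corner), and ordered row-major along the board
#' lattice with the first corner canonicalized to the one nearest the
#' image top-left.
#'
#' @param image numeric matrix (rows = v, cols = u).
#' @param spec a \code{checkerboard_spec}.
#' @param smooth_sigma Gaussian pre-smoothing sigma in px.
#' @return n x 2 matrix of 0-based (u, v) sub-pixel corner coordinates,
#'   row-major in board order.
#' @export
detect_corners <- function(image, spec, smooth_sigma = 1.0) {
  n_exp <- spec$inner_rows * spec$inner_cols
  g <- gaussian_blur(image, smooth_sigma)
  nr <- nrow(g); nc <- ncol(g)
  ## second derivatives by central differences
  Ixx <- g[, c(1, 1:(nc - 1))] - 2 * g + g[, c(2:nc, nc)]
  Iyy <- g[c(1, 1:(nr - 1)), ] - 2 * g + g[c(2:nr, nr), ]
  gx <- (g[, c(2:nc, nc)] - g[, c(1, 1:(nc - 1))]) / 2
  Ixy <- (gx[c(2:nr, nr), ] - gx[c(1, 1:(nr - 1)), ]) / 2
  resp <- Ixy^2 - Ixx * Iyy
  cand <- local_maxima(resp, threshold = 0)
  if (nrow(cand) < n_exp)
    stop("checkerboard corner detection failed: found ", nrow(cand),
         " of ", n_exp, " corners", call. = FALSE)
  ## keep candidates clearly above the weakest plausible true corner
  cand <- cand[cand$value >= 0.5 * cand$value[n_exp], , drop = FALSE]
  cand <- cand[seq_len(min(nrow(cand), 2L * n_exp)), , drop = FALSE]
  ## sub-pixel refinement by the gradient-orthogonality condition
  pts <- t(vapply(seq_len(nrow(cand)), function(i)
    refine_saddle(g, cand$u[i], cand$v[i]), c(0, 0)))
  ## if still more than expected, keep the strongest n_exp
  if (nrow(pts) > n_exp) pts <- pts[seq_len(n_exp), , drop = FALSE]
  ordered <- order_grid_corners(pts, spec)
  colnames(ordered) <- c("u", "v")
  ordered
}

#' Gradient-orthogonality sub-pixel corner refinement
#'
#' At a saddle corner every local image gradient is orthogonal to the
#' offset from the corner, so the corner solves the weighted normal
#' equations sum(w G) q = sum(w G p) with G the gradient outer product at
#' sample p. Iterated with window recentring until the update falls below
#' 1e-4 px.
#' @keywords internal
refine_saddle <- function(g, u, v, r = 4L, iters = 8L) {
  nr <- nrow(g); nc <- ncol(g)
  gx <- (g[, c(2:nc, nc)] - g[, c(1, 1:(nc - 1))]) / 2
  gy <- (g[c(2:nr, nr), ] - g[c(1, 1:(nr - 1)), ]) / 2
  off <- expand.grid(du = -r:r, dv = -r:r)
  w <- exp(-(off$du^2 + off$dv^2) / (2 * (r / 2)^2))
  q <- c(u, v)
  for (it in seq_len(iters)) {
    pu <- q[1] + off$du; pv <- q[2] + off$dv
    sgx <- bilinear_sample(gx, pu, pv)
    sgy <- bilinear_sample(gy, pu, pv)
    a11 <- sum(w * sgx^2); a12 <- sum(w * sgx * sgy); a22 <- sum(w * sgy^2)
    b1 <- sum(w * (sgx^2 * pu + sgx * sgy * pv))
    b2 <- sum(w * (sgx * sgy * pu + sgy^2 * pv))
    det <- a11 * a22 - a12^2
    if (abs(det) < 1e-12) break
    qn <- c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det
    step <- sqrt(sum((qn - q)^2))
    ## never leave the detection pixel's neighborhood
    qn <- pmin(pmax(qn, c(u, v) - r), c(u, v) + r)
    q <- qn
    if (step < 1e-4) break
  }
  q
}

#' Order detected lattice points row-major along the board axes
#' @keywords internal
order_grid_corners <- function(pts, spec) {
  n <- nrow(pts)
  ## two lattice directions from nearest-neighbor vectors
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  nnv <- pts[apply(D, 1, which.min), , drop = FALSE] - pts
  ang <- atan2(nnv[, 2], nnv[, 1]) %% pi
  a0 <- ang[1]
  dAng <- abs(((ang - a0 + pi / 2) %% pi) - pi / 2)
  fam1 <- dAng < pi / 6
  axis_of <- function(vv) {
    s <- svd(vv)$v[, 1]
    unit3(c(s, 0))[1:2]
  }
  ax1 <- axis_of(nnv[fam1, , drop = FALSE])
  ax2 <- if (any(!fam1)) axis_of(nnv[!fam1, , drop = FALSE]) else
    c(-ax1[2], ax1[1])
  try_orient <- function(row_axis, col_axis, nrow_g, ncol_g) {
    t <- pts %*% row_axis
    o <- order(t)
    rows <- split(o, rep(seq_len(nrow_g), each = ncol_g))
    ## validate: within-row spread along row_axis must be small vs row gaps
    centers <- vapply(rows, function(i) mean(t[i]), 0)
    spread <- vapply(rows, function(i) diff(range(t[i])), 0)
    gaps <- diff(sort(centers))
    if (length(gaps) && max(spread) > 0.6 * min(gaps)) return(NULL)
    idx <- unlist(lapply(rows, function(i) i[order(pts[i, ] %*% col_axis)]))
    matrix(pts[idx, ], ncol = 2)
  }
  res <- try_orient(ax2, ax1, spec$inner_rows, spec$inner_cols)
  if (is.null(res))
    res <- try_orient(ax1, ax2, spec$inner_rows, spec$inner_cols)
  if (is.null(res) && spec$inner_rows != spec$inner_cols) {
    res <- try_orient(ax2, ax1, spec$inner_cols, spec$inner_rows)
    if (!is.null(res)) {
      ## transpose the grid back to row-major in the requested shape
      m <- array(seq_len(n), c(spec$inner_rows, spec$inner_cols))
      res <- res[as.numeric(t(matrix(seq_len(n), spec$inner_cols,
                                     spec$inner_rows, byrow = TRUE))), ,
                 drop = FALSE]
    }
  }
  if (is.null(res))
    stop("checkerboard corner detection failed: candidates do not form a ",
         spec$inner_rows, "x", spec$inner_cols, " lattice", call. = FALSE)
  ## canonicalize: first corner nearest the image top-left
  grid <- array(seq_len(n), c(spec$inner_cols, spec$inner_rows))
  corner_ids <- c(grid[1, 1], grid[spec$inner_cols, 1],
                  grid[1, spec$inner_rows],
                  grid[spec$inner_cols, spec$inner_rows])
  scores <- rowSums(res[corner_ids, , drop = FALSE])
  k <- which.min(scores)
  flip_cols <- k %in% c(2, 4); flip_rows <- k %in% c(3, 4)
  idx <- matrix(seq_len(n), spec$inner_cols, spec$inner_rows)
  if (flip_cols) idx <- idx[rev(seq_len(spec$inner_cols)), , drop = FALSE]
  if (flip_rows) idx <- idx[, rev(seq_len(spec$inner_rows)), drop = FALSE]
  res[as.numeric(idx), , drop = FALSE]
}

## ---- corners CSV ----

#' Write detected corners to CSV
#'
#' Columns: view_id, camera_id, corner_index (0-based, row-major), u, v.
#' @param views paired views as for \code{\link{calibrate_stereo}}.
#' @param path output CSV path.
#' @param header optional comment lines.
#' @export
write_corners_csv <- function(views, path, header = NULL) {
  rows <- do.call(rbind, lapply(seq_along(views), function(i) {
    do.call(rbind, lapply(1:2, function(camid) {
      m <- views[[i]][[paste0("cam", camid)]]
      data.frame(view_id = i, camera_id = camid,
                 corner_index = seq_len(nrow(m)) - 1L,
                 u = m[, 1], v = m[, 2])
    }))
  }))
  write_table_csv(rows, path, header)
}

#' Read corners CSV back into paired views
#' @param path CSV written by \code{\link{write_corners_csv}}.
#' @return list of paired views.
#' @export
read_corners_csv <- function(path) {
  df <- read_table_csv(path)
  lapply(sort(unique(df$view_id)), function(i) {
    one <- function(camid) {
      d <- df[df$view_id == i & df$camera_id == camid, ]
      d <- d[order(d$corner_index), ]
      cbind(u = d$u, v = d$v)
    }
    list(cam1 = one(1), cam2 = one(2))
  })
}
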