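## Camera geometry: pinhole projection with two-coefficient radial distortion,
## undistortion, stereo rectification, ray-midpoint triangulation, and the
## refractive-index depth correction.
##
## Conventions used throughout the package:
##   * Pixel coordinates are 0-based with pixel centers at integer positions;
##     u is the column (horizontal) coordinate, v the row (vertical).
##   * World coordinates are in mm. The default world frame has its origin at
##     the intersection of the two optical axes (the nominal focal plane),
##     z pointing away from the cameras along the bisector of the two axes
##     (i.e. z increases with depth into the sample), and x horizontal along
##     the baseline direction.
##   * Extrinsics map world to camera: X_cam = R %*% X_world + t.

#' Camera intrinsics with two-coefficient radial distortion
#'
#' A minimal pinhole model: focal lengths \code{fx}, \code{fy} and principal
#' point \code{cx}, \code{cy} in pixels, skew fixed at zero, and radial
#' distortion \code{(1 + k1 r^2 + k2 r^4)} applied to the normalized image
#' coordinates.
#'
#' @param fx,fy focal lengths in pixels (must be > 0).
#' @param cx,cy principal point in pixels (0-based).
#' @param k1,k2 radial distortion coefficients (dimensionless).
#' @param sensor_size integer length-2, sensor width and height in pixels;
#'   used only to validate that the principal point lies on the sensor.
#' @return an object of class \code{"camera_intrinsics"}.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, k1 = 0, k2 = 0,
                              sensor_size = NULL) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive", call. = FALSE)
  if (!is.null(sensor_size)) {
    if (cx < 0 || cx > sensor_size[1] - 1 || cy < 0 || cy > sensor_size[2] - 1)
      stop("principal point lies outside the sensor", call. = FALSE)
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, k1 = k1, k2 = k2),
            class = "camera_intrinsics")
}

#' Camera extrinsics (world-to-camera rigid transform)
#'
#' @param R 3x3 rotation mapping world to camera coordinates
#'   (orthonormal, det +1, checked to 1e-9).
#' @param t length-3 translation in mm; \code{X_cam = R X_world + t}.
#' @return an object of class \code{"camera_extrinsics"}.
#' @export
camera_extrinsics <- function(R, t) {
  assert_rotation(R)
  structure(list(R = R, t = as.numeric(t)), class = "camera_extrinsics")
}

#' Optical center of a camera in world coordinates
#' @param extr a \code{camera_extrinsics} object.
#' @return length-3 numeric, mm.
#' @export
camera_center <- function(extr) as.numeric(-t(extr$R) %*% extr$t)

#' Optics configuration of the detection path
#'
#' Defaults follow a x0.37-magnification SWIR detection module with 15 um
#' sensor pixel pitch on a 640x512 sensor, so one sensor pixel corresponds to
#' \code{15 / 0.37 = 40.5} um in the object plane.
#'
#' @param magnification dimensionless detection magnification.
#' @param pixel_pitch sensor pixel pitch in um.
#' @param sensor_size integer length-2, width x height in pixels.
#' @return an object of class \code{"optics_config"} with the derived
#'   \code{object_pixel} (um in the object plane) field.
#' @export
optics_config <- function(magnification = 0.37, pixel_pitch = 15,
                          sensor_size = c(640L, 512L)) {
  if (magnification <= 0 || pixel_pitch <= 0)
    stop("magnification and pixel_pitch must be positive", call. = FALSE)
  structure(list(magnification = magnification,
                 pixel_pitch = pixel_pitch,
                 sensor_size = as.integer(sensor_size),
                 object_pixel = pixel_pitch / magnification),
            class = "optics_config")
}

#' Immersion medium configuration for refractive depth correction
#'
#' @param refractive_index medium refractive index (>= 1; water 1.33).
#' @param interface_z world z of the flat air/medium boundary, mm.
#' @return an object of class \code{"medium_config"}.
#' @export
medium_config <- function(refractive_index = 1.33, interface_z = 0) {
  if (refractive_index < 1)
    stop("refractive_index must be >= 1", call. = FALSE)
  structure(list(refractive_index = refractive_index,
                 interface_z = interface_z),
            class = "medium_config")
}

#' Assemble a stereo rig from two calibrated cameras
#'
#' @param cam1,cam2 lists with fields \code{intrinsics}
#'   (\code{camera_intrinsics}) and \code{extrinsics}
#'   (\code{camera_extrinsics}).
#' @param theta nominal vergence half-angle in degrees (metadata; the
#'   geometry is carried entirely by the extrinsics).
#' @param optics an \code{optics_config}.
#' @param rectify if TRUE (default) the rectification transforms are
#'   computed immediately via \code{\link{rectify_rig}}.
#' @return an object of class \code{"stereo_rig"}.
#' @export
stereo_rig <- function(cam1, cam2, theta = 20, optics = optics_config(),
                       rectify = TRUE) {
  rig <- structure(list(cam1 = cam1, cam2 = cam2, theta = theta,
                        optics = optics,
                        rect1 = NULL, rect2 = NULL, rect_intrinsics = NULL),
                   class = "stereo_rig")
  if (rectify) rig <- rectify_rig(rig)
  rig
}

#' Build the canonical symmetric vergence rig
#'
#' Constructs the dual-view geometry used throughout: two identical cameras
#' whose optical axes lie in the world x-z plane, tilted symmetrically by
#' \code{+/- theta} degrees about the world y axis, both aimed at the world
#' origin from a distance \code{working_distance}. With the default optics
#' this reproduces the disparity/depth sensitivity
#' \code{d(disparity)/dz = 2 sin(theta) / object_pixel}.
#'
#' @param theta vergence half-angle in degrees.
#' @param optics an \code{optics_config}.
#' @param working_distance camera-center-to-origin distance in mm. The
#'   default 185 mm corresponds to a 50 mm lens at x0.37 magnification.
#' @param k1,k2 length-2 radial distortion coefficients (camera 1, camera 2).
#' @return a rectified \code{"stereo_rig"}.
#' @export
make_stereo_rig <- function(theta = 20, optics = optics_config(),
                            working_distance = 185,
                            k1 = c(0, 0), k2 = c(0, 0)) {
  f_px <- optics$magnification * working_distance / (optics$pixel_pitch / 1000)
  cx <- (optics$sensor_size[1] - 1) / 2
  cy <- (optics$sensor_size[2] - 1) / 2
  th <- theta * pi / 180
  mk <- function(s, k1c, k2c) {
    ## viewing direction (world): tilted from +z by s*theta about y
    zc <- c(s * sin(th), 0, cos(th))
    yc <- c(0, 1, 0)
    xc <- cross3(yc, zc)
    R <- rbind(xc, yc, zc)
    dimnames(R) <- NULL
    C <- -working_distance * zc
    list(intrinsics = camera_intrinsics(f_px, f_px, cx, cy, k1c, k2c,
                                        optics$sensor_size),
         extrinsics = camera_extrinsics(R, as.numeric(-R %*% C)))
  }
  stereo_rig(mk(-1, k1[1], k2[1]), mk(+1, k1[2], k2[2]),
             theta = theta, optics = optics)
}

#' Project world points through a camera model
#'
#' Pinhole projection of the normalized camera-frame coordinates, radially
#' distorted by \code{(1 + k1 r^2 + k2 r^4)}, then mapped through the focal
#' lengths and principal point.
#'
#' @param X numeric n x 3 matrix (or length-3 vector) of world points, mm.
#' @param intr a \code{camera_intrinsics}.
#' @param extr a \code{camera_extrinsics}.
#' @return n x 2 matrix of pixel coordinates (u, v), 0-based.
#' @export
project_points <- function(X, intr, extr) {
  X <- rbind3(X)
  Xc <- X %*% t(extr$R) + matrix(extr$t, nrow(X), 3, byrow = TRUE)
  if (any(Xc[, 3] <= 0))
    stop("point at or behind the camera plane (camera-frame Z <= 0)",
         call. = FALSE)
  xn <- Xc[, 1] / Xc[, 3]
  yn <- Xc[, 2] / Xc[, 3]
  r2 <- xn^2 + yn^2
  d <- 1 + intr$k1 * r2 + intr$k2 * r2^2
  cbind(u = intr$fx * xn * d + intr$cx,
        v = intr$fy * yn * d + intr$cy)
}

## coerce a vector / data.frame to an n x 3 numeric matrix
#' @keywords internal
rbind3 <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, 1)
  storage.mode(X) <- "double"
  X
}

#' Undistort pixel coordinates to normalized camera coordinates
#'
#' Inverts the radial distortion model by damped fixed-point iteration
#' (max 50 iterations, tolerance 1e-10 normalized units) and removes the
#' focal/principal-point mapping.
#'
#' @param points n x 2 matrix of pixel coordinates (u, v).
#' @param intr a \code{camera_intrinsics}.
#' @param sensor_size optional length-2; out-of-bounds points trigger a
#'   warning but are still processed.
#' @return n x 2 matrix of undistorted normalized coordinates (x, y).
#' @export
undistort_points <- function(points, intr, sensor_size = NULL) {
  p <- rbind2cols(points)
  if (!is.null(sensor_size)) {
    oob <- p[, 1] < 0 | p[, 1] > sensor_size[1] - 1 |
      p[, 2] < 0 | p[, 2] > sensor_size[2] - 1
    if (any(oob))
      warning(sum(oob), " point(s) outside the sensor bounds")
  }
  xd <- (p[, 1] - intr$cx) / intr$fx
  yd <- (p[, 2] - intr$cy) / intr$fy
  x <- xd; y <- yd
  if (intr$k1 != 0 || intr$k2 != 0) {
    converged <- FALSE
    for (it in seq_len(50L)) {
      r2 <- x^2 + y^2
      d <- 1 + intr$k1 * r2 + intr$k2 * r2^2
      xn <- xd / d; yn <- yd / d
      step <- max(abs(xn - x), abs(yn - y))
      ## mild damping keeps the iteration stable for strong distortion
      x <- x + 0.9 * (xn - x); y <- y + 0.9 * (yn - y)
      if (step < 1e-10) { converged <- TRUE; break }
    }
    if (!converged) {
      i <- which.max(abs(xd / (1 + intr$k1 * (x^2 + y^2) +
                                 intr$k2 * (x^2 + y^2)^2) - x))
      stop(sprintf(
        "undistortion did not converge for point %d at (%.2f, %.2f)",
        i, p[i, 1], p[i, 2]), call. = FALSE)
    }
  }
  cbind(x = x, y = y)
}

#' @keywords internal
rbind2cols <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) p <- matrix(p, 1)
  storage.mode(p) <- "double"
  p
}

#' Compute stereo rectification transforms for a rig
#'
#' Rotates both cameras to a common orientation whose x-axis lies along the
#' baseline and whose z-axis is the (orthogonalized) mean viewing direction.
#' Because both new axes are orthogonal to the baseline, the rectified
#' projections of any world point share the vertical coordinate exactly
#' (noiseless), reducing stereo matching to a 1D search in u.
#'
#' @param rig a \code{stereo_rig}.
#' @return the rig with \code{rect1}, \code{rect2} (rotations applied to
#'   camera-frame directions) and \code{rect_intrinsics} populated.
#' @export
rectify_rig <- function(rig) {
  C1 <- camera_center(rig$cam1$extrinsics)
  C2 <- camera_center(rig$cam2$extrinsics)
  b <- C2 - C1
  bl <- sqrt(sum(b^2))
  if (bl < 1e-9) stop("zero baseline: cameras are coincident", call. = FALSE)
  e1 <- b / bl
  ## keep e1 roughly aligned with camera 1's x-axis so disparity keeps sign
  if (sum(e1 * rig$cam1$extrinsics$R[1, ]) < 0) e1 <- -e1
  z1 <- rig$cam1$extrinsics$R[3, ]
  z2 <- rig$cam2$extrinsics$R[3, ]
  za <- unit3(z1 + z2)
  e3 <- unit3(za - sum(za * e1) * e1)
  e2 <- cross3(e3, e1)
  Rnew <- rbind(e1, e2, e3)
  dimnames(Rnew) <- NULL
  i1 <- rig$cam1$intrinsics; i2 <- rig$cam2$intrinsics
  rig$rect1 <- Rnew %*% t(rig$cam1$extrinsics$R)
  rig$rect2 <- Rnew %*% t(rig$cam2$extrinsics$R)
  rig$rect_intrinsics <- camera_intrinsics(
    fx = mean(c(i1$fx, i1$fy, i2$fx, i2$fy)),
    fy = mean(c(i1$fx, i1$fy, i2$fx, i2$fy)),
    cx = mean(c(i1$cx, i2$cx)), cy = mean(c(i1$cy, i2$cy)))
  rig$baseline <- bl
  rig
}

#' Map pixel detections into the rectified frames
#'
#' Undistorts pixel coordinates and reprojects them through the
#' rectification rotation into the shared rectified pinhole model.
#'
#' @param points n x 2 pixel coordinates in camera \code{cam}.
#' @param rig a rectified \code{stereo_rig}.
#' @param cam 1 or 2.
#' @return n x 2 matrix of rectified pixel coordinates (u, v).
#' @export
rectified_coords <- function(points, rig, cam = 1) {
  stopifnot(!is.null(rig$rect1))
  camrec <- if (cam == 1) rig$cam1 else rig$cam2
  Rr <- if (cam == 1) rig$rect1 else rig$rect2
  n <- undistort_points(points, camrec$intrinsics)
  dirs <- cbind(n[, 1], n[, 2], 1) %*% t(Rr)
  ri <- rig$rect_intrinsics
  cbind(u = ri$fx * dirs[, 1] / dirs[, 3] + ri$cx,
        v = ri$fy * dirs[, 2] / dirs[, 3] + ri$cy)
}

#' Project world points directly into a rectified view (noise-free helper)
#' @keywords internal
rectified_project <- function(X, rig, cam = 1) {
  p <- project_points(X,
                      if (cam == 1) rig$cam1$intrinsics else rig$cam2$intrinsics,
                      if (cam == 1) rig$cam1$extrinsics else rig$cam2$extrinsics)
  rectified_coords(p, rig, cam)
}

#' Triangulate corresponding undistorted points to a world point
#'
#' Back-projects each undistorted normalized point as a ray from its camera
#' center and returns the midpoint of the shortest segment joining the two
#' rays, together with the segment length (ray gap) as a quality metric.
#'
#' @param p1,p2 n x 2 matrices of undistorted normalized coordinates in
#'   camera 1 and camera 2.
#' @param rig a \code{stereo_rig}.
#' @return list with \code{points} (n x 3 world mm) and \code{ray_gap}
#'   (length-n, mm).
#' @export
triangulate <- function(p1, p2, rig) {
  p1 <- rbind2cols(p1); p2 <- rbind2cols(p2)
  R1 <- rig$cam1$extrinsics$R; R2 <- rig$cam2$extrinsics$R
  C1 <- camera_center(rig$cam1$extrinsics)
  C2 <- camera_center(rig$cam2$extrinsics)
  d1 <- cbind(p1[, 1], p1[, 2], 1) %*% R1  # rows: R1^T %*% (x, y, 1)
  d2 <- cbind(p2[, 1], p2[, 2], 1) %*% R2
  w0 <- matrix(C1 - C2, nrow(d1), 3, byrow = TRUE)
  a <- rowSums(d1 * d1); bb <- rowSums(d1 * d2); cc <- rowSums(d2 * d2)
  dd <- rowSums(d1 * w0); ee <- rowSums(d2 * w0)
  den <- a * cc - bb^2
  bad <- den < 1e-12 * a * cc
  if (any(bad))
    stop("near-parallel rays for ", sum(bad), " correspondence(s)",
         call. = FALSE)
  s <- (bb * ee - cc * dd) / den
  t <- (a * ee - bb * dd) / den
  P1 <- matrix(C1, nrow(d1), 3, byrow = TRUE) + d1 * s
  P2 <- matrix(C2, nrow(d1), 3, byrow = TRUE) + d2 * t
  gap <- sqrt(rowSums((P1 - P2)^2))
  X <- (P1 + P2) / 2
  colnames(X) <- c("x", "y", "z")
  list(points = X, ray_gap = gap)
}

#' Rescale apparent depth below a flat refractive interface
#'
#' Stereo triangulation through a flat air/medium interface compresses the
#' apparent depth by the medium's refractive index; the depth extent below
#' the interface is therefore multiplied by n (1.33 for water). Lateral
#' coordinates and points above the interface are returned unchanged.
#'
#' @param x either a numeric vector of z coordinates / z extents (mm) or an
#'   n x 3 matrix of world points.
#' @param medium a \code{medium_config}.
#' @return same shape as \code{x}, corrected.
#' @export
correct_refraction <- function(x, medium) {
  n <- medium$refractive_index; z0 <- medium$interface_z
  fix <- function(z) ifelse(z > z0, z0 + n * (z - z0), z)
  if (is.matrix(x) || is.data.frame(x)) {
    x <- rbind3(x)
    x[, 3] <- fix(x[, 3])
    x
  } else fix(x)
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat("Stereo rig (vergence half-angle ", x$theta, " deg)\n", sep = "")
  for (i in 1:2) {
    cam <- if (i == 1) x$cam1 else x$cam2
    k <- cam$intrinsics
    cat(sprintf("  cam%d: fx=%.1f fy=%.1f cx=%.1f cy=%.1f k1=%.4g k2=%.4g\n",
                i, k$fx, k$fy, k$cx, k$cy, k$k1, k$k2))
  }
  if (!is.null(x$baseline))
    cat(sprintf("  baseline: %.2f mm; rectified\n", x$baseline))
  invisible(x)
}

#' Write a stereo rig to a plain-text key-value file
#'
#' Schema: per camera \code{camN.fx fy cx cy k1 k2}, \code{camN.R} as nine
#' numbers row-major, \code{camN.t} in mm; plus \code{theta} and the optics
#' fields. Readable back with \code{\link{read_rig}}.
#'
#' @param rig a \code{stereo_rig}.
#' @param path output file path.
#' @export
write_rig <- function(rig, path) {
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(paste("theta", num(rig$theta)),
             paste("optics.magnification", num(rig$optics$magnification)),
             paste("optics.pixel_pitch", num(rig$optics$pixel_pitch)),
             paste("optics.sensor_size", num(rig$optics$sensor_size)))
  for (i in 1:2) {
    cam <- if (i == 1) rig$cam1 else rig$cam2
    k <- cam$intrinsics; e <- cam$extrinsics
    pre <- paste0("cam", i, ".")
    lines <- c(lines,
               paste0(pre, "fx ", num(k$fx)), paste0(pre, "fy ", num(k$fy)),
               paste0(pre, "cx ", num(k$cx)), paste0(pre, "cy ", num(k$cy)),
               paste0(pre, "k1 ", num(k$k1)), paste0(pre, "k2 ", num(k$k2)),
               paste0(pre, "R ", num(as.numeric(t(e$R)))),
               paste0(pre, "t ", num(e$t)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a stereo rig from its key-value file
#' @param path file written by \code{\link{write_rig}}.
#' @return a rectified \code{"stereo_rig"}.
#' @export
read_rig <- function(path) {
  kv <- read_keyvalue(path)
  g <- function(key) as.numeric(strsplit(trimws(kv[[key]]), "\\s+")[[1]])
  cam <- function(i) {
    pre <- paste0("cam", i, ".")
    list(intrinsics = camera_intrinsics(g(paste0(pre, "fx")),
                                        g(paste0(pre, "fy")),
                                        g(paste0(pre, "cx")),
                                        g(paste0(pre, "cy")),
                                        g(paste0(pre, "k1")),
                                        g(paste0(pre, "k2"))),
         extrinsics = camera_extrinsics(
           matrix(g(paste0(pre, "R")), 3, 3, byrow = TRUE),
           g(paste0(pre, "t"))))
  }
  optics <- optics_config(g("optics.magnification"),
                          g("optics.pixel_pitch"),
                          g("optics.sensor_size"))
  stereo_rig(cam(1), cam(2), theta = g("theta"), optics = optics)
}
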