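## Synthetic dual-view scene simulator with exact ground truth: static
## droplets, axially scanned checkerboards, tilted-tube and knot phantoms,
## and a cortical vessel network with flowing droplets, rendered through the
## full camera model with depth-dependent PSF broadening, signal attenuation,
## Poisson shot noise and Gaussian read noise.

#' Run code with a locally scoped RNG seed
#'
#' Sets the seed, runs \code{expr}, and restores the previous RNG state so
#' simulation calls are reproducible without disturbing the caller's RNG.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Depth-dependent PSF broadening and attenuation in scattering media
#'
#' The imaged spot sigma grows linearly with depth below the interface,
#' \code{sigma(z) = sigma0 (1 + beta (z - interface))}, and the detected
#' amplitude decays exponentially, \code{exp(-mu (z - interface))}. The
#' surface sigma defaults to the diffraction limit of the detection path
#' (FWHM 27.7 um) expressed as a Gaussian sigma.
#'
#' @param sigma0_um surface PSF sigma, um in the object plane.
#' @param beta_per_mm fractional sigma growth per mm of depth.
#' @param mu_per_mm amplitude attenuation coefficient per mm of depth.
#' @param interface_z world z of the medium surface, mm.
#' @return an object of class \code{"scattering_model"} with functions
#'   \code{sigma_um(z)} and \code{attenuation(z)}.
#' @export
scattering_model <- function(sigma0_um = 27.7 / (2 * sqrt(2 * log(2))),
                             beta_per_mm = 1.0, mu_per_mm = 0.55,
                             interface_z = 0) {
  force(sigma0_um); force(beta_per_mm); force(mu_per_mm); force(interface_z)
  structure(list(
    sigma0_um = sigma0_um, beta_per_mm = beta_per_mm,
    mu_per_mm = mu_per_mm, interface_z = interface_z,
    sigma_um = function(z) sigma0_um * (1 + beta_per_mm *
                                          pmax(z - interface_z, 0)),
    attenuation = function(z) exp(-mu_per_mm * pmax(z - interface_z, 0))),
    class = "scattering_model")
}

#' Flow specification for droplet injection
#'
#' Droplet diameters follow a lognormal law matching the measured
#' micro-droplet size distribution (mean 4.73 um, SD 2.25 um); brightness
#' scales with droplet volume (diameter cubed).
#'
#' @param speed flow speed along the centerline, mm/s (phantom range 2-4).
#' @param rate droplet arrival rate per second (whole scene).
#' @param diameter_mean,diameter_sd mean and SD of the droplet diameter, um.
#' @param photons expected integrated signal (counts) of a mean-diameter
#'   droplet at the surface.
#' @return an object of class \code{"flow_spec"}.
#' @export
flow_spec <- function(speed = 3, rate = 2, diameter_mean = 4.73,
                      diameter_sd = 2.25, photons = 20000) {
  if (speed <= 0 || rate < 0) stop("invalid flow parameters", call. = FALSE)
  cv2 <- (diameter_sd / diameter_mean)^2
  structure(list(speed = speed, rate = rate,
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 meanlog = log(diameter_mean) - log(1 + cv2) / 2,
                 sdlog = sqrt(log(1 + cv2)),
                 photons = photons),
            class = "flow_spec")
}

#' Scene specification
#'
#' @param variant one of "static_point", "checkerboard_scan",
#'   "tilted_tube", "knot", "vessel_network".
#' @param ... variant-specific geometry parameters (see
#'   \code{\link{build_scene}}).
#' @return an object of class \code{"scene_spec"}.
#' @export
scene_spec <- function(variant = c("static_point", "checkerboard_scan",
                                   "tilted_tube", "knot", "vessel_network"),
                       ...) {
  variant <- match.arg(variant)
  structure(c(list(variant = variant), list(...)), class = "scene_spec")
}

## resample a polyline to fine, arc-length-parameterized form
#' @keywords internal
make_centerline <- function(points, label = "", step_mm = 0.005,
                            lumen_radius_mm = 0) {
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  ss <- seq(0, L, by = step_mm)
  if (ss[length(ss)] < L) ss <- c(ss, L)
  P <- cbind(stats::approx(s, points[, 1], ss)$y,
             stats::approx(s, points[, 2], ss)$y,
             stats::approx(s, points[, 3], ss)$y)
  structure(list(points = P, s = ss, length = L, label = label,
                 lumen_radius = lumen_radius_mm),
            class = "centerline")
}

#' Unit tangent of a centerline at arc length(s)
#' @keywords internal
centerline_tangent <- function(cl, s) {
  d <- 0.01
  P0 <- centerline_at(cl, pmax(s - d, 0))
  P1 <- centerline_at(cl, pmin(s + d, cl$length))
  T <- P1 - P0
  T / pmax(sqrt(rowSums(T^2)), 1e-12)
}

#' Position along a centerline at given arc length(s)
#' @keywords internal
centerline_at <- function(cl, s) {
  cbind(stats::approx(cl$s, cl$points[, 1], s, rule = 2)$y,
        stats::approx(cl$s, cl$points[, 2], s, rule = 2)$y,
        stats::approx(cl$s, cl$points[, 3], s, rule = 2)$y)
}

#' Build the parametric geometry of a scene
#'
#' Variants:
#' \describe{
#'   \item{static_point}{a single immobile droplet at \code{position}
#'     (default origin).}
#'   \item{checkerboard_scan}{a planar grid of checkerboard corners
#'     (default 6x9 squares of 1.34 mm) translated axially in
#'     \code{z_step_um} steps (default 5) over \code{z_range_mm}
#'     (default 3).}
#'   \item{tilted_tube}{a straight tube whose depth increases with a
#'     constant gradient \code{dz_dy} (default 0.5) along y over
#'     \code{length_mm} (default 4).}
#'   \item{knot}{two crossing circular arcs whose centerlines are
#'     separated axially by \code{separation_um} (default 231, the tube
#'     outer diameter) at \code{depth_mm} (default 2).}
#'   \item{vessel_network}{surface vessels following a spherical-cap
#'     cortex (radius \code{cap_radius_mm}, default 5) plus descending and
#'     ascending penetrating vessels reaching \code{penetration_um}
#'     (default 600) below the local surface.}
#' }
#'
#' @param spec a \code{scene_spec}.
#' @param volume optional shared-volume bounds (list with \code{min},
#'   \code{max} length-3 mm); geometry outside raises an error.
#' @return an object of class \code{"scene_geometry"} with fields
#'   \code{variant}, \code{centerlines} (list of arc-length parameterized
#'   polylines) and variant extras.
#' @export
build_scene <- function(spec, volume = NULL) {
  g <- switch(spec$variant,
    static_point = {
      pos <- spec$position %||% c(0, 0, 0)
      list(variant = "static_point", position = pos, centerlines = list())
    },
    checkerboard_scan = {
      board <- spec$board %||% checkerboard_spec(5, 8, 1.34)
      z_step <- (spec$z_step_um %||% 5) / 1000
      z_range <- spec$z_range_mm %||% 3
      zs <- seq(0, z_range, by = z_step) - z_range / 2
      bp <- board_points(board)
      bp <- bp - matrix(colMeans(bp), nrow(bp), 2, byrow = TRUE)
      list(variant = "checkerboard_scan", board = board, corners_xy = bp,
           z_layers = zs, centerlines = list())
    },
    tilted_tube = {
      len <- spec$length_mm %||% 4
      grad <- spec$dz_dy %||% 0.5
      z0 <- spec$z_start %||% 0
      lum <- (spec$lumen_radius_um %||% 68.5) / 1000  # 137 um I.D.
      half <- len / 2
      pts <- rbind(c(0, -half, z0),
                   c(0, half, z0 + grad * 2 * half))
      list(variant = "tilted_tube", dz_dy = grad,
           centerlines = list(make_centerline(pts, "tube",
                                              lumen_radius_mm = lum)))
    },
    knot = {
      sep <- (spec$separation_um %||% 231) / 1000
      z0 <- spec$depth_mm %||% 2
      r <- spec$arc_radius_mm %||% 1
      ## arcs cross on the y = 0 line; keeping the mirror symmetry across
      ## the x axis (not y) avoids epipolar-degenerate droplet pairs that
      ## would share the same rectified v in both views
      th <- seq(-2 * pi / 3, 2 * pi / 3, length.out = 201)
      arc1 <- cbind(r * sin(th), -r / 2 + r * cos(th), z0)
      arc2 <- cbind(r * sin(th), r / 2 - r * cos(th), z0 + sep)
      lum <- (spec$lumen_radius_um %||% 68.5) / 1000
      list(variant = "knot", separation_mm = sep,
           centerlines = list(make_centerline(arc1, "arc1",
                                              lumen_radius_mm = lum),
                              make_centerline(arc2, "arc2",
                                              lumen_radius_mm = lum)))
    },
    vessel_network = {
      R <- spec$cap_radius_mm %||% 5
      z_apex <- spec$surface_z %||% 0
      depth <- (spec$penetration_um %||% 600) / 1000
      surf_z <- function(x, y) z_apex + R - sqrt(pmax(R^2 - x^2 - y^2, 0))
      cls <- list()
      ## two surface vessels following the cap curvature
      for (y0 in c(-0.5, 0.6)) {
        xx <- seq(-1.5, 1.5, length.out = 121)
        cls[[length(cls) + 1]] <- make_centerline(
          cbind(xx, y0 + 0.2 * sin(2 * xx), surf_z(xx, y0)), "surface",
          lumen_radius_mm = 0.02)
      }
      ## penetrating vessels: descending (flow +z) and ascending (flow -z)
      pen <- spec$penetrating %||% list(c(-0.8, -0.5), c(0.8, 0.6))
      for (i in seq_along(pen)) {
        x0 <- pen[[i]][1]; y0 <- pen[[i]][2]
        zs <- surf_z(x0, y0)
        seg <- rbind(c(x0, y0, zs), c(x0, y0, zs + depth))
        lbl <- if (i %% 2 == 1) "descending" else "ascending"
        if (lbl == "ascending") seg <- seg[2:1, , drop = FALSE]
        cls[[length(cls) + 1]] <- make_centerline(seg, lbl,
                                                  lumen_radius_mm = 0.02)
      }
      list(variant = "vessel_network", cap_radius = R,
           penetration_mm = depth, centerlines = cls)
    })
  if (!is.null(volume)) {
    allpts <- do.call(rbind, c(lapply(g$centerlines, `[[`, "points"),
                               list(if (!is.null(g$position))
                                 matrix(g$position, 1) else NULL)))
    if (!is.null(allpts) && nrow(allpts) &&
        (any(allpts < matrix(volume$min, nrow(allpts), 3, byrow = TRUE)) ||
         any(allpts > matrix(volume$max, nrow(allpts), 3, byrow = TRUE))))
      stop("scene geometry extends outside the shared volume", call. = FALSE)
  }
  structure(g, class = "scene_geometry")
}

#' Simulate droplet flow through a scene
#'
#' Droplets are spawned at the entry of each centerline as a Poisson
#' process, advected at constant speed along the centerline, and removed at
#' the exit. Frame positions are sampled at the exposure midpoint.
#' Reproducible for a fixed seed.
#'
#' @param scene a \code{scene_geometry}.
#' @param flow a \code{flow_spec}.
#' @param duration acquisition duration, s.
#' @param frame_rate frame rate, Hz.
#' @param seed RNG seed.
#' @return ground-truth data frame (frame, droplet_id, centerline,
#'   x, y, z mm, diameter um, intensity counts), class
#'   \code{"ground_truth"}; for static scenes the single droplet is present
#'   in every frame.
#' @export
simulate_flow <- function(scene, flow, duration, frame_rate, seed = 1) {
  n_frames <- max(1L, floor(duration * frame_rate))
  t_frames <- (seq_len(n_frames) - 0.5) / frame_rate
  if (scene$variant == "static_point") {
    gt <- data.frame(frame = seq_len(n_frames), droplet_id = 1L,
                     centerline = 0L,
                     x = scene$position[1], y = scene$position[2],
                     z = scene$position[3],
                     diameter = flow$diameter_mean, intensity = flow$photons)
    class(gt) <- c("ground_truth", "data.frame")
    return(gt)
  }
  ncl <- length(scene$centerlines)
  if (ncl == 0) stop("scene has no flow centerlines", call. = FALSE)
  gt <- with_seed(seed, {
    out <- list(); id <- 0L
    for (ci in seq_len(ncl)) {
      cl <- scene$centerlines[[ci]]
      n <- stats::rpois(1, flow$rate / ncl * duration)
      if (n == 0) next
      t0 <- sort(stats::runif(n, 0, duration))
      dia <- stats::rlnorm(n, flow$meanlog, flow$sdlog)
      ## fixed radial position of each droplet within the tube lumen
      rr <- cl$lumen_radius * sqrt(stats::runif(n))
      phi <- stats::runif(n, 0, 2 * pi)
      for (i in seq_len(n)) {
        id <- id + 1L
        s <- flow$speed * (t_frames - t0[i])
        in_tube <- s >= 0 & s <= cl$length
        if (!any(in_tube)) next
        P <- centerline_at(cl, s[in_tube])
        if (cl$lumen_radius > 0) {
          Tg <- centerline_tangent(cl, s[in_tube])
          ref <- if (abs(Tg[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
          n1 <- t(apply(Tg, 1, function(tv) unit3(cross3(tv, ref))))
          n2 <- t(vapply(seq_len(nrow(Tg)), function(j)
            cross3(Tg[j, ], n1[j, ]), c(0, 0, 0)))
          P <- P + rr[i] * (cos(phi[i]) * n1 + sin(phi[i]) * n2)
        }
        out[[length(out) + 1]] <- data.frame(
          frame = which(in_tube), droplet_id = id, centerline = ci,
          x = P[, 1], y = P[, 2], z = P[, 3],
          diameter = dia[i],
          intensity = flow$photons * (dia[i] / flow$diameter_mean)^3)
      }
    }
    do.call(rbind, out)
  })
  if (is.null(gt))
    gt <- data.frame(frame = integer(0), droplet_id = integer(0),
                     centerline = integer(0), x = numeric(0),
                     y = numeric(0), z = numeric(0), diameter = numeric(0),
                     intensity = numeric(0))
  attr(gt, "n_frames") <- n_frames
  attr(gt, "frame_rate") <- frame_rate
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

#' Certify per-frame sparsity of a ground truth for stereo matching
#'
#' A scene is "sparse" when no frame contains two droplets closer than
#' \code{y_threshold} in rectified v in either view, so the y-coordinate
#' matching rule cannot produce identity errors.
#'
#' @param truth a \code{ground_truth}.
#' @param rig a rectified \code{stereo_rig}.
#' @param y_threshold rectified px.
#' @return TRUE/FALSE.
#' @export
is_sparse_scene <- function(truth, rig, y_threshold = 1.0) {
  for (k in unique(truth$frame)) {
    fr <- truth[truth$frame == k, , drop = FALSE]
    if (nrow(fr) < 2) next
    X <- cbind(fr$x, fr$y, fr$z)
    for (cam in 1:2) {
      vr <- rectified_project(X, rig, cam)[, 2]
      if (min(stats::dist(vr)) < y_threshold) return(FALSE)
    }
  }
  TRUE
}

#' Render dual-view image stacks from ground truth
#'
#' Each droplet is projected through both camera models (including radial
#' distortion) and drawn as an isotropic 2D Gaussian whose object-plane
#' sigma follows the scattering model's depth broadening and whose
#' integrated signal is attenuated as \code{exp(-mu depth)}; a static
#' background is added, Poisson shot noise then Gaussian read noise are
#' applied, and frames are clipped to the 16-bit range.
#'
#' @param truth a \code{ground_truth}.
#' @param rig a \code{stereo_rig} (its \code{optics} defines sensor size
#'   and object-plane pixel pitch).
#' @param scattering a \code{scattering_model}.
#' @param background static background level, counts.
#' @param read_noise Gaussian read noise SD, counts.
#' @param sigma_floor_px minimum rendered sigma in px (default 0.8; keeps
#'   Gaussian fitting well-posed although the physical diffraction-limited
#'   spot is smaller than one object pixel). Set 0 for the physical mode.
#' @param noiseless if TRUE, skip shot and read noise (background still
#'   added).
#' @param seed RNG seed.
#' @param frame_rate,exposure,transfer_gap acquisition metadata stored on
#'   the stacks.
#' @return list of two \code{image_stack}s (camera 1, camera 2).
#' @export
render_stack <- function(truth, rig, scattering = scattering_model(),
                         background = 100, read_noise = 2,
                         sigma_floor_px = 0.8, noiseless = FALSE, seed = 1,
                         frame_rate = NULL, exposure = NULL,
                         transfer_gap = NULL) {
  n_frames <- attr(truth, "n_frames") %||%
    (if (nrow(truth)) max(truth$frame) else 1L)
  W <- rig$optics$sensor_size[1]; H <- rig$optics$sensor_size[2]
  obj_px <- rig$optics$object_pixel
  render_one <- function(cam) {
    intr <- if (cam == 1) rig$cam1$intrinsics else rig$cam2$intrinsics
    extr <- if (cam == 1) rig$cam1$extrinsics else rig$cam2$extrinsics
    frames <- array(background, c(H, W, n_frames))
    if (nrow(truth)) {
      uv <- project_points(cbind(truth$x, truth$y, truth$z), intr, extr)
      sig_px <- pmax(scattering$sigma_um(truth$z) / obj_px, sigma_floor_px)
      amp <- truth$intensity * scattering$attenuation(truth$z) /
        (2 * pi * sig_px^2)
      for (r in seq_len(nrow(truth))) {
        u0 <- uv[r, 1]; v0 <- uv[r, 2]; s <- sig_px[r]
        rad <- ceiling(4 * s)
        us <- max(0, floor(u0) - rad):min(W - 1, ceiling(u0) + rad)
        vs <- max(0, floor(v0) - rad):min(H - 1, ceiling(v0) + rad)
        if (!length(us) || !length(vs)) next
        gu <- exp(-(us - u0)^2 / (2 * s^2))
        gv <- exp(-(vs - v0)^2 / (2 * s^2))
        frames[vs + 1, us + 1, truth$frame[r]] <-
          frames[vs + 1, us + 1, truth$frame[r]] +
          amp[r] * (gv %o% gu)
      }
    }
    if (!noiseless) {
      frames[] <- stats::rpois(length(frames), lambda = frames) +
        stats::rnorm(length(frames), 0, read_noise)
    }
    frames[] <- round(pmin(pmax(frames, 0), 65535))
    sat <- mean(frames >= 65535)
    if (sat > 0.1)
      warning(sprintf("%.1f%% of pixels saturated", 100 * sat))
    image_stack(frames, frame_rate = frame_rate, exposure = exposure,
                transfer_gap = transfer_gap, camera_id = cam)
  }
  with_seed(seed, list(render_one(1), render_one(2)))
}

#' Analytic checkerboard corner projections for calibration experiments
#'
#' Projects the board's inner corners through the full distortion model of
#' both cameras for every requested pose and adds Gaussian pixel noise:
#' the synthetic counterpart of running a corner detector on recorded
#' calibration images.
#'
#' @param spec a \code{checkerboard_spec}.
#' @param poses list of board placements in the world frame, each a list
#'   with rotation \code{R} and translation \code{t} (board frame to
#'   world).
#' @param rig the ground-truth \code{stereo_rig}.
#' @param noise_sd corner noise SD, px (0 = analytic projections).
#' @param seed RNG seed.
#' @return list of paired views (\code{cam1}, \code{cam2} corner matrices
#'   plus the true world corners in \code{truth}).
#' @export
render_checkerboard_views <- function(spec, poses, rig, noise_sd = 0,
                                      seed = 1) {
  bp <- cbind(board_points(spec), 0)
  W <- rig$optics$sensor_size[1]; H <- rig$optics$sensor_size[2]
  with_seed(seed, lapply(seq_along(poses), function(i) {
    po <- poses[[i]]
    Xw <- bp %*% t(po$R) + matrix(po$t, nrow(bp), 3, byrow = TRUE)
    p1 <- project_points(Xw, rig$cam1$intrinsics, rig$cam1$extrinsics)
    p2 <- project_points(Xw, rig$cam2$intrinsics, rig$cam2$extrinsics)
    inview <- function(p) all(p[, 1] >= 0 & p[, 1] <= W - 1 &
                                p[, 2] >= 0 & p[, 2] <= H - 1)
    if (!inview(p1) || !inview(p2))
      stop("board out of view for pose ", i, call. = FALSE)
    if (noise_sd > 0) {
      p1 <- p1 + matrix(stats::rnorm(length(p1), 0, noise_sd), nrow(p1))
      p2 <- p2 + matrix(stats::rnorm(length(p2), 0, noise_sd), nrow(p2))
    }
    list(cam1 = p1, cam2 = p2, truth = Xw)
  }))
}

#' Random calibration board poses filling the shared volume
#'
#' Generates gently tilted, laterally shifted board placements such as an
#' operator would record for stereo calibration.
#'
#' @param n number of poses.
#' @param spec a \code{checkerboard_spec} (used to centre the board).
#' @param seed RNG seed.
#' @param max_tilt_deg maximum tilt about x/y, degrees.
#' @param lateral_mm maximum lateral offset, mm.
#' @param z_range_mm depth range of the board centre, mm.
#' @return list of poses for \code{\link{render_checkerboard_views}}.
#' @export
make_board_poses <- function(n, spec, seed = 1, max_tilt_deg = 20,
                             lateral_mm = 5, z_range_mm = 2) {
  bp <- board_points(spec)
  center <- c(colMeans(bp), 0)
  with_seed(seed, lapply(seq_len(n), function(i) {
    ang <- stats::runif(3, -1, 1) *
      c(max_tilt_deg, max_tilt_deg, 180) * pi / 180
    R <- rotation_from_rvec(c(ang[1], 0, 0)) %*%
      rotation_from_rvec(c(0, ang[2], 0)) %*%
      rotation_from_rvec(c(0, 0, ang[3]))
    offs <- c(stats::runif(2, -lateral_mm, lateral_mm),
              stats::runif(1, -z_range_mm / 2, z_range_mm / 2))
    list(R = R, t = as.numeric(offs - R %*% center))
  }))
}

#' Fronto-parallel poses of an axially scanned board
#'
#' The board is centred laterally and translated along world z in uniform
#' steps, reproducing a motorized z-scan characterization.
#'
#' @param spec a \code{checkerboard_spec}.
#' @param z_step_um scan step, um.
#' @param z_range_mm total scan range, mm (centred on z = 0).
#' @return list of poses.
#' @export
make_zscan_poses <- function(spec, z_step_um = 5, z_range_mm = 3) {
  bp <- board_points(spec)
  center <- c(colMeans(bp), 0)
  zs <- seq(0, z_range_mm, by = z_step_um / 1000) - z_range_mm / 2
  lapply(zs, function(z)
    list(R = diag(3), t = c(-center[1], -center[2], z)))
}

#' Render a bright-field checkerboard image for corner-detection tests
#'
#' Rasterizes the board through the plane-to-image homography of the given
#' camera (no distortion), using an analytic soft-edged checker pattern
#' (tanh-smoothed square waves) so corners are exact intensity saddles,
#' plus slight Gaussian blur to emulate optical smoothing.
#'
#' @param spec a \code{checkerboard_spec}.
#' @param pose board placement (list with \code{R}, \code{t}, world frame).
#' @param intr,extr camera model (distortion ignored in rasterization).
#' @param sensor_size length-2 (W, H) px.
#' @param edge_width_mm soft-edge transition width on the board, mm.
#' @param blur_sigma optical blur sigma, px.
#' @return image matrix (rows = v, cols = u) in [0, 1].
#' @export
render_checkerboard_image <- function(spec, pose, intr, extr,
                                      sensor_size,
                                      edge_width_mm = spec$square_size / 30,
                                      blur_sigma = 0.8) {
  W <- sensor_size[1]; H <- sensor_size[2]
  ## homography: board plane (X, Y) -> pixel
  Rc <- extr$R %*% pose$R
  tc <- as.numeric(extr$R %*% pose$t + extr$t)
  K <- matrix(c(intr$fx, 0, 0, 0, intr$fy, 0, intr$cx, intr$cy, 1), 3, 3)
  Hm <- K %*% cbind(Rc[, 1], Rc[, 2], tc)
  Hinv <- solve(Hm)
  s <- spec$square_size
  ## board spans one square beyond the inner corners on each side
  xmin <- -s; xmax <- spec$inner_cols * s
  ymin <- -s; ymax <- spec$inner_rows * s
  ## soft square wave: sign alternates across square boundaries,
  ## s/pi sin(pi X / s) approximates the signed distance to the nearest edge
  sq <- function(X) tanh(sin(pi * X / s) * s / (pi * edge_width_mm))
  uu <- rep(0:(W - 1), each = H)
  vv <- rep(0:(H - 1), times = W)
  P <- Hinv %*% rbind(uu, vv, 1)
  X <- P[1, ] / P[3, ]; Y <- P[2, ] / P[3, ]
  inb <- X >= xmin & X <= xmax & Y >= ymin & Y <= ymax
  col <- 0.575 + 0.425 * sq(X) * sq(Y)
  img <- matrix(ifelse(inb, col, 0.6), H, W)
  gaussian_blur(img, blur_sigma)
}
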