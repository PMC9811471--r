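## Stereo pairing of localized spots across the two rectified views and
## conversion of accepted pairs to 3D world points.

#' Stereo matching configuration
#'
#' @param y_threshold maximum allowed rectified vertical offset between a
#'   pair of spots, px.
#' @param require_reciprocal_unique if TRUE (default) a pair is accepted
#'   only when each spot is the other's unique candidate; any spot with two
#'   or more candidates within the threshold voids all its pairings
#'   (ambiguity from several nearby droplets).
#' @return an object of class \code{"match_config"}.
#' @export
match_config <- function(y_threshold = 1.0, require_reciprocal_unique = TRUE) {
  if (y_threshold <= 0) stop("y_threshold must be positive", call. = FALSE)
  structure(list(y_threshold = y_threshold,
                 require_reciprocal_unique = require_reciprocal_unique),
            class = "match_config")
}

#' Match localized spots across the two views in one frame
#'
#' Spots from both cameras are mapped into the rectified frames; a pair is
#' accepted iff the camera-2 spot is the unique candidate within
#' \code{y_threshold} of the camera-1 spot and vice versa. Spots with
#' multiple candidates are excluded along with all their candidate
#' pairings, since proximity of several droplets makes identity ambiguous.
#'
#' @param spots1,spots2 spot data frames (single frame) from the two cameras.
#' @param rig a rectified \code{stereo_rig}.
#' @param cfg a \code{match_config}.
#' @return data frame of accepted pairs with original pixel coordinates,
#'   rectified coordinates, \code{dy_rect} and \code{disparity}.
#' @export
match_frame <- function(spots1, spots2, rig, cfg = match_config()) {
  empty <- data.frame(frame = integer(0), idx1 = integer(0),
                      idx2 = integer(0),
                      u1 = numeric(0), v1 = numeric(0),
                      u2 = numeric(0), v2 = numeric(0),
                      ur1 = numeric(0), vr1 = numeric(0),
                      ur2 = numeric(0), vr2 = numeric(0),
                      dy_rect = numeric(0), disparity = numeric(0))
  n1 <- nrow(spots1); n2 <- nrow(spots2)
  if (n1 == 0 || n2 == 0) return(empty)
  r1 <- rectified_coords(cbind(spots1$u, spots1$v), rig, 1)
  r2 <- rectified_coords(cbind(spots2$u, spots2$v), rig, 2)
  dy <- outer(r1[, 2], r2[, 2], `-`)
  cand <- abs(dy) < cfg$y_threshold
  c1 <- rowSums(cand); c2 <- colSums(cand)
  if (cfg$require_reciprocal_unique) {
    ok <- cand & (c1 == 1) & matrix(c2 == 1, n1, n2, byrow = TRUE)
  } else {
    ok <- cand & (c1 == 1)
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  i <- idx[, 1]; j <- idx[, 2]
  data.frame(frame = spots1$frame[i], idx1 = i, idx2 = j,
             u1 = spots1$u[i], v1 = spots1$v[i],
             u2 = spots2$u[j], v2 = spots2$v[j],
             ur1 = r1[i, 1], vr1 = r1[i, 2],
             ur2 = r2[j, 1], vr2 = r2[j, 2],
             dy_rect = r1[i, 2] - r2[j, 2],
             disparity = r1[i, 1] - r2[j, 1])
}

#' Match localized spots across all synchronized frames
#'
#' @param spots1,spots2 spot tables from the two cameras (with a
#'   \code{frame} column).
#' @param rig a rectified \code{stereo_rig}.
#' @param cfg a \code{match_config}.
#' @param n_frames1,n_frames2 optional frame counts of the two stacks; an
#'   error is raised when they differ (unsynchronized acquisitions).
#' @return data frame of pairs over all frames, with attribute
#'   \code{match_rate} = pairs / min(total spot counts).
#' @export
match_stack <- function(spots1, spots2, rig, cfg = match_config(),
                        n_frames1 = NULL, n_frames2 = NULL) {
  if (!is.null(n_frames1) && !is.null(n_frames2) && n_frames1 != n_frames2)
    stop("frame-count mismatch between cameras: ", n_frames1, " vs ",
         n_frames2, call. = FALSE)
  frames <- sort(unique(c(spots1$frame, spots2$frame)))
  out <- lapply(frames, function(k)
    match_frame(spots1[spots1$frame == k, , drop = FALSE],
                spots2[spots2$frame == k, , drop = FALSE], rig, cfg))
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) pairs <- match_frame(spots1[0, ], spots2[0, ], rig, cfg)
  denom <- min(nrow(spots1), nrow(spots2))
  attr(pairs, "match_rate") <- if (denom > 0) nrow(pairs) / denom else NA_real_
  pairs
}

#' Triangulate matched pairs into world points
#'
#' Undistorts the original pixel coordinates of each pair, triangulates by
#' the ray-midpoint method, optionally applies the refractive depth
#' correction, and drops points outside the volume of interest.
#'
#' @param pairs pair table from \code{\link{match_stack}}.
#' @param rig a \code{stereo_rig}.
#' @param medium optional \code{medium_config}; when given, depths below
#'   the interface are rescaled by the refractive index.
#' @param voi optional volume of interest, a list with \code{min} and
#'   \code{max} length-3 vectors (mm); out-of-volume points are dropped and
#'   the count reported via message and the \code{n_dropped} attribute.
#' @return data frame of world points: frame, x, y, z (mm), ray_gap (mm),
#'   refraction_corrected.
#' @export
pairs_to_points <- function(pairs, rig, medium = NULL, voi = NULL) {
  if (nrow(pairs) == 0)
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), ray_gap = numeric(0),
                      refraction_corrected = logical(0)))
  n1 <- undistort_points(cbind(pairs$u1, pairs$v1), rig$cam1$intrinsics)
  n2 <- undistort_points(cbind(pairs$u2, pairs$v2), rig$cam2$intrinsics)
  tr <- triangulate(n1, n2, rig)
  X <- tr$points
  corrected <- FALSE
  if (!is.null(medium)) {
    X <- correct_refraction(X, medium)
    corrected <- TRUE
  }
  keep <- rep(TRUE, nrow(X))
  if (!is.null(voi)) {
    keep <- X[, 1] >= voi$min[1] & X[, 1] <= voi$max[1] &
      X[, 2] >= voi$min[2] & X[, 2] <= voi$max[2] &
      X[, 3] >= voi$min[3] & X[, 3] <= voi$max[3]
    if (any(!keep))
      message(sum(!keep), " point(s) outside the volume of interest dropped")
  }
  out <- data.frame(frame = pairs$frame[keep],
                    x = X[keep, 1], y = X[keep, 2], z = X[keep, 3],
                    ray_gap = tr$ray_gap[keep],
                    refraction_corrected = corrected)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write matched pairs to CSV
#' @param pairs pair table.
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_pairs_csv <- function(pairs, path, header = NULL) {
  cols <- c("frame", "u1", "v1", "u2", "v2", "dy_rect", "disparity")
  write_table_csv(pairs[, cols], path, header)
}

#' Write world points to CSV
#' @param points point table from \code{\link{pairs_to_points}}.
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_points_csv <- function(points, path, header = NULL) {
  df <- data.frame(frame = points$frame, x_mm = points$x, y_mm = points$y,
                   z_mm = points$z, ray_gap_mm = points$ray_gap)
  write_table_csv(df, path, header)
}
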