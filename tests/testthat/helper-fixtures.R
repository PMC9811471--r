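## Shared fixtures: small-sensor rigs and synthetic frames, built in code.

## default-geometry rig on a reduced sensor (fast rendering/localization)
small_rig <- function(sensor = c(64, 64), theta = 20,
                      k1 = c(0, 0), k2 = c(0, 0)) {
  make_stereo_rig(theta = theta,
                  optics = optics_config(sensor_size = sensor),
                  k1 = k1, k2 = k2)
}

## wide-angle rig (short working distance): exercises large normalized
## radii so the radial distortion coefficients are identifiable
wide_rig <- function(k1 = c(0, 0), k2 = c(0, 0)) {
  make_stereo_rig(theta = 20, optics = optics_config(),
                  working_distance = 30, k1 = k1, k2 = k2)
}

## single frame with isotropic Gaussian spots at given sub-pixel positions
gauss_frame <- function(W, H, centers, amplitude = 2000, sigma = 1.5,
                        background = 100) {
  uu <- matrix(0:(W - 1), H, W, byrow = TRUE)
  vv <- matrix(0:(H - 1), H, W)
  fr <- matrix(background, H, W)
  centers <- matrix(centers, ncol = 2)
  for (i in seq_len(nrow(centers))) {
    fr <- fr + amplitude *
      exp(-((uu - centers[i, 1])^2 + (vv - centers[i, 2])^2) / (2 * sigma^2))
  }
  fr
}

## random in-volume world points around the focal plane of the default rig
random_points <- function(n, span = c(3, 3, 2)) {
  cbind(runif(n, -span[1], span[1]),
        runif(n, -span[2], span[2]),
        runif(n, -span[3], span[3]))
}

## project a world point through both cameras and return spot tables
truth_spots <- function(X, rig, frame = 1L) {
  X <- matrix(X, ncol = 3)
  p1 <- project_points(X, rig$cam1$intrinsics, rig$cam1$extrinsics)
  p2 <- project_points(X, rig$cam2$intrinsics, rig$cam2$extrinsics)
  list(s1 = data.frame(frame = frame, u = p1[, 1], v = p1[, 2]),
       s2 = data.frame(frame = frame, u = p2[, 1], v = p2[, 2]))
}

## brute-force min-cost one-to-one assignment (oracle for link_tracks)
brute_force_assignment <- function(cost, gate) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  cols <- seq_len(nc)
  ## enumerate all injective partial assignments via recursion
  rec <- function(i, used, acc, assign) {
    if (i > nr) {
      n <- sum(!is.na(assign))
      ## maximize link count, then minimize cost (matches gated LSAP)
      if (n > best_n || (n == best_n && acc < best_cost)) {
        best_n <<- n; best_cost <<- acc; best <<- assign
      }
      return(invisible())
    }
    rec(i + 1L, used, acc, c(assign, NA))          # leave row i unlinked
    for (j in cols[!used]) {
      if (cost[i, j] <= gate)
        rec(i + 1L, `[<-`(used, j, TRUE), acc + cost[i, j], c(assign, j))
    }
  }
  rec(1L, rep(FALSE, nc), 0, integer(0))
  best
}
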