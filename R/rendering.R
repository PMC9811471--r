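## Rendering of the compounded localization volume, per-voxel velocity maps,
## maximum-intensity projections, depth-coded maps and widefield-equivalent
## comparison images.

#' Accumulation voxel grid
#'
#' @param origin length-3 world coordinates (mm) of the corner of voxel
#'   (1,1,1).
#' @param dims integer length-3 voxel counts (nx, ny, nz).
#' @param voxel_size_um voxel edge length in um (default 10, about 3x the
#'   best expected localization SD).
#' @return an object of class \code{"voxel_grid"} with zeroed channels:
#'   \code{count}, summed velocity components and summed speed.
#' @export
voxel_grid <- function(origin, dims, voxel_size_um = 10) {
  dims <- as.integer(dims)
  if (any(dims < 1) || voxel_size_um <= 0)
    stop("zero-size grid", call. = FALSE)
  structure(list(origin = as.numeric(origin), dims = dims,
                 voxel_size = voxel_size_um,
                 count = array(0, dims),
                 sum_vx = array(0, dims), sum_vy = array(0, dims),
                 sum_vz = array(0, dims), sum_speed = array(0, dims)),
            class = "voxel_grid")
}

#' World coordinates to linear voxel indices (NA outside)
#' @keywords internal
voxel_index <- function(grid, X) {
  vs <- grid$voxel_size / 1000
  i <- floor((X[, 1] - grid$origin[1]) / vs) + 1
  j <- floor((X[, 2] - grid$origin[2]) / vs) + 1
  k <- floor((X[, 3] - grid$origin[3]) / vs) + 1
  ok <- i >= 1 & i <= grid$dims[1] & j >= 1 & j <= grid$dims[2] &
    k >= 1 & k <= grid$dims[3]
  lin <- rep(NA_real_, nrow(X))
  lin[ok] <- (k[ok] - 1) * grid$dims[1] * grid$dims[2] +
    (j[ok] - 1) * grid$dims[1] + i[ok]
  lin
}

#' Sample track segments at sub-voxel spacing
#'
#' Each step of each track is sampled at intervals of at most half a voxel;
#' per-sample velocity is the (constant) step velocity when present.
#' @keywords internal
sample_track_segments <- function(tracks, grid) {
  vs_half <- grid$voxel_size / 1000 / 2
  has_vel <- all(c("vx", "vy", "vz", "x1", "y1", "z1") %in% names(tracks))
  segs <- if (has_vel) {
    tracks
  } else {
    ## build consecutive segments from raw track points
    ids <- unique(tracks$track_id)
    do.call(rbind, lapply(ids, function(id) {
      tr <- tracks[tracks$track_id == id, , drop = FALSE]
      n <- nrow(tr)
      if (n < 2)
        return(data.frame(x = tr$x, y = tr$y, z = tr$z,
                          x1 = tr$x, y1 = tr$y, z1 = tr$z,
                          vx = 0, vy = 0, vz = 0, has_vel = FALSE))
      data.frame(x = tr$x[-n], y = tr$y[-n], z = tr$z[-n],
                 x1 = tr$x[-1], y1 = tr$y[-1], z1 = tr$z[-1],
                 vx = 0, vy = 0, vz = 0, has_vel = FALSE)
    }))
  }
  if (is.null(segs) || nrow(segs) == 0)
    return(cbind(matrix(numeric(0), 0, 3), vx = numeric(0),
                 vy = numeric(0), vz = numeric(0)))
  out <- vector("list", nrow(segs))
  for (r in seq_len(nrow(segs))) {
    p0 <- c(segs$x[r], segs$y[r], segs$z[r])
    p1 <- c(segs$x1[r], segs$y1[r], segs$z1[r])
    len <- sqrt(sum((p1 - p0)^2))
    nsmp <- max(1L, ceiling(len / vs_half)) + 1L
    tt <- seq(0, 1, length.out = nsmp)
    out[[r]] <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                      p0[2] + tt * (p1[2] - p0[2]),
                      p0[3] + tt * (p1[3] - p0[3]),
                      vx = segs$vx[r], vy = segs$vy[r], vz = segs$vz[r])
  }
  do.call(rbind, out)
}

#' Rasterize tracks into the visit-count volume
#'
#' Track segments are sampled at steps of at most half a voxel and
#' accumulated into per-voxel visit counts; out-of-grid samples are counted
#' and reported.
#'
#' @param tracks a \code{droplet_tracks} table (or the \code{steps} table
#'   from \code{\link{track_velocities}}).
#' @param grid a \code{voxel_grid}.
#' @return the grid with its \code{count} channel accumulated; attribute
#'   \code{n_clipped} counts dropped samples.
#' @export
rasterize_tracks <- function(tracks, grid) {
  smp <- sample_track_segments(tracks, grid)
  if (nrow(smp) == 0) {
    attr(grid, "n_clipped") <- 0L
    return(grid)
  }
  lin <- voxel_index(grid, smp[, 1:3, drop = FALSE])
  clipped <- sum(is.na(lin))
  if (clipped > 0)
    message(clipped, " sample(s) outside the voxel grid clipped")
  tab <- tabulate(lin[!is.na(lin)], nbins = prod(grid$dims))
  grid$count <- grid$count + array(tab, grid$dims)
  attr(grid, "n_clipped") <- clipped
  grid
}

#' Accumulate per-voxel mean velocities from tracked steps
#'
#' Each step's velocity vector is assigned to every voxel its segment
#' passes through (sampled at half-voxel spacing); the result holds the
#' component-wise arithmetic mean of all velocity samples per voxel plus
#' the mean speed (mean of |v|, which differs from |mean v| under opposing
#' flow).
#'
#' @param steps the \code{steps} table from \code{\link{track_velocities}}.
#' @param grid a \code{voxel_grid}.
#' @return list with \code{grid} (sums and counts accumulated),
#'   \code{mean_vx}, \code{mean_vy}, \code{mean_vz}, \code{mean_speed}
#'   arrays (NA where no sample fell).
#' @export
velocity_volume <- function(steps, grid) {
  smp <- sample_track_segments(steps, grid)
  nvox <- prod(grid$dims)
  if (nrow(smp) > 0) {
    lin <- voxel_index(grid, smp[, 1:3, drop = FALSE])
    ok <- !is.na(lin)
    lin <- lin[ok]
    smp <- smp[ok, , drop = FALSE]
    acc <- function(w) array(
      as.numeric(tapply2(w, lin, nvox)), grid$dims)
    grid$count <- grid$count + acc(rep(1, length(lin)))
    grid$sum_vx <- grid$sum_vx + acc(smp[, 4])
    grid$sum_vy <- grid$sum_vy + acc(smp[, 5])
    grid$sum_vz <- grid$sum_vz + acc(smp[, 6])
    grid$sum_speed <- grid$sum_speed +
      acc(sqrt(smp[, 4]^2 + smp[, 5]^2 + smp[, 6]^2))
  }
  cnt <- grid$count
  safe <- function(s) { m <- s / cnt; m[cnt == 0] <- NA_real_; m }
  list(grid = grid,
       mean_vx = safe(grid$sum_vx), mean_vy = safe(grid$sum_vy),
       mean_vz = safe(grid$sum_vz), mean_speed = safe(grid$sum_speed))
}

## weighted bincount on linear indices
#' @keywords internal
tapply2 <- function(w, lin, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, lin)
  out[as.numeric(rownames(s))] <- s
  out
}

#' Maximum-intensity projection of a volume
#'
#' @param volume 3D array ordered (x, y, z).
#' @param axis 1, 2 or 3 (or "x", "y", "z"): the axis projected out.
#' @return 2D matrix of per-line maxima.
#' @export
mip <- function(volume, axis = 3) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  if (length(volume) == 0) stop("empty volume", call. = FALSE)
  apply(volume, setdiff(1:3, axis), max)
}

#' Depth (z at maximum) map of a volume
#'
#' For each (x, y) line the z coordinate (mm, voxel centers) of the
#' along-depth maximum; NA where the line is identically zero.
#'
#' @param volume 3D array ordered (x, y, z).
#' @param grid the \code{voxel_grid} the volume lives on.
#' @return 2D matrix of depths in mm.
#' @export
depth_coded_map <- function(volume, grid) {
  vs <- grid$voxel_size / 1000
  k <- apply(volume, c(1, 2), which.max)
  zmap <- grid$origin[3] + (k - 0.5) * vs
  zmap[apply(volume, c(1, 2), max) == 0] <- NA_real_
  zmap
}

#' Widefield-equivalent image of a stack
#'
#' Superimposes all recorded frames (pixel-wise sum, or max) to mimic a
#' conventional long-exposure widefield acquisition, for comparison against
#' the localization-based reconstruction.
#'
#' @param stack an \code{image_stack}.
#' @param method "sum" (default) or "max".
#' @param subtract_bg subtract the temporal-mean background first.
#' @return 2D image matrix.
#' @export
widefield_equivalent <- function(stack, method = c("sum", "max"),
                                 subtract_bg = FALSE) {
  method <- match.arg(method)
  if (subtract_bg && dim(stack$frames)[3] >= 2)
    stack <- subtract_background(stack)
  apply(stack$frames, c(1, 2), if (method == "sum") sum else max)
}

#' FWHM of a line profile perpendicular to an axis
#'
#' Samples the image along a perpendicular cut through \code{center} and
#' fits a Gaussian plus constant; returns the full width at half maximum
#' \code{2 sqrt(2 log 2) sigma} in the coordinate units of \code{spacing}.
#'
#' @param image 2D matrix (rows = v, cols = u) or profile values.
#' @param center length-2 (u, v) point the cut passes through (0-based px).
#' @param direction length-2 unit vector of the cut direction.
#' @param half_length cut half-length in px.
#' @param spacing physical size of one px step (default 1).
#' @return list with \code{fwhm}, \code{sigma}, \code{profile}.
#' @export
line_profile_fwhm <- function(image, center, direction, half_length = 15,
                              spacing = 1) {
  dirn <- direction / sqrt(sum(direction^2))
  tt <- seq(-half_length, half_length, by = 0.5)
  us <- center[1] + tt * dirn[1]
  vs <- center[2] + tt * dirn[2]
  prof <- bilinear_sample(image, us, vs)
  b0 <- min(prof); a0 <- max(prof) - b0
  par0 <- c(A = a0, m = tt[which.max(prof)], s = half_length / 4, b = b0)
  fn <- function(p) p[1] * exp(-(tt - p[2])^2 / (2 * p[3]^2)) + p[4] - prof
  fit <- minpack.lm::nls.lm(par0, fn = fn)
  sigma <- abs(fit$par[3]) * spacing
  list(fwhm = unname(2 * sqrt(2 * log(2)) * sigma), sigma = unname(sigma),
       profile = data.frame(t = tt * spacing, value = prof))
}

#' @keywords internal
bilinear_sample <- function(image, u, v) {
  nr <- nrow(image); nc <- ncol(image)
  u <- pmin(pmax(u, 0), nc - 1); v <- pmin(pmax(v, 0), nr - 1)
  u0 <- pmin(floor(u), nc - 2); v0 <- pmin(floor(v), nr - 2)
  fu <- u - u0; fv <- v - v0
  i <- v0 + 1; j <- u0 + 1
  image[cbind(i, j)] * (1 - fu) * (1 - fv) +
    image[cbind(i, j + 1)] * fu * (1 - fv) +
    image[cbind(i + 1, j)] * (1 - fu) * fv +
    image[cbind(i + 1, j + 1)] * fu * fv
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d x %d x %d voxels of %.3g um, origin (%.2f, %.2f, %.2f) mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  total visit count: %.0f\n", sum(x$count)))
  invisible(x)
}

#' Quick-look plot of a voxel grid (top-view MIP)
#' @param x a \code{voxel_grid}.
#' @param axis projection axis (default "z").
#' @param ... passed to \code{image}.
#' @export
plot.voxel_grid <- function(x, axis = "z", ...) {
  m <- mip(x$count, axis)
  graphics::image(m, useRaster = TRUE, col = grDevices::hcl.colors(64),
                  ...)
  invisible(x)
}
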