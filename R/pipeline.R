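## Pipeline orchestration: configuration with the acquisition defaults,
## derived constants, and the end-to-end localize -> match -> triangulate ->
## track -> render run.

#' Pipeline configuration
#'
#' Flat, strictly validated configuration covering every stage. Defaults
#' mirror the in vivo acquisition: 20 ms exposure + 5 ms transfer gap
#' (40 Hz), x0.37 magnification at 15 um pixel pitch on a 640x512 sensor,
#' +/-20 deg vergence, MLD 300 um, refractive index 1.33.
#'
#' @param ... overrides of the default keys, using dotted names, e.g.
#'   \code{acquisition.exposure_ms = 50}.
#' @return an object of class \code{"pipeline_config"} (named list with
#'   dotted keys).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    acquisition.frame_rate_hz = 40,
    acquisition.exposure_ms = 20,
    acquisition.transfer_gap_ms = 5,
    optics.magnification = 0.37,
    optics.pixel_pitch_um = 15,
    optics.sensor_width_px = 640L,
    optics.sensor_height_px = 512L,
    optics.theta_deg = 20,
    medium.refractive_index = 1.33,
    medium.interface_z_mm = 0,
    localization.wavelet_level = 2L,
    localization.k_sigma = 4,
    localization.window_radius_px = 3L,
    localization.bg_method = "mean",
    match.y_threshold_px = 1.0,
    tracking.mld_um = 300,
    tracking.min_track_len = 5L,
    tracking.gap_closing = 0L,
    grid.voxel_size_um = 10,
    seeds.simulation = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @keywords internal
validate_config <- function(cfg) {
  implied <- 1000 / (cfg$acquisition.exposure_ms +
                       cfg$acquisition.transfer_gap_ms)
  if (abs(implied - cfg$acquisition.frame_rate_hz) >
      1e-6 * cfg$acquisition.frame_rate_hz)
    stop(sprintf(
      "config inconsistency: exposure %.4g + gap %.4g ms implies %.4f Hz, not %.4f Hz",
      cfg$acquisition.exposure_ms, cfg$acquisition.transfer_gap_ms,
      implied, cfg$acquisition.frame_rate_hz), call. = FALSE)
  if (cfg$tracking.mld_um <= 0 || cfg$match.y_threshold_px <= 0 ||
      cfg$optics.magnification <= 0)
    stop("config values out of range", call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from a key-value file
#' @param path config file (dotted keys, one per line).
#' @return a \code{pipeline_config}; unknown keys are rejected.
#' @export
read_config <- function(path) {
  kv <- read_keyvalue(path)
  kv <- lapply(kv, function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) v else x
  })
  do.call(pipeline_config, kv)
}

#' Write a pipeline configuration to a key-value file
#' @param cfg a \code{pipeline_config}.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  write_keyvalue(unclass(cfg), path)
}

#' @keywords internal
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(if (is.numeric(v)) formatC(v, format = "g", digits = 15)
          else as.character(v), collapse = ","), ""), collapse = ";")
  ## small rolling hash; enough to fingerprint a config in output headers
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Constants derived from a configuration
#'
#' Object-plane pixel size (pixel pitch / magnification: 15 um at x0.37
#' gives 40.5 um), frame rate implied by the exposure timing (20 + 5 ms
#' gives 40 Hz), frame period, and the maximum trackable speed
#' (MLD x frame rate: 300 um at 40 Hz gives 12 mm/s).
#'
#' @param cfg a \code{pipeline_config}.
#' @return named list: \code{object_pixel_um}, \code{frame_rate_hz},
#'   \code{frame_period_ms}, \code{max_speed_mm_s}.
#' @export
derived_constants <- function(cfg = pipeline_config()) {
  fr <- 1000 / (cfg$acquisition.exposure_ms + cfg$acquisition.transfer_gap_ms)
  list(object_pixel_um = cfg$optics.pixel_pitch_um / cfg$optics.magnification,
       frame_rate_hz = fr,
       frame_period_ms = 1000 / fr,
       max_speed_mm_s = cfg$tracking.mld_um / 1000 * fr)
}

#' Run the full reconstruction pipeline on a dual-view acquisition
#'
#' Localizes both stacks, matches spots across the rectified views,
#' triangulates accepted pairs (with optional refractive correction), links
#' and filters tracks, computes velocities, and rasterizes the compounded
#' localization volume and per-voxel velocity maps. Stage counts are
#' reported as messages; intermediates are returned (and optionally written
#' as CSV/TIFF when \code{outdir} is given).
#'
#' @param cfg a \code{pipeline_config}.
#' @param stack1,stack2 synchronized \code{image_stack}s.
#' @param rig a rectified \code{stereo_rig}.
#' @param medium optional \code{medium_config} (defaults from cfg when
#'   \code{use_medium = TRUE}).
#' @param use_medium apply refractive depth correction.
#' @param grid optional \code{voxel_grid}; built from the point cloud
#'   bounding box when NULL.
#' @param outdir optional output directory for CSV/TIFF artifacts.
#' @return list with spots1, spots2, pairs, points, tracks, velocity steps
#'   and summaries, volume grid, velocity volume and MIPs.
#' @export
run_pipeline <- function(cfg, stack1, stack2, rig, medium = NULL,
                         use_medium = FALSE, grid = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  n1 <- dim(stack1$frames)[3]; n2 <- dim(stack2$frames)[3]
  if (n1 != n2)
    stop(sprintf(
      "pipeline stage 'input' failed: frame-count mismatch (%d vs %d)",
      n1, n2), call. = FALSE)
  loc_par <- list(level = cfg$localization.wavelet_level,
                  k_sigma = cfg$localization.k_sigma,
                  window_radius = cfg$localization.window_radius_px,
                  bg_method = cfg$localization.bg_method)
  spots1 <- stage("localize", localize_stack(stack1, loc_par))
  spots2 <- stage("localize", localize_stack(stack2, loc_par))
  message("localize: ", nrow(spots1), " / ", nrow(spots2), " spots")
  mcfg <- match_config(cfg$match.y_threshold_px)
  pairs <- stage("match", match_stack(spots1, spots2, rig, mcfg,
                                      n_frames1 = n1, n_frames2 = n2))
  message("match: ", nrow(pairs), " pairs (rate ",
          sprintf("%.2f", attr(pairs, "match_rate") %||% NA), ")")
  if (is.null(medium) && use_medium)
    medium <- medium_config(cfg$medium.refractive_index,
                            cfg$medium.interface_z_mm)
  points <- stage("triangulate", pairs_to_points(pairs, rig, medium))
  message("triangulate: ", nrow(points), " points")
  tcfg <- tracking_config(cfg$tracking.mld_um, cfg$tracking.min_track_len,
                          cfg$tracking.gap_closing)
  tracks <- stage("track", filter_tracks(link_tracks(points, tcfg), tcfg))
  message("track: ", length(unique(tracks$track_id)), " tracks")
  vel <- stage("velocity",
               track_velocities(tracks, cfg$acquisition.frame_rate_hz))
  if (is.null(grid)) {
    if (nrow(points)) {
      vs <- cfg$grid.voxel_size_um / 1000
      lo <- c(min(points$x), min(points$y), min(points$z)) - vs
      hi <- c(max(points$x), max(points$y), max(points$z)) + vs
      grid <- voxel_grid(lo, pmax(ceiling((hi - lo) / vs), 1),
                         cfg$grid.voxel_size_um)
    } else {
      grid <- voxel_grid(c(0, 0, 0), c(1, 1, 1), cfg$grid.voxel_size_um)
    }
  }
  volume <- stage("render", rasterize_tracks(tracks, grid))
  velvol <- stage("render", velocity_volume(vel$steps, grid))
  mips <- list(z = mip(volume$count, 3), y = mip(volume$count, 2),
               x = mip(volume$count, 1))
  if (nrow(points) == 0)
    warning("no points reconstructed: empty tables and zero volume")
  res <- list(spots1 = spots1, spots2 = spots2, pairs = pairs,
              points = points, tracks = tracks,
              velocity_steps = vel$steps, velocity_summary = vel$summary,
              volume = volume, velocity = velvol, mips = mips,
              config = cfg)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0("config_hash=", config_hash(cfg),
                  " seed=", cfg$seeds.simulation)
    write_spots_csv(spots1, file.path(outdir, "spots_cam1.csv"), hdr)
    write_spots_csv(spots2, file.path(outdir, "spots_cam2.csv"), hdr)
    if (nrow(pairs)) write_pairs_csv(pairs, file.path(outdir, "pairs.csv"),
                                     hdr)
    write_points_csv(points, file.path(outdir, "points.csv"), hdr)
    write_tracks_csv(vel$steps, file.path(outdir, "tracks.csv"), hdr)
    write_volume_tiff(volume$count, grid, file.path(outdir, "volume.tif"))
  }
  res
}
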