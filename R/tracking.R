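## Particle tracking velocimetry: frame-to-frame linking of triangulated
## droplet positions under a max-linking-distance gate, short-track
## filtering, and velocity computation.

#' Tracking configuration
#'
#' @param mld_um max linking distance: the largest displacement of one
#'   droplet allowed between consecutive frames, um (default 300). Together
#'   with the frame rate this bounds the measurable speed
#'   (\code{\link{max_trackable_speed}}).
#' @param min_track_length minimum number of points for a track to be kept
#'   (default 5); removes false connections and stalled droplets.
#' @param gap_closing number of missed frames a track may bridge
#'   (default 0).
#' @return an object of class \code{"tracking_config"}.
#' @export
tracking_config <- function(mld_um = 300, min_track_length = 5L,
                            gap_closing = 0L) {
  if (mld_um <= 0) stop("mld_um must be positive", call. = FALSE)
  if (min_track_length < 2) stop("min_track_length must be >= 2",
                                 call. = FALSE)
  structure(list(mld_um = mld_um,
                 min_track_length = as.integer(min_track_length),
                 gap_closing = as.integer(gap_closing)),
            class = "tracking_config")
}

#' Link 3D points over time into trajectories
#'
#' For every consecutive frame pair, candidate links (distance <= MLD) are
#' resolved by an optimal one-to-one assignment minimizing the total squared
#' distance (Hungarian-style linear sum assignment, not greedy); unlinked
#' points start new tracks. With \code{gap_closing > 0}, track ends remain
#' linkable for that many missed frames under the same distance gate.
#' Deterministic for a fixed input.
#'
#' @param points data frame with columns \code{frame}, \code{x}, \code{y},
#'   \code{z} (mm); extra columns are carried through.
#' @param cfg a \code{tracking_config}.
#' @return data frame of track points (track_id, frame, x, y, z, ...),
#'   ordered by track then frame, class \code{"droplet_tracks"}.
#' @export
link_tracks <- function(points, cfg = tracking_config()) {
  mld_mm <- cfg$mld_um / 1000
  pts <- points[order(points$frame), , drop = FALSE]
  if (nrow(pts) == 0) {
    pts <- cbind(track_id = integer(0), pts)
    class(pts) <- c("droplet_tracks", "data.frame")
    return(pts)
  }
  pts$track_id <- NA_integer_
  frames <- sort(unique(pts$frame))
  next_id <- 1L
  ## open track ends: row index into pts, last frame, last position
  open_row <- integer(0)
  for (k in frames) {
    cur <- which(pts$frame == k)
    ## drop stale ends beyond the gap-closing horizon
    if (length(open_row)) {
      fresh <- pts$frame[open_row] >= k - 1L - cfg$gap_closing
      open_row <- open_row[fresh]
    }
    if (length(open_row) && length(cur)) {
      P <- as.matrix(pts[open_row, c("x", "y", "z")])
      Q <- as.matrix(pts[cur, c("x", "y", "z")])
      D2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
        outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
      D2 <- pmax(D2, 0)
      assign <- lsap_gated(D2, mld_mm^2)
      linked_cur <- logical(length(cur))
      for (i in seq_along(open_row)) {
        j <- assign[i]
        if (!is.na(j)) {
          pts$track_id[cur[j]] <- pts$track_id[open_row[i]]
          open_row[i] <- cur[j]
          linked_cur[j] <- TRUE
        }
      }
      new_pts <- cur[!linked_cur]
    } else {
      new_pts <- cur
    }
    for (j in new_pts) {
      pts$track_id[j] <- next_id
      next_id <- next_id + 1L
      open_row <- c(open_row, j)
    }
  }
  out <- pts[order(pts$track_id, pts$frame),
             c("track_id", setdiff(names(pts), "track_id")), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("droplet_tracks", "data.frame")
  out
}

#' Gated optimal linear-sum assignment
#'
#' Solves min-cost one-to-one assignment on a cost matrix where entries
#' above \code{gate} are forbidden; returns, for each row, the assigned
#' column or NA. Forbidden assignments returned by the padded LSAP solve
#' are discarded.
#' @keywords internal
lsap_gated <- function(cost, gate) {
  nr <- nrow(cost); nc <- ncol(cost)
  allowed <- cost <= gate
  out <- rep(NA_integer_, nr)
  if (!any(allowed)) return(out)
  big <- gate * (max(nr, nc) + 1) + 1
  C <- cost
  C[!allowed] <- big
  n <- max(nr, nc)
  Cp <- matrix(big, n, n)
  Cp[seq_len(nr), seq_len(nc)] <- C
  sol <- as.integer(clue::solve_LSAP(Cp))
  for (i in seq_len(nr)) {
    j <- sol[i]
    if (j <= nc && allowed[i, j]) out[i] <- j
  }
  out
}

#' Remove tracks shorter than the configured minimum length
#'
#' @param tracks a \code{droplet_tracks} table.
#' @param cfg a \code{tracking_config}.
#' @return filtered tracks; the number of removed tracks is reported via
#'   message and the \code{n_removed} attribute.
#' @export
filter_tracks <- function(tracks, cfg = tracking_config()) {
  len <- table(tracks$track_id)
  keep_ids <- as.integer(names(len)[len >= cfg$min_track_length])
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  n_removed <- length(len) - length(keep_ids)
  if (n_removed > 0)
    message(n_removed, " track(s) shorter than ", cfg$min_track_length,
            " frames removed")
  rownames(out) <- NULL
  attr(out, "n_removed") <- n_removed
  class(out) <- c("droplet_tracks", "data.frame")
  out
}

#' Per-step velocities of linked tracks
#'
#' Velocity of each consecutive step is displacement times frame rate
#' (steps bridging g missed frames are divided by g + 1 frame periods).
#' Lateral speed is \code{sqrt(vx^2 + vy^2)}, axial velocity is \code{vz}
#' (signed: positive = descending, away from the cameras), total speed the
#' vector norm.
#'
#' @param tracks a \code{droplet_tracks} table.
#' @param frame_rate acquisition frame rate, Hz.
#' @return list with \code{steps} (one row per step: track_id, frame, x, y,
#'   z of the step start, vx, vy, vz, v_lateral, v_axial, v_total, mm/s)
#'   and \code{summary} (per-track mean speeds and lengths).
#' @export
track_velocities <- function(tracks, frame_rate) {
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  ids <- unique(tracks$track_id)
  steps <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    n <- nrow(tr)
    if (n < 2) return(NULL)
    dt <- diff(tr$frame) / frame_rate
    vx <- diff(tr$x) / dt; vy <- diff(tr$y) / dt; vz <- diff(tr$z) / dt
    data.frame(track_id = id, frame = tr$frame[-n],
               x = tr$x[-n], y = tr$y[-n], z = tr$z[-n],
               x1 = tr$x[-1], y1 = tr$y[-1], z1 = tr$z[-1],
               vx = vx, vy = vy, vz = vz,
               v_lateral = sqrt(vx^2 + vy^2), v_axial = vz,
               v_total = sqrt(vx^2 + vy^2 + vz^2))
  })
  steps <- do.call(rbind, steps)
  if (is.null(steps))
    steps <- data.frame(track_id = integer(0), frame = integer(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                        vx = numeric(0), vy = numeric(0), vz = numeric(0),
                        v_lateral = numeric(0), v_axial = numeric(0),
                        v_total = numeric(0))
  summary <- if (nrow(steps)) {
    agg <- stats::aggregate(
      steps[, c("v_lateral", "v_axial", "v_total")],
      by = list(track_id = steps$track_id), FUN = mean)
    agg$n_steps <- as.numeric(table(steps$track_id)[
      as.character(agg$track_id)])
    agg
  } else {
    data.frame(track_id = integer(0), v_lateral = numeric(0),
               v_axial = numeric(0), v_total = numeric(0),
               n_steps = numeric(0))
  }
  list(steps = steps, summary = summary)
}

#' Maximum speed measurable by the tracker
#'
#' The max-linking-distance bounds the displacement a droplet may make
#' between consecutive frames, so the fastest trackable flow is
#' \code{MLD x frame_rate}: 300 um at 40 Hz gives 12 mm/s.
#'
#' @param cfg a \code{tracking_config}.
#' @param frame_rate acquisition frame rate, Hz.
#' @return maximum trackable speed, mm/s.
#' @export
max_trackable_speed <- function(cfg, frame_rate) {
  if (cfg$mld_um <= 0) stop("mld_um must be positive", call. = FALSE)
  cfg$mld_um / 1000 * frame_rate
}

#' Write tracks (with optional velocities) to CSV
#' @param tracks a \code{droplet_tracks} table or the \code{steps} table
#'   from \code{\link{track_velocities}}.
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_tracks_csv <- function(tracks, path, header = NULL) {
  cols <- intersect(c("track_id", "frame", "x", "y", "z",
                      "vx", "vy", "vz"), names(tracks))
  df <- as.data.frame(tracks)[, cols]
  names(df) <- sub("^([xyz])$", "\\1_mm", names(df))
  write_table_csv(df, path, header)
}
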