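test_that("linking follows the max-linking-distance semantics", {
  ## single droplet stepping 100 um/frame under MLD 300: one full track
  pts <- data.frame(frame = 1:10, x = (1:10) * 0.1, y = 0, z = 0)
  tr <- link_tracks(pts, tracking_config(mld_um = 300))
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  ## stepping 400 um/frame > MLD 300: fragments of length 1
  pts2 <- data.frame(frame = 1:10, x = (1:10) * 0.4, y = 0, z = 0)
  tr2 <- link_tracks(pts2, tracking_config(mld_um = 300))
  expect_equal(length(unique(tr2$track_id)), 10)

  ## invalid configs are rejected
  expect_error(tracking_config(mld_um = 0), "positive")
  expect_error(tracking_config(min_track_length = 1), ">= 2")
})

test_that("crossing droplets keep their identities", {
  ## two droplets crossing in x while separated in y more than they step
  set.seed(13)
  swaps <- 0L
  for (rep in 1:100) {
    n <- 15
    a <- data.frame(frame = 1:n, x = seq(-0.7, 0.7, length.out = n),
                    y = 0.25 + rnorm(n, 0, 0.005), z = 0, id = 1L)
    b <- data.frame(frame = 1:n, x = seq(0.7, -0.7, length.out = n),
                    y = -0.25 + rnorm(n, 0, 0.005), z = 0, id = 2L)
    tr <- link_tracks(rbind(a, b), tracking_config(mld_um = 300))
    for (tid in unique(tr$track_id)) {
      if (length(unique(tr$id[tr$track_id == tid])) > 1) swaps <- swaps + 1L
    }
  }
  expect_equal(swaps, 0L)
})

test_that("frame-to-frame linking equals brute-force optimal assignment", {
  set.seed(14)
  gate_mm <- 0.3
  for (rep in 1:40) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    P <- matrix(runif(n1 * 3, 0, 1), n1)
    Q <- matrix(runif(n2 * 3, 0, 1), n2)
    cost <- as.matrix(dist(rbind(P, Q)))[1:n1, n1 + 1:n2, drop = FALSE]^2
    got <- stereoloc:::lsap_gated(cost, gate_mm^2)
    want <- brute_force_assignment(cost, gate_mm^2)
    ## same number of links and same total cost (ties may permute)
    expect_equal(sum(!is.na(got)), sum(!is.na(want)))
    cost_of <- function(a) sum(cost[cbind(which(!is.na(a)),
                                          a[!is.na(a)])])
    expect_equal(cost_of(got), cost_of(want), tolerance = 1e-12)
  }
})

test_that("short tracks are filtered and spurious detections removed", {
  pts <- data.frame(frame = 1:10, x = (1:10) * 0.1, y = 0, z = 0)
  tr <- link_tracks(pts, tracking_config())
  ## min = 2 is the identity on a fully linked output
  expect_equal(nrow(filter_tracks(tr, tracking_config(min_track_length = 2))),
               nrow(tr))
  ## all length-1 tracks, min 5: empty
  lone <- data.frame(frame = 1:6, x = (1:6) * 10, y = 0, z = 0)
  trl <- link_tracks(lone, tracking_config(mld_um = 100))
  expect_equal(nrow(suppressMessages(
    filter_tracks(trl, tracking_config(min_track_length = 5)))), 0)

  ## 10% isolated spurious points: >= 95% removed by the length filter
  set.seed(15)
  real <- do.call(rbind, lapply(1:5, function(i)
    data.frame(frame = 1:20, x = (1:20) * 0.05, y = i, z = 0,
               spurious = FALSE)))
  fake <- data.frame(frame = sample(1:20, 11, replace = TRUE),
                     x = runif(11, 5, 50), y = runif(11, 5, 50),
                     z = runif(11, 5, 50), spurious = TRUE)
  tr2 <- suppressMessages(filter_tracks(
    link_tracks(rbind(real, fake), tracking_config()),
    tracking_config(min_track_length = 5)))
  expect_gte(1 - sum(tr2$spurious) / sum(fake$spurious), 0.95)
  expect_equal(sum(!tr2$spurious), nrow(real))
})

test_that("velocities come from displacement times frame rate", {
  ## 231.25 um between consecutive frames at 40 Hz: 9.25 mm/s
  tr <- link_tracks(data.frame(frame = 1:6, x = (0:5) * 0.23125, y = 0,
                               z = 0), tracking_config())
  v <- track_velocities(tr, 40)
  expect_equal(unique(round(v$steps$v_total, 10)), 9.25)

  ## static droplet: zero velocities
  trs <- link_tracks(data.frame(frame = 1:5, x = 1, y = 2, z = 3),
                     tracking_config())
  vs <- track_velocities(trs, 40)
  expect_true(all(vs$steps$v_total == 0))

  ## purely axial motion: lateral 0, |axial| = total
  tra <- link_tracks(data.frame(frame = 1:5, x = 0, y = 0,
                                z = (1:5) * 0.05), tracking_config())
  va <- track_velocities(tra, 40)
  expect_true(all(va$steps$v_lateral == 0))
  expect_equal(abs(va$steps$v_axial), va$steps$v_total)

  ## single-point track yields no velocity rows
  v1 <- track_velocities(link_tracks(data.frame(frame = 1, x = 0, y = 0,
                                                z = 0), tracking_config()),
                         40)
  expect_equal(nrow(v1$steps), 0)
})

test_that("the maximum trackable speed is MLD times frame rate", {
  expect_equal(max_trackable_speed(tracking_config(mld_um = 300), 40), 12)
  expect_equal(max_trackable_speed(tracking_config(mld_um = 300), 18), 5.4)
  cfg <- tracking_config(mld_um = 300)
  cfg$mld_um <- 0  # corrupted config caught at use
  expect_error(max_trackable_speed(cfg, 40), "positive")
})

test_that("tube-flow speeds are recovered within 5% end to end", {
  rig <- small_rig(sensor = c(200, 160))
  sc <- build_scene(scene_spec("tilted_tube", length_mm = 3, dz_dy = 0.3,
                               z_start = 0.2))
  for (v_true in c(2, 4)) {
    gt <- simulate_flow(sc, flow_spec(speed = v_true, rate = 1.5),
                        duration = 8, frame_rate = 18, seed = 21)
    st <- render_stack(gt, rig, seed = 22, frame_rate = 18)
    s1 <- localize_stack(st[[1]], list(bg_method = "median"))
    s2 <- localize_stack(st[[2]], list(bg_method = "median"))
    pts <- pairs_to_points(match_stack(s1, s2, rig), rig)
    tcfg <- tracking_config(mld_um = 1.5 * v_true / 18 * 1000,
                            min_track_length = 5)
    tr <- suppressMessages(filter_tracks(link_tracks(pts, tcfg), tcfg))
    vel <- track_velocities(tr, 18)
    expect_gt(nrow(vel$summary), 3)
    expect_equal(mean(vel$summary$v_total), v_true, tolerance = 0.05)
  }
})

test_that("descending and ascending vessels separate in axial velocity", {
  rig <- small_rig(sensor = c(96, 96))
  sc <- build_scene(scene_spec("vessel_network"))
  gt <- simulate_flow(sc, flow_spec(speed = 3, rate = 8), duration = 10,
                      frame_rate = 40, seed = 43)
  st <- render_stack(gt, rig, seed = 44, frame_rate = 40)
  s1 <- localize_stack(st[[1]], list(bg_method = "median"))
  s2 <- localize_stack(st[[2]], list(bg_method = "median"))
  pts <- pairs_to_points(match_stack(s1, s2, rig), rig)
  tcfg <- tracking_config(mld_um = 120, min_track_length = 5)
  tr <- suppressMessages(filter_tracks(link_tracks(pts, tcfg), tcfg))
  stp <- track_velocities(tr, 40)$steps
  ## the discrimination property presumes separated droplets; use the
  ## ground truth to exclude frames where two droplets co-occupy the same
  ## vessel within 2 x MLD (there, linking identity is undefined)
  crowded <- unique(unlist(lapply(split(gt, gt$centerline), function(g) {
    unlist(lapply(split(g, g$frame), function(f) {
      if (nrow(f) >= 2 && min(dist(cbind(f$x, f$y, f$z))) < 0.24)
        f$frame[1]
    }))
  })))
  ok_frame <- !(stp$frame %in% crowded | (stp$frame + 1) %in% crowded)
  ## classify steps by proximity to the two penetrating-vessel locations
  ## and axial dominance (surface vessels cross the same entry points)
  axial <- abs(stp$vz) > stp$v_lateral & ok_frame
  desc <- stp[axial & abs(stp$x + 0.8) < 0.12 & abs(stp$y + 0.5) < 0.12, ]
  asc <- stp[axial & abs(stp$x - 0.8) < 0.12 & abs(stp$y - 0.6) < 0.12, ]
  expect_gt(nrow(desc), 20)
  expect_gt(nrow(asc), 20)
  expect_gte(mean(desc$vz > 0), 0.99)
  expect_gte(mean(asc$vz < 0), 0.99)
})

test_that("tracks CSV carries ids, positions and velocities", {
  tr <- link_tracks(data.frame(frame = 1:4, x = (1:4) * 0.1, y = 0, z = 0),
                    tracking_config())
  v <- track_velocities(tr, 40)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(v$steps, path, header = "unit test")
  back <- read_table_csv(path)
  expect_named(back, c("track_id", "frame", "x_mm", "y_mm", "z_mm",
                       "vx", "vy", "vz"))
  expect_equal(back$vx, rep(4, 3))
})
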