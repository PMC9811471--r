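test_that("scene geometries honor their specifications", {
  ## zero-gradient tube is a constant-z line
  sc <- build_scene(scene_spec("tilted_tube", dz_dy = 0, z_start = 0.7))
  expect_equal(range(sc$centerlines[[1]]$points[, 3]), c(0.7, 0.7))

  ## knot: centerline z-separation at the crossing equals the configured
  ## outer diameter exactly
  kn <- build_scene(scene_spec("knot", separation_um = 231, depth_mm = 1))
  z1 <- unique(kn$centerlines[[1]]$points[, 3])
  z2 <- unique(kn$centerlines[[2]]$points[, 3])
  expect_equal(z2 - z1, 0.231)
  ## the arcs do cross in the xy plane
  d <- as.matrix(dist(rbind(kn$centerlines[[1]]$points[, 1:2],
                            kn$centerlines[[2]]$points[, 1:2])))
  n1 <- nrow(kn$centerlines[[1]]$points)
  expect_lt(min(d[1:n1, -(1:n1)]), 0.01)

  ## vessel network: penetrating segments stay within 600 um of the surface
  vn <- build_scene(scene_spec("vessel_network"))
  pen <- vn$centerlines[vapply(vn$centerlines, function(cl)
    cl$label %in% c("descending", "ascending"), TRUE)]
  expect_length(pen, 2)
  for (cl in pen)
    expect_lte(diff(range(cl$points[, 3])), 0.600 + 1e-9)

  ## geometry outside a declared volume errors
  expect_error(build_scene(scene_spec("tilted_tube", length_mm = 10),
                           volume = list(min = c(-2, -2, -2),
                                         max = c(2, 2, 2))),
               "volume")
})

test_that("flow simulation is a reproducible Poisson advection", {
  sc <- build_scene(scene_spec("tilted_tube"))
  ## rate 0: empty ground truth
  gt0 <- simulate_flow(sc, flow_spec(rate = 0), 5, 18, seed = 1)
  expect_equal(nrow(gt0), 0)

  ## per-frame displacement along the centerline is speed / frame_rate
  gt <- simulate_flow(sc, flow_spec(speed = 3, rate = 2), 10, 18, seed = 2)
  one <- gt[gt$droplet_id == gt$droplet_id[1], ]
  step <- sqrt(diff(one$x)^2 + diff(one$y)^2 + diff(one$z)^2)
  expect_equal(step, rep(3 / 18, length(step)), tolerance = 1e-6)

  ## identical seeds are bit-identical; different seeds differ
  gt_a <- simulate_flow(sc, flow_spec(rate = 2), 5, 18, seed = 33)
  gt_b <- simulate_flow(sc, flow_spec(rate = 2), 5, 18, seed = 33)
  expect_identical(gt_a, gt_b)
  gt_c <- simulate_flow(sc, flow_spec(rate = 2), 5, 18, seed = 34)
  expect_false(identical(gt_b, gt_c))

  ## droplet count matches Poisson statistics over 100 seeds
  rate <- 3; dur <- 4
  counts <- vapply(1:100, function(s)
    length(unique(simulate_flow(sc, flow_spec(rate = rate), dur, 18,
                                seed = s)$droplet_id)), 0)
  expect_lt(abs(mean(counts) - rate * dur),
            3 * sqrt(rate * dur / 100))
})

test_that("rendering follows the photometric and scattering model", {
  rig <- small_rig()
  ## no droplets, no background, no read noise: all-zero frames
  sc <- build_scene(scene_spec("tilted_tube"))
  gt0 <- simulate_flow(sc, flow_spec(rate = 0), 0.2, 18, seed = 1)
  st0 <- render_stack(gt0, rig, background = 0, read_noise = 0, seed = 1)
  expect_equal(sum(st0[[1]]$frames), 0)
  expect_equal(sum(st0[[2]]$frames), 0)

  ## identical seeds give bit-identical stacks
  scp <- build_scene(scene_spec("static_point"))
  gt <- simulate_flow(scp, flow_spec(), 0.25, 40)
  s_a <- render_stack(gt, rig, seed = 9)
  s_b <- render_stack(gt, rig, seed = 9)
  expect_identical(s_a[[1]]$frames, s_b[[1]]$frames)

  ## photometric linearity: doubling the droplet volume doubles the
  ## expected (pre-noise) spot integral
  gt2 <- gt; gt2$intensity <- 2 * gt$intensity
  n1 <- render_stack(gt, rig, background = 0, noiseless = TRUE)
  n2 <- render_stack(gt2, rig, background = 0, noiseless = TRUE)
  expect_equal(sum(n2[[1]]$frames), 2 * sum(n1[[1]]$frames),
               tolerance = 1e-3)

  ## fitted sigma is strictly larger at depth when broadening is on
  ## (wider sensor: the deep point parallax shifts the projection)
  rigw <- small_rig(sensor = c(160, 96))
  scat <- scattering_model(beta_per_mm = 1.0)
  fit_at <- function(z) {
    scz <- build_scene(scene_spec("static_point", position = c(0, 0, z)))
    gtz <- simulate_flow(scz, flow_spec(photons = 50000), 0.1, 40)
    stz <- render_stack(gtz, rigw, scattering = scat, noiseless = TRUE)
    s <- localize_stack(stz[[1]], list(subtract_bg = FALSE))
    mean(s$sigma)
  }
  expect_gt(fit_at(3), fit_at(0))
})

test_that("a rendered static droplet round-trips to 0.02 object pixels", {
  rig <- small_rig()
  sc <- build_scene(scene_spec("static_point", position = c(0.1, -0.2, 0.3)))
  gt <- simulate_flow(sc, flow_spec(), 0.1, 40)
  st <- render_stack(gt, rig, noiseless = TRUE)
  s1 <- localize_stack(st[[1]], list(subtract_bg = FALSE))
  s2 <- localize_stack(st[[2]], list(subtract_bg = FALSE))
  pts <- pairs_to_points(match_stack(s1, s2, rig), rig)
  err_mm <- sqrt((mean(pts$x) - 0.1)^2 + (mean(pts$y) + 0.2)^2 +
                   (mean(pts$z) - 0.3)^2)
  expect_lt(err_mm, 0.02 * rig$optics$object_pixel / 1000)
})

test_that("sparsity certification flags crowded scenes", {
  rig <- small_rig()
  sc <- build_scene(scene_spec("tilted_tube"))
  gt_sparse <- simulate_flow(sc, flow_spec(rate = 0.5), 10, 18, seed = 61)
  expect_true(is_sparse_scene(gt_sparse, rig, 1.0))
  ## two droplets at the same y are never sparse for the matcher
  gt2 <- data.frame(frame = 1L, droplet_id = 1:2, centerline = 1L,
                    x = c(-0.5, 0.5), y = 0, z = 0, diameter = 4.7,
                    intensity = 1)
  expect_false(is_sparse_scene(gt2, rig, 1.0))
})

test_that("checkerboard views render analytically with optional noise", {
  rig <- make_stereo_rig(k1 = c(-0.1, -0.08), k2 = c(0.05, 0.04))
  spec <- checkerboard_spec(4, 5, 2.0)
  poses <- make_board_poses(3, spec, seed = 71)
  v0 <- render_checkerboard_views(spec, poses, rig, noise_sd = 0)
  ## sigma = 0: corners equal analytic projections exactly
  Xw <- cbind(board_points(spec), 0) %*% t(poses[[2]]$R) +
    matrix(poses[[2]]$t, 20, 3, byrow = TRUE)
  expect_equal(v0[[2]]$cam1,
               project_points(Xw, rig$cam1$intrinsics, rig$cam1$extrinsics),
               tolerance = 1e-12)
  ## noise is reproducible under a fixed seed
  vn1 <- render_checkerboard_views(spec, poses, rig, noise_sd = 0.1,
                                   seed = 5)
  vn2 <- render_checkerboard_views(spec, poses, rig, noise_sd = 0.1,
                                   seed = 5)
  expect_identical(vn1, vn2)
  ## boards leaving the sensor name the offending pose
  bad <- poses
  bad[[3]]$t[1] <- bad[[3]]$t[1] + 100
  expect_error(render_checkerboard_views(spec, bad, rig), "pose 3")

  ## the z-scan protocol: 601 fronto-parallel layers 5 um apart over 3 mm
  zp <- make_zscan_poses(checkerboard_spec(5, 8, 1.34), 5, 3)
  expect_length(zp, 601)
  zs <- vapply(zp, function(p) p$t[3], 0)
  expect_equal(unique(round(diff(zs), 10)), 0.005)
})

test_that("stack TIFF round-trips counts through 16-bit pages", {
  set.seed(18)
  frames <- array(sample(0:2000, 16 * 20 * 3, replace = TRUE),
                  c(16, 20, 3))
  st <- image_stack(frames, frame_rate = 40, exposure = 20,
                    transfer_gap = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path, frame_rate = 40, exposure = 20,
                          transfer_gap = 5)
  expect_equal(dim(back$frames), dim(frames))
  expect_equal(back$frames, frames)
})

test_that("acquisition timing identity is enforced on stacks", {
  fr <- array(0, c(4, 4, 2))
  expect_error(image_stack(fr, frame_rate = 50, exposure = 20,
                           transfer_gap = 5), "inconsistent")
  st <- image_stack(fr, frame_rate = 40, exposure = 20, transfer_gap = 5)
  expect_equal(st$frame_rate, 40)
})
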