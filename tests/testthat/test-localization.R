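test_that("flat-field correction inverts the sensor non-uniformity model", {
  H <- 16; W <- 20
  st <- image_stack(array(100, c(H, W, 2)))
  ## unit gain, zero offset: identity
  ff1 <- flat_field(matrix(1, H, W))
  expect_equal(flat_field_correct(st, ff1)$frames, st$frames)
  ## offset equal to a constant frame: all zeros
  ffc <- flat_field(matrix(1, H, W), matrix(100, H, W))
  expect_true(all(flat_field_correct(st, ffc)$frames == 0))
  ## synthesize gain * I + offset, recover I
  set.seed(4)
  gain <- matrix(runif(H * W, 0.8, 1.2), H, W)
  offset <- matrix(runif(H * W, 0, 50), H, W)
  I0 <- matrix(runif(H * W, 0, 500), H, W)
  raw <- image_stack(array(gain * I0 + offset, c(H, W, 1)))
  rec <- flat_field_correct(raw, flat_field(gain, offset))
  expect_equal(rec$frames[, , 1], I0, tolerance = 1e-12)
  ## shape mismatch errors
  expect_error(flat_field_correct(st, flat_field(matrix(1, 4, 4))), "shape")
  expect_error(flat_field(matrix(0, H, W)), "positive")
})

test_that("temporal background subtraction follows its closed form", {
  set.seed(5)
  H <- 12; W <- 12; T_ <- 10
  base <- matrix(runif(H * W, 50, 150), H, W)
  frames <- array(rep(base, T_), c(H, W, T_))
  ## one transient spot in frame 3 of amplitude a survives at a (1 - 1/T)
  a <- 200
  frames[5, 7, 3] <- frames[5, 7, 3] + a
  out <- subtract_background(image_stack(frames))
  expect_equal(out$frames[5, 7, 3], a * (1 - 1 / T_), tolerance = 1e-12)
  ## static scene: all residuals ~ 0 away from the transient
  expect_lt(max(abs(out$frames[, , 1][-(5 + (7 - 1) * H)])), 1e-9)
  ## invariant to adding any constant to all frames
  out2 <- subtract_background(image_stack(frames + 123))
  expect_equal(out2$frames, out$frames, tolerance = 1e-9)
  ## single frame is an error
  expect_error(subtract_background(image_stack(array(1, c(4, 4, 1)))),
               "2 frames")
})

test_that("wavelet detection finds spots and respects its threshold", {
  ## zero frame: no candidates
  expect_equal(nrow(wavelet_detect(matrix(0, 64, 64))), 0)
  ## level too deep for the frame errors
  expect_error(wavelet_detect(matrix(0, 16, 16), level = 5), "level")

  ## single Gaussian spot at SNR ~ 20: exactly one candidate within 1 px
  set.seed(6)
  fr <- gauss_frame(64, 64, c(30.2, 40.7), amplitude = 200, sigma = 1.3,
                    background = 0) + matrix(rnorm(64 * 64, 0, 10), 64, 64)
  cand <- wavelet_detect(fr, 2, 4)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$u - 30.2)^2 + (cand$v - 40.7)^2), 1)

  ## 50 well-separated spots: all found, none spurious
  set.seed(7)
  gx <- rep(seq(10, 118, length.out = 10), 5)
  gy <- rep(seq(12, 116, length.out = 5), each = 10)
  centers <- cbind(gx + runif(50, -2, 2), gy + runif(50, -2, 2))
  fr50 <- gauss_frame(128, 128, centers, amplitude = 500, sigma = 1.2,
                      background = 0) +
    matrix(rnorm(128 * 128, 0, 5), 128, 128)
  cand50 <- wavelet_detect(fr50, 2, 4)
  expect_equal(nrow(cand50), 50)
  d <- sqrt(outer(cand50$u, centers[, 1], `-`)^2 +
              outer(cand50$v, centers[, 2], `-`)^2)
  expect_lt(max(apply(d, 1, min)), 1.5)

  ## doubling k_sigma never increases the number of detections
  expect_lte(nrow(wavelet_detect(fr50, 2, 8)), nrow(cand50))
})

test_that("Gaussian fitting reaches sub-0.01 px accuracy noiselessly", {
  fr <- gauss_frame(48, 48, c(10.30, 20.70), amplitude = 2000, sigma = 1.5,
                    background = 100)
  f <- fit_gaussian(fr, list(u = 10, v = 21), 3)
  expect_lt(abs(f$u - 10.30), 0.01)
  expect_lt(abs(f$v - 20.70), 0.01)
  expect_equal(f$sigma, 1.5, tolerance = 0.01)
  expect_equal(f$background, 100, tolerance = 0.5)
})

test_that("candidates on pure noise are rejected by the fit bounds", {
  set.seed(8)
  rejected <- replicate(100, {
    fr <- matrix(rnorm(15 * 15, 0, 10), 15, 15)
    is.null(fit_gaussian(fr, list(u = 7, v = 7), 3))
  })
  expect_gte(mean(rejected), 0.95)
})

test_that("localization precision scales as one over root photon count", {
  set.seed(11)
  Ns <- c(300, 1000, 3000, 10000, 30000)  # two decades
  sds <- vapply(Ns, function(N) {
    errs <- replicate(150, {
      s <- 1.3
      u0 <- 7 + runif(1, -0.5, 0.5)
      uu <- matrix(0:14, 15, 15, byrow = TRUE)
      vv <- matrix(0:14, 15, 15)
      lam <- N / (2 * pi * s^2) *
        exp(-((uu - u0)^2 + (vv - 7)^2) / (2 * s^2))
      fr <- matrix(rpois(225, lam), 15, 15)
      f <- fit_gaussian(fr, list(u = round(u0), v = 7), 5)
      if (is.null(f)) NA else f$u - u0
    })
    sd(errs, na.rm = TRUE)
  }, 0)
  slope <- unname(coef(lm(log(sds) ~ log(Ns)))[2])
  expect_lt(abs(slope - (-0.5)), 0.05)
})

test_that("localization is equivariant to integer frame shifts", {
  set.seed(9)
  fr <- gauss_frame(64, 64, rbind(c(20.3, 25.6), c(41.7, 38.2)),
                    amplitude = 1500, sigma = 1.4, background = 50) +
    matrix(rnorm(64 * 64, 0, 3), 64, 64)
  shift <- function(m, du, dv) {
    out <- matrix(50, nrow(m), ncol(m))
    out[(1 + dv):nrow(m), (1 + du):ncol(m)] <-
      m[1:(nrow(m) - dv), 1:(ncol(m) - du)]
    out
  }
  loc <- function(m) {
    st <- image_stack(array(pmax(m, 0), c(64, 64, 1)))
    s <- localize_stack(st, list(subtract_bg = FALSE))
    s[order(s$u), ]
  }
  s0 <- loc(fr)
  s1 <- loc(shift(fr, 5, 3))
  expect_equal(nrow(s0), 2)
  expect_equal(s1$u, s0$u + 5, tolerance = 1e-6)
  expect_equal(s1$v, s0$v + 3, tolerance = 1e-6)
})

test_that("localize_stack handles empty stacks and threshold monotonicity", {
  empty <- image_stack(array(0, c(32, 32, 3)))
  expect_equal(nrow(localize_stack(empty)), 0)

  set.seed(10)
  frames <- array(rpois(64 * 64 * 4, 100), c(64, 64, 4))
  frames[30, 30, ] <- frames[30, 30, ] + 800
  st <- image_stack(frames)
  n4 <- nrow(localize_stack(st, list(k_sigma = 4, subtract_bg = FALSE)))
  n8 <- nrow(localize_stack(st, list(k_sigma = 8, subtract_bg = FALSE)))
  expect_lte(n8, n4)
})

test_that("diffusion depth inverts a monotone sigma(z) calibration", {
  zs <- seq(0.5, 3, by = 0.1)
  curve <- data.frame(z = zs, sigma = 0.8 + 0.4 * (zs - 0.5))
  ## exact inverse at a node
  r <- diffusion_depth(curve$sigma[6], curve)
  expect_equal(r$z, curve$z[6])
  expect_false(r$clamped)
  ## clamped below the curve start, flagged
  r2 <- diffusion_depth(0.1, curve)
  expect_equal(r2$z, 0.5)
  expect_true(r2$clamped)
  ## non-monotone curve errors
  bad <- curve; bad$sigma[10] <- bad$sigma[2]
  expect_error(diffusion_depth(1, bad), "monotone")
})

test_that("single-camera diffusion depth fluctuates more than stereo depth", {
  ## the dual-view vs spot-size depth comparison: same frames, two readouts
  scat <- scattering_model(beta_per_mm = 1.5)
  rig <- small_rig()
  obj <- rig$optics$object_pixel
  zs <- seq(1.2, 3, by = 0.05)
  curve <- data.frame(z = zs, sigma = pmax(scat$sigma_um(zs) / obj, 0.8))
  sc <- build_scene(scene_spec("static_point", position = c(0, 0, 2)))
  gt <- simulate_flow(sc, flow_spec(), duration = 4, frame_rate = 40)
  st <- render_stack(gt, rig, scattering = scat, seed = 47)
  s1 <- localize_stack(st[[1]], list(subtract_bg = FALSE))
  s2 <- localize_stack(st[[2]], list(subtract_bg = FALSE))
  pts <- pairs_to_points(match_stack(s1, s2, rig), rig)
  zdiff <- diffusion_depth(s1$sigma, curve)
  ## both unbiased...
  expect_equal(mean(pts$z), 2, tolerance = 0.02)
  expect_equal(mean(zdiff$z), 2, tolerance = 0.05)
  ## ...but the single-camera estimate has a much larger spread
  expect_gt(sd(zdiff$z), 3 * sd(pts$z))
})

test_that("spots CSV writer round-trips through the reader", {
  spots <- data.frame(frame = 1:2, u = c(1.5, 2.5), v = c(3.25, 4.75),
                      amplitude = c(10, 20), background = c(1, 2),
                      sigma = c(1.1, 1.2), residual = c(0.1, 0.2),
                      camera_id = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spots_csv(spots, path, header = "test")
  back <- read_table_csv(path)
  expect_equal(back$u, spots$u)
  expect_equal(back$sigma, spots$sigma)
})
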