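test_that("calibration path is a serpentine raster with edge slow-down", {
  geom <- screen_geometry()
  p <- generate_calibration_path(geom, n_lines = 5)

  # vertical position never decreases, and there are exactly n_lines - 1
  # downward increments (runs of increasing y)
  dy <- diff(p$target_y_px)
  expect_true(all(dy >= 0))
  runs <- rle(dy > 0)
  expect_identical(sum(runs$values), 4L)

  m <- 50
  expect_true(all(p$target_x_px >= m & p$target_x_px <= geom$width_px - m))
  expect_true(all(p$target_y_px >= m & p$target_y_px <= geom$height_px - m))

  # sampling density is higher near the ends of a sweep than mid-line
  first_line <- p[p$target_y_px == p$target_y_px[1], ]
  x <- first_line$target_x_px
  span <- range(x)
  third <- diff(span) / 3
  ends <- sum(x < span[1] + third | x > span[2] - third)
  middle <- sum(x >= span[1] + third & x <= span[2] - third)
  expect_gt(ends, middle)

  # ~1 minute at 30 fps with the default speeds (within 20%)
  expect_gt(nrow(p), 1800 * 0.8)
  expect_lt(nrow(p), 1800 * 1.2)
})

test_that("gaze direction is a unit look-at vector", {
  expect_equal(gaze_direction(c(0, 0, 0), c(0, 0, 10)), c(0, 0, 1))
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3) + 5
    v <- gaze_direction(a, b)
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
    expect_equal(gaze_direction(b, a), -v, tolerance = 1e-12)
  }
  set.seed(6)
  norms <- replicate(1000, {
    sum(gaze_direction(rnorm(3), rnorm(3) + 10)^2)
  })
  expect_true(all(abs(norms - 1) < 1e-12))
  expect_error(gaze_direction(c(1, 2, 3), c(1, 2, 3)), "coincides")
})

test_that("only the eyeballs move with gaze; pose moves everything", {
  geom <- screen_geometry()
  cam <- camera_model(geom)
  face <- face_model()
  cfg <- simulation_config(noise_sd_px = 0, blink_probability = 0)
  frontal <- head_pose(yaw = 0)

  # screen-centre target, frontal symmetric pose: pupil projections are
  # mirror-symmetric about the projected face midline
  fr <- simulate_frame(c(geom$width_px / 2, geom$height_px / 2),
                       frontal, face, cam, cfg)
  expect_true(fr$valid)
  lp <- colMeans(fr$xy[paste0("left_pupil_c", 1:4), ])
  rp <- colMeans(fr$xy[paste0("right_pupil_c", 1:4), ])
  mid <- cam$principal_point[1]
  expect_equal(lp[1] - mid, -(rp[1] - mid), tolerance = 1e-6)
  expect_equal(lp[2], rp[2], tolerance = 1e-6)

  # distinct targets: pupils move, rigid landmarks do not
  fr2 <- simulate_frame(c(200, 200), frontal, face, cam, cfg)
  rigid <- c("left_lateral", "left_medial", "right_medial", "right_lateral",
             "lip_philtrum")
  pupils <- grep("pupil", rownames(fr$xy), value = TRUE)
  expect_equal(fr$xy[rigid, ], fr2$xy[rigid, ], tolerance = 1e-12)
  expect_gt(max(abs(fr$xy[pupils, ] - fr2$xy[pupils, ])), 0.5)

  # distinct poses, same target: rigid landmarks move too
  fr3 <- simulate_frame(c(geom$width_px / 2, geom$height_px / 2),
                        head_pose(yaw = 20), face, cam, cfg)
  expect_gt(max(abs(fr$xy[rigid, ] - fr3$xy[rigid, ])), 0.5)
})

test_that("landmark noise has the configured standard deviation", {
  geom <- screen_geometry()
  cam <- camera_model(geom)
  face <- face_model()
  cfg <- simulation_config(noise_sd_px = 1, blink_probability = 0)
  set.seed(21)
  n <- 8000
  xs <- replicate(n, simulate_frame(c(1280, 720), head_pose(), face, cam,
                                    cfg)$xy["lip_philtrum", ])
  expect_equal(sd(xs[1, ]), 1, tolerance = 0.1)
  expect_equal(sd(xs[2, ]), 1, tolerance = 0.1)
})

test_that("zero-noise feature map is injective over a screen grid", {
  geom <- screen_geometry()
  cam <- camera_model(geom)
  face <- face_model()
  cfg <- simulation_config(noise_sd_px = 0, blink_probability = 0)
  targets <- expand.grid(x = seq(100, 2460, length.out = 10),
                         y = seq(100, 1340, length.out = 10))
  feats <- t(apply(targets, 1, function(tg) {
    fr <- simulate_frame(as.numeric(tg), head_pose(), face, cam, cfg)
    obs <- as.data.frame(as.list(setNames(
      as.numeric(t(fr$xy)),
      as.vector(t(outer(rownames(fr$xy), c("_x", "_y"), paste0))))))
    as.numeric(assemble_features(obs))
  }))
  d <- as.matrix(dist(feats, method = "maximum"))
  diag(d) <- Inf
  expect_gt(min(d), 1e-6)
})

test_that("sessions are reproducible and respect the blink model", {
  s1 <- quick_session(seed = 42, blink_probability = 0.1)
  s2 <- quick_session(seed = 42, blink_probability = 0.1)
  expect_identical(s1$landmarks, s2$landmarks)
  expect_identical(s1$truth, s2$truth)
  expect_identical(nrow(s1$landmarks), nrow(s1$truth))
  expect_identical(s1$landmarks$frame, s1$truth$frame)

  # blink-free sessions keep all likelihoods high
  s0 <- quick_session(seed = 7, blink_probability = 0)
  lik <- as.matrix(s0$landmarks[grep("_likelihood$", names(s0$landmarks))])
  expect_true(all(lik >= 0.9))

  # blinks degrade pupil likelihoods only
  lik1 <- as.matrix(s1$landmarks[grep("_likelihood$", names(s1$landmarks))])
  low <- lik1 < 0.7
  expect_gt(sum(low), 0)
  expect_true(all(grepl("pupil", colnames(lik1)[colSums(low) > 0])))

  # multi-pose sessions concatenate one sub-session per pose
  s3 <- quick_session(seed = 1, poses = list(head_pose(yaw = -20),
                                             head_pose(yaw = 0),
                                             head_pose(yaw = 20)))
  expect_identical(nrow(s3$landmarks), 3L * nrow(s3$path))
  expect_identical(s3$landmarks$frame, seq_len(nrow(s3$landmarks)) - 1L)
})

test_that("DLC-dialect CSV writes and reads round-trip", {
  s <- quick_session(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(s$landmarks[1:100, ], path)

  # schema: three header rows, 1 + 3 * 13 columns
  hdr <- readLines(path, n = 3)
  expect_match(hdr[1], "^scorer,")
  expect_match(hdr[2], "^bodyparts,")
  expect_match(hdr[3], "^coords,")
  expect_identical(length(strsplit(hdr[3], ",")[[1]]), 40L)

  back <- read_dlc_csv(path)
  expect_identical(attr(back, "landmarks"), raw_landmark_names())
  expect_equal(as.data.frame(back),
               as.data.frame(s$landmarks[1:100, ]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # empty session -> header-only file, empty table back
  write_dlc_csv(s$landmarks[0, ], path)
  expect_identical(length(readLines(path)), 3L)
  expect_identical(nrow(read_dlc_csv(path)), 0L)

  # malformed headers are rejected with the offending row named
  writeLines(c("scorer,a", "wrong,b", "coords,x"), path)
  expect_error(read_dlc_csv(path), "row 2")
})
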