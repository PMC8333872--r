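#' Simulation configuration
#'
#' Noise and blink model for the synthetic landmark tracker. Tracked points
#' receive isotropic Gaussian pixel noise; each frame is independently a
#' "blink" with probability `blink_probability`, in which case the eight
#' pupil-rim points receive likelihoods drawn from `blink_likelihood_range`
#' (below the 0.7 filter threshold) while all other points keep normal
#' likelihoods. Non-blink likelihoods are drawn from
#' `normal_likelihood_range`.
#'
#' @param noise_sd_px Landmark noise standard deviation, frame pixels.
#' @param blink_probability Per-frame blink/occlusion probability. The
#'   default 0.027 reproduces the 2.7% removed-frame rate of the reference
#'   recording protocol.
#' @param blink_likelihood_range,normal_likelihood_range Uniform sampling
#'   intervals for likelihood scores.
#' @param fps Frame rate (Hz).
#' @param seed Integer seed; all session randomness derives from it.
#' @param poses List of [head_pose()] objects; default three poses at yaw
#'   -20, 0, +20 degrees.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(noise_sd_px = 1, blink_probability = 0.027,
                              blink_likelihood_range = c(0, 0.7),
                              normal_likelihood_range = c(0.95, 1),
                              fps = 30, seed = 1L,
                              poses = list(head_pose(yaw = -20),
                                           head_pose(yaw = 0),
                                           head_pose(yaw = 20))) {
  stopifnot(noise_sd_px >= 0, blink_probability >= 0, blink_probability <= 1,
            fps > 0, length(blink_likelihood_range) == 2,
            length(normal_likelihood_range) == 2)
  if (blink_likelihood_range[2] > 0.7 + 1e-12) {
    stop("blink likelihoods must stay below the 0.7 filter threshold")
  }
  structure(list(noise_sd_px = noise_sd_px,
                 blink_probability = blink_probability,
                 blink_likelihood_range = blink_likelihood_range,
                 normal_likelihood_range = normal_likelihood_range,
                 fps = fps, seed = as.integer(seed), poses = poses),
            class = "simulation_config")
}

#' Generate a serpentine smooth-pursuit calibration path
#'
#' A small target traverses the screen in alternating left-right horizontal
#' sweeps connected by downward increments, covering the whole surface. The
#' target slows near direction changes and speeds up mid-sweep, so more
#' frames are sampled near the screen edges -- the sampling bias the spatial
#' balancing step later removes. The speed multiplier along a sweep of
#' relative position u in [0, 1] is
#' `slow_factor + (fast_factor - slow_factor) * sin(pi * u)^2`; vertical
#' connectors move at `slow_factor` times the base speed.
#'
#' With the defaults (5 lines, 310 px/s base speed, 30 fps) a session lasts
#' about one minute. (The session time is governed by the harmonic mean of
#' the speed profile, 1/sqrt(slow_factor * fast_factor) of the base speed.)
#'
#' @param geom A [screen_geometry()].
#' @param n_lines Number of horizontal sweeps (>= 2).
#' @param fps Frame rate (Hz).
#' @param slow_factor,fast_factor Speed multipliers at sweep ends / middle;
#'   both positive, normally `slow_factor < 1 < fast_factor`.
#' @param margin_px Margin kept from every screen edge.
#' @param speed_px_per_s Base target speed in px/s.
#' @return Data frame with `frame` (0-based), `target_x_px`, `target_y_px`.
#' @export
generate_calibration_path <- function(geom = screen_geometry(), n_lines = 5,
                                      fps = 30, slow_factor = 0.4,
                                      fast_factor = 1.6, margin_px = 50,
                                      speed_px_per_s = 310) {
  assert_geometry(geom)
  stopifnot(n_lines >= 2, slow_factor > 0, fast_factor > 0, fps > 0,
            speed_px_per_s > 0, margin_px >= 0)
  x0 <- margin_px; x1 <- geom$width_px - margin_px
  y0 <- margin_px; y1 <- geom$height_px - margin_px
  if (x1 <= x0 || y1 <= y0) stop("margin leaves no traversal span")
  ys <- seq(y0, y1, length.out = n_lines)

  xs <- numeric(0); yy <- numeric(0)
  for (i in seq_len(n_lines)) {
    from <- if (i %% 2 == 1) x0 else x1
    to <- if (i %% 2 == 1) x1 else x0
    len <- abs(to - from)
    s <- 0
    repeat {
      xs <- c(xs, from + sign(to - from) * s); yy <- c(yy, ys[i])
      if (s >= len) break
      u <- s / len
      mult <- slow_factor + (fast_factor - slow_factor) * sin(pi * u)^2
      s <- min(len, s + speed_px_per_s * mult / fps)
    }
    if (i < n_lines) {  # vertical increment at the current side, slow speed
      vlen <- ys[i + 1] - ys[i]
      vstep <- speed_px_per_s * slow_factor / fps
      s <- vstep
      while (s < vlen) {
        xs <- c(xs, to); yy <- c(yy, ys[i] + s)
        s <- s + vstep
      }
    }
  }
  data.frame(frame = seq_along(xs) - 1L, target_x_px = xs, target_y_px = yy)
}

#' Simulate one tracked frame
#'
#' Rotates each eyeball so that its pupil axis points at the 3D screen
#' target, projects the 13 raw landmark points through the pinhole camera,
#' adds isotropic Gaussian noise and draws likelihood scores (with an
#' optional blink event degrading the pupil points). Randomness is taken
#' from the current R RNG state.
#'
#' @param target_px Length-2 screen target (px).
#' @param pose A [head_pose()].
#' @param face A [face_model()].
#' @param cam A [camera_model()].
#' @param cfg A [simulation_config()].
#' @return A named list: `xy` (13 x 2 matrix of frame px, rows named as
#'   [raw_landmark_names()]), `likelihood` (length 13), `blink` (logical),
#'   `valid` (FALSE if any landmark fell behind the camera).
#' @export
simulate_frame <- function(target_px, pose, face, cam, cfg) {
  stopifnot(inherits(pose, "head_pose"), inherits(face, "face_model"),
            inherits(cam, "camera_model"), inherits(cfg, "simulation_config"))
  target3d <- drop(screen_to_camera(cam, target_px))
  R <- rotation_matrix(pose)
  rigid_cam <- t(R %*% t(face$rigid)) +
    matrix(pose$position, nrow(face$rigid), 3, byrow = TRUE)
  eyes_cam <- t(R %*% t(face$eye_centers)) +
    matrix(pose$position, 2, 3, byrow = TRUE)

  pupil_pts <- matrix(NA_real_, 8, 3)
  phis <- pi / 4 + (0:3) * pi / 2
  for (e in 1:2) {
    g <- gaze_direction(eyes_cam[e, ], target3d)
    center <- eyes_cam[e, ] + face$eyeball_radius_mm * g
    uv <- orthobasis(g)
    ring <- face$iris_ring_radius_mm *
      (outer(cos(phis), uv[1, ]) + outer(sin(phis), uv[2, ]))
    pupil_pts[(e - 1) * 4 + (1:4), ] <-
      ring + matrix(center, 4, 3, byrow = TRUE)
  }

  # assemble in raw_landmark_names() order
  pts3d <- rbind(rigid_cam["left_lateral", ], pupil_pts[1:4, ],
                 rigid_cam["left_medial", ], rigid_cam["right_medial", ],
                 pupil_pts[5:8, ], rigid_cam["right_lateral", ],
                 rigid_cam["lip_philtrum", ])
  xy <- project_points(cam, pts3d)
  valid <- !anyNA(xy)
  if (cfg$noise_sd_px > 0) {
    xy <- xy + matrix(stats::rnorm(26, 0, cfg$noise_sd_px), 13, 2)
  }
  lik <- stats::runif(13, cfg$normal_likelihood_range[1],
                      cfg$normal_likelihood_range[2])
  blink <- stats::runif(1) < cfg$blink_probability
  if (blink) {
    pupil_idx <- grep("pupil", raw_landmark_names())
    lik[pupil_idx] <- stats::runif(length(pupil_idx),
                                   cfg$blink_likelihood_range[1],
                                   cfg$blink_likelihood_range[2])
  }
  rownames(xy) <- raw_landmark_names()
  names(lik) <- raw_landmark_names()
  list(xy = xy, likelihood = lik, blink = blink, valid = valid)
}

#' Simulate a full multi-pose calibration session
#'
#' Runs the calibration path once per head pose (the poses' sub-sessions are
#' concatenated with continuous frame indices) and returns a DLC-dialect
#' landmark table row-aligned with a ground-truth target table.
#'
#' @param path Calibration path from [generate_calibration_path()].
#' @param face A [face_model()].
#' @param cam A [camera_model()].
#' @param cfg A [simulation_config()]; `cfg$poses` defines the sub-sessions
#'   and `cfg$seed` all randomness.
#' @param n_frames Optional total frame budget; the concatenated session is
#'   truncated to this many frames.
#' @return List with `landmarks` (data frame: `frame` plus
#'   `<landmark>_x/_y/_likelihood` for the 13 raw landmarks), `truth`
#'   (data frame: `frame`, `target_x_px`, `target_y_px`) and `n_blinks`.
#' @export
simulate_session <- function(path, face = face_model(),
                             cam = camera_model(),
                             cfg = simulation_config(), n_frames = NULL) {
  stopifnot(is.data.frame(path), nrow(path) > 0, length(cfg$poses) > 0)
  set.seed(cfg$seed)
  n_per_pose <- nrow(path)
  n_total <- n_per_pose * length(cfg$poses)
  lm_names <- raw_landmark_names()
  out <- matrix(NA_real_, n_total, 39)
  truth <- matrix(NA_real_, n_total, 2)
  blinks <- logical(n_total)
  row <- 0L
  for (pose in cfg$poses) {
    for (i in seq_len(n_per_pose)) {
      row <- row + 1L
      fr <- simulate_frame(c(path$target_x_px[i], path$target_y_px[i]),
                           pose, face, cam, cfg)
      out[row, ] <- as.numeric(t(cbind(fr$xy, fr$likelihood)))
      truth[row, ] <- c(path$target_x_px[i], path$target_y_px[i])
      blinks[row] <- fr$blink
    }
  }
  if (!is.null(n_frames)) {
    n_keep <- min(n_frames, n_total)
    out <- out[seq_len(n_keep), , drop = FALSE]
    truth <- truth[seq_len(n_keep), , drop = FALSE]
    blinks <- blinks[seq_len(n_keep)]
  }
  cols <- as.vector(t(outer(lm_names, c("_x", "_y", "_likelihood"), paste0)))
  landmarks <- data.frame(frame = seq_len(nrow(out)) - 1L, out)
  names(landmarks) <- c("frame", cols)
  truth_df <- data.frame(frame = landmarks$frame,
                         target_x_px = truth[, 1], target_y_px = truth[, 2])
  list(landmarks = landmarks, truth = truth_df, n_blinks = sum(blinks))
}
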