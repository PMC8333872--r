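# Shared fixtures, built in code at test time.

# A short calibration session: default screen geometry, fast target so the
# session stays small, single or multiple poses.
quick_session <- function(seed = 1L, speed = 2500, noise_sd_px = 1,
                          blink_probability = 0, poses = NULL,
                          n_frames = NULL) {
  geom <- screen_geometry()
  path <- generate_calibration_path(geom, speed_px_per_s = speed)
  if (is.null(poses)) poses <- list(head_pose(yaw = 0))
  cfg <- simulation_config(noise_sd_px = noise_sd_px,
                           blink_probability = blink_probability,
                           seed = seed, poses = poses)
  sess <- simulate_session(path, face_model(), camera_model(geom), cfg,
                           n_frames = n_frames)
  c(sess, list(geom = geom, cfg = cfg, path = path))
}

# Preprocessed dataset from a quick session, as feature/target matrices.
quick_dataset <- function(seed = 1L, speed = 2500, noise_sd_px = 1,
                          poses = list(head_pose(yaw = 0))) {
  s <- quick_session(seed = seed, speed = speed, noise_sd_px = noise_sd_px,
                     poses = poses)
  pp <- preprocess_session(s$landmarks, s$truth, s$geom, seed = seed)
  ds <- pp$dataset
  fc <- feature_column_names()
  list(ds = ds, geom = s$geom,
       x = as.matrix(ds[fc]),
       y = as.matrix(ds[c("target_x_px", "target_y_px")]))
}

split_matrices <- function(qd, scale = 2560) {
  sel <- function(lbl) qd$ds$split == lbl
  list(xt = qd$x[sel("train"), ], yt = qd$y[sel("train"), ] / scale,
       xv = qd$x[sel("validation"), ], yv = qd$y[sel("validation"), ] / scale,
       xe = qd$x[sel("test"), ], ye = qd$y[sel("test"), ])
}

flatten_params <- function(p) c(as.numeric(p$W1), p$b1, as.numeric(p$W2), p$b2)

unflatten_params <- function(v, h) {
  i <- 0
  W1 <- matrix(v[i + 1:(h * 14)], h, 14); i <- i + h * 14
  b1 <- v[i + 1:h]; i <- i + h
  W2 <- matrix(v[i + 1:(2 * h)], 2, h); i <- i + 2 * h
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = v[i + 1:2]),
            class = "gaze_mlp")
}

# Max relative deviation between the analytic mini-batch gradient and
# central finite differences, over `n_repeats` random (params, batch) pairs.
gradient_check_max_rel <- function(n_repeats = 10, n_coords = 50,
                                   h = 20, eps = 1e-5, seed = 99) {
  set.seed(seed)
  worst <- 0
  for (r in seq_len(n_repeats)) {
    cfg <- train_config(n_hidden = h)
    p <- init_gaze_mlp(cfg)
    p$b1 <- stats::rnorm(h, 0, 0.5); p$b2 <- stats::rnorm(2, 0, 0.5)
    X <- matrix(stats::runif(14 * 4), 14, 4)
    Y <- matrix(stats::runif(2 * 4), 2, 4)
    gv <- flatten_params(gaze_mlp_grad(p, X, Y))
    pv <- flatten_params(p)
    for (j in sample(length(pv), n_coords)) {
      pp <- pv; pp[j] <- pp[j] + eps
      pm <- pv; pm[j] <- pm[j] - eps
      num <- (l2_loss(gaze_mlp_forward(unflatten_params(pp, h), X), Y) -
                l2_loss(gaze_mlp_forward(unflatten_params(pm, h), X), Y)) /
        (2 * eps)
      worst <- max(worst, abs(gv[j] - num) / max(abs(num), 1e-3))
    }
  }
  worst
}

# Validation-loss traces for five training runs differing in the random
# frame split and the training seed, mirroring repeated-training stability
# checks. Returns a list of trace data frames.
five_seed_traces <- function(max_epochs = 400) {
  s <- quick_session(seed = 3, speed = 2500, noise_sd_px = 1)
  lapply(1:5, function(k) {
    pp <- preprocess_session(s$landmarks, s$truth, s$geom, seed = k)
    qd <- list(ds = pp$dataset, geom = s$geom,
               x = as.matrix(pp$dataset[feature_column_names()]),
               y = as.matrix(pp$dataset[c("target_x_px", "target_y_px")]))
    m <- split_matrices(qd)
    cfg <- train_config(max_epochs = max_epochs, seed = 100 + k)
    train_gaze_mlp(m$xt, m$yt, m$xv, m$yv, cfg)$trace
  })
}

# Plateau bands (mean +/- within-run SD over the last third of evaluations)
# for a list of traces; TRUE if all bands pairwise overlap.
plateau_bands_overlap <- function(traces) {
  stats_ <- vapply(traces, function(tr) {
    tail_part <- tr$val_loss[tr$epoch > max(tr$epoch) * 2 / 3]
    c(mean(tail_part), stats::sd(tail_part))
  }, numeric(2))
  m <- stats_[1, ]; s <- stats_[2, ]
  for (i in 1:4) for (j in (i + 1):5) {
    if (abs(m[i] - m[j]) > s[i] + s[j]) return(FALSE)
  }
  TRUE
}
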