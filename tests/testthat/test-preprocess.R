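test_that("pupil centre is the mean of the four rim corners", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(pupil_center(sq), c(1, 1))
  p <- c(3.2, -1.5)
  expect_equal(pupil_center(rbind(p, p, p, p)), p, ignore_attr = TRUE)
  set.seed(8)
  q <- matrix(rnorm(8), 4, 2)
  brute <- c(sum(q[, 1]), sum(q[, 2])) / 4
  expect_equal(pupil_center(q), brute, tolerance = 1e-15)
  expect_error(pupil_center(q[1:3, ]), "4")
})

test_that("likelihood filter drops a frame iff any landmark is below threshold", {
  s <- quick_session(seed = 2, blink_probability = 0)
  lm <- s$landmarks
  res <- filter_low_likelihood(lm, 0.7)
  expect_identical(res$n_removed, 0L)
  expect_identical(nrow(res$kept), nrow(lm))

  # one landmark at 0.69 in one frame: exactly that frame goes (strict <)
  lm2 <- lm
  lm2$lip_philtrum_likelihood[5] <- 0.69
  lm2$left_lateral_likelihood[9] <- 0.7   # boundary value is kept
  res2 <- filter_low_likelihood(lm2, 0.7)
  expect_identical(res2$removed_frames, lm2$frame[5])
  expect_identical(res2$n_removed, 1L)
  expect_equal(res2$fraction_removed, 1 / nrow(lm2))

  # monotone in threshold: kept set shrinks as the threshold rises
  s3 <- quick_session(seed = 13, blink_probability = 0.2)
  kept_frames <- lapply(c(0.2, 0.5, 0.7, 0.9),
                        function(t) filter_low_likelihood(s3$landmarks, t)$kept$frame)
  for (i in 1:3) {
    expect_true(all(kept_frames[[i + 1]] %in% kept_frames[[i]]))
  }
})

test_that("injected blink rate is recovered by the filter", {
  s <- quick_session(seed = 31, speed = 310, blink_probability = 0.027,
                     poses = list(head_pose(yaw = -20), head_pose(yaw = 0)),
                     n_frames = 3569)
  expect_identical(nrow(s$landmarks), 3569L)
  res <- filter_low_likelihood(s$landmarks, 0.7)
  p <- 0.027
  tol <- 3 * sqrt(p * (1 - p) / 3569)
  expect_lt(abs(res$fraction_removed - p), tol)
})

test_that("feature assembly yields the 14-vector in the documented order", {
  # synthetic observation with distinct values per raw landmark coordinate
  lms <- raw_landmark_names()
  obs <- as.data.frame(as.list(setNames(
    seq_along(lms) * 10, paste0(lms, "_x"))))
  for (lm in lms) obs[[paste0(lm, "_y")]] <- obs[[paste0(lm, "_x")]] + 1
  f <- assemble_features(obs, norm_constant = 600)
  expect_identical(dim(f), c(1L, 14L))
  expect_identical(colnames(f), feature_column_names())
  # pupil centres are the average of the four rim corners
  expect_equal(f[1, "left_pupil_x"], mean(2:5 * 10) / 600,
               ignore_attr = TRUE)
  expect_equal(f[1, "right_pupil_x"], mean(8:11 * 10) / 600,
               ignore_attr = TRUE)
  expect_equal(f[1, "lip_philtrum_y"], (13 * 10 + 1) / 600,
               ignore_attr = TRUE)

  # homogeneous normalization: constants map to constants, scaling is linear
  obs600 <- obs; obs600[] <- 600
  expect_true(all(assemble_features(obs600) == 1))
  obs0 <- obs; obs0[] <- 0
  expect_true(all(assemble_features(obs0) == 0))
  obs_scaled <- obs; obs_scaled[] <- obs[] * 3
  expect_equal(assemble_features(obs_scaled), assemble_features(obs) * 3,
               tolerance = 1e-12)

  obs$lip_philtrum_x <- NULL
  expect_error(assemble_features(obs), "lip_philtrum")
})

test_that("spatial balancing equalizes occupied tiles at the minimum count", {
  geom <- screen_geometry()
  # three occupied tiles (edge 530) with counts 5, 3, 7
  mk <- function(n, cx, cy) data.frame(target_x_px = runif(n, cx - 50, cx + 50),
                                       target_y_px = runif(n, cy - 50, cy + 50))
  set.seed(4)
  samples <- rbind(mk(5, 265, 265), mk(3, 795, 265), mk(7, 1325, 265))
  expect_warning(bal <- balance_spatial(samples, geom, 530, seed = 1),
                 "tiles contain no samples")
  expect_identical(bal$min_count, 3L)
  expect_identical(nrow(bal$samples), 9L)
  expect_true(all(bal$per_tile$count_after == 3))

  # already-equal counts: a permutation-invariant subset of the same size
  expect_warning(bal2 <- balance_spatial(bal$samples, geom, 530, seed = 1))
  expect_identical(nrow(bal2$samples), 9L)

  # idempotence under the fixed seed policy
  expect_warning(bal3 <- balance_spatial(bal2$samples, geom, 530, seed = 1))
  expect_identical(bal2$samples, bal3$samples)

  expect_error(balance_spatial(samples[0, ], geom, 530, 1), "no samples")
})

test_that("balancing a simulated session removes the edge oversampling", {
  s <- quick_session(seed = 17, speed = 1200)
  pp_in <- data.frame(target_x_px = s$truth$target_x_px,
                      target_y_px = s$truth$target_y_px)
  grid <- tile_screen(s$geom, 530)
  before <- tabulate(tile_index(grid, pp_in$target_x_px,
                                pp_in$target_y_px)$tile, n_tiles(grid))
  expect_gt(sd(before[before > 0]), 0)  # raw counts are uneven
  bal <- balance_spatial(pp_in, s$geom, 530, seed = 2)
  after <- tabulate(tile_index(grid, bal$samples$target_x_px,
                               bal$samples$target_y_px)$tile, n_tiles(grid))
  expect_true(all(after[after > 0] == bal$min_count))
})

test_that("dataset splitting follows the 50/25/25 floor rule", {
  mk <- function(n) data.frame(i = seq_len(n))
  tab <- function(d) as.integer(table(d$split))
  expect_identical(tab(split_dataset(mk(100), seed = 1)), c(50L, 25L, 25L))
  expect_identical(tab(split_dataset(mk(101), seed = 1)), c(51L, 25L, 25L))
  expect_identical(tab(split_dataset(mk(7), seed = 1)), c(5L, 1L, 1L))

  a <- split_dataset(mk(100), seed = 5)
  b <- split_dataset(mk(100), seed = 5)
  c_ <- split_dataset(mk(100), seed = 6)
  expect_identical(a$split, b$split)
  expect_false(identical(a$split, c_$split))
  expect_error(split_dataset(mk(3)), "at least 4")
  expect_error(split_dataset(mk(10), fractions = c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("the preprocessing chain is deterministic and frame-aligned", {
  s <- quick_session(seed = 23, blink_probability = 0.05)
  p1 <- preprocess_session(s$landmarks, s$truth, s$geom, seed = 9)
  p2 <- preprocess_session(s$landmarks, s$truth, s$geom, seed = 9)
  expect_identical(p1$dataset, p2$dataset)
  expect_identical(p1$report$n_removed_by_filter, p2$report$n_removed_by_filter)

  # split is a partition
  expect_identical(sum(as.integer(table(p1$dataset$split))),
                   nrow(p1$dataset))

  # features stay within the normalized frame bounds
  f <- as.matrix(p1$dataset[feature_column_names()])
  expect_true(all(f > 0 & f < 650 / 600))

  expect_error(preprocess_session(s$landmarks[-1, ], s$truth, s$geom),
               "frame-aligned")
})
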