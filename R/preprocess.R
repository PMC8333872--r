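#' Pupil centre from four pupil-rim corners
#'
#' The pupil centre is estimated as the componentwise arithmetic mean of the
#' four tracked pupil-corner points.
#'
#' @param four_corner_points A 4 x 2 matrix (or coercible) of frame-pixel
#'   points.
#' @return Length-2 numeric pupil centre.
#' @export
pupil_center <- function(four_corner_points) {
  pts <- as.matrix(four_corner_points)
  if (!is.numeric(pts) || nrow(pts) != 4 || ncol(pts) != 2 ||
      !all(is.finite(pts))) {
    stop("`four_corner_points` must be exactly 4 finite (x, y) points")
  }
  colMeans(pts)
}

likelihood_cols <- function(observations) {
  grep("_likelihood$", names(observations), value = TRUE)
}

#' Remove frames with any low-likelihood landmark
#'
#' A frame is dropped if and only if the likelihood score of at least one
#' landmark is strictly below `threshold`. Corrupted frames (e.g. closed
#' eyes) typically carry low pupil likelihoods and are removed here.
#'
#' @param observations Landmark data frame (`frame` plus
#'   `<landmark>_x/_y/_likelihood` columns).
#' @param threshold Likelihood threshold in `[0, 1]`; default 0.7.
#' @return List with `kept` (filtered data frame), `removed_frames` (frame
#'   indices), `n_removed` and `fraction_removed`.
#' @export
filter_low_likelihood <- function(observations, threshold = 0.7) {
  stopifnot(is.data.frame(observations),
            threshold >= 0, threshold <= 1)
  lcols <- likelihood_cols(observations)
  if (length(lcols) == 0) stop("no likelihood columns found")
  lik <- as.matrix(observations[lcols])
  drop <- rowSums(lik < threshold) > 0
  list(kept = observations[!drop, , drop = FALSE],
       removed_frames = observations$frame[drop],
       n_removed = sum(drop),
       fraction_removed = if (nrow(observations)) mean(drop) else 0)
}

#' Assemble the 14-element feature vector(s)
#'
#' Derives the two pupil centres by averaging the four pupil-rim corners of
#' each eye ([pupil_center()]), orders the seven landmarks as
#' [feature_landmark_names()] (left lateral, left pupil, left medial, right
#' medial, right pupil, right lateral, lip) and divides every coordinate
#' homogeneously by `norm_constant`. With the default 600 (the larger camera
#' frame dimension) all features fall in roughly `[0, 1]` while relative
#' point positions are preserved.
#'
#' @param observations Landmark data frame containing the full raw landmark
#'   set ([raw_landmark_names()]).
#' @param norm_constant Homogeneous normalization constant; default 600.
#' @return n x 14 numeric matrix, columns `<landmark>_x`, `<landmark>_y` in
#'   the fixed feature order.
#' @export
assemble_features <- function(observations, norm_constant = 600) {
  stopifnot(is.data.frame(observations), norm_constant > 0)
  need <- raw_landmark_names()
  for (lm in need) {
    if (!all(paste0(lm, c("_x", "_y")) %in% names(observations))) {
      stop(sprintf("missing landmark '%s' in observations", lm))
    }
  }
  get <- function(lm, ax) observations[[paste0(lm, "_", ax)]]
  pupil <- function(side, ax) {
    rowMeans(cbind(get(paste0(side, "_pupil_c1"), ax),
                   get(paste0(side, "_pupil_c2"), ax),
                   get(paste0(side, "_pupil_c3"), ax),
                   get(paste0(side, "_pupil_c4"), ax)))
  }
  coord <- function(lm, ax) {
    if (lm == "left_pupil") pupil("left", ax)
    else if (lm == "right_pupil") pupil("right", ax)
    else get(lm, ax)
  }
  feats <- do.call(cbind, unlist(lapply(feature_landmark_names(), function(lm) {
    list(coord(lm, "x"), coord(lm, "y"))
  }), recursive = FALSE))
  colnames(feats) <- as.vector(t(outer(feature_landmark_names(),
                                       c("_x", "_y"), paste0)))
  feats / norm_constant
}

#' Spatially balance samples across screen tiles
#'
#' The slow-down of the calibration target near the screen edges oversamples
#' those regions. Balancing tiles the screen (default 530-px squares), takes
#' the smallest per-tile sample count over the *occupied* tiles, and draws
#' exactly that many samples uniformly without replacement from every
#' occupied tile. Empty tiles contribute nothing and trigger a warning.
#'
#' @param samples Data frame with `target_x_px`, `target_y_px` columns.
#' @param geom A [screen_geometry()].
#' @param edge_px Tile edge in pixels; default 530.
#' @param seed Integer seed for the subsampling.
#' @return List with `samples` (balanced subset, original row order),
#'   `per_tile` (data frame of tile, count_before, count_after) and
#'   `min_count`.
#' @export
balance_spatial <- function(samples, geom = screen_geometry(), edge_px = 530,
                            seed = 1L) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0) stop("no samples to balance")
  grid <- tile_screen(geom, edge_px)
  idx <- tile_index(grid, samples$target_x_px, samples$target_y_px)
  counts <- tabulate(idx$tile, nbins = n_tiles(grid))
  occupied <- which(counts > 0)
  if (length(occupied) < n_tiles(grid)) {
    warning(sprintf("%d of %d tiles contain no samples; balancing over occupied tiles only",
                    n_tiles(grid) - length(occupied), n_tiles(grid)))
  }
  m <- min(counts[occupied])
  set.seed(seed)
  keep <- unlist(lapply(occupied, function(tl) {
    rows <- which(idx$tile == tl)
    if (length(rows) == 1) rows else sample(rows, m)
  }))
  keep <- sort(keep)
  list(samples = samples[keep, , drop = FALSE],
       per_tile = data.frame(tile = occupied,
                             count_before = counts[occupied],
                             count_after = m),
       min_count = m)
}

#' Split samples into training / validation / test sets
#'
#' Uniformly random seeded partition. Validation and test sizes are
#' floor-based; the remainder goes to the training set, so 101 samples at
#' (0.50, 0.25, 0.25) give 51/25/25.
#'
#' @param samples Data frame of samples (n >= 4).
#' @param fractions Length-3 positive fractions (train, validation, test)
#'   summing to 1.
#' @param seed Integer seed.
#' @return `samples` with an added `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
split_dataset <- function(samples, fractions = c(0.50, 0.25, 0.25),
                          seed = 1L) {
  stopifnot(is.data.frame(samples), length(fractions) == 3,
            all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- nrow(samples)
  if (n < 4) stop("need at least 4 samples to split")
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  set.seed(seed)
  perm <- sample.int(n)
  split <- rep("train", n)
  split[perm[seq_len(n_val)]] <- "validation"
  split[perm[n_val + seq_len(n_test)]] <- "test"
  samples$split <- factor(split, levels = c("train", "validation", "test"))
  samples
}

#' Full preprocessing chain
#'
#' Filter low-likelihood frames, align with the ground-truth target trace,
#' assemble normalized features, spatially balance on the screen grid, and
#' split 50/25/25. Filtering precedes balancing so corrupted frames cannot
#' consume a tile's quota.
#'
#' @param landmarks Landmark data frame (e.g. [read_dlc_csv()] or
#'   [simulate_session()]).
#' @param truth Target data frame (`frame`, `target_x_px`, `target_y_px`),
#'   row-aligned with `landmarks` by frame index.
#' @param geom A [screen_geometry()].
#' @param likelihood_threshold Filter threshold; default 0.7.
#' @param balance_edge_px Balancing tile edge; default 530.
#' @param fractions Split fractions; default c(0.50, 0.25, 0.25).
#' @param norm_constant Feature normalization constant; default 600.
#' @param seed Integer master seed for balancing and splitting.
#' @return List with `dataset` (data frame: `frame`, 14 feature columns,
#'   `target_x_px`, `target_y_px`, `split`) and `report` (counts, per-tile
#'   table, split sizes, seeds).
#' @export
preprocess_session <- function(landmarks, truth, geom = screen_geometry(),
                               likelihood_threshold = 0.7,
                               balance_edge_px = 530,
                               fractions = c(0.50, 0.25, 0.25),
                               norm_constant = 600, seed = 1L) {
  stopifnot(is.data.frame(landmarks), is.data.frame(truth))
  if (nrow(landmarks) != nrow(truth) ||
      !all(landmarks$frame == truth$frame)) {
    stop("landmark and target tables are not frame-aligned")
  }
  flt <- filter_low_likelihood(landmarks, likelihood_threshold)
  kept_truth <- truth[match(flt$kept$frame, truth$frame), , drop = FALSE]
  feats <- assemble_features(flt$kept, norm_constant)
  ds <- data.frame(frame = flt$kept$frame, feats,
                   target_x_px = kept_truth$target_x_px,
                   target_y_px = kept_truth$target_y_px,
                   check.names = FALSE)
  bal_seed <- derive_seed(seed, "balance")
  split_seed <- derive_seed(seed, "split")
  bal <- balance_spatial(ds, geom, balance_edge_px, seed = bal_seed)
  ds <- split_dataset(bal$samples, fractions, seed = split_seed)
  rownames(ds) <- NULL
  list(dataset = ds,
       report = list(
         n_input = nrow(landmarks),
         n_removed_by_filter = flt$n_removed,
         fraction_removed = flt$fraction_removed,
         likelihood_threshold = likelihood_threshold,
         balance_edge_px = balance_edge_px,
         per_tile = bal$per_tile,
         min_tile_count = bal$min_count,
         n_balanced = nrow(ds),
         split_sizes = as.list(table(ds$split)),
         fractions = fractions,
         seed = seed, balance_seed = bal_seed, split_seed = split_seed))
}

#' Column names of the 14 feature columns
#' @return Character vector of length 14.
#' @export
feature_column_names <- function() {
  as.vector(t(outer(feature_landmark_names(), c("_x", "_y"), paste0)))
}
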