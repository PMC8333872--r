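#' Mean Euclidean error in pixels
#'
#' \deqn{E_{px} = \frac{1}{n}\sum_i \sqrt{\Delta x_i^2 + \Delta y_i^2}}
#' i.e. the mean of the per-sample error norms (not the norm of the mean
#' deviation).
#'
#' @param deltas n x 2 matrix of per-sample (dx, dy) deviations in px.
#' @return Scalar mean error in pixels.
#' @export
mean_error_px <- function(deltas) {
  d <- as.matrix(deltas)
  if (nrow(d) == 0) stop("empty input")
  stopifnot(ncol(d) == 2, all(is.finite(d)))
  mean(sqrt(rowSums(d^2)))
}

#' Histogram of error magnitudes
#'
#' Relative frequencies over `n_bins` equal-width bins spanning
#' `[0, max(errors)]`, with the median reported alongside.
#'
#' @param errors_dva Non-negative error magnitudes (any unit).
#' @param n_bins Number of bins; default 30.
#' @return List with `breaks`, `relative_frequency` (sums to 1), `mids`,
#'   `median`.
#' @export
error_histogram <- function(errors_dva, n_bins = 30) {
  stopifnot(length(errors_dva) > 0, all(is.finite(errors_dva)),
            all(errors_dva >= 0), n_bins >= 1)
  top <- max(errors_dva)
  if (top == 0) top <- .Machine$double.eps
  breaks <- seq(0, top, length.out = n_bins + 1)
  h <- graphics::hist(errors_dva, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(breaks = h$breaks,
       relative_frequency = h$counts / length(errors_dva),
       mids = h$mids,
       median = stats::median(errors_dva))
}

#' Per-region mean error map with neighbor fill
#'
#' Tiles the screen (default 160-px squares, 144 regions on the default
#' screen), averages the error of the ground-truth targets falling in each
#' tile, and fills tiles with no targets with the mean of their adjacent
#' (8-connected) occupied tiles in a single pass. Tiles with no occupied
#' neighbor remain `NA` and are flagged `"undefined"`; observed tile values
#' are never altered by the fill.
#'
#' @param truth_x,truth_y Ground-truth target coordinates (px).
#' @param errors Per-sample error magnitudes (same length).
#' @param geom A [screen_geometry()].
#' @param edge_px Tile edge; default 160.
#' @return List with `grid` (the [tile_screen()] object), `mean_error` and
#'   `count` (`n_rows` x `n_cols` matrices) and `status` (character matrix:
#'   `"observed"`, `"filled"`, `"undefined"`).
#' @export
region_error_map <- function(truth_x, truth_y, errors,
                             geom = screen_geometry(), edge_px = 160) {
  stopifnot(length(truth_x) == length(errors),
            length(truth_y) == length(errors))
  grid <- tile_screen(geom, edge_px)
  idx <- tile_index(grid, truth_x, truth_y)
  nr <- grid$n_rows; nc <- grid$n_cols
  mean_err <- matrix(NA_real_, nr, nc)
  count <- matrix(0L, nr, nc)
  agg <- tapply(errors, idx$tile, mean)
  cnt <- table(idx$tile)
  for (k in seq_along(agg)) {
    tl <- as.integer(names(agg)[k])
    r <- (tl - 1L) %/% nc + 1L; cc <- (tl - 1L) %% nc + 1L
    mean_err[r, cc] <- agg[[k]]
    count[r, cc] <- as.integer(cnt[[k]])
  }
  status <- matrix(ifelse(count > 0, "observed", "undefined"), nr, nc)
  filled <- mean_err
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (count[r, cc] > 0) next
    rr <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, cc - 1):min(nc, cc + 1)
    nb <- mean_err[rr, cs]          # original occupancy only: single pass
    nb_occ <- nb[count[rr, cs] > 0]
    if (length(nb_occ) > 0) {
      filled[r, cc] <- mean(nb_occ)
      status[r, cc] <- "filled"
    }
  }
  list(grid = grid, mean_error = filled, count = count, status = status)
}

#' Linear regression of error on eccentricity
#'
#' Ordinary least squares of error magnitude on Euclidean distance from the
#' screen centre, with the two-sided t-test p-value for the slope
#' (`n - 2` df). `mode = "region"` (the default) regresses per-tile mean
#' errors on tile-centre eccentricities; `mode = "sample"` uses the raw
#' per-sample errors.
#'
#' @param truth_x,truth_y Ground-truth target coordinates (px).
#' @param errors Per-sample error magnitudes.
#' @param geom A [screen_geometry()].
#' @param mode `"region"` or `"sample"`.
#' @param edge_px Tile edge for region mode; default 160.
#' @return List with `slope`, `intercept`, `p_value`, `n`, `mode`.
#' @export
eccentricity_regression <- function(truth_x, truth_y, errors,
                                    geom = screen_geometry(),
                                    mode = c("region", "sample"),
                                    edge_px = 160) {
  mode <- match.arg(mode)
  if (mode == "region") {
    rem <- region_error_map(truth_x, truth_y, errors, geom, edge_px)
    obs <- which(rem$status == "observed", arr.ind = TRUE)
    cx <- (obs[, "col"] - 0.5) * edge_px
    cy <- (obs[, "row"] - 0.5) * edge_px
    ecc <- eccentricity(cx, cy, geom)
    err <- rem$mean_error[obs]
  } else {
    ecc <- eccentricity(truth_x, truth_y, geom)
    err <- errors
  }
  if (length(err) < 3) stop("need at least 3 points for the regression")
  if (stats::sd(ecc) == 0) stop("degenerate design: constant eccentricity")
  fit <- stats::lm(err ~ ecc)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["ecc", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p_value = unname(cf["ecc", "Pr(>|t|)"]),
       n = length(err), mode = mode)
}

#' Gaussian kernel density of estimation offsets
#'
#' 2D Gaussian kernel density estimate of the (dx, dy) offsets between
#' estimated and true gaze positions, evaluated on a square grid centred on
#' (0, 0), with equally spaced density levels for contouring. Bandwidths
#' follow Scott's rule for two dimensions, `sd * n^(-1/6)` per axis
#' (recorded in the result); the density is computed with [MASS::kde2d()].
#'
#' @param dx,dy Per-sample offsets (px); at least two non-identical points.
#' @param grid_n Grid resolution per axis; default 400.
#' @param n_levels Number of density levels; default 12.
#' @return List with `x`, `y`, `z` (density grid), `levels`, `bandwidth`
#'   (Scott per-axis sd) and `n`.
#' @export
offset_density <- function(dx, dy, grid_n = 400, n_levels = 12) {
  stopifnot(length(dx) == length(dy), length(dx) >= 2,
            all(is.finite(dx)), all(is.finite(dy)))
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0) {
    stop("offsets are (near-)identical: kernel bandwidth would be singular")
  }
  n <- length(dx)
  bw <- c(stats::sd(dx), stats::sd(dy)) * n^(-1 / 6)
  lim <- max(abs(c(dx, dy))) * 1.1
  # kde2d divides h by 4 internally, so pass 4x the kernel sd
  kd <- MASS::kde2d(dx, dy, h = 4 * bw, n = grid_n,
                    lims = c(-lim, lim, -lim, lim))
  levels <- seq(0, max(kd$z), length.out = n_levels + 1)[-1]
  list(x = kd$x, y = kd$y, z = kd$z, levels = levels, bandwidth = bw, n = n)
}

#' Full error report for a set of gaze estimates
#'
#' Computes per-sample deviations (estimate minus ground truth), error
#' magnitudes in pixels and degrees of visual angle (each sample converted
#' individually via the width-based formula), and all summary analyses:
#' median dva error, mean pixel error, 30-bin histogram, 160-px region map
#' with neighbor fill, eccentricity regression and offset density.
#'
#' @param estimates n x 2 matrix of estimated screen positions (px).
#' @param truth n x 2 matrix of ground-truth positions (px).
#' @param geom A [screen_geometry()].
#' @param hist_bins Histogram bins; default 30.
#' @param region_edge_px Region-map tile edge; default 160.
#' @param kde_grid_n,kde_levels Offset-density settings; defaults 400, 12.
#' @param regression_mode `"region"` (default) or `"sample"`.
#' @return An object of class `gaze_error_report`: `per_sample` data frame
#'   (truth, estimate, dx, dy, error_px, error_dva) and `summaries` list.
#' @export
evaluate_gaze <- function(estimates, truth, geom = screen_geometry(),
                          hist_bins = 30, region_edge_px = 160,
                          kde_grid_n = 400, kde_levels = 12,
                          regression_mode = "region") {
  est <- as.matrix(estimates); tr <- as.matrix(truth)
  stopifnot(ncol(est) == 2, all(dim(est) == dim(tr)), nrow(est) > 0)
  dx <- est[, 1] - tr[, 1]
  dy <- est[, 2] - tr[, 2]
  error_px <- sqrt(dx^2 + dy^2)
  error_dva <- px_error_to_dva(error_px, geom)
  per_sample <- data.frame(truth_x = tr[, 1], truth_y = tr[, 2],
                           est_x = est[, 1], est_y = est[, 2],
                           dx = dx, dy = dy,
                           error_px = error_px, error_dva = error_dva)
  density <- tryCatch(offset_density(dx, dy, kde_grid_n, kde_levels),
                      error = function(e) NULL)
  summaries <- list(
    n = nrow(per_sample),
    median_dva = stats::median(error_dva),
    mean_error_px = mean_error_px(cbind(dx, dy)),
    histogram = error_histogram(error_dva, hist_bins),
    region_map = region_error_map(tr[, 1], tr[, 2], error_dva, geom,
                                  region_edge_px),
    regression = eccentricity_regression(tr[, 1], tr[, 2], error_dva, geom,
                                         mode = regression_mode,
                                         edge_px = region_edge_px),
    offset_density = density)
  structure(list(per_sample = per_sample, summaries = summaries,
                 geom = geom),
            class = "gaze_error_report")
}

#' @export
print.gaze_error_report <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("<gaze_error_report> n = %d test samples\n", s$n))
  cat(sprintf("  median error: %.3f dva (%.1f px at %g mm)\n",
              s$median_dva, dva_to_px_error(s$median_dva, x$geom),
              x$geom$viewing_distance_mm))
  cat(sprintf("  mean error:   %.1f px\n", s$mean_error_px))
  cat(sprintf("  eccentricity regression (%s): slope %.2e, p = %.3f\n",
              s$regression$mode, s$regression$slope, s$regression$p_value))
  invisible(x)
}

#' Serialize an error report
#'
#' Writes the summaries as JSON (histogram, region map, regression, density
#' settings) and the per-sample table as CSV.
#'
#' @param report A [evaluate_gaze()] report.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_error_report <- function(report, dir) {
  stopifnot(inherits(report, "gaze_error_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- report$summaries
  json <- list(
    n = s$n, median_dva = s$median_dva, mean_error_px = s$mean_error_px,
    histogram = s$histogram,
    region_map = list(edge_px = s$region_map$grid$edge_px,
                      n_cols = s$region_map$grid$n_cols,
                      n_rows = s$region_map$grid$n_rows,
                      mean_error = s$region_map$mean_error,
                      status = s$region_map$status),
    regression = s$regression,
    offset_density = if (!is.null(s$offset_density)) {
      list(grid_n = length(s$offset_density$x),
           levels = s$offset_density$levels,
           bandwidth = s$offset_density$bandwidth)
    })
  jsonlite::write_json(json, file.path(dir, "error_report.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  utils::write.csv(report$per_sample, file.path(dir, "per_sample.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Plot helpers for error reports
#'
#' `plot_region_map()` draws the per-tile mean-error image;
#' `plot_offset_density()` draws the offset density contours;
#' `plot_error_histogram()` the relative-frequency histogram with its
#' median line.
#'
#' @param report A [evaluate_gaze()] report.
#' @param ... Passed to the underlying base-graphics call.
#' @return Invisibly, the report.
#' @export
plot_region_map <- function(report, ...) {
  rm_ <- report$summaries$region_map
  graphics::image(x = seq_len(rm_$grid$n_cols) * rm_$grid$edge_px,
                  y = seq_len(rm_$grid$n_rows) * rm_$grid$edge_px,
                  z = t(rm_$mean_error), xlab = "screen x (px)",
                  ylab = "screen y (px)", ylim = rev(range(
                    c(0, rm_$grid$n_rows * rm_$grid$edge_px))), ...)
  invisible(report)
}

#' @rdname plot_region_map
#' @export
plot_offset_density <- function(report, ...) {
  d <- report$summaries$offset_density
  if (is.null(d)) stop("report has no offset density")
  graphics::contour(d$x, d$y, d$z, levels = d$levels,
                    xlab = expression(Delta * x ~ "(px)"),
                    ylab = expression(Delta * y ~ "(px)"), ...)
  invisible(report)
}

#' @rdname plot_region_map
#' @export
plot_error_histogram <- function(report, ...) {
  h <- report$summaries$histogram
  graphics::barplot(h$relative_frequency, width = diff(h$breaks),
                    space = 0, xlab = "error (dva)",
                    ylab = "relative frequency", ...)
  graphics::abline(v = h$median, lty = 2)
  invisible(report)
}
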