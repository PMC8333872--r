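#' Write a landmark table as a DeepLabCut-dialect CSV
#'
#' The dialect has three header rows -- `scorer` (one model label repeated),
#' `bodyparts` (each landmark name repeated three times) and `coords`
#' (`x,y,likelihood` per landmark) -- followed by one row per frame whose
#' first column is the frame index.
#'
#' @param landmarks Data frame as produced by [simulate_session()]: a
#'   `frame` column plus `<landmark>_x`, `<landmark>_y`,
#'   `<landmark>_likelihood` triples.
#' @param path Output file path.
#' @param scorer Label written in the scorer header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(landmarks, path, scorer = "gazekit_sim") {
  stopifnot(is.data.frame(landmarks), names(landmarks)[1] == "frame")
  value_cols <- names(landmarks)[-1]
  if (length(value_cols) %% 3 != 0) {
    stop("landmark table must have x, y, likelihood triples")
  }
  lm_names <- unique(sub("_(x|y|likelihood)$", "", value_cols))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, length(value_cols))),
                   collapse = ","), con)
  writeLines(paste(c("bodyparts", rep(lm_names, each = 3)), collapse = ","),
             con)
  writeLines(paste(c("coords", rep(c("x", "y", "likelihood"),
                                   length(lm_names))), collapse = ","), con)
  if (nrow(landmarks) > 0) {
    body <- cbind(format(landmarks$frame, trim = TRUE, scientific = FALSE),
                  vapply(landmarks[value_cols],
                         function(v) format(v, digits = 17, trim = TRUE,
                                            scientific = FALSE),
                         character(nrow(landmarks))))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a DeepLabCut-dialect CSV
#'
#' Companion reader for [write_dlc_csv()]; also accepts genuine DLC output
#' files with the same three-row header.
#'
#' @param path CSV file path.
#' @return Data frame with `frame` plus `<landmark>_x/_y/_likelihood`
#'   columns; the landmark names are stored in `attr(, "landmarks")`.
#' @export
read_dlc_csv <- function(path) {
  lines <- readLines(path, n = 3)
  if (length(lines) < 3) stop("DLC CSV must have three header rows")
  hdr <- lapply(lines, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  if (hdr[[1]][1] != "scorer") {
    stop("malformed DLC header: row 1 must start with 'scorer'")
  }
  if (hdr[[2]][1] != "bodyparts") {
    stop("malformed DLC header: row 2 must start with 'bodyparts'")
  }
  if (hdr[[3]][1] != "coords") {
    stop("malformed DLC header: row 3 must start with 'coords'")
  }
  bodyparts <- hdr[[2]][-1]
  coords <- hdr[[3]][-1]
  if (length(bodyparts) != length(coords) ||
      !all(coords == rep(c("x", "y", "likelihood"),
                         length(coords) / 3))) {
    stop("malformed DLC header: row 3 must repeat x,y,likelihood")
  }
  lm_names <- bodyparts[coords == "x"]
  col_names <- c("frame", paste0(bodyparts, "_", coords))
  n_body <- length(readLines(path)) - 3L
  if (n_body <= 0) {
    body <- as.data.frame(matrix(numeric(0), 0, length(col_names)))
  } else {
    body <- utils::read.csv(path, skip = 3, header = FALSE)
  }
  names(body) <- col_names
  body$frame <- as.integer(body$frame)
  attr(body, "landmarks") <- lm_names
  body
}

#' Write / read a ground-truth target table
#'
#' Plain CSV with columns `frame`, `target_x_px`, `target_y_px`.
#'
#' @param truth Data frame with those three columns.
#' @param path File path.
#' @return `path` (writer) or the data frame (reader).
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(all(c("frame", "target_x_px", "target_y_px") %in% names(truth)))
  utils::write.csv(truth[c("frame", "target_x_px", "target_y_px")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  truth <- utils::read.csv(path)
  if (!all(c("frame", "target_x_px", "target_y_px") %in% names(truth))) {
    stop("truth CSV must have frame, target_x_px, target_y_px columns")
  }
  truth$frame <- as.integer(truth$frame)
  truth
}
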