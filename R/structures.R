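# S3 containers shared across the pipeline. All are plain lists with a
# class attribute; fields are documented at the constructor.

LANDMARKS <- c("withers", "back", "croup", "tail_tip")

#' Construct a landmark series
#'
#' Timestamped 3D positions (cm) of the four tracked body landmarks for one
#' recording session, plus per-frame per-landmark tracking likelihoods.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param positions named list with elements `withers`, `back`, `croup`,
#'   `tail_tip`, each an n x 3 numeric matrix (columns x, y, z in cm).
#' @param likelihood n x 4 matrix of confidences in \[0, 1\] (columns in
#'   landmark order); defaults to all 1.
#' @param frame_rate sampling rate in Hz.
#' @param valid optional logical mask of usable frames (default all TRUE).
#' @return object of class `landmark_series`.
#' @export
landmark_series <- function(time, positions, likelihood = NULL,
                            frame_rate, valid = NULL) {
  n <- length(time)
  stopifnot(n > 0, frame_rate > 0, all(diff(time) > 0),
            setequal(names(positions), LANDMARKS))
  positions <- positions[LANDMARKS]
  for (lm in LANDMARKS) {
    p <- positions[[lm]]
    stopifnot(is.matrix(p), nrow(p) == n, ncol(p) == 3)
    if (any(!is.finite(p))) stop("non-finite coordinates for landmark ", lm)
  }
  if (is.null(likelihood)) likelihood <- matrix(1, n, 4)
  stopifnot(nrow(likelihood) == n, ncol(likelihood) == 4,
            all(likelihood >= 0 & likelihood <= 1))
  colnames(likelihood) <- LANDMARKS
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(list(time = as.numeric(time), positions = positions,
                 likelihood = likelihood, frame_rate = frame_rate,
                 valid = as.logical(valid)),
            class = "landmark_series")
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf("<landmark_series> %d frames @ %g Hz (%.1f s), %d valid\n",
              length(x$time), x$frame_rate,
              length(x$time) / x$frame_rate, sum(x$valid)))
  invisible(x)
}

#' @export
length.landmark_series <- function(x) length(x$time)

# Body-frame tail-tip trace: croup at the origin, croup->back along +y
# (so the tail extends toward -y), dog's right along +x, z up.
body_frame_trace <- function(time, tail, frame_rate, valid) {
  stopifnot(is.matrix(tail), ncol(tail) == 3, nrow(tail) == length(time))
  structure(list(time = as.numeric(time), tail = tail,
                 tail_xy = tail[, 1:2, drop = FALSE],
                 frame_rate = frame_rate, valid = as.logical(valid)),
            class = "body_frame_trace")
}

#' @export
print.body_frame_trace <- function(x, ...) {
  cat(sprintf("<body_frame_trace> %d frames @ %g Hz, %d valid\n",
              length(x$time), x$frame_rate, sum(x$valid)))
  invisible(x)
}

#' Construct a wagging-angle series
#'
#' Signed wagging angle in degrees per frame: negative = tail left of the
#' body axis, positive = right, in \[-180, 180\] on valid frames.
#'
#' @param theta numeric angle vector, degrees.
#' @param valid logical validity mask (same length).
#' @param frame_rate sampling rate, Hz.
#' @param time optional timestamps (seconds); defaults to frame times.
#' @return object of class `angle_series`.
#' @export
angle_series <- function(theta, valid, frame_rate, time = NULL) {
  n <- length(theta)
  stopifnot(length(valid) == n, frame_rate > 0)
  if (is.null(time)) time <- (seq_len(n) - 1) / frame_rate
  structure(list(theta = as.numeric(theta), valid = as.logical(valid),
                 frame_rate = frame_rate, time = as.numeric(time)),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d frames @ %g Hz, %d valid\n",
              length(x$theta), x$frame_rate, sum(x$valid)))
  invisible(x)
}

#' Write a landmark series to CSV (flat-column dialect)
#'
#' Columns: `time`, then `<landmark>_x/_y/_z/_likelihood` for each of
#' withers, back, croup, tail_tip. [read_landmarks()] reads this dialect
#' back losslessly.
#'
#' @param series a `landmark_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(series, path) {
  df <- data.frame(time = series$time)
  for (lm in LANDMARKS) {
    p <- series$positions[[lm]]
    df[[paste0(lm, "_x")]] <- p[, 1]
    df[[paste0(lm, "_y")]] <- p[, 2]
    df[[paste0(lm, "_z")]] <- p[, 3]
    df[[paste0(lm, "_likelihood")]] <- series$likelihood[, lm]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth to a sidecar CSV
#'
#' @param truth a `ground_truth` object from [simulate_session()].
#' @param path output CSV path (columns frame, motif, side, still).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth$frames, path, row.names = FALSE)
  invisible(path)
}
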