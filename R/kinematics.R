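# Kinematic parameters of tail wagging: the signed wagging angle, the
# angle extrema ("angles of wagging"), amplitudes (absolute differences of
# adjacent extrema), mean bout angular velocity, and bout segmentation
# (one bout = minimum extremum -> maximum -> back to a minimum).

#' Signed wagging angle from a body-frame trace
#'
#' The ground-plane angle between the spine axis and the croup-to-tail-tip
#' vector: 0 when the tail points straight back, negative when the tail is
#' left of the body axis, positive when right, in (-180, 180] degrees.
#' Frames where the tail tip's ground-plane projection coincides with the
#' croup are masked (the angle is undefined there).
#'
#' @param trace a `body_frame_trace`.
#' @param tol minimum ground-plane tail reach (cm) for a defined angle.
#' @return an `angle_series`.
#' @export
wagging_angle <- function(trace, tol = 1e-6) {
  stopifnot(inherits(trace, "body_frame_trace"))
  x <- trace$tail[, 1]; y <- trace$tail[, 2]
  r <- sqrt(x^2 + y^2)
  theta <- atan2(x, -y) * 180 / pi
  angle_series(theta, trace$valid & r >= tol, trace$frame_rate, trace$time)
}

#' Detect wagging-angle extrema
#'
#' Local maxima and minima of the angle series within each contiguous run
#' of valid frames, via sign changes of the first differences. Plateau ties
#' resolve to the first plateau index. Consecutive extrema alternate
#' between maxima and minima; swings smaller than `prominence` degrees are
#' pruned (smallest swing first), which keeps tracking-noise flutter from
#' fragmenting bouts.
#'
#' @param angles an `angle_series`.
#' @param prominence minimum |angle difference| between adjacent retained
#'   extrema, degrees; default 2.
#' @return data.frame with columns `frame`, `theta`, `type`
#'   (`"min"`/`"max"`) and `run` (valid-run id), ordered by frame.
#' @export
detect_extrema <- function(angles, prominence = 2) {
  stopifnot(inherits(angles, "angle_series"), prominence >= 0)
  v <- angles$valid & is.finite(angles$theta)
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  rid <- 0L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < 3L) next
    rid <- rid + 1L
    idx <- starts[k]:ends[k]
    ex <- run_extrema(angles$theta[idx], prominence)
    if (nrow(ex) == 0L) next
    ex$frame <- idx[ex$frame]
    ex$run <- rid
    out[[length(out) + 1L]] <- ex
  }
  if (!length(out))
    return(data.frame(frame = integer(0), theta = numeric(0),
                      type = character(0), run = integer(0)))
  do.call(rbind, out)
}

# Extrema of one contiguous series: sign flips of nonzero first
# differences, then prominence pruning of adjacent extremum pairs.
run_extrema <- function(x, prominence) {
  d <- diff(x)
  nz <- which(d != 0)
  empty <- data.frame(frame = integer(0), theta = numeric(0),
                      type = character(0))
  if (length(nz) < 2L) return(empty)
  s <- sign(d[nz])
  chg <- which(s[-1] != s[-length(s)])
  if (!length(chg)) return(empty)
  at <- nz[chg] + 1L               # first index of the plateau/turn
  type <- ifelse(s[chg] > 0, "max", "min")
  th <- x[at]
  # prune low-prominence adjacent pairs, smallest swing first; removing an
  # adjacent (min,max) pair always preserves alternation
  if (prominence > 0) {
    while (length(at) >= 2L) {
      sw <- abs(diff(th))
      j <- which.min(sw)
      if (sw[j] >= prominence) break
      keep <- setdiff(seq_along(at), c(j, j + 1L))
      at <- at[keep]; th <- th[keep]; type <- type[keep]
    }
    if (length(at) < 1L) return(empty)
  }
  data.frame(frame = at, theta = th, type = type)
}

#' Amplitude of a pair of adjacent wagging extrema
#'
#' Absolute difference of two adjacent extremal angles, in degrees;
#' ranges from 0 to 360.
#'
#' @param theta_i,theta_j adjacent extremal angles, degrees.
#' @return nonnegative amplitude, degrees.
#' @export
amplitude <- function(theta_i, theta_j) abs(theta_i - theta_j)

#' Segment wagging bouts from an extrema sequence
#'
#' One bout runs from a minimum extremum through the following maximum back
#' to the next minimum (left -> right -> left); bouts tile the extrema
#' sequence with shared endpoint minima, within each valid run. Leading
#' maxima before the first minimum of a run open no bout.
#'
#' @param extrema data.frame from [detect_extrema()].
#' @param angles the `angle_series` the extrema came from; when given, a
#'   bout's side is the sign of the mean angle over the bout's frames
#'   (robust for bouts spanning a side transition), otherwise the sign of
#'   the mean extremal angle.
#' @param frame_rate frames per second (carried into the bout table;
#'   taken from `angles` when available).
#' @return a `wag_bouts` data.frame: `bout`, `run`, `start`, `end` (frame
#'   indices), `side` (`"left"`/`"right"`/`"none"`), `amplitude_mean`
#'   (deg), `velocity` (deg/frame), `n_extrema`; per-bout extrema stored
#'   in attribute `"extrema"` (list of data.frames with `frame`,
#'   `theta`).
#' @export
segment_bouts <- function(extrema, angles = NULL, frame_rate = 150) {
  if (!is.null(angles)) frame_rate <- angles$frame_rate
  rows <- list(); exlist <- list()
  for (r in unique(extrema$run)) {
    ex <- extrema[extrema$run == r, , drop = FALSE]
    mins <- which(ex$type == "min")
    if (length(mins) < 2L) next
    for (k in mins[-length(mins)]) {
      if (k + 2L > nrow(ex)) break
      if (ex$type[k + 2L] != "min") next
      e3 <- ex[k:(k + 2L), , drop = FALSE]
      amps <- abs(diff(e3$theta))
      vel <- mean(amps / diff(e3$frame))
      ms <- if (is.null(angles)) mean(e3$theta) else
        mean(angles$theta[e3$frame[1]:e3$frame[3]])
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, start = e3$frame[1], end = e3$frame[3],
        side = if (ms < 0) "left" else if (ms > 0) "right" else "none",
        amplitude_mean = mean(amps), velocity = vel, n_extrema = 3L)
      exlist[[length(exlist) + 1L]] <- e3[, c("frame", "theta")]
    }
  }
  if (!length(rows)) {
    b <- data.frame(bout = integer(0), run = integer(0), start = integer(0),
                    end = integer(0), side = character(0),
                    amplitude_mean = numeric(0), velocity = numeric(0),
                    n_extrema = integer(0))
    attr(b, "extrema") <- list()
  } else {
    b <- do.call(rbind, rows)
    b <- cbind(bout = seq_len(nrow(b)), b)
    rownames(b) <- NULL
    attr(b, "extrema") <- exlist
  }
  attr(b, "frame_rate") <- frame_rate
  class(b) <- c("wag_bouts", "data.frame")
  b
}

#' Mean angular velocity of one bout
#'
#' Mean over adjacent extremum pairs of |angle difference| / frame gap,
#' reported in degrees per frame at the native frame rate.
#'
#' @param bout_extrema data.frame with columns `frame`, `theta` (one
#'   bout's extrema in temporal order, >= 2 rows).
#' @return velocity in degrees/frame.
#' @export
bout_velocity <- function(bout_extrema) {
  stopifnot(nrow(bout_extrema) >= 2L)
  dt <- diff(bout_extrema$frame)
  if (any(dt == 0)) stop("zero frame gap between adjacent extrema")
  mean(abs(diff(bout_extrema$theta)) / dt)
}

#' Convert a velocity from degrees/frame to degrees/second
#' @param v velocity in degrees/frame.
#' @param frame_rate frames per second.
#' @return velocity in degrees/second.
#' @export
deg_per_frame_to_deg_s <- function(v, frame_rate = 150) v * frame_rate

#' Extract per-bout traces for clustering
#'
#' @param bouts a `wag_bouts` table.
#' @param angles the `angle_series` the bouts were segmented from
#'   (required for `representation = "angle"`).
#' @param trace the `body_frame_trace` (required for the tail-tip
#'   representations).
#' @param representation `"angle"` (1-D angle series, the default),
#'   `"tailtip_2d"` (ground-plane trajectory) or `"tailtip_3d"`.
#' @return list of numeric vectors (`angle`) or matrices, one per bout.
#' @export
bout_traces <- function(bouts, angles = NULL, trace = NULL,
                        representation = c("angle", "tailtip_2d",
                                           "tailtip_3d")) {
  representation <- match.arg(representation)
  lapply(seq_len(nrow(bouts)), function(i) {
    idx <- bouts$start[i]:bouts$end[i]
    switch(representation,
      angle = angles$theta[idx],
      tailtip_2d = trace$tail_xy[idx, , drop = FALSE],
      tailtip_3d = trace$tail[idx, , drop = FALSE])
  })
}

#' Joint-distribution heat map of two kinematic variables
#'
#' Each observation (a_i, b_i) contributes a 2D Gaussian kernel
#' `Z_i = S exp(-((X - a_i)^2 + (Y - b_i)^2) / sigma^2)` on the grid, and
#' the map is the complement-product accumulation
#' `H = 1 - prod_i (1 - Z_i)`, elementwise, which saturates smoothly at 1
#' where observations pile up. With the default `S = sigma = 0.5`, one
#' isolated observation at a grid node peaks at 0.5 and two coincident
#' ones at 0.75.
#'
#' @param a,b paired observation vectors (e.g. extremal angle vs amplitude,
#'   or angle vs velocity), in the units of their axes.
#' @param n_grid grid resolution per axis (default 400).
#' @param a_range,b_range axis ranges; `a_range` defaults to
#'   c(-180, 180) (the angle axis), `b_range` to the data range.
#' @param S,sigma kernel scale and width (same units as the axes).
#' @return `n_grid` x `n_grid` matrix (rows = `b` axis, columns = `a`
#'   axis), values in \[0, 1\], with axis vectors attached as attributes
#'   `"a_axis"` and `"b_axis"`.
#' @export
joint_distribution_map <- function(a, b, n_grid = 400,
                                   a_range = c(-180, 180), b_range = NULL,
                                   S = 0.5, sigma = 0.5) {
  stopifnot(length(a) == length(b))
  if (is.null(b_range))
    b_range <- if (length(b)) range(b) else c(0, 1)
  ax <- seq(a_range[1], a_range[2], length.out = n_grid)
  bx <- seq(b_range[1], b_range[2], length.out = n_grid)
  acc <- matrix(0, n_grid, n_grid)       # sum of log(1 - Z_i)
  for (i in seq_along(a)) {
    za <- exp(-(ax - a[i])^2 / sigma^2)
    zb <- exp(-(bx - b[i])^2 / sigma^2)
    z <- S * outer(zb, za)
    acc <- acc + log1p(-z)
  }
  H <- 1 - exp(acc)
  attr(H, "a_axis") <- ax
  attr(H, "b_axis") <- bx
  H
}

#' Per-extremum kinematic table
#'
#' Pairs every extremal angle (each extremum once, in temporal order) with
#' an adjacent-pair amplitude — the swing to the next extremum in the same
#' valid run, or from the previous one for a run's last extremum — and with
#' the mean velocity of the bout containing it (the earlier bout at shared
#' endpoint minima; NA for extrema outside any complete bout). These are
#' the "dots" used by the asymmetry binning and the joint-distribution
#' maps.
#'
#' @param extrema data.frame from [detect_extrema()].
#' @param bouts the `wag_bouts` table segmented from the same extrema.
#' @return data.frame with columns `frame`, `theta`, `amplitude`,
#'   `velocity`, `bout`.
#' @export
extrema_table <- function(extrema, bouts) {
  if (!nrow(extrema))
    return(data.frame(frame = integer(0), theta = numeric(0),
                      amplitude = numeric(0), velocity = numeric(0),
                      bout = integer(0)))
  parts <- lapply(split(extrema, extrema$run), function(e) {
    nn <- nrow(e)
    if (nn < 2L) return(NULL)
    amp <- abs(diff(e$theta))
    data.frame(frame = e$frame, theta = e$theta,
               amplitude = c(amp, amp[nn - 1L]))
  })
  tab <- do.call(rbind, parts)
  tab <- tab[order(tab$frame), , drop = FALSE]
  rownames(tab) <- NULL
  tab$velocity <- NA_real_
  tab$bout <- NA_integer_
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      hit <- which(tab$frame >= bouts$start[i] & tab$frame <= bouts$end[i] &
                     is.na(tab$bout))
      tab$velocity[hit] <- bouts$velocity[i]
      tab$bout[hit] <- bouts$bout[i]
    }
  }
  tab
}
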