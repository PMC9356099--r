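# Preprocessing: likelihood filtering, Gaussian smoothing, body-frame
# alignment and stillness masking. Masking never deletes frames or alters
# coordinates; it only clears the validity flag, so frame counts and
# timestamps are preserved end to end.

#' Mask frames with low tracking likelihood
#'
#' A frame is masked when *any* landmark's likelihood falls below the
#' threshold (strictly `<`); default 0.9.
#'
#' @param series a `landmark_series`.
#' @param threshold likelihood cutoff in \[0, 1\].
#' @return the series with its validity mask updated.
#' @export
filter_likelihood <- function(series, threshold = 0.9) {
  stopifnot(inherits(series, "landmark_series"),
            threshold >= 0, threshold <= 1)
  bad <- apply(series$likelihood < threshold, 1L, any)
  series$valid <- series$valid & !bad
  series
}

# Gaussian smoothing of one signal with validity weights: invalid frames
# are excluded from the kernel support and the kernel renormalized over
# what remains (also handles series ends). sigma = 0 is the identity.
gaussian_smooth_vec <- function(x, valid, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(4 * sigma)
  ker <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- as.numeric(valid)
  xw <- x * w
  n <- length(x)
  pad <- function(v) c(rep(0, r), v, rep(0, r))
  xs <- pad(xw); ws <- pad(w)
  num <- den <- numeric(n)
  for (k in seq_along(ker)) {      # kernel is short; loop over offsets
    idx <- k:(k + n - 1L)
    num <- num + ker[k] * xs[idx]
    den <- den + ker[k] * ws[idx]
  }
  out <- ifelse(den > 0, num / den, x)
  out
}

#' Gaussian-smooth landmark coordinates
#'
#' Convolves every coordinate of every landmark with a normalized Gaussian
#' kernel (truncated at 4 sigma). Masked frames are excluded from the
#' kernel support, with the kernel renormalized over the remaining weight;
#' a constant trajectory is therefore left unchanged.
#'
#' @param series a `landmark_series`.
#' @param sigma_frames kernel standard deviation in frames; 0 = identity.
#' @return smoothed `landmark_series` (mask unchanged).
#' @export
smooth_gaussian <- function(series, sigma_frames = 2) {
  stopifnot(inherits(series, "landmark_series"), sigma_frames >= 0)
  if (sigma_frames == 0) return(series)
  for (lm in LANDMARKS) {
    p <- series$positions[[lm]]
    for (j in 1:3)
      p[, j] <- gaussian_smooth_vec(p[, j], series$valid, sigma_frames)
    series$positions[[lm]] <- p
  }
  series
}

#' Align the tail tip into the body frame
#'
#' Per frame, translates the croup to the origin and rotates about the
#' vertical axis so that the ground-plane projection of the croup-to-back
#' direction points along +y. The tail then extends toward -y; the dog's
#' right maps to +x. Only yaw is corrected (spine pitch/roll is left
#' alone), since the wagging angle lives in the ground plane.
#'
#' @param series a `landmark_series`.
#' @param tol minimum ground-plane back-croup separation (cm) below which a
#'   frame is masked (coincident landmarks leave the heading undefined).
#' @return a `body_frame_trace` of the tail tip.
#' @export
align_body_frame <- function(series, tol = 1e-6) {
  stopifnot(inherits(series, "landmark_series"))
  croup <- series$positions$croup
  back <- series$positions$back
  tail <- series$positions$tail_tip
  h <- back[, 1:2, drop = FALSE] - croup[, 1:2, drop = FALSE]
  hn <- sqrt(rowSums(h^2))
  degen <- hn < tol
  if (any(degen & series$valid))
    warning(sum(degen & series$valid),
            " frame(s) masked: back and croup coincide in the ground plane")
  hn[degen] <- 1
  ux <- h[, 1] / hn; uy <- h[, 2] / hn   # forward unit vector
  dx <- tail[, 1] - croup[, 1]
  dy <- tail[, 2] - croup[, 2]
  xb <- dx * uy - dy * ux                # projection on right vector (uy, -ux)
  yb <- dx * ux + dy * uy
  zb <- tail[, 3] - croup[, 3]
  body_frame_trace(series$time, cbind(x = xb, y = yb, z = zb),
                   series$frame_rate, series$valid & !degen)
}

#' Mask still (non-wagging) intervals
#'
#' Slides a window (stride 1) over the tail-tip trace and computes a single
#' positional spread scalar per window: the square root of the summed
#' per-axis sample variances of the 3D coordinates. Every frame covered by
#' any window whose spread is strictly below the threshold is masked.
#' Spread is computed from the raw coordinates regardless of prior masking,
#' so masking is monotone (it only removes frames).
#'
#' @param trace a `body_frame_trace`.
#' @param window_frames window width in frames (>= 2); default 50.
#' @param std_threshold_cm spread threshold in cm; default 1.2.
#' @return the trace with still frames masked; the per-window spread is
#'   attached as attribute `"window_std"`.
#' @export
mask_still_segments <- function(trace, window_frames = 50,
                                std_threshold_cm = 1.2) {
  stopifnot(inherits(trace, "body_frame_trace"), window_frames >= 2)
  n <- length(trace$time)
  if (n < window_frames) return(trace)
  w <- as.integer(window_frames)
  v <- rolling_var(trace$tail[, 1], w) +
       rolling_var(trace$tail[, 2], w) +
       rolling_var(trace$tail[, 3], w)
  sdw <- sqrt(v * w / (w - 1))           # sample (n-1) variance
  flag <- sdw < std_threshold_cm
  if (any(flag)) {
    delta <- integer(n + 1L)
    starts <- which(flag)
    for (s in starts) {                   # coverage via difference array
      delta[s] <- delta[s] + 1L
      delta[min(n, s + w - 1L) + 1L] <- delta[min(n, s + w - 1L) + 1L] - 1L
    }
    covered <- cumsum(delta[seq_len(n)]) > 0L
    trace$valid <- trace$valid & !covered
  }
  attr(trace, "window_std") <- sdw
  trace
}

#' Run the full preprocessing chain
#'
#' likelihood filter -> Gaussian smoothing -> body-frame alignment ->
#' stillness masking, with the package defaults at every stage.
#'
#' @param series a `landmark_series`.
#' @param likelihood_threshold see [filter_likelihood()].
#' @param sigma_frames see [smooth_gaussian()].
#' @param still_window,still_std see [mask_still_segments()].
#' @return a `body_frame_trace` ready for [wagging_angle()].
#' @export
preprocess_session <- function(series, likelihood_threshold = 0.9,
                               sigma_frames = 2, still_window = 50,
                               still_std = 1.2) {
  series <- filter_likelihood(series, likelihood_threshold)
  series <- smooth_gaussian(series, sigma_frames)
  trace <- align_body_frame(series)
  mask_still_segments(trace, still_window, still_std)
}
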