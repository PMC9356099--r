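# Reader dialects, likelihood filtering, Gaussian smoothing, body-frame
# alignment and stillness masking.

test_that("flat CSV round-trips and preserves likelihood", {
  n <- 3
  tail <- cbind(c(1, 2, 3), c(-18, -18, -18), c(15, 15, 15))
  lm <- toy_landmarks(tail)
  lm$likelihood[2, "tail_tip"] <- 0.5
  f <- tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  back <- read_landmarks(f, frame_rate = 150)
  expect_equal(length(back$time), n)
  expect_equal(back$likelihood[2, "tail_tip"], 0.5, ignore_attr = TRUE)
  expect_equal(back$positions$croup, lm$positions$croup,
               tolerance = 1e-9, ignore_attr = TRUE)
  unlink(f)
})

test_that("DLC three-row-header dialect parses to the same series", {
  lm <- toy_landmarks(cbind(c(5, 6), c(-19, -18), c(15, 15)))
  parts <- c("withers", "back", "croup", "tail_tip")
  hdr1 <- c("scorer", rep("net", 16))
  hdr2 <- c("bodyparts", rep(parts, each = 4))
  hdr3 <- c("coords", rep(c("x", "y", "z", "likelihood"), 4))
  rows <- t(sapply(1:2, function(i) {
    c(i - 1, unlist(lapply(parts, function(p)
      c(lm$positions[[p]][i, ], lm$likelihood[i, p]))))
  }))
  f <- tempfile(fileext = ".csv")
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), f)
  write.table(rows, f, sep = ",", append = TRUE, col.names = FALSE,
              row.names = FALSE)
  back <- read_landmarks(f, frame_rate = 150)
  expect_equal(back$positions$tail_tip, lm$positions$tail_tip,
               tolerance = 1e-6, ignore_attr = TRUE)
  # malformed header errors
  writeLines(c("scorer,a,b", "bodyparts,withers,withers", "coords,x,q",
               "0,1,2"), f)
  expect_error(read_landmarks(f, frame_rate = 150), "header")
  unlink(f)
})

test_that("non-monotone timestamps are rejected", {
  f <- tempfile(fileext = ".csv")
  lm <- toy_landmarks(cbind(c(1, 2), c(-18, -18), c(15, 15)))
  df <- data.frame(time = c(0.1, 0.1))
  for (p in c("withers", "back", "croup", "tail_tip")) {
    df[[paste0(p, "_x")]] <- lm$positions[[p]][, 1]
    df[[paste0(p, "_y")]] <- lm$positions[[p]][, 2]
    df[[paste0(p, "_z")]] <- lm$positions[[p]][, 3]
  }
  write.csv(df, f, row.names = FALSE)
  expect_error(read_landmarks(f), "increasing")
  unlink(f)
})

test_that("likelihood filter masks exactly the sub-threshold frames", {
  lm <- toy_landmarks(cbind(1:5, rep(-18, 5), rep(15, 5)))
  expect_true(all(filter_likelihood(lm)$valid))       # all 1.0
  lm$likelihood[3, "back"] <- 0.89
  f1 <- filter_likelihood(lm, 0.9)
  expect_identical(which(!f1$valid), 3L)
  expect_true(all(filter_likelihood(lm, 0)$valid))    # vacuous threshold
})

test_that("Gaussian smoothing: identity at sigma 0, constancy, impulse kernel", {
  lm <- toy_landmarks(cbind(sin(1:100), rep(-18, 100), rep(15, 100)))
  expect_identical(smooth_gaussian(lm, 0), lm)
  const <- toy_landmarks(cbind(rep(3, 50), rep(-18, 50), rep(15, 50)))
  sm <- smooth_gaussian(const, 2)
  expect_equal(sm$positions$tail_tip, const$positions$tail_tip,
               tolerance = 1e-10)
  # impulse response matches direct renormalized convolution
  x <- c(rep(0, 20), 1, rep(0, 20))
  sigma <- 1.5
  imp <- toy_landmarks(cbind(x, rep(-18, 41), rep(15, 41)))
  sm2 <- smooth_gaussian(imp, sigma)
  r <- ceiling(4 * sigma)
  ker <- exp(-((-r):r)^2 / (2 * sigma^2))
  expected <- sapply(1:41, function(i) {
    idx <- max(1, i - r):min(41, i + r)
    w <- ker[idx - i + r + 1]
    sum(w * x[idx]) / sum(w)
  })
  expect_equal(sm2$positions$tail_tip[, 1], expected, tolerance = 1e-10)
})

test_that("alignment is invariant to heading and places the tail correctly", {
  tail_body <- cbind(c(10, 0, -7), c(-10, -20, 0), c(15, 15, 15))
  for (h in c(0, pi / 2, 2.1)) {
    tr <- align_body_frame(toy_landmarks(tail_body, heading = h))
    expect_equal(tr$tail[, 1], tail_body[, 1], tolerance = 1e-9)
    expect_equal(tr$tail[, 2], tail_body[, 2], tolerance = 1e-9)
  }
  # tail on the spine axis behind the croup
  tr0 <- align_body_frame(toy_landmarks(cbind(0, -20, 15), heading = 1))
  expect_equal(as.numeric(tr0$tail[1, 1]), 0, tolerance = 1e-9)
  expect_lt(tr0$tail[1, 2], 0)
})

test_that("coincident back and croup masks the frame with a warning", {
  lm <- toy_landmarks(cbind(c(5, 5), c(-18, -18), c(15, 15)))
  lm$positions$back[2, ] <- lm$positions$croup[2, ]
  expect_warning(tr <- align_body_frame(lm), "coincide")
  expect_identical(tr$valid, c(TRUE, FALSE))
})

test_that("stillness masking follows the window spread rule", {
  frozen <- toy_trace(cbind(rep(1, 200), rep(-18, 200), rep(15, 200)))
  expect_false(any(mask_still_segments(frozen)$valid))
  # 5 cm sinusoid: per-window spread ~ 5/sqrt(2) cm, well above 1.2
  osc <- toy_trace(cbind(5 * sin(2 * pi * 4 * (0:999) / 150),
                         rep(-18, 1000), rep(15, 1000)))
  expect_true(all(mask_still_segments(osc)$valid))
  expect_true(all(mask_still_segments(frozen, std_threshold_cm = 0)$valid))
})

test_that("masking alters validity only and the pipeline keeps frame count", {
  ses <- simulate_session(sim_params(duration = 10, seed = 3))
  trace <- preprocess_session(ses$landmarks)
  expect_identical(length(trace$time), length(ses$landmarks$time))
  # coordinates in the trace equal those of an unmasked alignment
  tr2 <- align_body_frame(smooth_gaussian(
    filter_likelihood(ses$landmarks), 2))
  expect_identical(trace$tail, tr2$tail)
})
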