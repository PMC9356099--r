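# Shared fixtures, all built in code.

# Three well-separated wagging motifs (distinct frequency, amplitude and
# harmonic content) used by the recovery fixtures.
test_bank <- function() {
  data.frame(motif = 1:3, freq = c(2.5, 4, 5.5),
             a1 = c(12, 18, 24), a2 = c(0, 4, 2), phi2 = c(0, 1, 4),
             a3 = c(0, 0, 2.5), phi3 = c(0, 0, 2), zamp = c(1, 2, 3))
}

# A minimal landmark series with the dog standing at `heading` (radians,
# 0 = facing +y) and the tail tip at the given body-frame offsets.
toy_landmarks <- function(tail_body, heading = 0, frame_rate = 150) {
  n <- nrow(tail_body)
  u <- c(-sin(heading), cos(heading))
  r <- c(cos(heading), sin(heading))
  croup <- cbind(rep(0, n), rep(0, n), rep(40, n))
  back <- croup + cbind(rep(15 * u[1], n), rep(15 * u[2], n), rep(2, n))
  withers <- croup + cbind(rep(30 * u[1], n), rep(30 * u[2], n), rep(5, n))
  tail <- cbind(tail_body[, 1] * r[1] + tail_body[, 2] * u[1],
                tail_body[, 1] * r[2] + tail_body[, 2] * u[2],
                tail_body[, 3])
  landmark_series(time = (seq_len(n) - 1) / frame_rate,
                  positions = list(withers = withers, back = back,
                                   croup = croup, tail_tip = tail),
                  frame_rate = frame_rate)
}

# Body-frame trace straight from tail-tip coordinates.
toy_trace <- function(tail, frame_rate = 150, valid = NULL) {
  n <- nrow(tail)
  if (is.null(valid)) valid <- rep(TRUE, n)
  wagdyn:::body_frame_trace((seq_len(n) - 1) / frame_rate, tail,
                            frame_rate, valid)
}

# Angle series from a plain numeric vector.
toy_angles <- function(theta, frame_rate = 150) {
  angle_series(theta, valid = rep(TRUE, length(theta)),
               frame_rate = frame_rate)
}

# Angle-level cohort: per-animal motif banks, per-day bias, returning the
# segment labels table consumed by daily_bias_fractions().
cohort_labels <- function(rep_seed, biases, n_animals = 10, duration = 60) {
  labs <- vector("list", n_animals * length(biases))
  k <- 0L
  for (a in seq_len(n_animals)) {
    a_seed <- wagdyn:::split_seed(rep_seed, a)
    bank <- with_local_seed(a_seed, make_motif_bank(5, c(2, 6)))
    for (d in seq_along(biases)) {
      ang <- with_local_seed(wagdyn:::split_seed(a_seed, d),
        simulate_angle_session(bank, duration = duration, bias = biases[d],
                               still_fraction = 0.3))$angles
      seg <- segment_bias_test(ang)
      k <- k + 1L
      labs[[k]] <- data.frame(animal = a, day = d, label = seg$label)
    }
  }
  do.call(rbind, labs)
}

# Logistic-map series at full chaos (r = 4).
logistic_series <- function(n, x0 = 0.2345) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# All monotone alignment paths from (1,1) to (n,m) with unit steps
# (1,0), (0,1), (1,1) — the independent enumeration oracle for DTW.
enum_paths <- function(n, m) {
  out <- list()
  walk <- function(path) {
    last <- path[nrow(path), ]
    if (last[1] == n && last[2] == m) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (st in list(c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
      nx <- last + st
      if (nx[1] <= n && nx[2] <= m) walk(rbind(path, nx))
    }
  }
  walk(matrix(c(1L, 1L), 1))
  out
}
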