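# Synthetic session generator. Emulates the structure of a recorded
# dog-human interaction session: oscillatory tail wagging built from a bank
# of recurring motifs, a lateral bias controlling the side of each bout,
# contiguous still (non-wagging) intervals, slow whole-body drift and
# heading change, and isotropic Gaussian tracking noise. Every generated
# frame carries ground-truth labels (motif, side, stillness) so downstream
# stages have parameter-recovery tests.

#' Simulation parameters
#'
#' Parameter container for [simulate_session()]. Defaults describe one
#' 5-minute session at 150 frames/s with five wagging motifs between 2 and
#' 6 Hz, a lateral bias of 0.5 (no side preference), 30% still time and
#' 0.2 cm tracking noise.
#'
#' @param frame_rate sampling rate, Hz.
#' @param duration session length, seconds.
#' @param n_motifs number of distinct wagging motifs in the bank.
#' @param motif_freq_range length-2 range of motif frequencies, Hz.
#' @param bias target fraction of right-sided bouts (and hence of
#'   right-sided angle extrema), in \[0, 1\].
#' @param still_fraction fraction of frames without wagging, in \[0, 1\].
#' @param noise_sd isotropic Gaussian position noise, cm.
#' @param likelihood_dropout per-frame probability that one landmark gets a
#'   sub-0.9 tracking likelihood (emulates occasional tracking failures).
#' @param run_bouts number of consecutive bouts sharing a motif: NULL
#'   (default) draws geometric run lengths with mean 8; an integer fixes
#'   every run to that length (useful for recovery fixtures where segment
#'   durations must be comparable).
#' @param seed integer RNG seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(frame_rate = 150, duration = 300, n_motifs = 5,
                       motif_freq_range = c(2, 6), bias = 0.5,
                       still_fraction = 0.3, noise_sd = 0.2,
                       likelihood_dropout = 0.01, run_bouts = NULL,
                       seed = 1L) {
  stopifnot(frame_rate > 0, duration > 0, n_motifs >= 1,
            length(motif_freq_range) == 2, motif_freq_range[1] > 0,
            motif_freq_range[2] >= motif_freq_range[1])
  if (bias < 0 || bias > 1) stop("bias must be in [0, 1]")
  if (still_fraction < 0 || still_fraction > 1)
    stop("still_fraction must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(frame_rate = frame_rate, duration = duration,
                 n_motifs = n_motifs, motif_freq_range = motif_freq_range,
                 bias = bias, still_fraction = still_fraction,
                 noise_sd = noise_sd, likelihood_dropout = likelihood_dropout,
                 run_bouts = run_bouts, seed = as.integer(seed)),
            class = "sim_params")
}

# Body scale constants (cm / degrees): spine length 30 cm (croup->withers),
# planar tail reach 20 cm of a 25 cm tail, wagging centred +-45 deg off the
# midline so every extremum of a bout shares the bout's side.
SPINE_HALF <- 15
SPINE_FULL <- 30
TAIL_PLANAR <- 20
SIDE_CENTER <- 45

#' Draw a motif bank
#'
#' Each motif is one bout waveform: a sum of 1-3 harmonics of the motif
#' frequency with motif-specific amplitudes and phases (plus a vertical
#' oscillation amplitude), giving shapes that dynamic time warping can tell
#' apart. Drawn from the current RNG stream.
#'
#' @param n_motifs number of motifs.
#' @param freq_range length-2 frequency range, Hz.
#' @return data.frame with one row per motif.
#' @export
make_motif_bank <- function(n_motifs, freq_range = c(2, 6)) {
  data.frame(
    motif = seq_len(n_motifs),
    freq = runif(n_motifs, freq_range[1], freq_range[2]),
    a1 = runif(n_motifs, 12, 24),
    a2 = runif(n_motifs, 0, 0.45) * runif(n_motifs, 12, 24) * 0.5,
    phi2 = runif(n_motifs, 0, 2 * pi),
    a3 = runif(n_motifs, 0, 0.25) * runif(n_motifs, 12, 24) * 0.4,
    phi3 = runif(n_motifs, 0, 2 * pi),
    zamp = runif(n_motifs, 1, 3)
  )
}

# Evaluate motif waveform at cycle positions u (one bout = u in [0, 1),
# starting at the primary-harmonic minimum).
motif_wave <- function(u, m) {
  v <- u + 0.75
  m$a1 * sin(2 * pi * v) + m$a2 * sin(4 * pi * v + m$phi2) +
    m$a3 * sin(6 * pi * v + m$phi3)
}

#' Simulate a wagging-angle session with ground truth
#'
#' Angle-level core of the generator: produces the signed wagging-angle
#' series directly, without constructing landmark coordinates. Motifs occur
#' in runs (geometric run length); each bout's side is an independent
#' Bernoulli draw with probability `bias` of landing right, and a bout on
#' the right is the exact mirror image of the same motif's bout on the
#' left (theta = side x (centre + waveform)), so the construction is
#' mirror-symmetric and the realized fraction of right-sided extrema is a
#' binomial proportion converging to `bias`. Still intervals are inserted
#' as contiguous blocks with short cosine tapers.
#' Draws from the current RNG stream; wrap in [with_local_seed()]/`set.seed`
#' for reproducibility. Used by [simulate_session()] and directly wherever
#' only the angle trace matters (e.g. large statistical calibration runs).
#'
#' @param motif_bank data.frame from [make_motif_bank()].
#' @param frame_rate,duration,bias,still_fraction see [sim_params()].
#' @param run_mean_bouts mean number of consecutive bouts sharing a motif
#'   (geometric run lengths).
#' @param run_bouts fixed run length overriding `run_mean_bouts` when not
#'   NULL.
#' @return list with `angles` (an `angle_series`) and `truth` (a
#'   `ground_truth`: per-frame labels and a bout table).
#' @export
simulate_angle_session <- function(motif_bank, frame_rate = 150,
                                   duration = 300, bias = 0.5,
                                   still_fraction = 0.3,
                                   run_mean_bouts = 8, run_bouts = NULL) {
  n <- round(frame_rate * duration)
  n_still <- round(still_fraction * n)
  n_wag <- n - n_still

  # per-bout plan: motif (per run), side (per bout), length in frames
  bout_motif <- integer(0); bout_side <- integer(0); bout_len <- integer(0)
  total <- 0L
  prev_motif <- 0L
  n_motifs <- nrow(motif_bank)
  while (total < n_wag) {
    cand <- seq_len(n_motifs)
    if (n_motifs > 1L) cand <- setdiff(cand, prev_motif)
    mi <- if (length(cand) == 1L) cand else sample(cand, 1L)
    prev_motif <- mi
    run <- if (is.null(run_bouts)) 1L + stats::rgeom(1L, 1 / run_mean_bouts)
           else as.integer(run_bouts)
    per <- max(8L, round(frame_rate / motif_bank$freq[mi]))
    for (b in seq_len(run)) {
      if (total >= n_wag) break
      len <- min(per, n_wag - total)
      bout_motif <- c(bout_motif, mi)
      bout_side <- c(bout_side, if (runif(1) < bias) 1L else -1L)
      bout_len <- c(bout_len, len)
      total <- total + len
    }
  }
  n_bouts <- length(bout_len)

  # still blocks (contiguous, ~2 s each) inserted at bout boundaries
  still_blocks <- integer(0)
  remaining <- n_still
  while (remaining > 0L) {
    len <- min(remaining, max(60L, round(stats::rgamma(1, shape = 4, scale = 75))))
    if (remaining - len < 60L) len <- remaining
    still_blocks <- c(still_blocks, len)
    remaining <- remaining - len
  }
  n_blocks <- length(still_blocks)
  if (n_blocks > 0L) {
    slots <- if (n_bouts > 0L)
      sort(sample.int(n_bouts + 1L, n_blocks, replace = TRUE)) - 1L
    else rep(0L, n_blocks)  # all-still session: blocks only, no bouts
  } else slots <- integer(0)

  # assemble episodes in order
  theta <- numeric(n); center <- numeric(n); gate01 <- numeric(n)
  f_motif <- rep(NA_integer_, n); f_side <- rep(NA_integer_, n)
  f_still <- rep(FALSE, n)
  bouts <- data.frame(start = integer(n_bouts), end = integer(n_bouts),
                      motif = bout_motif,
                      side = ifelse(bout_side > 0, "right", "left"))
  pos <- 1L
  emit_still <- function(len) {
    idx <- pos:(pos + len - 1L)
    f_still[idx] <<- TRUE
    pos <<- pos + len
  }
  bi <- 0L
  for (len in still_blocks[slots == 0L]) emit_still(len)
  for (k in seq_len(n_bouts)) {
    bi <- bi + 1L
    len <- bout_len[k]
    idx <- pos:(pos + len - 1L)
    per <- max(8L, round(frame_rate / motif_bank$freq[bout_motif[k]]))
    u <- (seq_len(len) - 1L) / per
    theta[idx] <- bout_side[k] * motif_wave(u, motif_bank[bout_motif[k], ])
    center[idx] <- bout_side[k] * SIDE_CENTER
    gate01[idx] <- 1
    f_motif[idx] <- bout_motif[k]
    f_side[idx] <- bout_side[k]
    bouts$start[k] <- idx[1]; bouts$end[k] <- idx[len]
    pos <- pos + len
    if (n_blocks > 0L)
      for (len2 in still_blocks[slots == k]) emit_still(len2)
  }

  # smooth side-centre transitions (9-frame moving average) and taper wag
  # episode edges with a 12-frame half-cosine so theta is continuous
  if (n >= 9L) {
    ker <- rep(1 / 9, 9)
    center <- as.numeric(stats::filter(center, ker, sides = 2))
    center[is.na(center)] <- 0
  }
  gate <- gate01
  taper <- 12L
  edges_up <- which(diff(c(0, gate01)) == 1)
  edges_dn <- which(diff(c(gate01, 0)) == -1)
  ramp <- (1 - cos(pi * seq_len(taper) / (taper + 1))) / 2
  for (e in edges_up) {
    j <- e:min(n, e + taper - 1L)
    gate[j] <- pmin(gate[j], ramp[seq_along(j)])
  }
  for (e in edges_dn) {
    j <- max(1L, e - taper + 1L):e
    gate[j] <- pmin(gate[j], rev(ramp)[seq_along(j)])
  }
  theta_full <- (theta + center) * gate

  truth <- structure(list(
    frames = data.frame(frame = seq_len(n), motif = f_motif,
                        side = ifelse(is.na(f_side), NA_character_,
                                      ifelse(f_side > 0, "right", "left")),
                        still = f_still),
    bouts = bouts, motif_bank = motif_bank), class = "ground_truth")
  list(angles = angle_series(theta_full, valid = rep(TRUE, n),
                             frame_rate = frame_rate),
       truth = truth)
}

#' Simulate one session of landmark trajectories
#'
#' Generates a full `landmark_series` for one session: a rigid spine
#' (withers, back, croup) with slow heading change and positional drift,
#' a tail tip swinging laterally around the spine axis according to the
#' motif waveforms from [simulate_angle_session()], a motif-specific
#' vertical oscillation, and isotropic Gaussian tracking noise on every
#' landmark coordinate. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param motif_bank optional pre-drawn motif bank (used by
#'   [simulate_cohort()] to give each animal a persistent bank); drawn from
#'   `params$seed` when NULL.
#' @return list with `landmarks` (a `landmark_series`) and `truth`
#'   (a `ground_truth`).
#' @export
simulate_session <- function(params = sim_params(), motif_bank = NULL) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    if (is.null(motif_bank))
      motif_bank <- make_motif_bank(params$n_motifs, params$motif_freq_range)
    ang <- simulate_angle_session(motif_bank,
                                  frame_rate = params$frame_rate,
                                  duration = params$duration,
                                  bias = params$bias,
                                  still_fraction = params$still_fraction,
                                  run_bouts = params$run_bouts)
    n <- length(ang$angles$theta)
    fr <- params$frame_rate

    psi <- cumsum(rnorm(n, 0, 0.004))          # heading, rad (slow)
    croup <- cbind(cumsum(rnorm(n, 0, 0.01)),  # positional drift, cm
                   cumsum(rnorm(n, 0, 0.01)),
                   40 + rnorm(n, 0, 0.05))
    u <- cbind(-sin(psi), cos(psi))            # forward (croup -> back)
    r <- cbind(cos(psi), sin(psi))             # dog's right

    jit <- function() matrix(rnorm(3 * n, 0, 0.05), n, 3)
    back <- croup + cbind(SPINE_HALF * u, rep(2, n)) + jit()
    withers <- croup + cbind(SPINE_FULL * u, rep(5, n)) + jit()

    th <- ang$angles$theta * pi / 180
    xb <- TAIL_PLANAR * sin(th)
    yb <- -TAIL_PLANAR * cos(th)
    zamp <- rep(0, n)
    mot <- ang$truth$frames$motif
    ok <- !is.na(mot)
    zamp[ok] <- motif_bank$zamp[mot[ok]]
    tail_tip <- cbind(croup[, 1] + xb * r[, 1] + yb * u[, 1],
                      croup[, 2] + xb * r[, 2] + yb * u[, 2],
                      15 + zamp * sin(th))

    pos <- list(withers = withers, back = back, croup = croup,
                tail_tip = tail_tip)
    if (params$noise_sd > 0)
      pos <- lapply(pos, function(p) p + matrix(rnorm(3 * n, 0, params$noise_sd), n, 3))

    lik <- matrix(1, n, 4)
    if (params$likelihood_dropout > 0) {
      drop <- which(runif(n) < params$likelihood_dropout)
      if (length(drop))
        lik[cbind(drop, sample.int(4, length(drop), replace = TRUE))] <-
          runif(length(drop), 0, 0.89)
    }

    list(landmarks = landmark_series(time = (seq_len(n) - 1) / fr,
                                     positions = pos, likelihood = lik,
                                     frame_rate = fr),
         truth = ang$truth)
  })
}

#' Align detected bouts with simulation ground truth
#'
#' For each detected bout (or any frame-span table), reports the majority
#' ground-truth motif and side over its frames and whether the span lies
#' purely inside a single motif / side (spans straddling a transition are
#' ambiguous by construction and are best excluded from recovery
#' comparisons).
#'
#' @param spans data.frame with `start` and `end` frame columns (e.g. a
#'   `wag_bouts` table or a segment table).
#' @param truth a `ground_truth` object.
#' @return data.frame: `motif`, `side` (majority labels, NA if no labeled
#'   frames), `pure_motif`, `pure_side`.
#' @export
truth_bout_labels <- function(spans, truth) {
  fr <- truth$frames
  out <- lapply(seq_len(nrow(spans)), function(i) {
    idx <- spans$start[i]:spans$end[i]
    m <- fr$motif[idx]; m <- m[!is.na(m)]
    s <- fr$side[idx]; s <- s[!is.na(s)]
    data.frame(
      motif = if (length(m)) as.integer(names(which.max(table(m)))) else NA_integer_,
      side = if (length(s)) names(which.max(table(s))) else NA_character_,
      pure_motif = length(m) > 0 && length(unique(m)) == 1L,
      pure_side = length(s) > 0 && length(unique(s)) == 1L)
  })
  do.call(rbind, out)
}

#' Simulate a multi-animal, multi-day cohort
#'
#' Each animal receives its own persistent motif bank (its individual
#' wagging fingerprint) drawn from an animal-specific sub-seed of the
#' master seed; each day's session gets its own sub-seed, and the lateral
#' bias is linearly interpolated from `bias_drift[1]` on day 1 to
#' `bias_drift[2]` on the last day.
#'
#' @param n_animals,n_days cohort dimensions (both >= 1).
#' @param bias_drift length-2 start/end right-side bout fractions.
#' @param params [sim_params()] template applied to every session (its
#'   `bias` and `seed` fields are overridden per session).
#' @param seed master seed split into per-animal / per-day streams.
#' @return list with one element per session: `animal`, `day`, `bias`,
#'   `landmarks`, `truth`.
#' @export
simulate_cohort <- function(n_animals, n_days, bias_drift = c(0.5, 0.5),
                            params = sim_params(), seed = 1L) {
  stopifnot(n_animals >= 1, n_days >= 1, length(bias_drift) == 2)
  out <- list()
  for (a in seq_len(n_animals)) {
    a_seed <- split_seed(seed, a)
    bank <- with_local_seed(a_seed,
      make_motif_bank(params$n_motifs, params$motif_freq_range))
    for (d in seq_len(n_days)) {
      bias_d <- if (n_days == 1L) bias_drift[1] else
        bias_drift[1] + (d - 1) / (n_days - 1) * (bias_drift[2] - bias_drift[1])
      p <- params
      p$bias <- bias_d
      p$seed <- split_seed(a_seed, d)
      ses <- simulate_session(p, motif_bank = bank)
      out[[length(out) + 1L]] <- list(animal = a, day = d, bias = bias_d,
                                      landmarks = ses$landmarks,
                                      truth = ses$truth)
    }
  }
  out
}
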