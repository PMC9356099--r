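# Delay embedding, Wolf LLE properties, sliding profiles, state
# classification, spatial splitting, the module hierarchy and its
# transition graph / ethogram outputs.

test_that("delay embedding dimensions and degenerate cases", {
  E <- delay_embed(rnorm(300), m = 3, tau = 100)
  expect_identical(dim(E), c(100L, 3L))
  x <- rnorm(10)
  expect_equal(delay_embed(x, m = 1, tau = 5)[, 1], x)
  Ec <- delay_embed(rep(2, 50), m = 3, tau = 10)
  expect_true(all(Ec == 2))
  expect_error(delay_embed(rnorm(10), m = 3, tau = 100), "too short")
})

test_that("Wolf LLE: periodic low, stochastic positive, affine invariant", {
  t <- seq(0, 20, by = 1 / 150)
  s <- 30 * sin(2 * pi * 3.7 * t)
  expect_lte(as.numeric(wolf_lle(s[1:300], m = 3, tau = 100)), 0.02)
  set.seed(4)
  expect_gt(as.numeric(wolf_lle(rnorm(1000), m = 3, tau = 1)), 0)
  # rescaling the series with eps rescaled identically changes nothing
  x <- logistic_series(400)
  l1 <- wolf_lle(x, m = 2, tau = 1, eps = 0.05, standardize = FALSE)
  l2 <- wolf_lle(5 * x + 3, m = 2, tau = 1, eps = 0.25,
                 standardize = FALSE)
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-10)
  # constant series has zero exponent
  expect_equal(as.numeric(wolf_lle(rep(1, 400), m = 2, tau = 1)), 0)
})

test_that("sliding LLE window accounting and stability contrast", {
  n <- 3000
  tr <- toy_trace(cbind(10 * sin(2 * pi * 4 * (1:n) / 150),
                        -18 + 2 * cos(2 * pi * 4 * (1:n) / 150),
                        15 + sin(2 * pi * 8 * (1:n) / 150)))
  prof <- sliding_lle(tr, window = 300, stride = 300)
  expect_identical(nrow(prof), 10L)       # non-overlapping count
  prof2 <- sliding_lle(tr, window = 300, stride = 10)
  expect_identical(nrow(prof2), as.integer((n - 300) / 10 + 1))
  expect_lt(max(prof2$sum), 1)            # periodic motion: low everywhere
  # windows over an injected stochastic stretch show elevated LLE
  tr2 <- tr
  set.seed(9)
  tr2$tail[1200:1800, ] <- tr2$tail[1200:1800, ] +
    20 * (logistic_series(601) - 0.5)
  prof3 <- sliding_lle(tr2, window = 300, stride = 10)
  inside <- prof3$start >= 1200 & prof3$end <= 1800
  before <- prof3$end < 1200
  expect_gt(mean(prof3$sum[inside]), mean(prof3$sum[before]))
  # windows touching masked frames are skipped
  tr3 <- tr
  tr3$valid[500] <- FALSE
  prof4 <- sliding_lle(tr3, window = 300, stride = 10)
  expect_false(any(prof4$start <= 500 & prof4$end >= 500))
})

test_that("state classification uses the interpolated percentile threshold", {
  prof <- data.frame(start = c(1, 11, 21, 31), end = c(300, 310, 320, 330),
                     lx = 0, ly = 0, lz = 0, sum = c(0.1, 0.2, 0.3, 0.4))
  class(prof) <- c("lle_profile", "data.frame")
  cls <- classify_states(prof, 25)
  expect_equal(cls$threshold, 0.175)
  expect_identical(sum(cls$windows$stable), 1L)
  # all-equal values are all stable; percentile 100 keeps everything
  prof$sum <- rep(0.3, 4)
  expect_true(all(classify_states(prof, 25)$windows$stable))
  prof$sum <- c(0.1, 0.2, 0.3, 0.4)
  expect_true(all(classify_states(prof, 100)$windows$stable))
  # stable window share tracks the percentile when values are distinct
  prof2 <- data.frame(start = seq(1, 991, 10), end = seq(300, 1290, 10),
                      lx = 0, ly = 0, lz = 0, sum = seq(0.01, 1, 0.01))
  class(prof2) <- c("lle_profile", "data.frame")
  cls2 <- classify_states(prof2, 25)
  expect_equal(mean(cls2$windows$stable), 0.25, tolerance = 0.011)
})

test_that("spatial splitting follows the 0.8 cm anchor rule", {
  # stationary oscillation: bouts returning to the same point, one segment
  n <- 600
  th <- 30 * sin(2 * pi * 5 * (0:(n - 1)) / 150) * pi / 180
  tail <- cbind(20 * sin(th), -20 * cos(th), 15)
  tr <- toy_trace(tail)
  ang <- wagging_angle(tr)
  b <- segment_bouts(detect_extrema(ang), ang)
  expect_gt(nrow(b), 5)
  expect_identical(nrow(spatial_split(b, tr)), 1L)
  expect_identical(nrow(spatial_split(b, tr, gap_cm = Inf)), 1L)
  # a 5 cm postural shift mid-session splits at the shift
  tail2 <- tail
  shift_at <- b$start[ceiling(nrow(b) / 2)]
  tail2[shift_at:n, 1] <- tail2[shift_at:n, 1] + 5
  tr2 <- toy_trace(tail2)
  ang2 <- wagging_angle(tr2)
  b2 <- segment_bouts(detect_extrema(ang2), ang2)
  s2 <- spatial_split(b2, tr2)
  expect_gt(nrow(s2), 1L)
})

test_that("transition graph probabilities are row-stochastic with correct ratios", {
  lab <- data.frame(segment = 1:4, start = c(1, 101, 201, 301),
                    end = c(100, 200, 300, 400),
                    class = c("stable", "transient", "stable", "transient"),
                    module = c("SM1", "TM", "SM1", "TM"))
  tg <- transition_graph(lab)
  e <- tg$edges
  expect_equal(e$p[e$from == "SM1" & e$to == "TM"], 1)
  expect_equal(e$p[e$from == "TM" & e$to == "SM1"], 1)
  expect_equal(sum(tg$nodes$ratio), 1)
  # single label: no edges, full occupancy
  tg1 <- transition_graph(lab[1, ])
  expect_identical(nrow(tg1$edges), 0L)
  expect_equal(tg1$nodes$ratio, 1)
  # random labelings stay row-stochastic
  set.seed(13)
  for (r in 1:5) {
    k <- sample(2:5, 1)
    labs <- paste0("SM", sample(k, 30, replace = TRUE))
    labr <- data.frame(segment = 1:30, start = seq(1, 291, 10),
                       end = seq(10, 300, 10), class = "stable",
                       module = labs)
    tgr <- transition_graph(labr)
    out <- as.numeric(tapply(tgr$edges$p, tgr$edges$from, sum))
    expect_equal(out, rep(1, length(out)), tolerance = 1e-12)
  }
})

test_that("ethogram slices the module track into epochs", {
  lab <- data.frame(segment = 1:2, start = c(1, 9001), end = c(9000, 18000),
                    class = "stable", module = c("SM1", "SM2"))
  eth <- ethogram(lab, frame_rate = 150, epoch_s = 30)
  expect_length(eth$epochs, 4)            # 120 s -> four 30-s epochs
  expect_identical(unlist(eth$epochs), seq_len(18000))
  expect_identical(eth$track[1], "SM1")
  expect_identical(eth$track[18000], "SM2")
  empty <- ethogram(lab[0, ], frame_rate = 150)
  expect_length(empty$epochs, 0)
})

test_that("identical segments collapse to a single micro-module", {
  th <- rep(30 * sin(2 * pi * 5 * (0:29) / 150), 10) * pi / 180
  tail <- cbind(20 * sin(th), -20 * cos(th), 15)
  tr <- toy_trace(tail)
  segs <- data.frame(segment = 1:10, first_bout = 1:10, last_bout = 1:10,
                     start = seq(1, 271, 30), end = seq(30, 300, 30))
  expect_warning(
    lab <- module_hierarchy(segs, tr, rep("stable", 300), k = 3,
                            grid_size = 10),
    "k reduced")
  expect_true(all(lab$micro == 1L))
  expect_identical(length(unique(lab$module)), 1L)
})

test_that("planted motifs survive the full stability stack", {
  p <- sim_params(duration = 90, n_motifs = 3, seed = 42, bias = 1,
                  noise_sd = 0, likelihood_dropout = 0,
                  still_fraction = 0.2, run_bouts = 4)
  ses <- simulate_session(p, motif_bank = test_bank())
  trace <- preprocess_session(ses$landmarks)
  ang <- wagging_angle(trace)
  b <- segment_bouts(detect_extrema(ang), ang)
  prof <- sliding_lle(trace)
  cls <- classify_states(prof, 75, n_frames = length(trace$time))
  segs <- spatial_split(b, trace)
  lab <- module_hierarchy(segs, trace, cls$frame_class, k = 3,
                          grid_size = 20, seed = 1)
  st <- lab[lab$class == "stable", ]
  expect_gte(nrow(st), 20)
  gtl <- truth_bout_labels(st, ses$truth)
  expect_gte(adjusted_rand_index(st$module, gtl$motif), 0.8)
})
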