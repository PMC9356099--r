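# DTW properties, pairwise matrix construction, affinity propagation,
# silhouettes (against cluster::silhouette), session signatures,
# similarity and the 2-D embedding.

test_that("DTW identities and warping examples", {
  expect_equal(dtw_distance(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dtw_distance(c(0, 0, 0), c(0, 0, 1)), 1)
  expect_equal(dtw_distance(c(0, 1, 0), c(0, 1, 1, 0)), 0)
  expect_error(dtw_distance(numeric(0), 1), "empty")
  # multivariate traces
  X <- cbind(c(0, 1, 0), c(0, 0, 0))
  Y <- cbind(c(0, 1, 1, 0), c(0, 0, 0, 0))
  expect_equal(dtw_distance(X, Y), 0)
})

test_that("DTW is symmetric, nonnegative, zero iff equal, <= Euclidean", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1))
    d <- dtw_distance(x, y)
    expect_gte(d, 0)
    expect_equal(d, dtw_distance(y, x), tolerance = 1e-12)
    if (length(x) == length(y)) {
      expect_lte(d, sqrt(sum((x - y)^2)) + 1e-12)
      if (d == 0) expect_equal(x, y)
    }
  }
})

test_that("pairwise matrix is symmetric and matches elementwise DTW", {
  set.seed(3)
  traces <- replicate(8, rnorm(sample(5:9, 1)), simplify = FALSE)
  traces[[5]] <- traces[[2]]                # planted duplicate
  D <- pairwise_dtw(traces)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 8))
  expect_equal(D[2, 5], 0)
  for (k in 1:10) {
    ij <- sample(8, 2)
    expect_equal(D[ij[1], ij[2]],
                 dtw_distance(traces[[ij[1]]], traces[[ij[2]]]))
  }
  # permutation consistency
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  expect_equal(pairwise_dtw(traces[perm]), D[perm, perm])
})

test_that("affinity propagation recovers planted groups and degenerate cases", {
  set.seed(21)
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  ap <- ap_cluster(as.matrix(dist(x)))
  expect_identical(ap$k, 2L)
  expect_identical(ap$labels[1:10], rep(ap$labels[1], 10))
  expect_identical(ap$labels[11:20], rep(ap$labels[11], 10))
  # every exemplar belongs to its own cluster
  expect_identical(ap$labels[ap$exemplars], seq_len(ap$k))
  # all-identical points collapse to one cluster
  expect_identical(ap_cluster(matrix(0, 6, 6))$k, 1L)
  # singleton input is its own exemplar
  ap1 <- ap_cluster(matrix(0, 1, 1))
  expect_identical(ap1$k, 1L)
  expect_identical(ap1$exemplars, 1L)
  # deterministic
  ap_b <- ap_cluster(as.matrix(dist(x)))
  expect_identical(ap$labels, ap_b$labels)
})

test_that("silhouettes follow the formula and match cluster::silhouette", {
  # two well-separated tight pairs
  x <- c(0, 0.01, 10, 10.01)
  D <- as.matrix(dist(x))
  s <- silhouette_scores(D, c(1, 1, 2, 2))
  expect_true(all(s > 0.9))
  # equidistant point scores 0; singleton clusters score 0
  D3 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  expect_equal(silhouette_scores(D3, c(1, 1, 2))[3], 0)
  expect_true(all(is.na(silhouette_scores(D3, c(1, 1, 1)))))
  skip_if_not_installed("cluster")
  set.seed(8)
  pts <- matrix(rnorm(40), 20)
  Dr <- as.matrix(dist(pts))
  lab <- sample(1:3, 20, replace = TRUE)
  lab[1:3] <- 1:3                       # ensure every cluster present
  ours <- silhouette_scores(Dr, lab)
  ref <- cluster::silhouette(lab, dmatrix = Dr)[, "sil_width"]
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("session signatures normalize counts and pool back to totals", {
  labels <- c(1, 1, 2, 2, 3, 1)
  sessions <- c("s1", "s1", "s1", "s2", "s2", "s2")
  sig <- session_signature(labels, sessions)
  expect_equal(sig["s1", ], c(2 / 3, 1 / 3, 0), ignore_attr = TRUE)
  expect_equal(rowSums(sig), c(s1 = 1, s2 = 1))
  counts <- sig * as.vector(table(sessions)[rownames(sig)])
  expect_equal(colSums(counts), as.vector(tabulate(labels, 3)),
               ignore_attr = TRUE)
})

test_that("cosine session similarity: identical zero, disjoint one", {
  sig <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1))
  ss <- session_similarity(sig)
  expect_equal(ss$distance["a", "b"], 0, tolerance = 1e-12)
  expect_equal(ss$distance["a", "c"], 1, tolerance = 1e-12)
  expect_s3_class(ss$hclust, "hclust")
  f <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(ss$hclust, f)
  expect_true(grepl(";", readLines(f)[1]))
  unlink(f)
})

test_that("2-D embedding keeps planted separation and is deterministic", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 8, 0.3), 20))
  D <- as.matrix(dist(x))
  Y <- embed_2d(D)
  expect_identical(dim(Y), c(40L, 2L))
  expect_identical(Y, embed_2d(D))
  # nearest-neighbor purity between the two groups
  grp <- rep(1:2, each = 20)
  DY <- as.matrix(dist(Y)); diag(DY) <- Inf
  nn <- apply(DY, 1, which.min)
  expect_gt(mean(grp[nn] == grp), 0.9)
})

test_that("planted motifs are recovered by DTW-AP clustering", {
  ses <- simulate_session(sim_params(duration = 90, n_motifs = 3, seed = 42,
                                     bias = 1, noise_sd = 0,
                                     likelihood_dropout = 0,
                                     still_fraction = 0.2))
  trace <- preprocess_session(ses$landmarks)
  ang <- wagging_angle(trace)
  b <- segment_bouts(detect_extrema(ang), ang)
  ap <- ap_cluster(pairwise_dtw(bout_traces(b, angles = ang)))
  gtl <- truth_bout_labels(b, ses$truth)
  pure <- gtl$pure_motif
  expect_gt(sum(pure), 100)
  expect_gte(adjusted_rand_index(ap$labels[pure], gtl$motif[pure]), 0.8)
})
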