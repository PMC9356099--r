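# Attractor-like dynamics of the tail-tip trajectory: delay embedding,
# Wolf's largest-Lyapunov-exponent (LLE) estimator, sliding-window LLE
# profiles, stable/transient state classification by an LLE percentile
# threshold, spatial splitting of bout runs, the three-tier module
# hierarchy (DTW-AP, DTW-AP, k-means on voxelized trajectories), module
# transition graphs and ethograms.

#' Delay embedding of a scalar series
#'
#' Reconstructs an m-dimensional phase space from lagged copies:
#' point i is `(x_i, x_(i+tau), ..., x_(i+(m-1)tau))`.
#'
#' @param x numeric series.
#' @param m embedding dimension (default 3).
#' @param tau delay in samples (default 100).
#' @return matrix with `length(x) - (m-1)*tau` rows and `m` columns.
#' @export
delay_embed <- function(x, m = 3, tau = 100) {
  n <- length(x)
  npts <- n - (m - 1) * tau
  if (npts < 1L) stop("series too short for this embedding (need > (m-1)*tau)")
  vapply(seq_len(m) - 1L, function(k) x[(1 + k * tau):(npts + k * tau)],
         numeric(npts))
}

# Choose a replacement neighbor for fiducial point `i`: among points
# within eps (and above a small distance floor — numerically duplicated
# points, e.g. exact period repeats, carry no divergence information),
# the one whose replacement vector makes the smallest angle with the
# evolved vector `vprev`; nearest overall when no candidate lies within
# eps (relaxation, counted).
pick_neighbor <- function(Y, i, eps, vprev = NULL, floor_dist = eps * 1e-3) {
  d <- sqrt(rowSums((Y - matrix(Y[i, ], nrow(Y), ncol(Y), byrow = TRUE))^2))
  d[i] <- Inf
  d[d <= floor_dist] <- Inf
  cand <- which(d <= eps)
  relaxed <- FALSE
  if (!length(cand)) {
    relaxed <- TRUE
    j <- which.min(d)
  } else if (is.null(vprev) || sqrt(sum(vprev^2)) == 0) {
    j <- cand[which.min(d[cand])]
  } else {
    V <- Y[cand, , drop = FALSE] -
      matrix(Y[i, ], length(cand), ncol(Y), byrow = TRUE)
    cosang <- (V %*% vprev) / (d[cand] * sqrt(sum(vprev^2)))
    j <- cand[which.max(cosang)]
  }
  list(j = j, L = d[j], relaxed = relaxed)
}

#' Largest Lyapunov exponent by Wolf's algorithm
#'
#' Tracks the divergence between a fiducial trajectory and its nearest
#' neighbor in the delay-embedded phase space. In `"replacement"` mode the
#' pair evolves until their separation exceeds `eps`; the base-2 log of
#' the divergence ratio is recorded and a new neighbor is chosen within
#' `eps` minimizing the angle to the evolved vector (falling back to the
#' nearest point, with a diagnostic count, when none qualifies). The
#' exponent is the mean recorded log ratio over the M replacement steps,
#' in bits per replacement step. `"per_iteration"` mode replaces the
#' neighbor after every single step, giving bits per sample step (the
#' convention under which the fully chaotic logistic map has exponent 1).
#'
#' @param x scalar series.
#' @param m,tau embedding dimension and delay (defaults 3, 100).
#' @param eps separation threshold; by default interpreted on the
#'   standardized series (see `standardize`).
#' @param standardize center/scale the series to unit variance before
#'   embedding, making `eps` amplitude-independent (default TRUE); set
#'   FALSE to apply `eps` in raw coordinate units.
#' @param mode `"replacement"` (default) or `"per_iteration"`.
#' @return the exponent (bits per step), with attributes `M` (number of
#'   recorded steps) and `relaxed` (replacements that needed the eps
#'   relaxation). A constant series returns 0.
#' @export
wolf_lle <- function(x, m = 3, tau = 100, eps = 0.16, standardize = TRUE,
                     mode = c("replacement", "per_iteration")) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(x)))
  if (standardize) {
    s <- sd(x)
    if (s == 0) return(structure(0, M = 0L, relaxed = 0L))
    x <- (x - mean(x)) / s
  }
  Y <- delay_embed(x, m, tau)
  N <- nrow(Y)
  if (N < 3L) stop("too few embedded points")
  dist_ij <- function(i, j) sqrt(sum((Y[i, ] - Y[j, ])^2))

  logs <- numeric(0)
  relaxed <- 0L
  nb <- pick_neighbor(Y, 1L, eps)
  if (!is.finite(nb$L)) return(structure(0, M = 0L, relaxed = 0L))
  i <- 1L; j <- nb$j; L <- nb$L
  if (nb$relaxed) relaxed <- relaxed + 1L

  if (mode == "per_iteration") {
    while (i < N && j < N) {
      i <- i + 1L; j <- j + 1L
      Lp <- dist_ij(i, j)
      if (L > 0 && Lp > 0) logs <- c(logs, log2(Lp / L))
      if (i >= N) break
      vprev <- Y[j, ] - Y[i, ]
      nb <- pick_neighbor(Y, i, eps, vprev)
      if (!is.finite(nb$L)) break
      if (nb$relaxed) relaxed <- relaxed + 1L
      j <- nb$j; L <- nb$L
    }
  } else {
    repeat {
      Lp <- NA_real_
      while (i < N && j < N) {
        i <- i + 1L; j <- j + 1L
        Lp <- dist_ij(i, j)
        if (Lp > eps) break
      }
      if (is.finite(Lp) && L > 0 && Lp > 0)
        logs <- c(logs, log2(Lp / L))
      if (i >= N || j >= N) break
      vprev <- Y[j, ] - Y[i, ]
      nb <- pick_neighbor(Y, i, eps, vprev)
      if (!is.finite(nb$L)) break
      if (nb$relaxed) relaxed <- relaxed + 1L
      j <- nb$j; L <- nb$L
    }
  }
  lam <- if (length(logs)) mean(logs) else 0
  structure(lam, M = length(logs), relaxed = relaxed)
}

#' Sliding-window LLE profile of a tail-tip trace
#'
#' Computes [wolf_lle()] per coordinate axis (x, y, z of the body-frame
#' tail tip) in windows of `window` frames advanced by `stride`, and their
#' per-window sum, which indexes the local stability of wagging. Windows
#' containing any masked frame are skipped.
#'
#' @param trace a `body_frame_trace`.
#' @param window,stride window width and stride in frames (defaults 300,
#'   10).
#' @param m,tau,eps,standardize passed to [wolf_lle()].
#' @return `lle_profile` data.frame: `start`, `end`, `lx`, `ly`, `lz`,
#'   `sum` (one row per evaluated window).
#' @export
sliding_lle <- function(trace, window = 300, stride = 10, m = 3,
                        tau = 100, eps = 0.16, standardize = TRUE) {
  stopifnot(inherits(trace, "body_frame_trace"), window >= 2, stride >= 1)
  n <- length(trace$time)
  npts <- window - (m - 1) * tau
  if (npts < 1L) stop("window too short for the embedding")
  if (npts < 50L)
    warning("only ", npts, " embedded points per window; ",
            "LLE estimates will be noisy")
  starts <- seq.int(1L, max(1L, n - window + 1L), by = stride)
  starts <- starts[starts + window - 1L <= n]
  rows <- lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    if (!all(trace$valid[idx])) return(NULL)
    l <- vapply(1:3, function(ax)
      as.numeric(wolf_lle(trace$tail[idx, ax], m, tau, eps, standardize)),
      numeric(1))
    data.frame(start = s, end = s + window - 1L,
               lx = l[1], ly = l[2], lz = l[3], sum = sum(l))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), lx = numeric(0),
               ly = numeric(0), lz = numeric(0), sum = numeric(0))
  attr(out, "window") <- window
  attr(out, "stride") <- stride
  class(out) <- c("lle_profile", "data.frame")
  out
}

#' Classify windows and frames as stable or transient
#'
#' The stability threshold is the given percentile (linear interpolation)
#' of the session's summed-LLE distribution; windows at or below it are
#' stable. Each frame inherits the majority class of the windows covering
#' it (ties resolve to stable); contiguous same-class frames merge into
#' spans.
#'
#' @param profile an `lle_profile`.
#' @param percentile stability percentile, 0-100 (default 25).
#' @param n_frames session length in frames (default: last window end).
#' @return list: `threshold`, `windows` (profile plus `stable` flag),
#'   `frame_class` (per-frame `"stable"`/`"transient"`/NA), `spans`
#'   (data.frame `start`, `end`, `class`).
#' @export
classify_states <- function(profile, percentile = 25, n_frames = NULL) {
  stopifnot(nrow(profile) >= 4L, percentile >= 0, percentile <= 100)
  thr <- as.numeric(quantile(profile$sum, percentile / 100, type = 7))
  stable <- profile$sum <= thr
  if (is.null(n_frames)) n_frames <- max(profile$end)
  votes_s <- integer(n_frames + 1L); votes_t <- integer(n_frames + 1L)
  for (w in seq_len(nrow(profile))) {     # coverage difference arrays
    a <- profile$start[w]; b <- profile$end[w]
    if (stable[w]) {
      votes_s[a] <- votes_s[a] + 1L; votes_s[b + 1L] <- votes_s[b + 1L] - 1L
    } else {
      votes_t[a] <- votes_t[a] + 1L; votes_t[b + 1L] <- votes_t[b + 1L] - 1L
    }
  }
  cs <- cumsum(votes_s[seq_len(n_frames)])
  ct <- cumsum(votes_t[seq_len(n_frames)])
  frame_class <- rep(NA_character_, n_frames)
  cov <- cs + ct > 0L
  frame_class[cov] <- ifelse(cs[cov] >= ct[cov], "stable", "transient")

  spans <- NULL
  r <- rle(ifelse(is.na(frame_class), "<gap>", frame_class))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values != "<gap>"
  spans <- data.frame(start = starts[keep], end = ends[keep],
                      class = r$values[keep])
  prof2 <- profile
  prof2$stable <- stable
  list(threshold = thr, windows = prof2, frame_class = frame_class,
       spans = spans)
}

#' Split consecutive bouts into spatial segments
#'
#' Consecutive bouts accumulate into one segment as long as the Euclidean
#' distance between the segment's start point (body-frame tail-tip
#' position at the first bout's start frame) and the current bout's end
#' point stays within `gap_cm`; exceeding it — or a temporal discontinuity
#' between bouts — closes the segment. This groups wagging that stays in
#' one place while splitting at postural shifts.
#'
#' @param bouts a `wag_bouts` table in temporal order.
#' @param trace the `body_frame_trace` the bouts live on.
#' @param gap_cm spatial tolerance in cm (default 0.8).
#' @return data.frame: `segment`, `first_bout`, `last_bout`, `start`,
#'   `end` (frames).
#' @export
spatial_split <- function(bouts, trace, gap_cm = 0.8) {
  n <- nrow(bouts)
  if (n == 0L)
    return(data.frame(segment = integer(0), first_bout = integer(0),
                      last_bout = integer(0), start = integer(0),
                      end = integer(0)))
  pos <- function(f) trace$tail[f, ]
  seg_id <- integer(n)
  cur <- 1L
  anchor <- pos(bouts$start[1])
  seg_id[1] <- cur
  for (i in seq_len(n)[-1]) {
    contiguous <- bouts$start[i] == bouts$end[i - 1L] &&
      bouts$run[i] == bouts$run[i - 1L]
    d <- sqrt(sum((anchor - pos(bouts$end[i]))^2))
    if (!contiguous || d > gap_cm) {
      cur <- cur + 1L
      anchor <- pos(bouts$start[i])
    }
    seg_id[i] <- cur
  }
  out <- do.call(rbind, lapply(seq_len(cur), function(s) {
    ix <- which(seg_id == s)
    data.frame(segment = s, first_bout = ix[1], last_bout = ix[length(ix)],
               start = bouts$start[ix[1]], end = bouts$end[ix[length(ix)]])
  }))
  out
}

#' Three-tier module hierarchy over wagging segments
#'
#' Stable segments (majority of frames classified stable) go through:
#' (1) DTW + affinity propagation over the segments' 3D tail-tip traces,
#' giving micro-modules; (2) DTW + affinity propagation over the
#' micro-module exemplar segments, giving mini-modules; (3) each
#' mini-module exemplar trace is min-max normalized into the unit cube,
#' voxelized into a `grid_size`^3 occupancy histogram, reduced by PCA to
#' at most `n_pc` components and grouped by k-means into `k` stable
#' modules (SM1..SMk). Transient segments are pooled into the single
#' transient module TM.
#'
#' @param segments segment table from [spatial_split()].
#' @param trace the `body_frame_trace`.
#' @param frame_class per-frame classification from [classify_states()].
#' @param k number of stable modules (default 8); reduced with a warning
#'   when fewer mini-modules exist.
#' @param grid_size voxel grid resolution per axis (default 100).
#' @param n_pc maximum principal components kept (default 20).
#' @param seed seed for the k-means restarts (50 restarts; the caller's
#'   RNG state is untouched).
#' @param stable_min_frac minimum fraction of stable frames for a segment
#'   to count as stable (default 0.5).
#' @param tier2_min minimum number of micro-modules before the mini-module
#'   tier runs (default 30); below it, mini-modules equal micro-modules.
#' @return `module_labeling` data.frame: `segment`, `start`, `end`,
#'   `class` (`"stable"`/`"transient"`), `micro`, `mini`, `module`
#'   (`"SM<i>"` or `"TM"`); micro-step silhouette scores in attribute
#'   `"micro_silhouette"`.
#' @export
module_hierarchy <- function(segments, trace, frame_class, k = 8,
                             grid_size = 100, n_pc = 20, seed = 1L,
                             stable_min_frac = 0.5, tier2_min = 30) {
  n <- nrow(segments)
  stable_frac <- vapply(seq_len(n), function(i) {
    fc <- frame_class[segments$start[i]:segments$end[i]]
    mean(fc == "stable", na.rm = TRUE)
  }, numeric(1))
  is_stable <- !is.na(stable_frac) & stable_frac >= stable_min_frac
  out <- data.frame(segment = segments$segment, start = segments$start,
                    end = segments$end,
                    class = ifelse(is_stable, "stable", "transient"),
                    micro = NA_integer_, mini = NA_integer_,
                    module = "TM", stringsAsFactors = FALSE)
  sIdx <- which(is_stable)
  if (length(sIdx) < 2L)
    stop("need at least 2 stable segments for the module hierarchy")

  traces <- lapply(sIdx, function(i)
    trace$tail[segments$start[i]:segments$end[i], , drop = FALSE])

  # tier 1: micro-modules
  D1 <- pairwise_dtw(traces)
  ap1 <- ap_cluster(D1)
  micro_sil <- silhouette_scores(D1, ap1$labels)

  # tier 2: mini-modules over micro exemplars. This tier exists to reduce
  # scale when tier 1 yields many micro-modules; on small exemplar sets it
  # only discards resolution (and would starve the final k-means below k
  # groups), so it runs only above `tier2_min` micro-modules and only if
  # it keeps at least k mini-modules.
  ex1 <- ap1$exemplars
  mini_of_micro <- seq_along(ex1)
  ex2 <- ex1
  if (length(ex1) >= max(tier2_min, k)) {
    D2 <- pairwise_dtw(traces[ex1])
    ap2 <- ap_cluster(D2)
    if (ap2$k >= k) {
      mini_of_micro <- ap2$labels
      ex2 <- ex1[ap2$exemplars]        # segment index (within sIdx) per mini
    }
  }
  n_mini <- length(ex2)

  # tier 3: k-means on PCA-reduced voxel occupancy of mini exemplars
  all_pts <- do.call(rbind, traces[ex2])
  ranges <- apply(all_pts, 2L, range)
  feats <- t(vapply(ex2,
                    function(i) voxelize_trace(traces[[i]], grid_size, ranges),
                    numeric(grid_size^3)))
  kk <- min(k, n_mini)
  if (kk < k) warning("only ", n_mini, " mini-modules; k reduced to ", kk)
  if (n_mini <= kk) {          # nothing to merge: one module per mini
    module_of_mini <- seq_len(n_mini)
  } else {
    pc <- prcomp(feats, center = TRUE, scale. = FALSE)
    nc <- min(n_pc, ncol(pc$x))
    scores <- pc$x[, seq_len(nc), drop = FALSE]
    km <- with_local_seed(seed, kmeans(scores, centers = kk, nstart = 50))
    module_of_mini <- km$cluster
  }

  micro <- ap1$labels
  mini <- mini_of_micro[micro]
  module <- module_of_mini[mini]
  out$micro[sIdx] <- micro
  out$mini[sIdx] <- mini
  out$module[sIdx] <- paste0("SM", module)
  attr(out, "micro_silhouette") <- micro_sil
  attr(out, "k") <- kk
  class(out) <- c("module_labeling", "data.frame")
  out
}

# Voxelize a 3D trace into a grid^3 occupancy histogram (normalized by
# point count) over a shared normalized trajectory space: `ranges` is a
# 2 x 3 matrix of per-axis min/max common to all traces being compared,
# so relative position and amplitude stay discriminative. Flat axes map
# to the central voxel.
voxelize_trace <- function(X, grid_size, ranges = apply(X, 2L, range)) {
  U <- vapply(1:3, function(j) {
    lo <- ranges[1, j]; hi <- ranges[2, j]
    if (hi > lo) (X[, j] - lo) / (hi - lo) else rep(0.5, nrow(X))
  }, numeric(nrow(X)))
  if (!is.matrix(U)) U <- matrix(U, ncol = 3)
  ix <- pmin(pmax(floor(U * grid_size) + 1L, 1L), grid_size)
  lin <- (ix[, 3] - 1L) * grid_size^2 + (ix[, 2] - 1L) * grid_size + ix[, 1]
  tabulate(lin, nbins = grid_size^3) / nrow(X)
}

#' Module transition graph
#'
#' Empirical first-order transition probabilities between the module
#' labels of consecutive segments, plus each module's occupancy ratio
#' (share of labeled frames).
#'
#' @param labeling a `module_labeling`.
#' @return `transition_graph` list: `nodes` (module, ratio), `edges`
#'   (from, to, n, p); outgoing probabilities sum to 1 per non-terminal
#'   node, ratios sum to 1.
#' @export
transition_graph <- function(labeling) {
  lab <- labeling[order(labeling$start), , drop = FALSE]
  dur <- lab$end - lab$start + 1L
  occ <- tapply(dur, lab$module, sum)
  nodes <- data.frame(module = names(occ),
                      ratio = as.numeric(occ) / sum(dur))
  edges <- data.frame(from = character(0), to = character(0),
                      n = integer(0), p = numeric(0))
  if (nrow(lab) >= 2L) {
    from <- lab$module[-nrow(lab)]
    to <- lab$module[-1]
    tab <- table(from, to)
    idx <- which(tab > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(from = rownames(tab)[idx[, 1]],
                          to = colnames(tab)[idx[, 2]],
                          n = as.integer(tab[idx]))
      tot <- tapply(edges$n, edges$from, sum)
      edges$p <- edges$n / as.numeric(tot[edges$from])
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d modules, %d transitions\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a transition graph to GraphML and an edge-list CSV
#' @param graph a `transition_graph`.
#' @param graphml_path,edges_path output paths (NULL to skip either).
#' @return NULL, invisibly.
#' @export
write_transition_graph <- function(graph, graphml_path = NULL,
                                   edges_path = NULL) {
  if (!is.null(edges_path))
    write.csv(graph$edges, edges_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                       vertices = graph$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(NULL)
}

#' Ethogram: per-frame module track sliced into epochs
#'
#' @param labeling a `module_labeling`.
#' @param frame_rate frames per second.
#' @param epoch_s epoch length in seconds (default 30).
#' @param n_frames track length (default: last segment end; 0 gives an
#'   empty ethogram).
#' @return `ethogram` list: `track` (per-frame module label, NA between
#'   segments), `epochs` (list of frame-index vectors), `epoch_s`.
#' @export
ethogram <- function(labeling, frame_rate = 150, epoch_s = 30,
                     n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- if (nrow(labeling)) max(labeling$end) else 0L
  track <- rep(NA_character_, n_frames)
  for (i in seq_len(nrow(labeling)))
    track[labeling$start[i]:labeling$end[i]] <- labeling$module[i]
  per <- max(1L, round(epoch_s * frame_rate))
  epochs <- if (n_frames > 0L)
    split(seq_len(n_frames), (seq_len(n_frames) - 1L) %/% per)
  else list()
  structure(list(track = track, epochs = unname(epochs),
                 epoch_s = epoch_s), class = "ethogram")
}
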