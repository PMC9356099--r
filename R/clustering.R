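# Bout clustering: dynamic-time-warping distances, affinity-propagation
# exemplar clustering, silhouette validation, per-session cluster-ID
# signatures ("fingerprints"), cosine session similarity with hierarchical
# clustering, and a 2-D embedding of the distance matrix for figures.

#' Dynamic-time-warping distance between two traces
#'
#' Minimum accumulated squared point distance over all monotone alignment
#' paths (unit steps right/down/diagonal, endpoints anchored), reported as
#' the square root of the accumulated cost so the distance scales linearly
#' with amplitude. Works on 1-D series (numeric vectors) or multivariate
#' traces (rows = time, columns = coordinates). Not a metric: the triangle
#' inequality need not hold, but symmetry, nonnegativity and
#' `dtw_distance(x, x) == 0` do.
#'
#' @param x,y numeric vectors or matrices with equal column counts.
#' @return nonnegative distance.
#' @export
dtw_distance <- function(x, y) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  Y <- if (is.matrix(y)) y else matrix(as.numeric(y), ncol = 1L)
  if (nrow(X) == 0L || nrow(Y) == 0L) stop("empty trace")
  if (ncol(X) != ncol(Y)) stop("traces differ in dimension")
  sqrt(.dtw_cost(X, Y))
}

#' Pairwise DTW distance matrix over bouts
#'
#' Each pair is computed once and mirrored, so the matrix is symmetric
#' with a zero diagonal by construction.
#'
#' @param traces list of bout traces (vectors or matrices, see
#'   [bout_traces()]).
#' @param meta optional data.frame of per-bout metadata (e.g. animal, day,
#'   bout id), attached as attribute `"meta"`.
#' @return n x n symmetric distance matrix.
#' @export
pairwise_dtw <- function(traces, meta = NULL) {
  n <- length(traces)
  stopifnot(n >= 2L)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- dtw_distance(traces[[i]], traces[[j]])
  if (!is.null(meta)) attr(D, "meta") <- meta
  D
}

#' Affinity-propagation clustering of a distance matrix
#'
#' Frey-Dueck affinity propagation on similarities `S = -D`, with the
#' shared preference set to the median off-diagonal similarity by default.
#' Message passing is damped and fully deterministic (a tiny fixed
#' tie-breaking offset replaces the random jitter usually used to resolve
#' symmetric degeneracies).
#'
#' @param D symmetric nonnegative distance matrix, zero diagonal.
#' @param preference shared exemplar preference; `"median"` (default),
#'   `"min"`, or a numeric value.
#' @param damping message damping in \[0.5, 1); default 0.9.
#' @param maxit maximum iterations (default 1000).
#' @param convits stop after this many iterations without a change in the
#'   exemplar set (default 100).
#' @return `ap_clustering` list: `labels` (1..k per point), `exemplars`
#'   (point index per cluster), `k`, `iterations`, `converged`.
#' @export
ap_cluster <- function(D, preference = "median", damping = 0.9,
                       maxit = 1000, convits = 100) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n == 1L)
    return(structure(list(labels = 1L, exemplars = 1L, k = 1L,
                          iterations = 0L, converged = TRUE),
                     class = "ap_clustering"))
  if (max(D) == 0)  # all points identical: one cluster, first as exemplar
    return(structure(list(labels = rep(1L, n), exemplars = 1L, k = 1L,
                          iterations = 0L, converged = TRUE),
                     class = "ap_clustering"))
  S <- -D
  off <- S[row(S) != col(S)]
  pref <- if (identical(preference, "median")) median(off)
          else if (identical(preference, "min")) min(off)
          else as.numeric(preference)
  diag(S) <- pref
  # deterministic symmetry-breaking jitter, far below the data scale
  scl <- (max(off) - min(off)) + abs(pref) + 1
  jit <- outer(seq_len(n), seq_len(n), function(i, j) ((i * 31L + j * 17L) %% 97L))
  S <- S + scl * 1e-10 * jit

  A <- matrix(0, n, n); R <- matrix(0, n, n)
  ex_prev <- rep(FALSE, n); stable <- 0L; it <- 0L
  idx <- seq_len(n)
  while (it < maxit) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, i1)]
    AS[cbind(idx, i1)] <- -Inf
    m2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(idx, i1)] <- S[cbind(idx, i1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- pmin(Rp * 0 + rep(cs, each = n) - Rp, 0)
    diag(Anew) <- cs - diag(Rp)
    A <- damping * A + (1 - damping) * Anew

    ex <- (diag(A) + diag(R)) > 0
    if (identical(ex, ex_prev)) stable <- stable + 1L else stable <- 0L
    ex_prev <- ex
    if (stable >= convits && any(ex)) break
  }
  if (it >= maxit && stable < convits)
    stop("affinity propagation did not converge after ", it,
         " iterations (", sum(ex_prev), " exemplar candidates; ",
         "try stronger damping or a lower preference)")
  exemplars <- which(ex_prev)
  if (!length(exemplars)) exemplars <- which.max(diag(A) + diag(R))
  assign_to <- max.col(S[, exemplars, drop = FALSE], ties.method = "first")
  assign_to[exemplars] <- seq_along(exemplars)
  structure(list(labels = assign_to, exemplars = exemplars,
                 k = length(exemplars), iterations = it,
                 converged = TRUE),
            class = "ap_clustering")
}

#' @export
print.ap_clustering <- function(x, ...) {
  cat(sprintf("<ap_clustering> %d points, %d clusters, %d iterations\n",
              length(x$labels), x$k, x$iterations))
  invisible(x)
}

#' Silhouette scores from a distance matrix and labels
#'
#' For point i with mean intra-cluster distance `a_i` and mean distance to
#' the nearest other cluster `b_i`, the silhouette is
#' `(b_i - a_i) / max(a_i, b_i)`, in \[-1, 1\]. Members of singleton
#' clusters score 0; with a single cluster overall every score is NA.
#'
#' @param D symmetric distance matrix.
#' @param labels integer cluster labels (length nrow(D)).
#' @return numeric vector of per-point silhouette scores.
#' @export
silhouette_scores <- function(D, labels) {
  n <- nrow(D)
  stopifnot(length(labels) == n)
  cl <- unique(labels)
  if (length(cl) < 2L) return(rep(NA_real_, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { out[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]),
                    function(c2) mean(D[i, labels == c2]), numeric(1)))
    m <- max(a, b)
    out[i] <- if (m == 0) 0 else (b - a) / m
  }
  out
}

#' Per-session cluster-ID signature
#'
#' The normalized frequency vector of global cluster IDs among a session's
#' bouts — the session's behavioural fingerprint.
#'
#' @param labels per-bout cluster labels (1..k).
#' @param sessions per-bout session keys (same length).
#' @param k number of global clusters (default `max(labels)`).
#' @return matrix (sessions x k), each row summing to 1, rownames =
#'   session keys.
#' @export
session_signature <- function(labels, sessions, k = max(labels)) {
  stopifnot(length(labels) == length(sessions), length(labels) >= 1L)
  keys <- unique(sessions)
  sig <- t(vapply(keys, function(s) {
    tabulate(labels[sessions == s], nbins = k)
  }, integer(k)))
  if (any(rowSums(sig) == 0)) stop("session with no bouts")
  sig <- sig / rowSums(sig)
  rownames(sig) <- as.character(keys)
  sig
}

#' Session similarity, dendrogram and same- vs different-dog test
#'
#' Cosine distances between session signatures, an average-linkage
#' dendrogram over them, and (when per-session animal IDs are given) a
#' two-sided Welch t-test comparing distances between sessions of the same
#' dog with distances between sessions of different dogs.
#'
#' @param signatures signature matrix from [session_signature()].
#' @param animals optional per-session animal IDs (length nrow).
#' @return list: `distance` (session x session cosine-distance matrix),
#'   `hclust` (average linkage), and if `animals` was given `test` with
#'   `p`, `mean_same`, `mean_different`, `n_same`, `n_different`.
#' @export
session_similarity <- function(signatures, animals = NULL) {
  n <- nrow(signatures)
  stopifnot(n >= 2L)
  D <- matrix(0, n, n, dimnames = list(rownames(signatures),
                                       rownames(signatures)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- cosine_distance(signatures[i, ],
                                            signatures[j, ])
  hc <- hclust(as.dist(D), method = "average")
  out <- list(distance = D, hclust = hc)
  if (!is.null(animals)) {
    stopifnot(length(animals) == n)
    same <- outer(animals, animals, "==") & upper.tri(D)
    diff_ <- !outer(animals, animals, "==") & upper.tri(D)
    ds <- D[same]; dd <- D[diff_]
    wt <- welch_test(ds, dd)
    out$test <- list(p = wt$p, mean_same = mean(ds),
                     mean_different = mean(dd),
                     n_same = length(ds), n_different = length(dd))
  }
  out
}

#' Export a session dendrogram as Newick text
#' @param hc an `hclust` object (e.g. from [session_similarity()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' 2-D embedding of a distance matrix
#'
#' Classical (metric) multidimensional scaling of the precomputed bout
#' distance matrix, for visualization: distances are approximated by a
#' rank-2 Euclidean configuration. Fully deterministic.
#'
#' @param D symmetric distance matrix.
#' @param k embedding dimension (default 2).
#' @return n x k coordinate matrix.
#' @export
embed_2d <- function(D, k = 2) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 2L)
  Y <- cmdscale(as.dist(D), k = k)
  if (ncol(Y) < k)  # degenerate configurations can drop dimensions
    Y <- cbind(Y, matrix(0, nrow(Y), k - ncol(Y)))
  Y
}
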