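# Left/right wagging asymmetry: per kinematic bin (counts of left- and
# right-sided angle extrema), per 20-s session segment (Welch's t-test on
# sub-segment frame counts), and per day across a cohort (Mann-Whitney
# with Holm-Šídák correction).

#' Asymmetric wagging index
#'
#' Default mode returns the normalized count difference
#' `(Xr - Xl) / (Xl + Xr)`: -1 means every counted extremum was left-sided
#' (complete left bias), +1 complete right bias, 0 perfect balance; NA
#' where a bin holds no extrema. The `paper_literal` mode instead returns
#' `(Xl - Xr) / max|Xl - Xr|`, normalizing the raw count differences by
#' their largest magnitude across the supplied bins (note its sign runs
#' opposite to the default mode: +1 is the strongest *left* excess).
#'
#' @param Xl,Xr nonnegative counts of left- and right-sided extrema
#'   (vectors = per-bin counts).
#' @param mode `"default"` or `"paper_literal"`.
#' @return index values in \[-1, 1\] (NA where undefined).
#' @export
asymmetry_index <- function(Xl, Xr, mode = c("default", "paper_literal")) {
  mode <- match.arg(mode)
  stopifnot(length(Xl) == length(Xr), all(Xl >= 0), all(Xr >= 0))
  if (mode == "default") {
    tot <- Xl + Xr
    ifelse(tot > 0, (Xr - Xl) / tot, NA_real_)
  } else {
    d <- Xl - Xr
    mx <- max(abs(d))
    if (mx == 0) return(rep(NA_real_, length(d)))
    d / mx
  }
}

#' Binned left/right asymmetry over a kinematic variable
#'
#' Assigns every angle extremum to a bin of the chosen kinematic variable
#' (its adjacent-pair amplitude or its bout's mean velocity), counts
#' left-sided (angle < 0) and right-sided (angle > 0) extrema per bin, and
#' computes the per-bin asymmetry index.
#'
#' @param dots per-extremum table from [extrema_table()].
#' @param by `"amplitude"` or `"velocity"`.
#' @param n_bins number of bins (default 100).
#' @param value_range binning range; defaults to c(0, 360) for amplitude
#'   and the data range for velocity.
#' @param mode index mode, see [asymmetry_index()].
#' @return `asymmetry_matrix` data.frame: `bin`, `lo`, `hi`, `Xl`, `Xr`,
#'   `index`.
#' @export
binned_asymmetry <- function(dots, by = c("amplitude", "velocity"),
                             n_bins = 100, value_range = NULL,
                             mode = "default") {
  by <- match.arg(by)
  stopifnot(nrow(dots) >= 1)
  val <- dots[[by]]
  keep <- is.finite(val) & dots$theta != 0
  val <- val[keep]; theta <- dots$theta[keep]
  if (is.null(value_range))
    value_range <- if (by == "amplitude") c(0, 360) else range(val)
  edges <- seq(value_range[1], value_range[2], length.out = n_bins + 1L)
  bin <- findInterval(val, edges, rightmost.closed = TRUE, all.inside = TRUE)
  Xl <- tabulate(bin[theta < 0], nbins = n_bins)
  Xr <- tabulate(bin[theta > 0], nbins = n_bins)
  out <- data.frame(bin = seq_len(n_bins), lo = edges[-(n_bins + 1L)],
                    hi = edges[-1], Xl = Xl, Xr = Xr,
                    index = asymmetry_index(Xl, Xr, mode))
  class(out) <- c("asymmetry_matrix", "data.frame")
  out
}

#' Per-segment left/right bias test
#'
#' Divides the session into `n_segments` equal time segments (15 segments
#' of 20 s for a 5-min session), each into `n_subsegments` sub-segments,
#' counts valid frames with the tail left (angle < 0) and right (angle >
#' 0) of the body axis per sub-segment, and compares the two count vectors
#' per segment with a two-tailed Welch t-test. A segment is labelled
#' `"left"` or `"right"` by the ordering of the mean counts when
#' p < alpha, else `"none"`. Frames beyond the last full sub-segment are
#' dropped from the tail end; theta == 0 frames count to neither side.
#'
#' @param angles an `angle_series`.
#' @param n_segments,n_subsegments grid dimensions (defaults 15 x 30).
#' @param alpha significance level (default 0.05).
#' @return `segment_bias` data.frame: `segment`, `mean_left`,
#'   `mean_right`, `p`, `label`, `degenerate` (zero-variance Welch
#'   fallback used), `all_masked`; per-sub-segment counts attached as
#'   attributes `"left_counts"`/`"right_counts"` (segments x
#'   sub-segments).
#' @export
segment_bias_test <- function(angles, n_segments = 15, n_subsegments = 30,
                              alpha = 0.05) {
  stopifnot(inherits(angles, "angle_series"),
            n_segments >= 1, n_subsegments >= 2)
  n <- length(angles$theta)
  per <- n %/% (n_segments * n_subsegments)
  if (per < 1L) stop("session too short for the segment grid")
  use <- per * n_segments * n_subsegments
  sub <- rep(seq_len(n_segments * n_subsegments), each = per)
  left <- angles$valid[1:use] & angles$theta[1:use] < 0
  right <- angles$valid[1:use] & angles$theta[1:use] > 0
  lc <- tapply(left, sub, sum)
  rc <- tapply(right, sub, sum)
  lmat <- matrix(lc, n_segments, n_subsegments, byrow = TRUE)
  rmat <- matrix(rc, n_segments, n_subsegments, byrow = TRUE)
  res <- data.frame(segment = seq_len(n_segments), mean_left = NA_real_,
                    mean_right = NA_real_, p = NA_real_, label = "none",
                    degenerate = FALSE, all_masked = FALSE)
  for (s in seq_len(n_segments)) {
    l <- lmat[s, ]; r <- rmat[s, ]
    if (all(l + r == 0)) {
      res$all_masked[s] <- TRUE
      next
    }
    wt <- welch_test(l, r)
    res$mean_left[s] <- mean(l); res$mean_right[s] <- mean(r)
    res$p[s] <- wt$p; res$degenerate[s] <- wt$degenerate
    if (!is.na(wt$p) && wt$p < alpha)
      res$label[s] <- if (mean(l) > mean(r)) "left" else "right"
  }
  attr(res, "left_counts") <- lmat
  attr(res, "right_counts") <- rmat
  class(res) <- c("segment_bias", "data.frame")
  res
}

#' Day-level bias fractions and day-pair comparisons
#'
#' Pools segment labels over animals to per-day fractions of left-, right-
#' and no-bias segments, and compares every day pair for every label with
#' a Mann-Whitney test across animals (each animal contributes its own
#' label fraction), Holm-Šídák adjusted over the whole family of day-pair
#' x label comparisons at level `alpha`.
#'
#' @param labels data.frame with columns `animal`, `day`, `label` (one row
#'   per session segment; `label` in left/right/none).
#' @param alpha family significance level (default 0.05).
#' @return list with `fractions` (per-day pooled label fractions),
#'   `per_animal` (per animal x day label fractions), and `comparisons`
#'   (day pair x label, raw and adjusted p, significance) — `comparisons`
#'   is NULL with fewer than 2 animals or days.
#' @export
daily_bias_fractions <- function(labels, alpha = 0.05) {
  stopifnot(all(c("animal", "day", "label") %in% names(labels)),
            all(labels$label %in% c("left", "right", "none")))
  days <- sort(unique(labels$day))
  animals <- sort(unique(labels$animal))
  lvls <- c("left", "right", "none")

  frac_of <- function(lab) {
    tab <- table(factor(lab, levels = lvls))
    as.numeric(tab) / length(lab)
  }
  fractions <- do.call(rbind, lapply(days, function(d) {
    f <- frac_of(labels$label[labels$day == d])
    data.frame(day = d, left = f[1], right = f[2], none = f[3])
  }))

  per_animal <- do.call(rbind, lapply(animals, function(a) {
    do.call(rbind, lapply(days, function(d) {
      lab <- labels$label[labels$animal == a & labels$day == d]
      if (!length(lab)) return(NULL)
      f <- frac_of(lab)
      data.frame(animal = a, day = d, left = f[1], right = f[2],
                 none = f[3])
    }))
  }))
  rownames(per_animal) <- NULL

  comparisons <- NULL
  if (length(animals) >= 2L && length(days) >= 2L) {
    pairs <- utils::combn(days, 2L)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      d1 <- pairs[1, k]; d2 <- pairs[2, k]
      do.call(rbind, lapply(lvls, function(lv) {
        x <- per_animal[[lv]][per_animal$day == d1]
        y <- per_animal[[lv]][per_animal$day == d2]
        p <- suppressWarnings(
          wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
        if (is.nan(p)) p <- 1   # all values tied across both days
        data.frame(day_a = d1, day_b = d2, label = lv, p = p)
      }))
    }))
    comparisons$p_adj <- p_adjust_holm_sidak(comparisons$p)
    comparisons$significant <- comparisons$p_adj < alpha
    rownames(comparisons) <- NULL
  }
  list(fractions = fractions, per_animal = per_animal,
       comparisons = comparisons)
}
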