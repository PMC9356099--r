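# Landmark table input. Two CSV dialects are supported:
#   * "flat": one header row, columns time + <landmark>_x/_y/_z and
#     optionally <landmark>_likelihood (what write_landmarks() emits);
#   * "dlc": the three-row pose-estimation header (scorer / bodyparts /
#     coords) with a leading frame-index column, coords x/y/z/likelihood.

#' Read a landmark table
#'
#' @param path CSV file path.
#' @param format_hint `"auto"` (default), `"flat"` or `"dlc"`.
#' @param frame_rate sampling rate in Hz; required to build timestamps for
#'   the DLC dialect (which stores frame indices, not times) and used as
#'   metadata otherwise.
#' @return a `landmark_series`. Missing likelihood columns default to 1.
#' @export
read_landmarks <- function(path, format_hint = c("auto", "flat", "dlc"),
                           frame_rate = 150) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 2L)
  looks_dlc <- grepl("scorer", strsplit(first[1], ",")[[1]][1],
                     ignore.case = TRUE) ||
    any(grepl("bodyparts", first, ignore.case = TRUE))
  fmt <- if (format_hint == "auto") (if (looks_dlc) "dlc" else "flat")
         else format_hint
  if (fmt == "dlc") read_landmarks_dlc(path, frame_rate)
  else read_landmarks_flat(path, frame_rate)
}

canon_landmark <- function(x) {
  x <- gsub("[ .-]", "_", tolower(trimws(x)))
  x[x %in% c("tailtip", "tail_tip", "tail")] <- "tail_tip"
  x
}

read_landmarks_flat <- function(path, frame_rate) {
  df <- read.csv(path, check.names = FALSE)
  names(df) <- canon_landmark(names(df))
  if (!"time" %in% names(df)) stop("flat dialect requires a 'time' column")
  time <- df$time
  if (any(diff(time) <= 0)) stop("timestamps are not strictly increasing")
  n <- nrow(df)
  pos <- list(); lik <- matrix(1, n, 4); colnames(lik) <- LANDMARKS
  for (lm in LANDMARKS) {
    cols <- paste0(lm, "_", c("x", "y", "z"))
    if (!all(cols %in% names(df)))
      stop("malformed header: missing columns for landmark ", lm)
    pos[[lm]] <- as.matrix(df[cols])
    lc <- paste0(lm, "_likelihood")
    if (lc %in% names(df)) lik[, lm] <- df[[lc]]
  }
  landmark_series(time, pos, lik, frame_rate)
}

read_landmarks_dlc <- function(path, frame_rate) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) < 4L) stop("malformed header: DLC table too short")
  bodyparts <- canon_landmark(as.character(unlist(raw[2, -1])))
  coords <- tolower(trimws(as.character(unlist(raw[3, -1]))))
  if (!all(coords %in% c("x", "y", "z", "likelihood")))
    stop("malformed header: unexpected coords row entries")
  dat <- raw[-(1:3), , drop = FALSE]
  vals <- as.matrix(vapply(dat[, -1, drop = FALSE],
                           function(col) as.numeric(col),
                           numeric(nrow(dat))))
  if (nrow(dat) == 1L) vals <- matrix(vals, nrow = 1L)
  n <- nrow(vals)
  pos <- list(); lik <- matrix(1, n, 4); colnames(lik) <- LANDMARKS
  for (lm in LANDMARKS) {
    sel <- function(cc) which(bodyparts == lm & coords == cc)
    ix <- c(sel("x"), sel("y"), sel("z"))
    if (length(ix) != 3L)
      stop("malformed header: missing x/y/z for landmark ", lm)
    pos[[lm]] <- vals[, ix, drop = FALSE]
    il <- sel("likelihood")
    if (length(il) == 1L) lik[, lm] <- vals[, il]
  }
  time <- (seq_len(n) - 1) / frame_rate
  landmark_series(time, pos, lik, frame_rate)
}
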