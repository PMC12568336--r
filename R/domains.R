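#' Insulation score track
#'
#' For every bin, averages the balanced signal in the off-diagonal diamond
#' crossing that bin -- pixels (a, b) with a in [i-w, i-1] and b in
#' [i+1, i+w], where w is the window in bins -- and reports
#' log2(diamond mean / chromosome mean of diamond means). Low scores mark
#' regions that insulate their neighbours from each other, i.e. candidate
#' TAD boundaries. Bins whose diamond does not fit within the chromosome
#' are NA.
#'
#' @param cm A balanced `contact_matrix`.
#' @param window Window size in bp; must be a multiple of the resolution and
#'   at least 2 bins (default 100 kb).
#' @return List of class `insulation_track`: `score` (per-bin log2 insulation,
#'   NA where undefined), `raw` (diamond means), `window`, `resolution`,
#'   `chrom`.
#' @export
insulation <- function(cm, window = 1e5) {
  if (!cm$balanced) stop("matrix must be balanced")
  w <- window / cm$resolution
  if (w != round(w)) stop("window must be a multiple of the resolution")
  w <- as.integer(w)
  if (w < 2) stop("window must span at least 2 bins")
  M <- cm_dense(cm, balanced = TRUE)
  n <- cm$nbins
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- (i - w):(i - 1); b <- (i + 1):(i + w)
    if (a[1] < 1 || b[w] > n) next
    raw[i] <- mean(M[a, b], na.rm = TRUE)
  }
  mu <- mean(raw[raw > 0], na.rm = TRUE)
  score <- ifelse(!is.na(raw) & raw > 0 & !is.na(mu), log2(raw / mu), NA_real_)
  structure(list(score = score, raw = raw, window = window,
                 resolution = cm$resolution, chrom = cm$chrom),
            class = "insulation_track")
}

# indices of strict-or-plateau local minima/maxima of a vector with NAs;
# minima must be interior (a monotone track has none), maxima may sit at the
# ends so that boundary deltas near track edges still have a flank
local_extrema <- function(x, minima = TRUE) {
  if (!minima) x <- -x
  n <- length(x)
  out <- integer()
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    lo <- i - 1; while (lo >= 1 && is.na(x[lo])) lo <- lo - 1
    hi <- i + 1; while (hi <= n && is.na(x[hi])) hi <- hi + 1
    if (minima && (lo < 1 || hi > n)) next
    left_ok <- lo < 1 || x[lo] > x[i]   # strict on the left breaks plateaus
    right_ok <- hi > n || x[hi] >= x[i]
    if (left_ok && right_ok) out <- c(out, i)
  }
  out
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score whose boundary
#' strength (delta) -- the mean of the nearest flanking local maxima minus
#' the minimum value -- reaches `delta_threshold`. Minima within two bins of
#' each other are merged to the deeper one. The top strength quartile is
#' labelled "strong".
#'
#' @param track An `insulation_track`.
#' @param delta_threshold Minimum delta (default 0.05, in log2 insulation
#'   units).
#' @param smooth_bins Width (bins) of a moving average applied to the score
#'   before extremum detection (default 3; 1 disables). Sampling-noise
#'   ripples inside a broad insulation dip otherwise split it into several
#'   shallow minima.
#' @return data.frame of class `boundary_set`: chrom, bin (0-based), start,
#'   end, score (insulation at the minimum), delta, strong.
#' @export
call_boundaries <- function(track, delta_threshold = 0.05, smooth_bins = 3) {
  x <- track$score
  if (smooth_bins > 1) {
    k <- 2 * floor(smooth_bins / 2) + 1
    num <- stats::filter(ifelse(is.na(x), 0, x), rep(1, k), sides = 2)
    den <- stats::filter(as.numeric(!is.na(x)), rep(1, k), sides = 2)
    sm <- as.numeric(num / den)
    x <- ifelse(is.na(x), NA_real_, ifelse(is.na(sm), x, sm))
  }
  mins <- local_extrema(x, minima = TRUE)
  maxs <- local_extrema(x, minima = FALSE)
  empty <- data.frame(chrom = character(), bin = integer(), start = numeric(),
                      end = numeric(), score = numeric(), delta = numeric(),
                      strong = logical())
  class(empty) <- c("boundary_set", "data.frame")
  if (!length(mins) || !length(maxs)) return(empty)
  delta <- vapply(mins, function(i) {
    left <- maxs[maxs < i]; right <- maxs[maxs > i]
    fl <- c(if (length(left)) x[max(left)], if (length(right)) x[min(right)])
    if (!length(fl)) return(NA_real_)
    mean(fl) - x[i]
  }, 1)
  keep <- !is.na(delta) & delta >= delta_threshold
  mins <- mins[keep]; delta <- delta[keep]
  if (!length(mins)) return(empty)
  # merge minima within 2 bins to the deeper one
  o <- order(mins)
  mins <- mins[o]; delta <- delta[o]
  merged_i <- integer(); merged_d <- numeric()
  cur_i <- mins[1]; cur_d <- delta[1]
  for (k in seq_along(mins)[-1]) {
    if (mins[k] - cur_i <= 2) {
      if (x[mins[k]] < x[cur_i]) { cur_i <- mins[k]; cur_d <- delta[k] }
    } else {
      merged_i <- c(merged_i, cur_i); merged_d <- c(merged_d, cur_d)
      cur_i <- mins[k]; cur_d <- delta[k]
    }
  }
  merged_i <- c(merged_i, cur_i); merged_d <- c(merged_d, cur_d)
  # refine each minimum to the center of its valley: broad insulation dips
  # (diamond wider than the boundary) are flat at the bottom, so the raw
  # argmin wanders within the plateau; the valley midpoint is the boundary
  n <- length(x)
  merged_i <- vapply(seq_along(merged_i), function(k) {
    i <- merged_i[k]
    tol <- x[i] + 0.1 * merged_d[k]
    lo <- i; while (lo > 1 && !is.na(x[lo - 1]) && x[lo - 1] <= tol) lo <- lo - 1
    hi <- i; while (hi < n && !is.na(x[hi + 1]) && x[hi + 1] <= tol) hi <- hi + 1
    as.integer(round((lo + hi) / 2))
  }, 1L)
  res <- track$resolution
  out <- data.frame(
    chrom = track$chrom, bin = merged_i - 1L,
    start = (merged_i - 1) * res, end = merged_i * res,
    score = x[merged_i], delta = merged_d,
    strong = merged_d >= stats::quantile(merged_d, 0.75))
  class(out) <- c("boundary_set", "data.frame")
  out
}

#' Average 1D signal pileup at boundaries
#'
#' Extracts windows of a binned 1D signal track centered on boundary
#' midpoints and averages them bin-wise, the standard check that (for
#' example) CTCF is enriched at strong TAD boundaries.
#'
#' @param signal data.frame with chrom, start, end, value: a constant-width
#'   binned signal track (bedGraph-like), non-overlapping and sorted.
#' @param boundaries A `boundary_set`; with `strong_only = TRUE` (default)
#'   only top-quartile boundaries are piled.
#' @param flank Flank on each side of the boundary midpoint, in bp.
#' @param strong_only Restrict to boundaries flagged strong.
#' @return List of class `pileup_profile`: `offset` (bp relative to the
#'   boundary midpoint), `mean_signal`, `n_windows`, `n_skipped` (windows
#'   extending past a chromosome end).
#' @export
boundary_pileup <- function(signal, boundaries, flank = 2e5,
                            strong_only = TRUE) {
  if (strong_only) boundaries <- boundaries[boundaries$strong, , drop = FALSE]
  if (nrow(boundaries) == 0) stop("nothing to pile: empty boundary list")
  bw <- unique(signal$end - signal$start)
  if (length(bw) > 1) bw <- stats::median(signal$end - signal$start)
  nb <- floor(flank / bw)
  offsets <- (-nb:nb) * bw
  acc <- matrix(NA_real_, nrow(boundaries), length(offsets))
  skipped <- 0L
  for (r in seq_len(nrow(boundaries))) {
    ch <- boundaries$chrom[r]
    midpoint <- (boundaries$start[r] + boundaries$end[r]) / 2
    s <- signal[signal$chrom == ch, , drop = FALSE]
    if (!nrow(s)) { skipped <- skipped + 1L; next }
    centers <- midpoint + offsets
    if (min(centers) < min(s$start) || max(centers) >= max(s$end)) {
      skipped <- skipped + 1L
      next
    }
    idx <- findInterval(centers, s$start)
    v <- s$value[idx]
    v[centers >= s$end[idx]] <- 0  # gap in the track
    acc[r, ] <- v
  }
  used <- stats::complete.cases(acc)
  if (!any(used)) stop("all pileup windows skipped (boundaries too close to chromosome ends)")
  structure(list(offset = offsets,
                 mean_signal = colMeans(acc[used, , drop = FALSE]),
                 n_windows = sum(used), n_skipped = skipped),
            class = "pileup_profile")
}
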