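# weighted pool-adjacent-violators: non-increasing fit of y with weights w
pava_nonincreasing <- function(y, w) {
  n <- length(y)
  if (n == 0) return(numeric())
  val <- y; wt <- w; size <- rep(1L, n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
    while (m > 1 && val[m - 1] < val[m]) {
      tot <- wt[m - 1] + wt[m]
      val[m - 1] <- (val[m - 1] * wt[m - 1] + val[m] * wt[m]) / tot
      wt[m - 1] <- tot
      size[m - 1] <- size[m - 1] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], size[seq_len(m)])
}

#' Distance-stratified expected contact model
#'
#' Fits the background expectation for cis contacts at a fixed resolution:
#' bin-pair distances are grouped into (default 100) equal-occupancy strata
#' -- each stratum holding approximately the same number of observed
#' contacts -- and the per-bin-pair contact probability of a stratum is its
#' contact sum divided by (N x possible bin pairs in the stratum), where N
#' is the chromosome's total cis contact count. A weighted monotone
#' (non-increasing) isotonic regression is applied across strata so the
#' expectation decays with distance.
#'
#' @param cm A raw (unbalanced) cis `contact_matrix`.
#' @param n_strata Target number of equal-occupancy distance strata
#'   (default 100); reduced with a warning when there are fewer contacts or
#'   distinct distances.
#' @param min_dist_bins Minimum bin-pair distance tested (default 1 bin:
#'   the diagonal is never part of the model).
#' @return List of class `expected_model`: data.frame `strata` (dist_lo,
#'   dist_hi in bins, n_pairs, count, prob), `prob_at` (function: distance
#'   in bins -> probability), `N` (total cis contacts), `resolution`,
#'   `chrom`.
#' @export
fit_expected <- function(cm, n_strata = 100, min_dist_bins = 1) {
  stopifnot(inherits(cm, "contact_matrix"))
  tri <- cm_triplets(cm)
  tri <- tri[tri$bin2 - tri$bin1 >= min_dist_bins]
  N <- sum(tri$count)
  if (N == 0) stop("no cis contacts to model")
  n <- cm$nbins
  dmax <- n - 1
  d_all <- min_dist_bins:dmax
  obs_d <- rep(0, length(d_all))
  agg <- tri[, .(s = sum(count)), by = .(d = bin2 - bin1)]
  obs_d[match(agg$d, d_all)] <- agg$s
  npairs_d <- n - d_all
  if (N < n_strata) {
    n_strata <- max(1L, as.integer(N))
    warning(sprintf("fewer contacts than strata; reduced to %d strata", n_strata))
  }
  # equal-occupancy split on the cumulative observed counts
  cum <- cumsum(obs_d)
  targets <- seq_len(n_strata - 1) * N / n_strata
  cut_idx <- unique(findInterval(targets, cum) + 1)
  starts <- sort(unique(c(1, cut_idx)))
  starts <- starts[starts <= length(d_all)]
  ends <- c(starts[-1] - 1, length(d_all))
  strata <- data.frame(
    dist_lo = d_all[starts], dist_hi = d_all[ends],
    n_pairs = vapply(seq_along(starts), function(k)
      sum(npairs_d[starts[k]:ends[k]]), 1),
    count = vapply(seq_along(starts), function(k)
      sum(obs_d[starts[k]:ends[k]]), 1))
  strata$prob <- strata$count / (N * strata$n_pairs)
  strata$prob <- pava_nonincreasing(strata$prob, strata$n_pairs)
  lo <- strata$dist_lo
  prob <- strata$prob
  prob_at <- function(d_bins) prob[pmax(1, findInterval(d_bins, lo))]
  structure(list(strata = strata, prob_at = prob_at, N = N,
                 resolution = cm$resolution, chrom = cm$chrom,
                 min_dist_bins = min_dist_bins),
            class = "expected_model")
}

#' Binomial significance of cis interactions
#'
#' Tests every nonzero cis bin pair against the distance-stratified expected
#' model: p is the upper-tail binomial probability of observing at least the
#' observed count among N trials with the stratum's per-bin-pair
#' probability; the expected count is N x probability, O/E the ratio of
#' observed to expected, and q the Benjamini-Hochberg adjustment over the
#' tested set (per chromosome). Midpoints are reported at bin centers.
#'
#' @param cm The raw cis `contact_matrix` the model was fitted on.
#' @param model An `expected_model` from [fit_expected()].
#' @return data.frame of class `interaction_table`: chrom1, mid1, chrom2,
#'   mid2, observed, expected, OE, p, q, plus attribute `resolution`.
#'   Records with expected = 0 and observed > 0 carry `OE = Inf` and are
#'   flagged in the `infinite_enrichment` column.
#' @export
test_interactions <- function(cm, model) {
  stopifnot(inherits(model, "expected_model"))
  if (cm$resolution != model$resolution) stop("resolution mismatch")
  tri <- cm_triplets(cm)
  tri <- tri[tri$bin2 - tri$bin1 >= model$min_dist_bins]
  d <- tri$bin2 - tri$bin1
  prob <- model$prob_at(d)
  expected <- model$N * prob
  p <- stats::pbinom(tri$count - 1, size = model$N, prob = prob,
                     lower.tail = FALSE)
  inf_enr <- expected == 0 & tri$count > 0
  OE <- ifelse(expected > 0, tri$count / expected, Inf)
  res <- cm$resolution
  out <- data.frame(
    chrom1 = cm$chrom, mid1 = tri$bin1 * res + res / 2,
    chrom2 = cm$chrom, mid2 = tri$bin2 * res + res / 2,
    observed = tri$count, expected = expected, OE = OE,
    p = p, q = stats::p.adjust(p, method = "BH"),
    infinite_enrichment = inf_enr)
  out <- out[order(out$p, out$mid1, out$mid2), ]
  rownames(out) <- NULL
  attr(out, "resolution") <- res
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Query an interaction table at a locus pair
#'
#' Returns the tested record(s) whose bin midpoints -- extended by half the
#' resolution on each side -- fall within the two query intervals. An
#' explicit not-found result distinguishes "no contact detected" from a
#' filtered record.
#'
#' @param interactions An `interaction_table`.
#' @param chrom Chromosome of both anchors.
#' @param anchor1,anchor2 Numeric c(start, end) query intervals in bp
#'   (anchor1 upstream of anchor2).
#' @return List of class `locus_query`: `found` (logical), `hits` (the
#'   matching rows; more than one row is flagged `ambiguous`).
#' @export
query_locus <- function(interactions, chrom, anchor1, anchor2) {
  res <- attr(interactions, "resolution")
  h <- res / 2
  in_iv <- function(mid, iv) (mid + h) > iv[1] & (mid - h) < iv[2]
  hit <- interactions$chrom1 == chrom & interactions$chrom2 == chrom &
    in_iv(interactions$mid1, anchor1) & in_iv(interactions$mid2, anchor2)
  hits <- interactions[hit, , drop = FALSE]
  structure(list(found = nrow(hits) > 0, hits = hits,
                 ambiguous = nrow(hits) > 1),
            class = "locus_query")
}

#' Rank trans contacts and summarize per-chromosome-pair intensity
#'
#' Extracts the top k inter-chromosomal bin pairs by raw contact count (ties
#' broken by (chrom1, bin1, chrom2, bin2) order) and the chromosome-pair
#' matrix of mean contact count over all bin pairs of each chromosome pair.
#'
#' @param cset A `contact_set` with trans matrices.
#' @param k Number of top contacts (default 500); when fewer nonzero trans
#'   bin pairs exist, all are returned with a warning.
#' @return List of class `trans_ranking`: `top` (data.frame chrom1, bin1,
#'   start1, chrom2, bin2, start2, count) and `pair_means` (named matrix).
#' @export
rank_trans <- function(cset, k = 500) {
  chroms <- names(cset$cis)
  pm <- matrix(0, length(chroms), length(chroms),
               dimnames = list(chroms, chroms))
  rows <- list()
  for (key in names(cset$trans)) {
    cc <- strsplit(key, "|", fixed = TRUE)[[1]]
    m <- cset$trans[[key]]
    pm[cc[1], cc[2]] <- pm[cc[2], cc[1]] <- sum(m@x) / (nrow(m) * ncol(m))
    t <- methods::as(m, "TsparseMatrix")
    if (length(t@x))
      rows[[key]] <- data.table::data.table(
        chrom1 = cc[1], bin1 = t@i, chrom2 = cc[2], bin2 = t@j, count = t@x)
  }
  top <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(chrom1 = character(), bin1 = integer(),
                           chrom2 = character(), bin2 = integer(),
                           count = numeric())
  if (nrow(top) < k && nrow(top) > 0)
    warning(sprintf("only %d nonzero trans bin pairs (< k = %d)", nrow(top), k))
  ord <- stats::setNames(seq_along(chroms), chroms)
  top <- top[order(-top$count, ord[top$chrom1], top$bin1,
                   ord[top$chrom2], top$bin2)]
  top <- top[seq_len(min(k, nrow(top)))]
  res <- cset$resolution
  top[, `:=`(start1 = bin1 * res, start2 = bin2 * res)]
  structure(list(top = top[], pair_means = pm), class = "trans_ranking")
}
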