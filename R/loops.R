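#' Call chromatin loops by local-neighborhood enrichment
#'
#' A deterministic dot caller in the HiCCUPS tradition: a candidate pixel is
#' a local maximum of the raw cis contact map whose observed count exceeds
#' the expectation of each of four local neighborhoods -- donut (radius 5
#' bins, inner exclusion 2 bins), lower-left quadrant, horizontal and
#' vertical bands. Every neighborhood expectation is distance-corrected:
#' E_k = (sum of observed in the neighborhood / sum of the distance-decay
#' expectation there) x decay expectation at the pixel's distance. The
#' p-value is the upper-tail Poisson probability of the observed count under
#' the largest neighborhood expectation, q the Benjamini-Hochberg adjustment
#' over all candidates, and calls within 2 bins of a stronger call are
#' merged into it. Only pixels with distance in [2 bins, `max_dist`] are
#' tested; the matrix must be balanced so that low-coverage bins are masked.
#'
#' @param cm A balanced `contact_matrix` (5 or 10 kb resolution in typical
#'   use). Raw counts drive the Poisson model; the balancing mask excludes
#'   unreliable bins.
#' @param q_threshold FDR threshold in (0, 1) (default 0.1).
#' @param donut_radius,donut_inner Donut outer radius and inner exclusion in
#'   bins (defaults 5 and 2).
#' @param max_dist Maximum anchor separation tested, bp (default 10 Mb).
#' @param min_count Minimum raw count for a candidate pixel (default 2).
#' @return data.frame of class `loop_calls`: chrom, start1, end1, start2,
#'   end2 (anchor bins, 0-based half-open), bin1, bin2, distance (midpoint
#'   to midpoint), observed, exp_donut, exp_ll, exp_h, exp_v, p, q --
#'   filtered to q < `q_threshold` and sorted by q.
#' @export
call_loops <- function(cm, q_threshold = 0.1, donut_radius = 5,
                       donut_inner = 2, max_dist = 1e7, min_count = 2) {
  if (!cm$balanced) stop("matrix must be balanced before loop calling")
  if (q_threshold <= 0 || q_threshold >= 1) stop("q_threshold must be in (0,1)")
  n <- cm$nbins
  res <- cm$resolution
  r <- donut_radius; ri <- donut_inner
  if (n <= 2 * r + 1) {
    warning(sprintf("%s shorter than the donut; skipped", cm$chrom))
    return(empty_loops())
  }
  M <- as.matrix(cm$counts)
  M <- M + t(M) - diag(diag(M), n)
  # distance-decay expectation per diagonal (mean count at that distance)
  decay <- vapply(0:(n - 1), function(d)
    mean(M[cbind(seq_len(n - d), seq_len(n - d) + d)]), 1)
  D <- matrix(decay[abs(outer(seq_len(n), seq_len(n), "-")) + 1], n, n)

  maxd_bins <- floor(max_dist / res)
  tri <- cm_triplets(cm)
  tri <- tri[tri$count >= min_count &
             (tri$bin2 - tri$bin1) >= 2 &
             (tri$bin2 - tri$bin1) <= maxd_bins &
             !cm$mask[tri$bin1 + 1] & !cm$mask[tri$bin2 + 1]]
  if (nrow(tri) == 0) return(empty_loops())

  # neighborhood offset masks (relative row/col offsets)
  grid <- expand.grid(dr = -r:r, dc = -r:r)
  ring <- grid[pmax(abs(grid$dr), abs(grid$dc)) > ri &
               pmax(abs(grid$dr), abs(grid$dc)) <= r, ]
  donut <- ring[!(ring$dr == 0 | ring$dc == 0), ]       # exclude the cross
  ll <- ring[ring$dr > 0 & ring$dc < 0, ]               # lower-left quadrant
  hband <- ring[ring$dr == 0, ]
  vband <- ring[ring$dc == 0, ]
  nb <- list(donut = donut, ll = ll, h = hband, v = vband)

  i <- tri$bin1 + 1; j <- tri$bin2 + 1
  inside <- i - r >= 1 & j + r <= n & i + r <= n & j - r >= 1
  tri <- tri[inside]; i <- i[inside]; j <- j[inside]
  if (nrow(tri) == 0) return(empty_loops())

  exp_k <- function(off) {
    s_obs <- s_exp <- rep(0, length(i))
    for (q in seq_len(nrow(off))) {
      ii <- i + off$dr[q]; jj <- j + off$dc[q]
      s_obs <- s_obs + M[cbind(ii, jj)]
      s_exp <- s_exp + D[cbind(ii, jj)]
    }
    ifelse(s_exp > 0, s_obs / s_exp, 0) * D[cbind(i, j)]
  }
  E <- vapply(nb, exp_k, numeric(length(i)))
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)

  # local maximum within the inner exclusion square and above each expectation
  is_locmax <- vapply(seq_along(i), function(k) {
    win <- M[(i[k] - ri):(i[k] + ri), (j[k] - ri):(j[k] + ri)]
    M[i[k], j[k]] >= max(win)
  }, TRUE)
  lambda <- apply(E, 1, max)
  cand <- is_locmax & tri$count > lambda & lambda > 0
  if (!any(cand)) return(empty_loops())
  tri <- tri[cand]; E <- E[cand, , drop = FALSE]; lambda <- lambda[cand]

  p <- stats::ppois(tri$count - 1, lambda, lower.tail = FALSE)
  # BH over the full tested universe: every unmasked pixel in the distance
  # band counts toward m, not only the enumerated candidates (whose p-values
  # are the smallest); skipped pixels contribute p ~ 1
  m_total <- sum(vapply(2:min(maxd_bins, n - 1), function(d)
    sum(!cm$mask[seq_len(n - d)] & !cm$mask[seq_len(n - d) + d]), 1))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m_total / seq_along(o)))))
  q <- numeric(length(p)); q[o] <- q_sorted
  out <- data.frame(
    chrom = cm$chrom,
    bin1 = tri$bin1, bin2 = tri$bin2,
    start1 = tri$bin1 * res, end1 = (tri$bin1 + 1) * res,
    start2 = tri$bin2 * res, end2 = (tri$bin2 + 1) * res,
    distance = (tri$bin2 - tri$bin1) * res,
    observed = tri$count,
    exp_donut = E[, "donut"], exp_ll = E[, "ll"],
    exp_h = E[, "h"], exp_v = E[, "v"],
    p = p, q = q)
  out <- out[out$q < q_threshold, , drop = FALSE]
  out <- out[order(out$p, out$bin1, out$bin2), ]
  # merge calls within 2 bins to the strongest (earlier = stronger)
  keep <- rep(TRUE, nrow(out))
  for (k in seq_len(nrow(out))) {
    if (!keep[k]) next
    close <- keep & abs(out$bin1 - out$bin1[k]) <= 2 &
      abs(out$bin2 - out$bin2[k]) <= 2
    close[seq_len(k)] <- FALSE
    keep[close] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "resolution") <- res
  class(out) <- c("loop_calls", "data.frame")
  out
}

empty_loops <- function() {
  out <- data.frame(chrom = character(), bin1 = integer(), bin2 = integer(),
                    start1 = numeric(), end1 = numeric(), start2 = numeric(),
                    end2 = numeric(), distance = numeric(), observed = numeric(),
                    exp_donut = numeric(), exp_ll = numeric(), exp_h = numeric(),
                    exp_v = numeric(), p = numeric(), q = numeric())
  class(out) <- c("loop_calls", "data.frame")
  out
}

#' Call loops on every chromosome of a contact set
#' @param cset A balanced `contact_set`.
#' @param ... Passed to [call_loops()].
#' @return Combined `loop_calls` across chromosomes.
#' @export
call_loops_all <- function(cset, ...) {
  parts <- lapply(cset$cis, call_loops, ...)
  out <- do.call(rbind, c(parts, make.row.names = FALSE))
  attr(out, "resolution") <- cset$resolution
  class(out) <- c("loop_calls", "data.frame")
  out
}

#' Loop distance histogram (six categories)
#'
#' Groups loop anchor separations into the six standard categories:
#' <200 kb, 200-400 kb, 400-600 kb, 600-800 kb, 800 kb-1 Mb, and >1 Mb.
#' Boundaries are lower-inclusive/upper-exclusive except the final category,
#' which is strictly greater than 1 Mb (so exactly 1 Mb falls in
#' "800 kb-1 Mb").
#'
#' @param loops A `loop_calls` data.frame (uses the `distance` column).
#' @return data.frame: category, count, fraction (0 when there are no loops).
#' @export
distance_histogram <- function(loops) {
  labels <- c("<200 kb", "200-400 kb", "400-600 kb", "600-800 kb",
              "800 kb-1 Mb", ">1 Mb")
  d <- loops$distance
  idx <- as.integer(ifelse(d < 2e5, 1L, ifelse(d < 4e5, 2L, ifelse(d < 6e5, 3L,
         ifelse(d < 8e5, 4L, ifelse(d <= 1e6, 5L, 6L))))))
  counts <- tabulate(idx, nbins = 6)
  data.frame(category = factor(labels, levels = labels), count = counts,
             fraction = if (sum(counts) > 0) counts / sum(counts) else
               rep(0, 6))
}

# unique anchors of a loop set as a BED-style data.frame (0-based half-open)
loop_anchors <- function(loops) {
  a <- rbind(
    data.frame(chrom = loops$chrom, start = loops$start1, end = loops$end1),
    data.frame(chrom = loops$chrom, start = loops$start2, end = loops$end2))
  unique(a)
}

# >= 1 bp overlap of BED-style intervals (both 0-based half-open)
overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  gx <- bed_to_granges(x)
  gy <- bed_to_granges(y)
  IRanges::overlapsAny(gx, gy, ignore.strand = TRUE)
}

#' Annotate loop anchors with accessibility and histone marks
#'
#' An anchor is accessible iff it overlaps at least one ATAC peak by >= 1 bp
#' (half-open intervals); each chromatin mark is flagged the same way.
#' Accessible anchors are classified by their H3K4me1/H3K4me3 status into
#' `me1_only`, `me3_only`, `both` or `neither`, and the class summary
#' reports counts with percentages of accessible anchors at one-decimal
#' rounding.
#'
#' @param loops A `loop_calls` data.frame.
#' @param atac BED-style data.frame of ATAC peaks (chrom, start, end;
#'   0-based half-open).
#' @param marks Named list of BED-style data.frames; recognized names:
#'   `H3K4me1`, `H3K4me3`, `H3K27ac`, `CTCF` (any subset).
#' @return List of class `anchor_annotation`: `anchors` (data.frame with
#'   accessible flag, one logical column per mark, and `class` for
#'   accessible anchors), `summary` (class, count, percent of accessible).
#' @export
annotate_anchors <- function(loops, atac, marks = list()) {
  anchors <- loop_anchors(loops)
  anchors$accessible <- overlaps_any(anchors, atac)
  for (mk in names(marks))
    anchors[[mk]] <- overlaps_any(anchors[, c("chrom", "start", "end")],
                                  marks[[mk]])
  me1 <- if ("H3K4me1" %in% names(marks)) anchors$H3K4me1 else
    rep(FALSE, nrow(anchors))
  me3 <- if ("H3K4me3" %in% names(marks)) anchors$H3K4me3 else
    rep(FALSE, nrow(anchors))
  cls <- ifelse(me1 & me3, "both", ifelse(me1, "me1_only",
         ifelse(me3, "me3_only", "neither")))
  cls[!anchors$accessible] <- NA  # class defined for accessible anchors only
  anchors$class <- cls
  acc <- anchors[anchors$accessible, , drop = FALSE]
  summary <- anchor_class_summary(table(factor(
    acc$class, levels = c("me1_only", "me3_only", "both", "neither"))),
    total = nrow(acc))
  structure(list(anchors = anchors, summary = summary),
            class = "anchor_annotation")
}

#' Anchor class percentage summary
#'
#' Converts per-class counts of accessible loop anchors into the reported
#' count + percentage table, with percentages of the accessible total
#' rounded to one decimal.
#'
#' @param counts Named numeric vector of per-class counts.
#' @param total Total accessible anchors (the percentage basis).
#' @return data.frame: class, count, percent.
#' @export
anchor_class_summary <- function(counts, total) {
  data.frame(class = names(counts), count = as.numeric(counts),
             percent = if (total > 0)
               round(100 * as.numeric(counts) / total, 1) else
               rep(0, length(counts)),
             row.names = NULL)
}

#' Overlap loops with structural deletions
#'
#' Reports, for every loop, the deletion intervals intersecting either
#' anchor by >= 1 bp (half-open), deduplicated per loop (a deletion spanning
#' both anchors is reported once), and the reverse map from each deletion to
#' its hit loops.
#'
#' @param loops A `loop_calls` data.frame.
#' @param deletions BED-style data.frame (chrom, start, end, name).
#' @return List of class `variant_overlap`: `by_loop` (data.frame loop_index,
#'   deletion name/coords, which anchor(s) hit) and `by_deletion` (named
#'   list of loop indices).
#' @export
overlap_variants <- function(loops, deletions) {
  if (is.null(deletions$name)) deletions$name <- sprintf("del%03d", seq_len(nrow(deletions)))
  rows <- list()
  if (nrow(loops) > 0 && nrow(deletions) > 0) {
    a1 <- data.frame(chrom = loops$chrom, start = loops$start1, end = loops$end1)
    a2 <- data.frame(chrom = loops$chrom, start = loops$start2, end = loops$end2)
    g1 <- bed_to_granges(a1); g2 <- bed_to_granges(a2)
    gd <- bed_to_granges(deletions)
    h1 <- GenomicRanges::findOverlaps(g1, gd, ignore.strand = TRUE)
    h2 <- GenomicRanges::findOverlaps(g2, gd, ignore.strand = TRUE)
    q1 <- S4Vectors::queryHits(h1); q2 <- S4Vectors::queryHits(h2)
    hits <- unique(rbind(
      data.frame(loop = q1, del = S4Vectors::subjectHits(h1),
                 anchor = rep(1L, length(q1))),
      data.frame(loop = q2, del = S4Vectors::subjectHits(h2),
                 anchor = rep(2L, length(q2)))))
    if (nrow(hits)) {
      agg <- stats::aggregate(anchor ~ loop + del, data = hits,
                              FUN = function(a) paste(sort(unique(a)), collapse = ","))
      rows <- data.frame(
        loop_index = agg$loop,
        deletion = deletions$name[agg$del],
        del_chrom = deletions$chrom[agg$del],
        del_start = deletions$start[agg$del],
        del_end = deletions$end[agg$del],
        anchors_hit = agg$anchor)
    }
  }
  by_loop <- if (is.data.frame(rows)) rows[order(rows$loop_index), ] else
    data.frame(loop_index = integer(), deletion = character(),
               del_chrom = character(), del_start = numeric(),
               del_end = numeric(), anchors_hit = character())
  rownames(by_loop) <- NULL
  by_del <- split(by_loop$loop_index, by_loop$deletion)
  structure(list(by_loop = by_loop, by_deletion = by_del),
            class = "variant_overlap")
}
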