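#' Contact matrix constructor
#'
#' A binned, sparse, upper-triangular cis contact matrix at a fixed
#' resolution, optionally carrying ICE balancing weights and a per-bin mask.
#'
#' @param counts Upper-triangular `dgCMatrix` (or coercible sparse matrix).
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @return Object of class `contact_matrix`.
#' @keywords internal
contact_matrix <- function(counts, chrom, resolution) {
  counts <- methods::as(counts, "CsparseMatrix")
  structure(list(counts = counts, chrom = chrom,
                 resolution = as.numeric(resolution),
                 nbins = nrow(counts),
                 weights = NULL, mask = rep(FALSE, nrow(counts)),
                 balanced = FALSE),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix %s: %d bins @ %g bp, %.0f contacts%s\n",
              x$chrom, x$nbins, x$resolution, sum(x$counts@x),
              if (x$balanced) ", balanced" else ""))
  invisible(x)
}

# sparse triplets (0-based bins) of the upper triangle
cm_triplets <- function(cm) {
  t <- methods::as(cm$counts, "TsparseMatrix")
  data.table::data.table(bin1 = t@i, bin2 = t@j, count = t@x)
}

# dense symmetric (optionally balanced) matrix; masked bins set to NA
cm_dense <- function(cm, balanced = FALSE) {
  M <- as.matrix(cm$counts)
  M <- M + t(M) - diag(diag(M), nrow(M))
  if (balanced) {
    if (!cm$balanced) stop("matrix is not balanced; run balance() first")
    w <- cm$weights
    M <- M * outer(w, w)
  }
  M[cm$mask, ] <- NA
  M[, cm$mask] <- NA
  M
}

#' Bin valid pairs into contact matrices
#'
#' Bins each valid record (per the classification contract: trans, or cis
#' with separation >= 1 kb, deduplicated and mapped) into fixed-width bins
#' with the cooler convention: bin i covers the 0-based half-open interval
#' [i*res, (i+1)*res), so a 1-based position p falls in bin
#' floor((p-1)/res). Cis counts are stored once in the upper triangle; trans
#' counts per ordered chromosome pair.
#'
#' @param records Classified `pair_records` (a `valid` column is used when
#'   present; otherwise all records are binned).
#' @param genome A `genome_spec`.
#' @param resolution Bin size in bp (> 0).
#' @return Object of class `contact_set`: list with `cis` (named list of
#'   `contact_matrix`), `trans` (named list `"chrA|chrB"` of sparse
#'   matrices), `resolution`, `genome`, `n_valid`, `n_cis`, `n_trans`.
#' @export
bin_pairs <- function(records, genome, resolution) {
  if (resolution <= 0) stop("resolution must be > 0")
  rec <- data.table::as.data.table(records)
  if ("valid" %in% names(rec)) rec <- rec[rec$valid == TRUE]
  chroms <- analysis_chroms(genome)
  lens <- genome$lengths[chroms]
  nbins <- stats::setNames(as.integer(ceiling(lens / resolution)), chroms)
  rec[, `:=`(b1 = floor((pos1 - 1) / resolution),
             b2 = floor((pos2 - 1) / resolution))]

  cis <- list()
  for (ch in chroms) {
    x <- rec[rec$chrom1 == ch & rec$chrom2 == ch]
    agg <- if (nrow(x)) x[, .N, by = .(b1, b2)] else
      data.table::data.table(b1 = integer(), b2 = integer(), N = integer())
    counts <- Matrix::sparseMatrix(i = agg$b1 + 1, j = agg$b2 + 1, x = agg$N,
                                   dims = c(nbins[ch], nbins[ch]))
    cis[[ch]] <- contact_matrix(counts, ch, resolution)
  }

  trans <- list()
  tr <- rec[rec$chrom1 != rec$chrom2]
  if (nrow(tr)) {
    tr[, key := paste(chrom1, chrom2, sep = "|")]
    for (k in unique(tr$key)) {
      x <- tr[tr$key == k]
      cc <- strsplit(k, "|", fixed = TRUE)[[1]]
      agg <- x[, .N, by = .(b1, b2)]
      trans[[k]] <- Matrix::sparseMatrix(
        i = agg$b1 + 1, j = agg$b2 + 1, x = agg$N,
        dims = c(nbins[cc[1]], nbins[cc[2]]))
    }
  }

  structure(list(cis = cis, trans = trans, resolution = resolution,
                 genome = genome, n_valid = nrow(rec),
                 n_cis = nrow(rec) - nrow(tr), n_trans = nrow(tr)),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set: %d chromosome(s) @ %g bp, %d valid pairs (%d cis / %d trans)\n",
              length(x$cis), x$resolution, x$n_valid, x$n_cis, x$n_trans))
  invisible(x)
}

#' ICE balancing (iterative proportional fitting)
#'
#' Computes multiplicative per-bin weights so that the balanced matrix
#' `counts[i,j] * w[i] * w[j]` has uniform marginals on unmasked bins.
#' Bins with zero coverage, or coverage below the `mask_quantile` percentile,
#' are masked and receive NA weights. Raw counts are preserved.
#'
#' @param cm A cis `contact_matrix`.
#' @param tol Convergence tolerance on the maximum relative marginal
#'   deviation (default 1e-5).
#' @param max_iter Maximum iterations (default 200); non-convergence emits a
#'   warning and flags the partial weights.
#' @param mask_quantile Coverage percentile below which bins are masked
#'   (default 0.02).
#' @return The `contact_matrix` with `weights`, `mask`, `balanced = TRUE`,
#'   and attributes `iterations`/`converged` in `$ice`.
#' @export
balance <- function(cm, tol = 1e-5, max_iter = 200, mask_quantile = 0.02) {
  stopifnot(inherits(cm, "contact_matrix"))
  S <- cm$counts + Matrix::t(cm$counts)
  Matrix::diag(S) <- Matrix::diag(cm$counts)
  cov <- Matrix::rowSums(S)
  mask <- cov == 0
  if (any(!mask)) {
    thr <- stats::quantile(cov[!mask], mask_quantile)
    mask <- mask | cov < thr
  }
  n <- cm$nbins
  b <- rep(1, n)
  b[mask] <- NA
  converged <- FALSE
  iter <- 0L
  idx <- which(!mask)
  if (length(idx)) {
    for (iter in seq_len(max_iter)) {
      binv <- ifelse(is.na(b), 0, 1 / b)
      m <- as.numeric(Matrix::Diagonal(n, x = binv) %*% S %*% binv)
      rel <- m[idx] / mean(m[idx])
      b[idx] <- b[idx] * rel
      if (max(abs(rel - 1)) < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning(sprintf("ICE did not converge in %d iterations; weights are partial",
                      max_iter))
  }
  # scale weights so the balanced matrix preserves total mass
  w <- 1 / b
  bal_tot <- sum(cm_triplets(cm)[, count * w[bin1 + 1] * w[bin2 + 1]], na.rm = TRUE)
  raw_tot <- sum(cm$counts@x[!is.na(cm$counts@x)])
  if (bal_tot > 0) w <- w * sqrt(raw_tot / bal_tot)
  cm$weights <- w
  cm$mask <- mask
  cm$balanced <- TRUE
  cm$ice <- list(iterations = iter, converged = converged)
  cm
}

#' Balance every cis matrix in a contact set
#' @param cset A `contact_set`.
#' @param ... Passed to [balance()].
#' @return The set with balanced cis matrices.
#' @export
balance_all <- function(cset, ...) {
  cset$cis <- lapply(cset$cis, balance, ...)
  cset
}

#' Per-bin cis and total coverage
#'
#' Sums, for every genomic bin, the contacts with sides in that bin,
#' separately for cis and for all (cis + trans) contacts, and reports the
#' cis/total ratio. The genome-wide mean ratio (over covered bins) mirrors
#' the cis-to-total coverage QC statistic.
#'
#' @param cset A `contact_set` with both cis and trans matrices.
#' @return List: `track` (data.table chrom, bin, start, end, cis, total,
#'   ratio; ratio NA where total = 0) and `mean_ratio`.
#' @export
coverage <- function(cset) {
  res <- cset$resolution
  rows <- list()
  for (ch in names(cset$cis)) {
    cm <- cset$cis[[ch]]
    S <- cm$counts + Matrix::t(cm$counts)
    Matrix::diag(S) <- Matrix::diag(cm$counts)
    cis_cov <- Matrix::rowSums(S)
    tot <- cis_cov
    for (k in names(cset$trans)) {
      cc <- strsplit(k, "|", fixed = TRUE)[[1]]
      if (cc[1] == ch) tot <- tot + Matrix::rowSums(cset$trans[[k]])
      if (cc[2] == ch) tot <- tot + Matrix::colSums(cset$trans[[k]])
    }
    start <- (seq_len(cm$nbins) - 1) * res
    rows[[ch]] <- data.table::data.table(
      chrom = ch, bin = seq_len(cm$nbins) - 1L, start = start,
      end = pmin(start + res, cset$genome$lengths[ch]),
      cis = cis_cov, total = tot,
      ratio = ifelse(tot > 0, cis_cov / tot, NA_real_))
  }
  track <- data.table::rbindlist(rows)
  list(track = track[], mean_ratio = mean(track$ratio, na.rm = TRUE))
}

#' Contact-probability decay curve P(s)
#'
#' Pools cis contacts into log-spaced distance bins (default 8 per decade)
#' and reports, per bin, the mean contact probability per bin pair:
#' (contacts in the distance bin) / (total cis contacts x possible bin pairs
#' at those distances). With this normalization the probabilities integrate
#' to unit cis mass: sum over bins of probability x bin-pair count = 1.
#' Curves are returned per chromosome and pooled ("all").
#'
#' @param cset A `contact_set`.
#' @param bins_per_decade Log-spaced distance bins per decade (default 8).
#' @param smooth Width (in bins) of an optional log-space moving average
#'   applied to the probabilities; 0 (default) disables smoothing.
#' @return data.table with chrom, dist_lo, dist_hi, dist_mid (geometric
#'   mean), n_pairs (possible bin pairs), count, prob. Chromosomes shorter
#'   than two bins are skipped with a warning.
#' @export
contact_decay <- function(cset, bins_per_decade = 8, smooth = 0) {
  res <- cset$resolution
  per_chrom <- list()
  maxd <- max(vapply(cset$cis, function(cm) cm$nbins, 1)) * res
  edges <- 10^(seq(log10(res), log10(maxd) + 1 / bins_per_decade,
                   by = 1 / bins_per_decade))
  for (ch in names(cset$cis)) {
    cm <- cset$cis[[ch]]
    if (cm$nbins < 2) {
      warning(sprintf("%s shorter than 2 bins; skipped", ch))
      next
    }
    tri <- cm_triplets(cm)
    tri <- tri[tri$bin2 > tri$bin1]
    d <- (tri$bin2 - tri$bin1) * res
    ib <- findInterval(d, edges)
    cnt <- tapply(tri$count, factor(ib, levels = seq_along(edges)), sum)
    cnt[is.na(cnt)] <- 0
    # possible bin pairs per distance bin: sum over distances of (nbins - d)
    dd <- seq_len(cm$nbins - 1) * res
    ibd <- findInterval(dd, edges)
    npairs <- tapply(cm$nbins - seq_len(cm$nbins - 1),
                     factor(ibd, levels = seq_along(edges)), sum)
    npairs[is.na(npairs)] <- 0
    per_chrom[[ch]] <- data.table::data.table(
      chrom = ch, bin = seq_along(edges), dist_lo = edges,
      dist_hi = c(edges[-1], edges[length(edges)] * 10^(1 / bins_per_decade)),
      count = as.numeric(cnt), n_pairs = as.numeric(npairs))
  }
  if (!length(per_chrom)) stop("no usable chromosomes")
  all <- data.table::rbindlist(per_chrom)[
    , .(chrom = "all", count = sum(count), n_pairs = sum(n_pairs)),
    by = .(bin, dist_lo, dist_hi)]
  curve <- data.table::rbindlist(list(data.table::rbindlist(per_chrom), all),
                                 use.names = TRUE, fill = TRUE)
  total <- stats::setNames(
    c(vapply(per_chrom, function(x) sum(x$count), 1), all = sum(all$count)),
    c(names(per_chrom), "all"))
  curve[, prob := ifelse(n_pairs > 0, count / (total[chrom] * n_pairs), NA_real_)]
  curve[, dist_mid := sqrt(dist_lo * dist_hi)]
  if (smooth > 0) {
    k <- 2 * floor(smooth / 2) + 1  # odd window
    curve[, prob := {
      p <- prob
      sm <- stats::filter(ifelse(is.na(p), 0, p), rep(1 / k, k), sides = 2)
      wt <- stats::filter(as.numeric(!is.na(p)), rep(1 / k, k), sides = 2)
      ifelse(!is.na(p) & wt > 0, as.numeric(sm / wt), p)
    }, by = chrom]
  }
  curve[]
}

#' Fit the power-law decay exponent from a P(s) curve
#'
#' Log-log regression of probability on distance over a distance window.
#'
#' @param curve Output of [contact_decay()].
#' @param chrom Which curve to fit (default "all").
#' @param range Distance window in bp (default 30 kb - 3 Mb).
#' @return The fitted slope (so a generator exponent alpha appears as
#'   approximately -alpha).
#' @export
fit_decay_slope <- function(curve, chrom = "all", range = c(3e4, 3e6)) {
  x <- curve[curve$chrom == chrom & !is.na(curve$prob) & curve$prob > 0 &
               curve$dist_mid >= range[1] & curve$dist_mid <= range[2], ]
  if (nrow(x) < 3) stop("too few decay bins in the fit range")
  unname(stats::coef(stats::lm(log10(prob) ~ log10(dist_mid), data = x))[2])
}

#' Fixed-bin genome-wide view
#'
#' Aggregates every chromosome to exactly `n_bins` equal-sized coarse bins
#' regardless of its length (native bin b maps to coarse bin
#' floor(b * n_bins / nbins)), then assembles the genome-wide matrix
#' including trans blocks on the same grid. Contact mass is conserved.
#'
#' @param cset A `contact_set`.
#' @param n_bins Coarse bins per chromosome (default 100).
#' @return List: `matrix` (dense (n_bins x n_chroms)^2, upper-triangle
#'   symmetric-completed), `chroms`, `n_bins`.
#' @export
fixed_bin_view <- function(cset, n_bins = 100) {
  chroms <- names(cset$cis)
  nc <- length(chroms)
  M <- matrix(0, n_bins * nc, n_bins * nc)
  offs <- stats::setNames((seq_len(nc) - 1) * n_bins, chroms)
  coarse <- function(b, nb) pmin(floor(b * n_bins / nb), n_bins - 1)
  add_counts <- function(i, j, x) {
    agg <- rowsum(x, group = (j - 1) * nrow(M) + i)
    idx <- as.numeric(rownames(agg))
    M[idx] <<- M[idx] + agg[, 1]
  }
  for (ch in chroms) {
    cm <- cset$cis[[ch]]
    if (cm$nbins < n_bins)
      warning(sprintf("%s has %d native bins < %d coarse bins", ch, cm$nbins, n_bins))
    tri <- cm_triplets(cm)
    if (nrow(tri))
      add_counts(coarse(tri$bin1, cm$nbins) + offs[ch] + 1,
                 coarse(tri$bin2, cm$nbins) + offs[ch] + 1, tri$count)
  }
  for (k in names(cset$trans)) {
    cc <- strsplit(k, "|", fixed = TRUE)[[1]]
    t <- methods::as(cset$trans[[k]], "TsparseMatrix")
    if (length(t@x))
      add_counts(coarse(t@i, nrow(t)) + offs[cc[1]] + 1,
                 coarse(t@j, ncol(t)) + offs[cc[2]] + 1, t@x)
  }
  M <- M + t(M) - diag(diag(M), nrow(M))
  list(matrix = M, chroms = chroms, n_bins = n_bins)
}

#' Pearson correlation between replicate contact matrices
#'
#' Correlates two contact sets over the union of nonzero cis bin pairs
#' within a distance cap, after a log(1 + x) transform of raw counts. The
#' cap prevents the near-diagonal signal from dominating the coefficient.
#'
#' @param a,b `contact_set`s on the same genome and resolution.
#' @param max_dist Distance cap in bp (default 5 Mb).
#' @return Pearson r; NA (with a warning) when the supports are disjoint.
#' @export
correlate_replicates <- function(a, b, max_dist = 5e6) {
  if (a$resolution != b$resolution) stop("resolutions differ")
  xs <- ys <- list()
  for (ch in intersect(names(a$cis), names(b$cis))) {
    ta <- cm_triplets(a$cis[[ch]]); tb <- cm_triplets(b$cis[[ch]])
    res <- a$resolution
    ta <- ta[(ta$bin2 - ta$bin1) * res <= max_dist]
    tb <- tb[(tb$bin2 - tb$bin1) * res <= max_dist]
    merged <- merge(ta, tb, by = c("bin1", "bin2"), all = TRUE,
                    suffixes = c("_a", "_b"))
    xs[[ch]] <- ifelse(is.na(merged$count_a), 0, merged$count_a)
    ys[[ch]] <- ifelse(is.na(merged$count_b), 0, merged$count_b)
  }
  x <- unlist(xs); y <- unlist(ys)
  if (!length(x)) {
    warning("disjoint or empty supports; correlation undefined")
    return(NA_real_)
  }
  stats::cor(log1p(x), log1p(y))
}
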