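#' Build promoter intervals from TSS and ATAC peaks
#'
#' For every TSS record: if the TSS position overlaps at least one ATAC
#' peak, the promoter takes the union (min start to max end) of the
#' overlapping peak coordinates; otherwise it is the strand-aware window
#' [TSS - upstream, TSS + downstream) on the + strand and
#' [TSS - downstream, TSS + upstream) on the - strand, clipped to the
#' chromosome bounds. All coordinates are 0-based half-open.
#'
#' @param tss BED-style data.frame (chrom, start, end, name = gene symbol,
#'   strand); the TSS position is the `start` coordinate. Records with a
#'   missing strand are treated as "+" with a warning; a TSS beyond the
#'   chromosome end is rejected.
#' @param peaks BED-style data.frame of ATAC peaks, or NULL for none.
#' @param upstream,downstream Window sizes in bp (defaults 2000 and 500).
#' @param genome Optional `genome_spec` for end clipping.
#' @return data.frame of class `promoter_set`: chrom, start, end, gene,
#'   strand, source ("atac_peak" or "window").
#' @export
build_promoters <- function(tss, peaks = NULL, upstream = 2000,
                            downstream = 500, genome = NULL) {
  tss <- as.data.frame(tss)
  if (nrow(tss) == 0)
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), gene = character(),
                                strand = character(), source = character()),
                     class = c("promoter_set", "data.frame")))
  strand <- tss$strand
  bad_strand <- !(strand %in% c("+", "-"))
  if (any(bad_strand)) {
    warning(sprintf("%d TSS record(s) without strand treated as '+'",
                    sum(bad_strand)))
    strand[bad_strand] <- "+"
  }
  if (!is.null(genome)) {
    lens <- genome$lengths[tss$chrom]
    beyond <- !is.na(lens) & tss$start >= lens
    if (any(beyond)) {
      warning(sprintf("%d TSS record(s) beyond the chromosome end rejected",
                      sum(beyond)))
      tss <- tss[!beyond, , drop = FALSE]
      strand <- strand[!beyond]
    }
  }
  pos <- tss$start  # 0-based TSS coordinate
  n <- nrow(tss)
  start <- end <- numeric(n)
  source <- character(n)
  has_peaks <- !is.null(peaks) && nrow(peaks) > 0
  for (r in seq_len(n)) {
    ov <- if (has_peaks)
      which(peaks$chrom == tss$chrom[r] & peaks$start <= pos[r] &
              peaks$end > pos[r]) else integer()
    if (length(ov)) {
      start[r] <- min(peaks$start[ov])
      end[r] <- max(peaks$end[ov])
      source[r] <- "atac_peak"
    } else {
      if (strand[r] == "+") {
        start[r] <- pos[r] - upstream; end[r] <- pos[r] + downstream
      } else {
        start[r] <- pos[r] - downstream; end[r] <- pos[r] + upstream
      }
      source[r] <- "window"
    }
  }
  start <- pmax(start, 0)
  if (!is.null(genome)) {
    lens <- genome$lengths[tss$chrom]
    end <- ifelse(is.na(lens), end, pmin(end, lens))
  }
  out <- data.frame(chrom = tss$chrom, start = start, end = end,
                    gene = tss$name, strand = strand, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Subset significant interactions to promoter-anchored ones
#'
#' Extends each interaction side's bin midpoint by half the bin size both
#' up- and downstream ([mid - res/2, mid + res/2), half-open) and keeps the
#' interaction iff either side overlaps at least one promoter by >= 1 bp,
#' annotating each side with all overlapped gene symbols.
#'
#' @param interactions An `interaction_table` (from [test_interactions()]).
#' @param promoters A `promoter_set`.
#' @param resolution Bin size in bp; must match the interaction table's
#'   resolution attribute (error on mismatch).
#' @return data.frame of class `promoter_interactions`: the retained
#'   interaction rows plus `genes1`, `genes2` (comma-separated symbols, ""
#'   when none) and `promoter_side` ("1", "2" or "1,2").
#' @export
subset_promoter_interactions <- function(interactions, promoters, resolution) {
  res_attr <- attr(interactions, "resolution")
  if (!is.null(res_attr) && res_attr != resolution)
    stop(sprintf("resolution mismatch: interactions at %g bp, requested %g bp",
                 res_attr, resolution))
  h <- resolution / 2
  side_genes <- function(chrom, mid) {
    iv_start <- mid - h; iv_end <- mid + h  # 0-based half-open
    vapply(seq_along(mid), function(r) {
      ov <- promoters$chrom == chrom[r] &
        promoters$start < iv_end[r] & promoters$end > iv_start[r]
      paste(sort(unique(promoters$gene[ov])), collapse = ",")
    }, "")
  }
  g1 <- side_genes(interactions$chrom1, interactions$mid1)
  g2 <- side_genes(interactions$chrom2, interactions$mid2)
  keep <- nzchar(g1) | nzchar(g2)
  out <- as.data.frame(interactions)[keep, , drop = FALSE]
  out$genes1 <- g1[keep]
  out$genes2 <- g2[keep]
  out$promoter_side <- ifelse(nzchar(out$genes1) & nzchar(out$genes2), "1,2",
                              ifelse(nzchar(out$genes1), "1", "2"))
  rownames(out) <- NULL
  attr(out, "resolution") <- resolution
  class(out) <- c("promoter_interactions", "data.frame")
  out
}

#' Filter promoter-anchored interactions by a gene list
#'
#' Keeps an interaction iff at least one of its annotated gene symbols is in
#' the list (case-sensitive exact match). The typical use is restricting to
#' a cell-type-specific differentially-expressed gene list, which is an
#' input here, not a computation.
#'
#' @param pint A `promoter_interactions` data.frame.
#' @param genes Character vector of gene symbols.
#' @return The filtered `promoter_interactions`.
#' @export
filter_by_genes <- function(pint, genes) {
  split_genes <- function(s) strsplit(s, ",", fixed = TRUE)
  hit <- vapply(seq_len(nrow(pint)), function(r) {
    anns <- c(split_genes(pint$genes1[r])[[1]], split_genes(pint$genes2[r])[[1]])
    any(anns %in% genes)
  }, TRUE)
  if (!length(hit)) hit <- logical(0)
  out <- pint[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "resolution") <- attr(pint, "resolution")
  class(out) <- class(pint)
  out
}
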