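#' Simulation parameters for the synthetic pair generator
#'
#' Describes the statistical world the generator emulates: a power-law decay
#' of cis contact probability with genomic separation, a trans-contact
#' background, PCR duplication and unmapped fractions, a planted A/B
#' compartment checkerboard, planted TAD blocks, and planted focal loops.
#'
#' @param n_pairs Total number of pair records to emit (including duplicates
#'   and unmapped records).
#' @param alpha Decay exponent: cis contact probability is proportional to
#'   s^-alpha over distances s in [1 kb, chromosome length]. Mammalian Hi-C
#'   decay exponents are close to 1 in the 100 kb - 1 Mb range, so 1.0 is the
#'   default.
#' @param trans_frac Fraction of mapped, non-duplicate, non-self-ligation
#'   records that are inter-chromosomal, in [0, 1]. Default 0.30, the
#'   trans share observed in typical deeply filtered Micro-C libraries.
#' @param dup_rate Fraction of mapped records that are exact PCR duplicates,
#'   in [0, 1).
#' @param unmapped_rate Fraction of all records emitted with the sentinel
#'   chromosome "!" (4DN convention for an unmapped side), in [0, 1).
#' @param self_ligation_frac Fraction of mapped non-duplicate records that are
#'   sub-1 kb same-strand pairs emulating self-ligation artifacts.
#' @param comp_block Compartment checkerboard block size in bp (alternating
#'   A/B blocks of this size along every chromosome).
#' @param comp_strength Multiplicative up-weight (>= 1) for cis contacts whose
#'   two sides fall in same-label compartment blocks; 1 disables the
#'   checkerboard.
#' @param tad_boundaries Named list (by chromosome) of boundary positions in
#'   bp; contacts that do not cross a boundary are up-weighted by
#'   `tad_strength`. NULL plants no domains.
#' @param tad_strength Multiplicative up-weight (>= 1) for within-TAD cis
#'   contacts.
#' @param loops data.frame with columns `chrom`, `pos1`, `pos2`,
#'   `multiplier` (> 1): focal bin pairs whose contact count is raised to
#'   `multiplier` times the local background. NULL plants no loops.
#' @param bin_size Bin size (bp) of the truth grid used for compartment
#'   labels and loop bin pairs. Default 10 kb, the working resolution of the
#'   downstream analyses.
#' @param seed Integer seed; the full fixture is byte-identical across runs
#'   for a fixed seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 1e5,
                       alpha = 1.0,
                       trans_frac = 0.30,
                       dup_rate = 0.10,
                       unmapped_rate = 0.05,
                       self_ligation_frac = 0,
                       comp_block = 500e3,
                       comp_strength = 1,
                       tad_boundaries = NULL,
                       tad_strength = 1,
                       loops = NULL,
                       bin_size = 1e4,
                       seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (alpha <= 0) stop("alpha must be > 0")
  stopifnot(trans_frac >= 0, trans_frac <= 1,
            dup_rate >= 0, dup_rate < 1,
            unmapped_rate >= 0, unmapped_rate < 1,
            self_ligation_frac >= 0, self_ligation_frac < 1,
            comp_strength >= 1, tad_strength >= 1,
            comp_block > 0, bin_size > 0)
  if (!is.null(loops)) {
    loops <- as.data.frame(loops)
    need <- c("chrom", "pos1", "pos2", "multiplier")
    if (!all(need %in% names(loops)))
      stop("loops needs columns chrom, pos1, pos2, multiplier")
    if (any(loops$multiplier <= 1)) stop("loop multipliers must be > 1")
    if (any(loops$pos2 <= loops$pos1)) stop("loop anchors must satisfy pos1 < pos2")
  }
  structure(list(
    n_pairs = as.integer(n_pairs), alpha = alpha, trans_frac = trans_frac,
    dup_rate = dup_rate, unmapped_rate = unmapped_rate,
    self_ligation_frac = self_ligation_frac,
    comp_block = comp_block, comp_strength = comp_strength,
    tad_boundaries = tad_boundaries, tad_strength = tad_strength,
    loops = loops, bin_size = bin_size, seed = as.integer(seed)
  ), class = "sim_params")
}

#' Compartment checkerboard label for positions
#'
#' @param pos Positions (1-based bp).
#' @param comp_block Block size in bp.
#' @return Character vector "A"/"B": blocks with even index are A.
#' @keywords internal
checkerboard_label <- function(pos, comp_block) {
  ifelse(floor((pos - 1) / comp_block) %% 2 == 0, "A", "B")
}

# index of the TAD a position falls in (0 = before first boundary)
tad_index <- function(pos, boundaries) {
  if (is.null(boundaries) || !length(boundaries)) return(rep(0L, length(pos)))
  findInterval(pos, sort(boundaries))
}

# sample cis distances from the discretized power law: support k*1000 for
# k = 1..K with pmf proportional to k^-alpha, plus sub-kb jitter
sample_cis_distance <- function(n, chrom_len, alpha) {
  K <- max(1L, floor((chrom_len - 1000) / 1000))
  k <- sample.int(K, n, replace = TRUE, prob = seq_len(K)^(-alpha))
  d <- k * 1000 + sample.int(1000, n, replace = TRUE) - 1L
  pmin(d, chrom_len - 1)
}

#' Simulate Micro-C ligation-pair records with planted structure
#'
#' Draws pair records according to a `sim_params` world: cis distances follow
#' a discretized power law at 1 kb granularity; same-compartment and
#' within-TAD contacts are up-weighted by acceptance-rejection; planted loop
#' bin pairs receive extra contacts so that their count is `multiplier` times
#' the local background; stated fractions of trans, duplicate, unmapped and
#' self-ligation records are emitted. The returned truth object carries the
#' planted compartment labels, boundaries and loops for recovery tests.
#'
#' @param genome A `genome_spec`. Blacklisted chromosomes are not simulated.
#' @param params A `sim_params`.
#' @return A list with elements:
#'   \describe{
#'     \item{pairs}{data.table of records (readID, chrom1, pos1, chrom2,
#'       pos2, strand1, strand2), in randomized emission order.}
#'     \item{truth}{`synthetic_truth`: per-bin compartment labels (with an
#'       `activity` column usable as an E1 orientation track), boundary list,
#'       loop list, and the `sim_params` used.}
#'   }
#' @export
simulate_pairs <- function(genome, params) {
  stopifnot(inherits(genome, "genome_spec"), inherits(params, "sim_params"))
  chroms <- analysis_chroms(genome)
  lens <- genome$lengths[chroms]
  if (!is.null(params$loops)) {
    bad <- !(params$loops$chrom %in% chroms) |
      params$loops$pos2 > lens[params$loops$chrom] | params$loops$pos1 < 1
    if (any(bad)) stop("loop anchor outside the (non-blacklisted) genome")
  }
  set.seed(params$seed)

  n <- params$n_pairs
  n_unmapped <- round(params$unmapped_rate * n)
  n_mapped <- n - n_unmapped
  n_dup <- round(params$dup_rate * n_mapped)
  n_orig <- n_mapped - n_dup
  n_selflig <- round(params$self_ligation_frac * n_orig)
  n_rest <- n_orig - n_selflig
  n_trans <- round(params$trans_frac * n_rest)
  n_cis <- n_rest - n_trans

  rstrand <- function(m) sample(c("+", "-"), m, replace = TRUE)

  ## -- trans background: chromosomes weighted by length, positions uniform
  trans <- NULL
  if (n_trans > 0) {
    if (length(chroms) < 2) stop("trans pairs need >= 2 analysis chromosomes")
    c1 <- sample(chroms, n_trans, replace = TRUE, prob = lens)
    c2 <- vapply(c1, function(cc) sample(chroms[chroms != cc], 1,
                 prob = lens[chroms != cc]), character(1))
    trans <- data.table::data.table(
      chrom1 = c1, pos1 = floor(stats::runif(n_trans) * lens[c1]) + 1,
      chrom2 = c2, pos2 = floor(stats::runif(n_trans) * lens[c2]) + 1,
      strand1 = rstrand(n_trans), strand2 = rstrand(n_trans))
  }

  ## -- cis background with compartment/TAD acceptance-rejection
  cis <- NULL
  if (n_cis > 0) {
    wmax <- params$comp_strength * params$tad_strength
    got <- 0L
    chunks <- list()
    p_hat <- 1 / wmax  # acceptance-rate estimate, updated per batch
    while (got < n_cis) {
      m <- as.integer(min(2e6, max(1000, ceiling((n_cis - got) / p_hat * 1.1))))
      cc <- sample(chroms, m, replace = TRUE, prob = lens)
      d <- numeric(m)
      for (ch in unique(cc)) {
        idx <- which(cc == ch)
        d[idx] <- sample_cis_distance(length(idx), lens[ch], params$alpha)
      }
      p1 <- floor(stats::runif(m) * (lens[cc] - d)) + 1
      p2 <- p1 + d
      w <- rep(1, m)
      if (params$comp_strength > 1) {
        same <- checkerboard_label(p1, params$comp_block) ==
                checkerboard_label(p2, params$comp_block)
        w <- w * ifelse(same, params$comp_strength, 1)
      }
      if (params$tad_strength > 1 && !is.null(params$tad_boundaries)) {
        same_tad <- rep(TRUE, m)
        for (ch in unique(cc)) {
          idx <- which(cc == ch)
          b <- params$tad_boundaries[[ch]]
          same_tad[idx] <- tad_index(p1[idx], b) == tad_index(p2[idx], b)
        }
        w <- w * ifelse(same_tad, params$tad_strength, 1)
      }
      keep <- stats::runif(m) < w / wmax
      chunk <- data.table::data.table(
        chrom1 = cc[keep], pos1 = p1[keep], chrom2 = cc[keep], pos2 = p2[keep],
        strand1 = rstrand(sum(keep)), strand2 = rstrand(sum(keep)))
      chunks[[length(chunks) + 1L]] <- chunk
      got <- got + nrow(chunk)
      p_hat <- max(0.005, nrow(chunk) / m)
    }
    cis <- data.table::rbindlist(chunks)[seq_len(n_cis)]
  }

  ## -- planted loops: raise the loop bin pair to multiplier x local background
  loop_extra <- NULL
  if (!is.null(params$loops) && nrow(params$loops) > 0 && !is.null(cis)) {
    bs <- params$bin_size
    lb1 <- floor((params$loops$pos1 - 1) / bs)
    lb2 <- floor((params$loops$pos2 - 1) / bs)
    extras <- list()
    for (i in seq_len(nrow(params$loops))) {
      L <- params$loops[i, ]
      onchr <- cis[cis$chrom1 == L$chrom, ]
      b <- sum(floor((onchr$pos1 - 1) / bs) == lb1[i] &
               floor((onchr$pos2 - 1) / bs) == lb2[i])
      n_extra <- round((L$multiplier - 1) * max(b, 1))
      if (n_extra > 0) {
        s1 <- lb1[i] * bs + 1; s2 <- lb2[i] * bs + 1
        e1 <- min(s1 + bs - 1, lens[L$chrom]); e2 <- min(s2 + bs - 1, lens[L$chrom])
        extras[[length(extras) + 1L]] <- data.table::data.table(
          chrom1 = L$chrom, pos1 = floor(stats::runif(n_extra) * (e1 - s1 + 1)) + s1,
          chrom2 = L$chrom, pos2 = floor(stats::runif(n_extra) * (e2 - s2 + 1)) + s2,
          strand1 = rstrand(n_extra), strand2 = rstrand(n_extra))
      }
    }
    if (length(extras)) loop_extra <- data.table::rbindlist(extras)
    # keep the total record count at n_pairs: the loop contacts displace an
    # equal number of background cis pairs
    if (!is.null(loop_extra) && nrow(loop_extra) < nrow(cis))
      cis <- cis[seq_len(nrow(cis) - nrow(loop_extra))]
  }

  ## -- self-ligation artifacts: sub-1 kb, same strand
  selflig <- NULL
  if (n_selflig > 0) {
    cc <- sample(chroms, n_selflig, replace = TRUE, prob = lens)
    d <- sample.int(900, n_selflig, replace = TRUE) + 99L  # 100..999 bp
    p1 <- floor(stats::runif(n_selflig) * (lens[cc] - d)) + 1
    ss <- rstrand(n_selflig)
    selflig <- data.table::data.table(
      chrom1 = cc, pos1 = p1, chrom2 = cc, pos2 = p1 + d,
      strand1 = ss, strand2 = ss)
  }

  mapped <- data.table::rbindlist(list(cis, trans, selflig, loop_extra),
                                  use.names = TRUE)

  ## -- PCR duplicates: verbatim re-emission of existing mapped records
  if (n_dup > 0) {
    dup <- mapped[sample.int(nrow(mapped), n_dup, replace = TRUE), ]
    mapped <- data.table::rbindlist(list(mapped, dup))
  }

  ## -- unmapped records: sentinel chromosome "!"
  if (n_unmapped > 0) {
    unm <- data.table::data.table(
      chrom1 = "!", pos1 = 0L, chrom2 = "!", pos2 = 0L,
      strand1 = "+", strand2 = "+")[rep(1L, n_unmapped)]
    mapped <- data.table::rbindlist(list(mapped, unm))
  }

  pairs <- mapped[sample.int(nrow(mapped)), ]
  pairs[, readID := sprintf("r%08d", .I)]
  data.table::setcolorder(pairs, c("readID", "chrom1", "pos1", "chrom2",
                                   "pos2", "strand1", "strand2"))

  ## -- ground truth on the bin grid
  bs <- params$bin_size
  comp <- data.table::rbindlist(lapply(chroms, function(ch) {
    nb <- ceiling(lens[ch] / bs)
    start <- (seq_len(nb) - 1) * bs
    data.table::data.table(
      chrom = ch, bin = seq_len(nb) - 1L, start = start,
      end = pmin(start + bs, lens[ch]),
      label = checkerboard_label(start + 1, params$comp_block))
  }))
  comp[, activity := as.numeric(label == "A")]
  loops_out <- if (is.null(params$loops)) {
    data.frame(chrom = character(), pos1 = numeric(), pos2 = numeric(),
               multiplier = numeric())
  } else {
    params$loops[order(params$loops$chrom, params$loops$pos1,
                       params$loops$pos2), , drop = FALSE]
  }
  truth <- structure(list(
    compartments = comp,
    boundaries = params$tad_boundaries,
    loops = loops_out,
    params = params
  ), class = "synthetic_truth")

  list(pairs = pairs[], truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d labelled bins, %d boundary chromosome(s), %d loop(s)\n",
              nrow(x$compartments),
              length(x$boundaries), nrow(x$loops)))
  invisible(x)
}

#' Generate peak, TSS and deletion fixtures matched to a synthetic truth
#'
#' Builds BED-style annotation tables around the planted structure: a
#' configurable fraction of planted loop anchors receive overlapping ATAC and
#' H3K4me1/H3K4me3 peaks, CTCF peaks are placed at planted TAD boundaries,
#' TSS records (strand + gene symbol) are planted at a fraction of anchors
#' and at random background positions, and deletion intervals can be placed
#' over a chosen planted loop anchor. All intervals are 0-based half-open
#' (BED convention).
#'
#' @param genome A `genome_spec`.
#' @param truth A `synthetic_truth` from [simulate_pairs()].
#' @param seed Integer seed.
#' @param frac_anchors_marked Fraction of planted loop anchors that receive an
#'   overlapping ATAC peak (and, among those, H3K4me1/H3K4me3 peaks per
#'   `frac_me1`/`frac_me3`).
#' @param frac_me1,frac_me3 Fractions of marked anchors receiving each
#'   histone-mark peak.
#' @param n_background Number of background peaks per track (placed away from
#'   planted anchors).
#' @param n_tss Number of background TSS records.
#' @param frac_tss_at_anchors Fraction of planted anchors that also receive a
#'   TSS (gene symbols `anchorGene<i>`).
#' @param deletion_over_loop Integer index (1-based, into `truth$loops`) of a
#'   loop whose distal anchor is covered by a deletion interval; NA places
#'   only background deletions.
#' @param n_deletions Number of background deletion intervals (placed away
#'   from planted anchors).
#' @return List of data.frames (chrom, start, end, name, score, strand):
#'   `atac`, `h3k4me1`, `h3k4me3`, `h3k27ac`, `ctcf`, `tss`, `deletions`.
#' @export
generate_annotations <- function(genome, truth, seed = 1L,
                                 frac_anchors_marked = 1,
                                 frac_me1 = 0.5, frac_me3 = 0.3,
                                 n_background = 50, n_tss = 50,
                                 frac_tss_at_anchors = 0.5,
                                 deletion_over_loop = NA,
                                 n_deletions = 3) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(as.integer(seed))
  chroms <- analysis_chroms(genome)
  lens <- genome$lengths[chroms]
  bs <- truth$params$bin_size

  bed <- function(chrom, start, end, name, strand = ".") {
    data.frame(chrom = chrom, start = start, end = end, name = name,
               score = rep(0L, length(chrom)),
               strand = rep(strand, length.out = length(chrom)),
               stringsAsFactors = FALSE)
  }
  empty <- bed(character(), numeric(), numeric(), character(), character())

  # planted anchor bins (0-based half-open)
  anchors <- NULL
  if (nrow(truth$loops) > 0) {
    a <- rbind(
      data.frame(chrom = truth$loops$chrom,
                 start = floor((truth$loops$pos1 - 1) / bs) * bs),
      data.frame(chrom = truth$loops$chrom,
                 start = floor((truth$loops$pos2 - 1) / bs) * bs))
    a$end <- a$start + bs
    anchors <- unique(a)
  }

  rand_intervals <- function(m, width) {
    cc <- sample(chroms, m, replace = TRUE, prob = lens)
    st <- floor(stats::runif(m) * pmax(1, lens[cc] - width))
    bed(cc, st, st + width, sprintf("bg%04d", seq_len(m)))
  }
  avoid_anchors <- function(x) {
    if (is.null(anchors) || nrow(x) == 0) return(x)
    keep <- rep(TRUE, nrow(x))
    for (i in seq_len(nrow(anchors))) {
      hit <- x$chrom == anchors$chrom[i] &
        x$start < anchors$end[i] & x$end > anchors$start[i]
      keep <- keep & !hit
    }
    x[keep, , drop = FALSE]
  }

  # anchor-overlapping peaks
  atac <- avoid_anchors(rand_intervals(n_background, 400))
  me1 <- avoid_anchors(rand_intervals(n_background, 600))
  me3 <- avoid_anchors(rand_intervals(n_background, 600))
  k27 <- avoid_anchors(rand_intervals(n_background, 600))
  if (!is.null(anchors) && frac_anchors_marked > 0) {
    k <- ceiling(frac_anchors_marked * nrow(anchors))
    sel <- anchors[sample.int(nrow(anchors), k), , drop = FALSE]
    mid <- floor((sel$start + sel$end) / 2)
    atac <- rbind(atac, bed(sel$chrom, mid - 200, mid + 200,
                            sprintf("anchorATAC%03d", seq_len(k))))
    k1 <- round(frac_me1 * k)
    if (k1 > 0) {
      i1 <- seq_len(k1)
      me1 <- rbind(me1, bed(sel$chrom[i1], mid[i1] - 300, mid[i1] + 300,
                            sprintf("anchorMe1_%03d", i1)))
    }
    k3 <- round(frac_me3 * k)
    if (k3 > 0) {
      i3 <- seq_len(k3)
      me3 <- rbind(me3, bed(sel$chrom[i3], mid[i3] - 300, mid[i3] + 300,
                            sprintf("anchorMe3_%03d", i3)))
    }
  }

  # CTCF at planted TAD boundaries
  ctcf <- avoid_anchors(rand_intervals(n_background, 300))
  if (!is.null(truth$boundaries)) {
    for (ch in names(truth$boundaries)) {
      b <- truth$boundaries[[ch]]
      if (length(b))
        ctcf <- rbind(ctcf, bed(ch, pmax(0, b - 150), b + 150,
                                sprintf("%s_boundary%02d", ch, seq_along(b))))
    }
  }

  # TSS: background + a fraction at planted anchors
  cc <- sample(chroms, n_tss, replace = TRUE, prob = lens)
  tpos <- floor(stats::runif(n_tss) * (lens[cc] - 1))
  tss <- bed(cc, tpos, tpos + 1, sprintf("gene%04d", seq_len(n_tss)),
             strand = sample(c("+", "-"), n_tss, replace = TRUE))
  if (!is.null(anchors) && frac_tss_at_anchors > 0) {
    k <- ceiling(frac_tss_at_anchors * nrow(anchors))
    sel <- anchors[seq_len(k), , drop = FALSE]
    mid <- floor((sel$start + sel$end) / 2)
    tss <- rbind(tss, bed(sel$chrom, mid, mid + 1,
                          sprintf("anchorGene%03d", seq_len(k)),
                          strand = sample(c("+", "-"), k, replace = TRUE)))
  }

  # deletions: background + optionally one over a chosen loop's distal anchor
  dels <- if (n_deletions > 0) avoid_anchors(rand_intervals(n_deletions, 50e3)) else empty
  if (nrow(dels)) dels$name <- sprintf("del_bg%02d", seq_len(nrow(dels)))
  if (!is.na(deletion_over_loop)) {
    if (deletion_over_loop < 1 || deletion_over_loop > nrow(truth$loops))
      stop("deletion_over_loop is not a valid loop index")
    L <- truth$loops[deletion_over_loop, ]
    b2 <- floor((L$pos2 - 1) / bs) * bs
    dels <- rbind(dels, bed(L$chrom, b2 - 2000, b2 + bs + 2000,
                            sprintf("del_loop%d", deletion_over_loop)))
  }

  list(atac = atac, h3k4me1 = me1, h3k4me3 = me3, h3k27ac = k27,
       ctcf = ctcf, tss = tss, deletions = dels)
}
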