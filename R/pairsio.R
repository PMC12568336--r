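#' Parse 4DN-style pair records
#'
#' Reads ligation-pair records (readID chrom1 pos1 chrom2 pos2 strand1
#' strand2) from a .pairs text file or an in-memory table, normalizes side
#' order to the upper-triangle convention (chrom1 before chrom2 in genome
#' order; pos1 <= pos2 within a chromosome), flags records on the sentinel
#' chromosome "!" as unmapped, drops records touching blacklisted
#' chromosomes, and rejects records on unknown chromosomes or with positions
#' outside the chromosome, counting every rejection class.
#'
#' @param input Path to a .pairs file (header lines starting with `#` are
#'   skipped) or a data.frame/data.table with the seven record columns.
#' @param genome A `genome_spec`.
#' @return A `data.table` of class `pair_records` with columns readID,
#'   chrom1, pos1, strand1, chrom2, pos2, strand2, mapped, duplicate
#'   (initialized NA until [deduplicate()]), and attribute `parse_counts`:
#'   total_records, malformed, unknown_chrom, out_of_bounds, blacklisted.
#'   Malformed or rejected lines are reported (first offending line number)
#'   via warning.
#' @export
parse_pairs <- function(input, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  malformed <- integer()
  if (is.character(input) && length(input) == 1) {
    lines <- readLines(input)
    keep <- !grepl("^#", lines) & nzchar(lines)
    lineno <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    # tolerate space-separated records
    one <- lengths(parts) == 1
    parts[one] <- strsplit(vapply(parts[one], `[`, "", 1), "[ ]+")
    bad <- lengths(parts) < 7
    if (any(bad)) {
      malformed <- lineno[bad]
      warning(sprintf("%d malformed pair line(s); first at line %d",
                      sum(bad), malformed[1]))
      parts <- parts[!bad]
    }
    col <- function(i) vapply(parts, `[`, "", i)
    rec <- data.table::data.table(
      readID = col(1), chrom1 = col(2), pos1 = suppressWarnings(as.numeric(col(3))),
      chrom2 = col(4), pos2 = suppressWarnings(as.numeric(col(5))),
      strand1 = col(6), strand2 = col(7))
  } else {
    rec <- data.table::as.data.table(input)
    rec <- rec[, c("readID", "chrom1", "pos1", "chrom2", "pos2",
                   "strand1", "strand2"), with = FALSE]
    rec[, `:=`(pos1 = as.numeric(pos1), pos2 = as.numeric(pos2))]
  }
  total <- nrow(rec) + length(malformed)

  badpos <- is.na(rec$pos1) | is.na(rec$pos2)
  if (any(badpos)) {
    malformed <- c(malformed, which(badpos))
    warning(sprintf("%d pair record(s) with non-numeric positions", sum(badpos)))
    rec <- rec[!badpos]
  }

  unmapped <- rec$chrom1 == "!" | rec$chrom2 == "!"
  known <- function(ch) ch %in% genome$chroms | ch == "!"
  unknown <- !known(rec$chrom1) | !known(rec$chrom2)
  n_unknown <- sum(unknown & !unmapped)

  black <- rec$chrom1 %in% genome$blacklist | rec$chrom2 %in% genome$blacklist
  n_black <- sum(black & !unknown)

  len1 <- genome$lengths[rec$chrom1]
  len2 <- genome$lengths[rec$chrom2]
  oob <- (!unmapped) & (rec$pos1 < 1 | rec$pos2 < 1 |
                        (!is.na(len1) & rec$pos1 > len1) |
                        (!is.na(len2) & rec$pos2 > len2))
  n_oob <- sum(oob & !unknown & !black)

  keep <- !unknown & !black & !oob
  rec <- rec[keep]
  unmapped <- unmapped[keep]

  # upper-triangle normalization in genome order
  ord <- stats::setNames(seq_along(genome$chroms), genome$chroms)
  o1 <- ord[rec$chrom1]; o2 <- ord[rec$chrom2]
  swap <- !unmapped & (o1 > o2 | (o1 == o2 & rec$pos1 > rec$pos2))
  if (any(swap)) {
    w <- which(swap)
    c1 <- rec$chrom1[w]; p1 <- rec$pos1[w]; s1 <- rec$strand1[w]
    data.table::set(rec, w, c("chrom1", "pos1", "strand1"),
                    list(rec$chrom2[w], rec$pos2[w], rec$strand2[w]))
    data.table::set(rec, w, c("chrom2", "pos2", "strand2"), list(c1, p1, s1))
  }
  rec[, mapped := !unmapped]
  rec[, duplicate := NA]
  data.table::setattr(rec, "parse_counts", list(
    total_records = total, malformed = length(malformed),
    unknown_chrom = n_unknown, out_of_bounds = n_oob, blacklisted = n_black))
  data.table::setattr(rec, "class", c("pair_records", class(rec)))
  rec[]
}

#' Chimeric (distal ligation) pair test
#'
#' A mapped pair is chimeric -- i.e. a genuine ligation junction rather than
#' a self-ligated or undigested fragment -- if any of three criteria holds:
#' the sides map to different chromosomes; the mapping orientation is
#' atypical (anything other than the inward-facing convergent configuration,
#' `+` on the leftmost side and `-` on the rightmost, which is what
#' self-ligation and undigested products produce); or the sides are more
#' than `distance_threshold` bp apart (strictly).
#'
#' @param records `pair_records` (upper-triangle normalized), mapped on both
#'   sides; unmapped records raise an error.
#' @param distance_threshold Distance cutoff in bp (default 2000); a
#'   separation of exactly the threshold is not chimeric.
#' @return Logical vector, one flag per record.
#' @export
is_chimeric <- function(records, distance_threshold = 2000) {
  if (any(!records$mapped))
    stop("is_chimeric is undefined for unmapped records")
  trans <- records$chrom1 != records$chrom2
  inward <- records$strand1 == "+" & records$strand2 == "-"
  far <- abs(records$pos2 - records$pos1) > distance_threshold
  trans | !inward | far
}

#' Retain only chimeric pairs
#'
#' Applies [is_chimeric()] to the mapped records and drops the rest
#' (self-ligation and undigested artifacts). Unmapped records are kept and
#' remain flagged. The number of removed records is appended to the parse
#' counts as `non_chimeric`.
#'
#' @param records `pair_records`.
#' @param distance_threshold Passed to [is_chimeric()].
#' @return Filtered `pair_records`.
#' @export
filter_chimeric <- function(records, distance_threshold = 2000) {
  counts <- attr(records, "parse_counts")
  chim <- rep(TRUE, nrow(records))
  chim[records$mapped] <- is_chimeric(records[records$mapped == TRUE],
                                      distance_threshold)
  out <- records[chim]
  counts$non_chimeric <- sum(!chim)
  data.table::setattr(out, "parse_counts", counts)
  data.table::setattr(out, "class", class(records))
  out[]
}

#' Sort pair records by coordinates
#' @param records `pair_records`.
#' @return Records sorted by (chrom1, pos1, chrom2, pos2, strand1, strand2),
#'   unmapped records last.
#' @export
sort_pairs <- function(records) {
  out <- records[order(!records$mapped, records$chrom1, records$pos1,
                       records$chrom2, records$pos2,
                       records$strand1, records$strand2)]
  data.table::setattr(out, "parse_counts", attr(records, "parse_counts"))
  data.table::setattr(out, "class", class(records))
  out[]
}

#' Flag PCR duplicates
#'
#' Within each group of mapped records sharing the exact 6-tuple (chrom1,
#' pos1, strand1, chrom2, pos2, strand2), exactly one record is left
#' unflagged and the rest are marked duplicates. No positional slack is
#' allowed: at Micro-C mononucleosome precision, identical coordinates and
#' strands are the PCR/optical duplicate signature. Input must be
#' coordinate-sorted (see [sort_pairs()]).
#'
#' @param records `pair_records`, sorted by (chrom1, pos1, chrom2, pos2).
#' @return Records with the `duplicate` flag set (FALSE on unmapped records,
#'   which are not deduplicated).
#' @export
deduplicate <- function(records) {
  m <- records[records$mapped == TRUE]
  if (nrow(m) > 1) {
    o <- order(m$chrom1, m$pos1, m$chrom2, m$pos2)
    if (!identical(o, seq_len(nrow(m))))
      stop("records must be sorted by (chrom1, pos1, chrom2, pos2); see sort_pairs()")
  }
  dup <- rep(FALSE, nrow(records))
  dup[records$mapped] <- duplicated(
    m[, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")])
  out <- data.table::copy(records)
  out[, duplicate := dup]
  data.table::setattr(out, "parse_counts", attr(records, "parse_counts"))
  data.table::setattr(out, "class", class(records))
  out[]
}

#' Classify pair records by interaction type and distance
#'
#' Assigns each record exactly one category: `unmapped`, `duplicate`,
#' `trans`, or one of three cis distance strata with lower-inclusive
#' boundaries -- `cis_lt_1kb` (< 1,000 bp), `cis_1kb_to_10kb`
#' ([1,000, 10,000) bp) and `cis_ge_10kb` (>= 10,000 bp). A record is
#' `valid` iff it is trans or cis with separation >= 1 kb, and neither a
#' duplicate nor unmapped.
#'
#' @param records `pair_records` (after [deduplicate()]; records with an NA
#'   duplicate flag are treated as non-duplicates).
#' @return Records with `category` (factor) and `valid` (logical) columns.
#' @export
classify_pairs <- function(records) {
  dup <- !is.na(records$duplicate) & records$duplicate
  dist <- abs(records$pos2 - records$pos1)
  cis <- records$mapped & records$chrom1 == records$chrom2
  cat <- ifelse(!records$mapped, "unmapped",
         ifelse(dup, "duplicate",
         ifelse(!cis, "trans",
         ifelse(dist < 1000, "cis_lt_1kb",
         ifelse(dist < 10000, "cis_1kb_to_10kb", "cis_ge_10kb")))))
  out <- data.table::copy(records)
  out[, category := factor(cat, levels = c("unmapped", "duplicate", "trans",
                                           "cis_lt_1kb", "cis_1kb_to_10kb",
                                           "cis_ge_10kb"))]
  out[, valid := records$mapped & !dup & (!cis | dist >= 1000)]
  data.table::setattr(out, "parse_counts", attr(records, "parse_counts"))
  data.table::setattr(out, "class", class(records))
  out[]
}

.summary_rows <- data.frame(
  key = c("total", "unmapped", "mapped", "duplicate", "nodup",
          "cis", "trans", "valid", "cis_lt_1kb", "cis_ge_1kb", "cis_ge_10kb"),
  label = c("Total Read Pairs", "Unmapped Read Pairs", "Mapped Read Pairs",
            "PCR Dup Read Pairs", "No-Dup Read Pairs",
            "No-Dup Cis Read Pairs", "No-Dup Trans Read Pairs",
            "No-Dup Valid Read Pairs (cis >= 1 kb + trans)",
            "No-Dup Cis Read Pairs < 1 kb", "No-Dup Cis Read Pairs >= 1 kb",
            "No-Dup Cis Read Pairs >= 10 kb"),
  basis = c(rep("total", 5), rep("nodup", 6)),
  stringsAsFactors = FALSE)

#' Read-pair accounting summary
#'
#' Builds the standard read-accounting table: counts and percentages for
#' total, unmapped, mapped, PCR-duplicate and deduplicated ("no-dup")
#' read pairs on the basis of total read pairs, and cis/trans/valid and cis
#' distance strata on the basis of no-dup read pairs. Percentages are
#' rounded to two decimals. Input is either a classified `pair_records`
#' table or a named count vector (keys `total`, `unmapped`, `mapped`,
#' `duplicate`, `nodup`, `cis`, `trans`, `valid`, `cis_lt_1kb`,
#' `cis_ge_1kb`, `cis_ge_10kb`), whose self-consistency is validated:
#' a violated identity aborts with the identity named.
#'
#' @param x Classified records (from [classify_pairs()]) or named counts.
#' @return data.frame with columns category, count, percent, basis
#'   (`"Proportion of Total Read Pairs"` / `"Proportion of No-Dup Read
#'   Pairs"`).
#' @export
summarize_pairs <- function(x) {
  if (inherits(x, "pair_records") || is.data.frame(x)) {
    pc <- attr(x, "parse_counts")
    cat <- table(x$category)
    mapped <- sum(x$mapped)
    dup <- as.numeric(cat[["duplicate"]])
    counts <- c(
      total = if (!is.null(pc)) pc$total_records else nrow(x),
      unmapped = as.numeric(cat[["unmapped"]]),
      mapped = mapped,
      duplicate = dup,
      nodup = mapped - dup,
      cis = as.numeric(cat[["cis_lt_1kb"]] + cat[["cis_1kb_to_10kb"]] +
                         cat[["cis_ge_10kb"]]),
      trans = as.numeric(cat[["trans"]]),
      valid = sum(x$valid),
      cis_lt_1kb = as.numeric(cat[["cis_lt_1kb"]]),
      cis_ge_1kb = as.numeric(cat[["cis_1kb_to_10kb"]] + cat[["cis_ge_10kb"]]),
      cis_ge_10kb = as.numeric(cat[["cis_ge_10kb"]]))
  } else {
    counts <- unlist(x)
    missing <- setdiff(.summary_rows$key, names(counts))
    if (length(missing))
      stop("missing counts: ", paste(missing, collapse = ", "))
    counts <- counts[.summary_rows$key]
    chk <- function(ok, identity)
      if (!isTRUE(ok)) stop("inconsistent counts: identity violated: ", identity)
    chk(counts["mapped"] + counts["unmapped"] <= counts["total"],
        "mapped + unmapped <= total")
    chk(counts["nodup"] + counts["duplicate"] == counts["mapped"],
        "nodup + duplicate = mapped")
    chk(counts["cis"] + counts["trans"] == counts["nodup"],
        "cis + trans = nodup")
    chk(counts["cis_lt_1kb"] + counts["cis_ge_1kb"] == counts["cis"],
        "cis_lt_1kb + cis_ge_1kb = cis")
    chk(counts["valid"] == counts["trans"] + counts["cis_ge_1kb"],
        "valid = trans + cis_ge_1kb")
    chk(counts["cis_ge_10kb"] <= counts["cis_ge_1kb"],
        "cis_ge_10kb <= cis_ge_1kb")
  }
  basis_n <- c(total = counts[["total"]], nodup = counts[["nodup"]])
  if (any(basis_n == 0))
    warning("degenerate basis: zero total or no-dup count; percentages set to 0")
  pct <- ifelse(basis_n[.summary_rows$basis] > 0,
                round(100 * counts / basis_n[.summary_rows$basis], 2), 0)
  data.frame(category = .summary_rows$label,
             count = as.numeric(counts),
             percent = as.numeric(pct),
             basis = ifelse(.summary_rows$basis == "total",
                            "Proportion of Total Read Pairs",
                            "Proportion of No-Dup Read Pairs"),
             stringsAsFactors = FALSE)
}

#' Library complexity curve (Lander-Waterman model)
#'
#' Fits the one-parameter Lander-Waterman saturation model
#' C(N) = L (1 - exp(-N/L)) to a single observed (total, distinct) point by
#' monotone root-finding for the library size L, then evaluates the expected
#' number of distinct read pairs over a depth grid. The curve is 0 at depth
#' 0, non-decreasing, and concave. When distinct = total no saturation is
#' detectable (L is infinite and the curve is the identity).
#'
#' @param total_reads Total read pairs sequenced (> 0).
#' @param distinct_reads Distinct read pairs observed (0 < distinct <= total).
#' @param depth_grid Numeric vector of sequencing depths to evaluate.
#' @return List of class `complexity_curve`: `depth`, `expected_distinct`,
#'   `library_size` (Inf when undetectable), `saturation_detectable`.
#' @export
complexity_curve <- function(total_reads, distinct_reads,
                             depth_grid = seq(0, 2 * total_reads,
                                              length.out = 21)) {
  if (distinct_reads <= 0 || distinct_reads > total_reads)
    stop("need 0 < distinct_reads <= total_reads")
  if (distinct_reads == total_reads) {
    warning("distinct = total: no saturation detectable; curve is the identity")
    return(structure(list(depth = depth_grid, expected_distinct = depth_grid,
                          library_size = Inf, saturation_detectable = FALSE),
                     class = "complexity_curve"))
  }
  f <- function(L) L * (1 - exp(-total_reads / L)) - distinct_reads
  upper <- max(total_reads^2 / (2 * (total_reads - distinct_reads)),
               distinct_reads) * 10
  L <- stats::uniroot(f, lower = distinct_reads / 2, upper = upper,
                      extendInt = "upX", tol = 1e-9 * distinct_reads)$root
  structure(list(depth = depth_grid,
                 expected_distinct = L * (1 - exp(-depth_grid / L)),
                 library_size = L, saturation_detectable = TRUE),
            class = "complexity_curve")
}
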