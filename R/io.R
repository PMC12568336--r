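#' Write pair records as 4DN-style .pairs text
#'
#' Emits a minimal pairs file: `## pairs format v1.0` header, one
#' `#chromsize:` line per chromosome, a `#columns:` line, then one record per
#' line with columns readID chrom1 pos1 chrom2 pos2 strand1 strand2.
#'
#' @param pairs data.frame/data.table with the seven record columns.
#' @param path Output file path.
#' @param genome Optional `genome_spec` for the chromsize header lines.
#' @return `path`, invisibly.
#' @export
write_pairs_file <- function(pairs, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  if (!is.null(genome))
    writeLines(sprintf("#chromsize: %s %d", genome$chroms,
                       as.integer(genome$lengths)), con)
  writeLines("#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2", con)
  utils::write.table(
    as.data.frame(pairs)[, c("readID", "chrom1", "pos1", "chrom2", "pos2",
                             "strand1", "strand2")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a two-column chrom.sizes table
#' @param genome A `genome_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(genome$chroms, as.integer(genome$lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes table into a genome_spec
#' @param path Two-column (name, length) tab-separated file.
#' @param blacklist Chromosomes to blacklist.
#' @return A `genome_spec`.
#' @export
read_chrom_sizes <- function(path, blacklist = character()) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  genome_spec(stats::setNames(x$length, x$chrom), blacklist = blacklist)
}

#' Write intervals as BED6
#'
#' @param x data.frame with chrom, start, end and optionally name, score,
#'   strand (filled with ".", 0, "." when absent). Coordinates are written
#'   as-is and must already be 0-based half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as.data.frame(x)
  if (is.null(x$name)) x$name <- "."
  if (is.null(x$score)) x$score <- 0L
  if (is.null(x$strand)) x$strand <- "."
  utils::write.table(
    x[, c("chrom", "start", "end", "name", "score", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (3-6 columns, 0-based half-open)
#'
#' Malformed lines (fewer than three fields, non-numeric coordinates, or
#' start >= end) raise an error naming the first offending line.
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end, name, score, strand (missing
#'   optional columns filled with ".", 0, ".").
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), strand = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("malformed BED line %d: fewer than 3 fields", which(nf < 3)[1]))
  get <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i) p[i] else default, character(1))
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop(sprintf("malformed BED line %d: bad coordinates", bad[1]))
  data.frame(chrom = get(1, "."), start = start, end = end,
             name = get(4, "."),
             score = suppressWarnings(as.numeric(get(5, "0"))),
             strand = get(6, "."), stringsAsFactors = FALSE)
}

#' Write a per-bin track as bedGraph
#' @param x data.frame with chrom, start, end, value.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, name = "track") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", name), con)
  keep <- !is.na(x$value)
  utils::write.table(as.data.frame(x)[keep, c("chrom", "start", "end", "value")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV with a header
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# BED (0-based half-open) -> GRanges (1-based closed)
bed_to_granges <- function(bed) {
  if (nrow(bed) == 0)
    return(GenomicRanges::GRanges())
  strand <- if (is.null(bed$strand)) rep("*", nrow(bed)) else
    ifelse(bed$strand %in% c("+", "-"), bed$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1, end = bed$end),
    strand = strand)
  if (!is.null(bed$name)) gr$name <- bed$name
  gr
}
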