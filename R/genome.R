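#' Genome specification
#'
#' A minimal description of a genome assembly: an ordered set of chromosome
#' names, their lengths in bp, and an optional blacklist of chromosomes whose
#' pairs are dropped during parsing (typically the mitochondrial and Y
#' chromosomes, which carry non-nuclear or sex-specific signal).
#'
#' @param lengths Named integer/numeric vector of chromosome lengths (bp).
#'   Names are the chromosome names; order is the genome order used for
#'   upper-triangle normalization of pair records.
#' @param blacklist Character vector of chromosome names to exclude from
#'   analysis. Must be a subset of `names(lengths)`.
#' @return An object of class `genome_spec`.
#' @examples
#' gs <- genome_spec(c(chr1 = 5e6, chr2 = 3e6, chrM = 16299), blacklist = "chrM")
#' @export
genome_spec <- function(lengths, blacklist = character()) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("chromosome lengths must carry unique names")
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  if (!all(blacklist %in% names(lengths)))
    stop("blacklist must be a subset of the chromosome names")
  structure(list(
    chroms = names(lengths),
    lengths = stats::setNames(as.numeric(lengths), names(lengths)),
    blacklist = as.character(blacklist)
  ), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosomes, %.1f Mb total\n",
              length(x$chroms), sum(x$lengths) / 1e6))
  if (length(x$blacklist))
    cat("  blacklisted:", paste(x$blacklist, collapse = ", "), "\n")
  invisible(x)
}

#' Chromosomes retained for analysis (blacklist removed)
#' @param genome A `genome_spec`.
#' @return Character vector of usable chromosome names, in genome order.
#' @export
analysis_chroms <- function(genome) {
  setdiff(genome$chroms, genome$blacklist)
}

#' Generate a random genome specification
#'
#' Draws chromosome lengths uniformly within a range. Chromosomes are named
#' `chr1..chrN`; when `with_blacklist` is TRUE a short `chrM` contig is
#' appended and blacklisted, which exercises the parser's rejection path.
#'
#' @param n_chroms Number of (analysis) chromosomes, >= 1.
#' @param length_range Length-2 numeric: min/max chromosome length in bp.
#'   A single number gives all chromosomes that exact length.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param with_blacklist Append a blacklisted `chrM` contig (16,299 bp).
#' @param min_length Minimum admissible chromosome length (bp); lengths below
#'   it raise an invalid-config error. Default 10 x 10 kb, i.e. ten bins at
#'   the default working resolution.
#' @return A `genome_spec`.
#' @export
generate_genome <- function(n_chroms, length_range, seed = 1L,
                            with_blacklist = FALSE, min_length = 1e5) {
  if (n_chroms < 1) stop("n_chroms must be >= 1")
  length_range <- rep(as.numeric(length_range), length.out = 2)
  if (any(length_range < min_length))
    stop(sprintf("chromosome lengths below the minimum of %g bp", min_length))
  set.seed(as.integer(seed))
  lens <- if (length_range[1] == length_range[2]) rep(length_range[1], n_chroms)
          else round(stats::runif(n_chroms, length_range[1], length_range[2]))
  names(lens) <- paste0("chr", seq_len(n_chroms))
  bl <- character()
  if (with_blacklist) {
    lens <- c(lens, chrM = 16299)
    bl <- "chrM"
  }
  genome_spec(lens, blacklist = bl)
}
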