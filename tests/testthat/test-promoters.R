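gsP <- genome_spec(c(chr1 = 1e6))

test_that("promoter construction follows the peak-else-window rule", {
  tss <- data.frame(chrom = "chr1", start = c(10000, 10000, 1000),
                    end = c(10001, 10001, 1001),
                    name = c("gA", "gB", "gC"), score = 0,
                    strand = c("+", "+", "+"))
  peaks <- data.frame(chrom = "chr1", start = 9900, end = 10300)
  pr <- build_promoters(tss[1, ], peaks = NULL, genome = gsP)
  expect_equal(c(pr$start, pr$end), c(8000, 10500))
  expect_equal(pr$source, "window")

  pr2 <- build_promoters(tss[2, ], peaks = peaks, genome = gsP)
  expect_equal(c(pr2$start, pr2$end), c(9900, 10300))
  expect_equal(pr2$source, "atac_peak")

  pr3 <- build_promoters(tss[3, ], peaks = NULL, genome = gsP)
  expect_equal(c(pr3$start, pr3$end), c(0, 1500))  # clipped at 0

  # minus strand: window flipped
  tssm <- transform(tss[1, ], strand = "-")
  prm <- build_promoters(tssm, peaks = NULL, genome = gsP)
  expect_equal(c(prm$start, prm$end), c(9500, 12000))

  # overlapping peaks union
  peaks2 <- rbind(peaks, data.frame(chrom = "chr1", start = 9000, end = 10100))
  pru <- build_promoters(tss[2, ], peaks = peaks2, genome = gsP)
  expect_equal(c(pru$start, pru$end), c(9000, 10300))

  expect_warning(build_promoters(transform(tss[1, ], strand = "."),
                                 genome = gsP), "without strand")
  expect_warning(build_promoters(
    data.frame(chrom = "chr1", start = 2e6, end = 2e6 + 1, name = "far",
               score = 0, strand = "+"), genome = gsP), "rejected")
})

test_that("promoter construction matches a brute-force interval oracle", {
  set.seed(55)
  n <- 300
  tss <- data.frame(chrom = "chr1",
                    start = sample.int(9e5, n) + 2e4, name = sprintf("g%03d", 1:n),
                    score = 0, strand = sample(c("+", "-"), n, replace = TRUE))
  tss$end <- tss$start + 1
  np <- 200
  pk <- data.frame(chrom = "chr1", start = sample.int(9.5e5, np))
  pk$end <- pk$start + sample.int(2000, np)
  pr <- build_promoters(tss, peaks = pk, genome = gsP)
  for (r in seq_len(n)) {
    ov <- which(pk$start <= tss$start[r] & pk$end > tss$start[r])
    if (length(ov)) {
      expect_equal(pr$start[r], min(pk$start[ov]))
      expect_equal(pr$end[r], max(pk$end[ov]))
      expect_equal(pr$source[r], "atac_peak")
    } else if (tss$strand[r] == "+") {
      expect_equal(pr$start[r], max(0, tss$start[r] - 2000))
      expect_equal(pr$end[r], tss$start[r] + 500)
    } else {
      expect_equal(pr$start[r], max(0, tss$start[r] - 500))
      expect_equal(pr$end[r], tss$start[r] + 2000)
    }
  }
})

mk_interactions <- function(mid1, mid2, res = 1e4) {
  it <- data.frame(chrom1 = "chr1", mid1 = mid1, chrom2 = "chr1", mid2 = mid2,
                   observed = 5, expected = 1, OE = 5, p = 1e-4, q = 1e-3,
                   infinite_enrichment = FALSE)
  attr(it, "resolution") <- res
  class(it) <- c("interaction_table", "data.frame")
  it
}

test_that("promoter-anchored subsetting uses half-open extended midpoints", {
  prom <- structure(data.frame(chrom = "chr1", start = 100000, end = 101000,
                               gene = "gX", strand = "+", source = "window"),
                    class = c("promoter_set", "data.frame"))
  it <- mk_interactions(mid1 = c(105000, 305000, 115000),
                        mid2 = c(505000, 605000, 505000))
  # side-1 bin [100000,110000) contains the promoter -> retained
  pi <- subset_promoter_interactions(it, prom, 1e4)
  expect_equal(nrow(pi), 1)
  expect_equal(pi$genes1, "gX")
  expect_equal(pi$promoter_side, "1")

  # promoter exactly abutting the extended interval is dropped (half-open):
  # side [110000,120000) vs promoter ending at 110000... end > start fails
  prom_abut <- transform(prom, start = 105000 + 5000, end = 105000 + 6000)
  it_abut <- mk_interactions(mid1 = 105000, mid2 = 505000)
  expect_equal(nrow(subset_promoter_interactions(it_abut,
    structure(prom_abut, class = class(prom)), 1e4)), 0)

  expect_error(subset_promoter_interactions(it, prom, 5e3), "mismatch")
})

test_that("gene-list filtering is exact-match and commutes with subsetting", {
  prom <- structure(data.frame(
    chrom = "chr1", start = c(1e5, 3e5, 5e5), end = c(1e5, 3e5, 5e5) + 1000,
    gene = c("gA", "gB", "gC"), strand = "+", source = "window"),
    class = c("promoter_set", "data.frame"))
  it <- mk_interactions(mid1 = c(105000, 305000, 505000, 705000),
                        mid2 = c(905000, 905000, 905000, 905000))
  pi <- subset_promoter_interactions(it, prom, 1e4)
  expect_equal(nrow(pi), 3)
  expect_true(all(nzchar(paste0(pi$genes1, pi$genes2))))  # non-empty contract

  expect_equal(nrow(filter_by_genes(pi, character())), 0)
  expect_equal(nrow(filter_by_genes(pi, c("gA", "gB", "gC"))), nrow(pi))
  one <- filter_by_genes(pi, "gB")
  expect_equal(nrow(one), 1)
  expect_equal(one$genes1, "gB")
  expect_equal(nrow(filter_by_genes(pi, "ga")), 0)  # case-sensitive

  # subset-then-filter equals filter applied after subsetting on the same input
  a <- filter_by_genes(subset_promoter_interactions(it, prom, 1e4), "gC")
  b <- subset_promoter_interactions(it, prom[prom$gene == "gC", ], 1e4)
  expect_equal(a$mid1, b$mid1)
  expect_equal(a$mid2, b$mid2)
})
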