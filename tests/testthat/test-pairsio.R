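gs2 <- genome_spec(c(chr1 = 1e6, chr2 = 1e6, chrM = 16299), blacklist = "chrM")

mkrec <- function(chrom1, pos1, strand1, chrom2, pos2, strand2) {
  parse_pairs(data.frame(readID = sprintf("r%d", seq_along(chrom1)),
                         chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
                         pos2 = pos2, strand1 = strand1, strand2 = strand2),
              gs2)
}

test_that("parse_pairs normalizes side order and handles rejects", {
  rec <- mkrec("chr2", 100, "+", "chr1", 200, "-")
  expect_equal(rec$chrom1, "chr1")
  expect_equal(rec$pos1, 200)
  expect_equal(rec$strand1, "-")

  rec <- mkrec(c("!", "chr1"), c(0, 300), c("+", "+"),
               c("!", "chr1"), c(0, 100), c("+", "-"))
  expect_equal(rec$mapped, c(FALSE, TRUE))
  expect_equal(rec$pos1[2], 100)  # within-chromosome position swap

  rec <- mkrec(c("chr1", "chr1"), c(100, 2e6), c("+", "+"),
               c("chr1", "chr1"), c(500, 2e6 + 10), c("-", "-"))
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "parse_counts")$out_of_bounds, 1)

  rec <- mkrec(c("chrM", "chr1"), c(10, 10), c("+", "+"),
               c("chrM", "chr1"), c(20, 2000), c("-", "-"))
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "parse_counts")$blacklisted, 1)

  tmp <- tempfile(fileext = ".pairs")
  writeLines(c("## pairs format v1.0", "r1\tchr1\t100\tchr1\t5000\t+\t-",
               "broken line"), tmp)
  expect_warning(rec <- parse_pairs(tmp, gs2), "malformed")
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "parse_counts")$malformed, 1)
})

test_that("is_chimeric matches the enumeration oracle over all configurations", {
  strands <- expand.grid(s1 = c("+", "-"), s2 = c("+", "-"),
                         stringsAsFactors = FALSE)
  cases <- list()
  for (k in seq_len(nrow(strands)))
    for (d in c(0, 1999, 2000, 2001))
      for (same in c(TRUE, FALSE))
        cases[[length(cases) + 1]] <- data.frame(
          s1 = strands$s1[k], s2 = strands$s2[k], d = d, same = same)
  cases <- do.call(rbind, cases)
  rec <- mkrec(rep("chr1", nrow(cases)), rep(5000, nrow(cases)), cases$s1,
               ifelse(cases$same, "chr1", "chr2"), 5000 + cases$d, cases$s2)
  # parse normalization never swaps here: chr1 <= chr2 and pos1 <= pos2
  got <- is_chimeric(rec, 2000)
  oracle <- (!cases$same) | !(cases$s1 == "+" & cases$s2 == "-") |
    (cases$d > 2000)
  expect_equal(got, oracle)
  expect_error(is_chimeric(mkrec("!", 0, "+", "!", 0, "+")), "unmapped")
})

test_that("chimeric worked examples", {
  expect_true(is_chimeric(mkrec("chr1", 100, "+", "chr2", 100, "-")))
  expect_false(is_chimeric(mkrec("chr1", 100, "+", "chr1", 2100, "-")))
  expect_true(is_chimeric(mkrec("chr1", 100, "+", "chr1", 600, "+")))
})

test_that("deduplicate keeps one record per identical 6-tuple", {
  for (k in 1:5) {
    rec <- mkrec(rep("chr1", k), rep(100, k), rep("+", k),
                 rep("chr1", k), rep(5000, k), rep("-", k))
    dd <- deduplicate(sort_pairs(rec))
    expect_equal(sum(dd$duplicate), k - 1)
  }
  # same positions, different strands: not duplicates
  rec <- mkrec(c("chr1", "chr1"), c(100, 100), c("+", "-"),
               c("chr1", "chr1"), c(5000, 5000), c("-", "-"))
  dd <- deduplicate(sort_pairs(rec))
  expect_equal(sum(dd$duplicate), 0)

  unsorted <- mkrec(c("chr1", "chr1"), c(900, 100), c("+", "+"),
                    c("chr1", "chr1"), c(5000, 5000), c("-", "-"))
  expect_error(deduplicate(unsorted), "sorted")
})

test_that("classification thresholds and partition", {
  rec <- mkrec(rep("chr1", 4), c(100, 100, 100, 100), rep("+", 4),
               c("chr1", "chr1", "chr1", "chr2"),
               c(1099, 1100, 10100, 500), rep("-", 4))
  cl <- classify_pairs(deduplicate(sort_pairs(rec)))
  cl <- cl[order(cl$pos2)]
  expect_equal(as.character(cl$category[cl$chrom2 == "chr2"]), "trans")
  expect_true(cl$valid[cl$chrom2 == "chr2"])
  d <- abs(cl$pos2 - cl$pos1)
  expect_equal(as.character(cl$category[d == 999 & cl$chrom2 == "chr1"]),
               "cis_lt_1kb")
  expect_false(cl$valid[d == 999 & cl$chrom2 == "chr1"])
  expect_equal(as.character(cl$category[d == 1000]), "cis_1kb_to_10kb")
  expect_equal(as.character(cl$category[d == 10000]), "cis_ge_10kb")
  expect_true(cl$valid[d == 10000])

  # partition property on a simulated set
  fx <- fx_loops()
  cl <- fx$records
  nodup <- cl[cl$mapped & !cl$duplicate, ]
  tab <- table(nodup$category)
  expect_equal(sum(tab[c("trans", "cis_lt_1kb", "cis_1kb_to_10kb",
                         "cis_ge_10kb")]), nrow(nodup))
  expect_equal(sum(tab[c("unmapped", "duplicate")]), 0)
})

test_that("summarize_pairs reproduces printed accounting and validates input", {
  smry <- summarize_pairs(published_counts)
  pct <- setNames(smry$percent, smry$category)
  expect_equal(unname(pct["Mapped Read Pairs"]), 57.55)
  expect_equal(unname(pct["No-Dup Read Pairs"]), 26.92)
  expect_equal(unname(pct["No-Dup Valid Read Pairs (cis >= 1 kb + trans)"]), 95.20)

  bad <- published_counts
  bad["trans"] <- bad["trans"] + 1
  expect_error(summarize_pairs(bad), "cis \\+ trans = nodup")

  zero <- setNames(rep(0, length(published_counts)), names(published_counts))
  expect_warning(smryz <- summarize_pairs(zero), "degenerate")
  expect_true(all(smryz$percent == 0))
})

test_that("summarize_pairs recovers generator fractions from records", {
  fx <- fx_loops()
  smry <- summarize_pairs(fx$records)
  cnt <- setNames(smry$count, smry$category)
  n_total <- cnt[["Total Read Pairs"]]
  expect_equal(n_total, 1e6)
  # unmapped ~5% of total, dup ~10% of mapped, trans ~30% of no-dup
  expect_lt(abs(cnt[["Unmapped Read Pairs"]] / n_total - 0.05),
            3 * sqrt(0.05 * 0.95 / n_total))
  expect_lt(abs(cnt[["PCR Dup Read Pairs"]] / cnt[["Mapped Read Pairs"]] - 0.10),
            3 * sqrt(0.1 * 0.9 / cnt[["Mapped Read Pairs"]]))
  expect_lt(abs(cnt[["No-Dup Trans Read Pairs"]] / cnt[["No-Dup Read Pairs"]] - 0.30),
            3 * sqrt(0.3 * 0.7 / cnt[["No-Dup Read Pairs"]]))
})

test_that("complexity curve solves the Lander-Waterman model", {
  cc <- complexity_curve(1e6, 5e5, depth_grid = seq(0, 4e6, length.out = 41))
  expect_equal(cc$expected_distinct[1], 0)
  # self-consistency: model reproduces the input point
  fit <- cc$library_size * (1 - exp(-1e6 / cc$library_size))
  expect_lt(abs(fit - 5e5) / 5e5, 1e-6)
  # non-decreasing and concave
  d1 <- diff(cc$expected_distinct)
  expect_true(all(d1 >= 0))
  expect_true(all(diff(d1) <= 1e-6))
  expect_warning(cc2 <- complexity_curve(1e6, 1e6), "no saturation")
  expect_false(cc2$saturation_detectable)
  expect_error(complexity_curve(100, 0), "distinct")
})
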