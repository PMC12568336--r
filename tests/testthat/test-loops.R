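test_that("planted loops are recovered with high precision and recall", {
  fx <- fx_loops()
  calls <- call_loops(fx$cset$cis$chr1, q_threshold = 0.1)
  res <- 1e4
  tb1 <- floor((fx$loops$pos1 - 1) / res)
  tb2 <- floor((fx$loops$pos2 - 1) / res)
  match_truth <- function(b1, b2)
    any(abs(tb1 - b1) <= 1 & abs(tb2 - b2) <= 1)
  tp <- sum(mapply(match_truth, calls$bin1, calls$bin2))
  recall <- mean(mapply(function(a, b)
    any(abs(calls$bin1 - a) <= 1 & abs(calls$bin2 - b) <= 1), tb1, tb2))
  precision <- if (nrow(calls)) tp / nrow(calls) else 0
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)

  # stricter threshold yields a subset of calls
  calls05 <- call_loops(fx$cset$cis$chr1, q_threshold = 0.05)
  key <- function(x) paste(x$bin1, x$bin2)
  expect_true(all(key(calls05) %in% key(calls)))

  expect_error(call_loops(fx$cset$cis$chr2), "balanced")
})

test_that("loop-free fixtures produce essentially no calls", {
  fx <- fx_null()
  calls <- call_loops(fx$cm, q_threshold = 0.1)
  n <- fx$cm$nbins
  tested_pixels <- sum(vapply(2:min(1000, n - 1), function(d)
    sum(!fx$cm$mask[seq_len(n - d)] & !fx$cm$mask[seq_len(n - d) + d]), 1))
  expect_lte(nrow(calls), tested_pixels / 1e4)
})

test_that("distance histogram respects category boundaries and partitions", {
  mk <- function(d) data.frame(distance = d)
  h <- distance_histogram(mk(c(2e5, 199999, 4e5, 1e6, 1000001, 750000)))
  cnt <- setNames(h$count, as.character(h$category))
  expect_equal(unname(cnt["<200 kb"]), 1)        # 199,999
  expect_equal(unname(cnt["200-400 kb"]), 1)     # exactly 200 kb
  expect_equal(unname(cnt["400-600 kb"]), 1)     # exactly 400 kb
  expect_equal(unname(cnt["600-800 kb"]), 1)     # 750 kb
  expect_equal(unname(cnt["800 kb-1 Mb"]), 1)    # exactly 1 Mb
  expect_equal(unname(cnt[">1 Mb"]), 1)          # 1,000,001
  expect_equal(sum(h$count), 6)

  h0 <- distance_histogram(mk(numeric()))
  expect_true(all(h0$count == 0))
  expect_true(all(h0$fraction == 0))

  fx <- fx_loops()
  calls <- call_loops(fx$cset$cis$chr1)
  hh <- distance_histogram(calls)
  expect_equal(sum(hh$count), nrow(calls))
})

test_that("anchor annotation flags overlap and classifies accessible anchors", {
  loops <- data.frame(chrom = "chr1",
                      bin1 = c(0, 10), bin2 = c(50, 60),
                      start1 = c(0, 1e5), end1 = c(1e4, 1.1e5),
                      start2 = c(5e5, 6e5), end2 = c(5.1e5, 6.1e5),
                      distance = c(5e5, 5e5), observed = 5,
                      exp_donut = 1, exp_ll = 1, exp_h = 1, exp_v = 1,
                      p = 0.01, q = 0.01)
  class(loops) <- c("loop_calls", "data.frame")
  atac <- data.frame(chrom = "chr1", start = c(5000, 5.05e5), end = c(6000, 5.06e5))
  me1 <- data.frame(chrom = "chr1", start = 5500, end = 5600)
  ann <- annotate_anchors(loops, atac, marks = list(H3K4me1 = me1))
  a <- ann$anchors
  expect_equal(sum(a$accessible), 2)
  expect_equal(a$class[a$start == 0], "me1_only")
  expect_equal(a$class[a$start == 5e5], "neither")
  expect_true(all(is.na(a$class[!a$accessible])))

  # exact abutment is no overlap under half-open semantics
  abut <- data.frame(chrom = "chr1", start = 1e4, end = 2e4)
  ann2 <- annotate_anchors(loops, abut)
  expect_false(ann2$anchors$accessible[ann2$anchors$start == 0])

  # empty marks: every accessible anchor is "neither"
  ann3 <- annotate_anchors(loops, atac, marks = list())
  expect_true(all(ann3$anchors$class[ann3$anchors$accessible] == "neither"))
})

test_that("interval intersection agrees with the all-pairs oracle", {
  set.seed(77)
  n <- 600
  mkiv <- function(n) {
    st <- sample.int(1e6, n)
    data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = st, end = st + sample.int(5000, n))
  }
  x <- mkiv(n); y <- mkiv(n)
  got <- loopscape:::overlaps_any(x, y)
  expect_equal(got, overlap_oracle(x, y))
})

test_that("deletion overlap reports the planted loop and deduplicates", {
  fx <- fx_loops()
  ann <- generate_annotations(fx$genome, fx$sim$truth, seed = 3,
                              deletion_over_loop = 1, n_deletions = 2)
  calls <- call_loops(fx$cset$cis$chr1)
  ov <- overlap_variants(calls, ann$deletions)
  planted <- ov$by_loop[grepl("del_loop1", ov$by_loop$deletion), ]
  expect_gte(nrow(planted), 1)
  # at least one reported loop sits at the first planted loop's anchors
  truth <- fx$sim$truth$loops[1, ]
  res <- 1e4
  expect_true(any(
    abs(calls$bin2[planted$loop_index] - floor((truth$pos2 - 1) / res)) <= 1 &
    abs(calls$bin1[planted$loop_index] - floor((truth$pos1 - 1) / res)) <= 1))

  # a deletion spanning both anchors is reported once per loop
  loops1 <- calls[1, , drop = FALSE]
  span <- data.frame(chrom = loops1$chrom, start = loops1$start1 - 10,
                     end = loops1$end2 + 10, name = "span")
  ov2 <- overlap_variants(loops1, span)
  expect_equal(nrow(ov2$by_loop), 1)
  expect_equal(ov2$by_loop$anchors_hit, "1,2")

  ov3 <- overlap_variants(calls, data.frame(chrom = character(),
                                            start = numeric(), end = numeric(),
                                            name = character()))
  expect_equal(nrow(ov3$by_loop), 0)
})
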