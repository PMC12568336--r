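test_that("generate_genome is deterministic and honors config", {
  g1 <- generate_genome(1, 1e6, seed = 7)
  expect_equal(unname(g1$lengths), 1e6)
  expect_equal(g1$chroms, "chr1")

  g2a <- generate_genome(2, c(5e6, 9e6), seed = 3)
  g2b <- generate_genome(2, c(5e6, 9e6), seed = 3)
  expect_identical(g2a, g2b)

  g3 <- generate_genome(3, 2e6, seed = 1, with_blacklist = TRUE)
  expect_true("chrM" %in% g3$chroms)
  expect_equal(g3$blacklist, "chrM")
  expect_false("chrM" %in% analysis_chroms(g3))

  expect_error(generate_genome(1, 5e4, seed = 1), "minimum")
  expect_error(genome_spec(c(chr1 = 1e6), blacklist = "chrX"), "subset")
})

test_that("simulated fractions match the stated world within 3 binomial s.e.", {
  genome <- genome_spec(c(chr1 = 20e6, chr2 = 10e6))
  params <- sim_params(n_pairs = 1e5, alpha = 1, trans_frac = 0.30,
                       dup_rate = 0.10, unmapped_rate = 0.05, seed = 99)
  sim <- simulate_pairs(genome, params)
  expect_equal(nrow(sim$pairs), 1e5)

  rec <- process_pairs(sim$pairs, genome)
  n_unm <- sum(!rec$mapped)
  se_u <- sqrt(0.05 * 0.95 / 1e5)
  expect_lt(abs(n_unm / 1e5 - 0.05), 3 * se_u)

  n_mapped <- sum(rec$mapped)
  n_dup <- sum(rec$duplicate)
  se_d <- sqrt(0.10 * 0.90 / n_mapped)
  expect_lt(abs(n_dup / n_mapped - 0.10), 3 * se_d)

  nodup <- rec[rec$mapped & !rec$duplicate, ]
  n_trans <- sum(nodup$chrom1 != nodup$chrom2)
  se_t <- sqrt(0.30 * 0.70 / nrow(nodup))
  expect_lt(abs(n_trans / nrow(nodup) - 0.30), 3 * se_t)
})

test_that("zero-loop params give empty truth and the fixture is reproducible", {
  genome <- genome_spec(c(chr1 = 2e6))
  params <- sim_params(n_pairs = 5000, comp_strength = 1, trans_frac = 0,
                       seed = 4)
  a <- simulate_pairs(genome, params)
  b <- simulate_pairs(genome, params)
  expect_equal(nrow(a$truth$loops), 0)
  expect_identical(as.data.frame(a$pairs), as.data.frame(b$pairs))
  expect_identical(a$truth$compartments, b$truth$compartments)
  annA <- generate_annotations(genome, a$truth, seed = 2)
  annB <- generate_annotations(genome, a$truth, seed = 2)
  expect_identical(annA, annB)
})

test_that("cis distances follow the discretized power law (log-log slope)", {
  fx <- fx_slope(1.0)
  p <- fx$sim$pairs
  d <- abs(p$pos2 - p$pos1)[p$chrom1 == p$chrom2 & p$chrom1 != "!"]
  br <- 10^seq(log10(1000), log10(5e7), by = 0.125)
  h <- hist(d, breaks = c(br, 1e9), plot = FALSE)
  dens <- h$counts[seq_len(length(br) - 1)] / diff(br)
  mid <- sqrt(br[-length(br)] * br[-1])
  ok <- dens > 0 & mid >= 3e4 & mid <= 3e6
  slope <- unname(coef(lm(log10(dens[ok]) ~ log10(mid[ok])))[2])
  expect_lt(abs(slope - (-1.0)), 0.1)
})

test_that("planted loop bin pairs exceed distance-matched background", {
  fx <- fx_loops()
  cm <- fx$cset$cis$chr1
  tri <- loopscape:::cm_triplets(cm)
  res <- 1e4
  lb1 <- floor((fx$loops$pos1 - 1) / res)
  lb2 <- floor((fx$loops$pos2 - 1) / res)
  for (i in seq_along(lb1)) {
    obs <- tri$count[tri$bin1 == lb1[i] & tri$bin2 == lb2[i]]
    obs <- if (length(obs)) obs else 0
    d <- lb2[i] - lb1[i]
    bg <- mean(tri$count[tri$bin2 - tri$bin1 == d &
                           !(tri$bin1 == lb1[i] & tri$bin2 == lb2[i])])
    expect_gt(obs, bg)
  }
})

test_that("annotation fixtures respect the anchor-marking fraction", {
  fx <- fx_loops()
  ann0 <- generate_annotations(fx$genome, fx$sim$truth, seed = 1,
                               frac_anchors_marked = 0)
  ann1 <- generate_annotations(fx$genome, fx$sim$truth, seed = 1,
                               frac_anchors_marked = 1)
  res <- 1e4
  anchors <- unique(rbind(
    data.frame(chrom = fx$loops$chrom,
               start = floor((fx$loops$pos1 - 1) / res) * res),
    data.frame(chrom = fx$loops$chrom,
               start = floor((fx$loops$pos2 - 1) / res) * res)))
  anchors$end <- anchors$start + res
  hit0 <- overlap_oracle(anchors, ann0$atac)
  hit1 <- overlap_oracle(anchors, ann1$atac)
  expect_false(any(hit0))
  expect_true(all(hit1))
})

test_that("invalid loop anchors are rejected", {
  genome <- genome_spec(c(chr1 = 1e6))
  bad <- data.frame(chrom = "chr1", pos1 = 1e5, pos2 = 2e6, multiplier = 5)
  params <- sim_params(n_pairs = 1000, loops = bad, seed = 1)
  expect_error(simulate_pairs(genome, params), "outside")
  expect_error(sim_params(n_pairs = 10, loops = data.frame(
    chrom = "chr1", pos1 = 1, pos2 = 2, multiplier = 1)), "> 1")
})
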