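test_that("binning arithmetic and mass conservation", {
  gs <- genome_spec(c(chr1 = 1e5))
  rec <- parse_pairs(data.frame(
    readID = c("a", "b", "c"), chrom1 = "chr1", pos1 = c(1, 15000, 15000),
    chrom2 = "chr1", pos2 = c(10001, 25000, 25000),
    strand1 = "+", strand2 = "-"), gs)
  cset <- bin_pairs(rec, gs, 1e4)
  tri <- loopscape:::cm_triplets(cset$cis$chr1)
  expect_equal(tri$count[tri$bin1 == 0 & tri$bin2 == 1], 1)
  expect_equal(tri$count[tri$bin1 == 1 & tri$bin2 == 2], 2)
  expect_error(bin_pairs(rec, gs, 0), "resolution")

  fx <- fx_loops()
  mass <- sum(vapply(fx$cset$cis, function(cm) sum(cm$counts@x), 1)) +
    sum(vapply(fx$cset$trans, function(m) sum(m@x), 1))
  expect_equal(mass, fx$cset$n_valid)
  expect_equal(fx$cset$n_valid, sum(fx$records$valid))
})

test_that("ICE balancing: uniform fixed point, marginal uniformity, idempotence", {
  # uniform off-diagonal matrix is a fixed point (equal weights)
  n <- 30
  U <- matrix(1, n, n)
  cmU <- loopscape:::contact_matrix(
    Matrix::Matrix(U * upper.tri(U, diag = TRUE), sparse = TRUE), "chrU", 1e4)
  bU <- balance(cmU, mask_quantile = 0)
  w <- bU$weights[!bU$mask]
  expect_lt(diff(range(w)) / mean(w), 1e-4)

  fx <- fx_tad()
  cm <- fx$cm
  expect_true(cm$ice$converged)
  # balanced marginals uniform within tolerance on unmasked bins
  M <- loopscape:::cm_dense(cm, balanced = TRUE)
  marg <- rowSums(M, na.rm = TRUE)[!cm$mask]
  expect_lt(max(abs(marg / mean(marg) - 1)), 1e-3)
  # idempotence: balancing the balanced matrix barely changes weights
  bal <- loopscape:::contact_matrix(
    Matrix::Matrix(ifelse(is.na(M), 0, M) * upper.tri(M, diag = TRUE),
                   sparse = TRUE), cm$chrom, cm$resolution)
  b2 <- balance(bal, mask_quantile = 0)
  w2 <- b2$weights[!cm$mask & !b2$mask]
  expect_lt(stats::sd(w2) / mean(w2), 1e-3)

  # all-zero row is masked with undefined weight
  Z <- matrix(0, 10, 10); Z[1, 2] <- 5; Z[2, 3] <- 5; Z[1, 3] <- 5
  cmZ <- loopscape:::contact_matrix(Matrix::Matrix(Z, sparse = TRUE), "z", 1e4)
  bZ <- balance(cmZ, mask_quantile = 0)
  expect_true(bZ$mask[10])
  expect_true(is.na(bZ$weights[10]))
})

test_that("coverage track and cis/total ratio", {
  gs <- genome_spec(c(chr1 = 2e6, chr2 = 2e6))
  params <- sim_params(n_pairs = 5e4, trans_frac = 0.4, dup_rate = 0,
                       unmapped_rate = 0, seed = 13)
  sim <- simulate_pairs(gs, params)
  cset <- bin_pairs(process_pairs(sim$pairs, gs), gs, 1e4)
  cov <- coverage(cset)
  expect_true(all(cov$track$cis <= cov$track$total))
  expect_lt(abs(cov$mean_ratio - 0.6), 0.03)

  # cis-only fixture: ratio 1 wherever covered
  params0 <- sim_params(n_pairs = 2e4, trans_frac = 0, dup_rate = 0,
                        unmapped_rate = 0, seed = 13)
  sim0 <- simulate_pairs(gs, params0)
  cov0 <- coverage(bin_pairs(process_pairs(sim0$pairs, gs), gs, 1e4))
  expect_true(all(cov0$track$ratio[!is.na(cov0$track$ratio)] == 1))
  expect_true(all(is.na(cov0$track$ratio[cov0$track$total == 0])))
})

test_that("decay curve recovers the exponent and integrates to unit mass", {
  fx <- fx_slope(1.0)
  dec <- contact_decay(fx$cset)
  expect_lt(abs(fit_decay_slope(dec) - (-1.0)), 0.1)
  allc <- dec[dec$chrom == "all" & !is.na(dec$prob), ]
  expect_equal(sum(allc$prob * allc$n_pairs), 1, tolerance = 1e-9)
})

test_that("same-alpha chromosomes give similar decay profiles", {
  gs <- genome_spec(c(chr1 = 10e6, chr2 = 10e6))
  params <- sim_params(n_pairs = 2e5, alpha = 1, trans_frac = 0, dup_rate = 0,
                       unmapped_rate = 0, seed = 17)
  sim <- simulate_pairs(gs, params)
  cset <- bin_pairs(process_pairs(sim$pairs, gs), gs, 1e4)
  dec <- contact_decay(cset)
  s1 <- fit_decay_slope(dec, chrom = "chr1", range = c(3e4, 3e6))
  s2 <- fit_decay_slope(dec, chrom = "chr2", range = c(3e4, 3e6))
  expect_lt(abs(s1 - s2), 0.1)
})

test_that("fixed-bin view aggregates to 100 bins per chromosome, conserving mass", {
  gs <- genome_spec(c(chr1 = 1e6, chr2 = 2e6))
  params <- sim_params(n_pairs = 2e4, trans_frac = 0.3, dup_rate = 0,
                       unmapped_rate = 0, seed = 19)
  sim <- simulate_pairs(gs, params)
  cset <- bin_pairs(process_pairs(sim$pairs, gs), gs, 1e4)
  fv <- fixed_bin_view(cset, n_bins = 100)
  expect_equal(dim(fv$matrix), c(200, 200))
  # upper-triangle mass equals the number of valid pairs
  upper <- sum(fv$matrix[upper.tri(fv$matrix, diag = TRUE)])
  expect_equal(upper, cset$n_valid)
  # 1 Mb chromosome at 10 kb: each coarse bin pools exactly one native bin
  cm <- cset$cis$chr1
  native <- as.matrix(cm$counts)
  native <- native + t(native) - diag(diag(native), nrow(native))
  expect_equal(unname(fv$matrix[1:100, 1:100]), unname(native))
  expect_warning(fixed_bin_view(
    bin_pairs(process_pairs(sim$pairs, gs), gs, 2e4), n_bins = 100),
    "native bins")
})

test_that("replicate correlation behaves as expected", {
  # dense-enough replicates: 2e5 pairs on 5 Mb at 20 kb bins
  gs <- genome_spec(c(chr1 = 5e6))
  p1 <- sim_params(n_pairs = 2e5, trans_frac = 0, dup_rate = 0,
                   unmapped_rate = 0, seed = 31)
  p2 <- sim_params(n_pairs = 2e5, trans_frac = 0, dup_rate = 0,
                   unmapped_rate = 0, seed = 32)
  csA <- bin_pairs(process_pairs(simulate_pairs(gs, p1)$pairs, gs), gs, 2e4)
  csB <- bin_pairs(process_pairs(simulate_pairs(gs, p2)$pairs, gs), gs, 2e4)
  expect_equal(correlate_replicates(csA, csA), 1)
  r_indep <- correlate_replicates(csA, csB)
  expect_lt(r_indep, 1)
  expect_gt(r_indep, 0.5)  # same decay structure correlates strongly
  # permuted-bin copy: destroy the distance structure
  cmA <- csA$cis$chr1
  set.seed(1)
  perm <- sample(cmA$nbins)
  MA <- as.matrix(cmA$counts)
  MA <- MA + t(MA) - diag(diag(MA), nrow(MA))
  MP <- MA[perm, perm]
  MP[lower.tri(MP)] <- 0
  csP <- csA
  csP$cis$chr1 <- loopscape:::contact_matrix(
    Matrix::Matrix(MP, sparse = TRUE), "chr1", 2e4)
  r_perm <- correlate_replicates(csA, csP)
  expect_lt(abs(r_perm), 0.2)
  expect_gt(r_indep, r_perm)
})
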