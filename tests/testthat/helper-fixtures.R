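# Shared synthetic fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx_cache))
    assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

process_pairs <- function(pairs, genome) {
  classify_pairs(deduplicate(sort_pairs(parse_pairs(pairs, genome))))
}

# five planted loops at 10x enrichment, 1e6 pairs, two chromosomes
fx_loops <- function() fixture("loops", function() {
  genome <- genome_spec(c(chr1 = 20e6, chr2 = 10e6))
  loops <- data.frame(
    chrom = "chr1",
    pos1 = c(2e6, 5e6, 8e6, 11e6, 3e6) + 5000,
    pos2 = c(2.5e6, 6.2e6, 8.4e6, 12.5e6, 3.8e6) + 5000,
    multiplier = 10)
  params <- sim_params(n_pairs = 1e6, alpha = 1, trans_frac = 0.3,
                       dup_rate = 0.10, unmapped_rate = 0.05,
                       comp_strength = 1, loops = loops, seed = 42)
  sim <- simulate_pairs(genome, params)
  rec <- process_pairs(sim$pairs, genome)
  cset <- bin_pairs(rec, genome, 1e4)
  cset$cis$chr1 <- balance(cset$cis$chr1)
  list(genome = genome, params = params, sim = sim, records = rec,
       cset = cset, loops = loops)
})

# four planted TAD boundaries at 4x contrast
fx_tad <- function() fixture("tad", function() {
  genome <- genome_spec(c(chr1 = 10e6))
  bnd <- list(chr1 = c(2e6, 4e6, 6e6, 8e6))
  params <- sim_params(n_pairs = 1e6, alpha = 1, trans_frac = 0,
                       dup_rate = 0, unmapped_rate = 0, comp_strength = 1,
                       tad_boundaries = bnd, tad_strength = 4, seed = 8)
  sim <- simulate_pairs(genome, params)
  cm <- balance(bin_pairs(process_pairs(sim$pairs, genome), genome, 1e4)$cis$chr1)
  list(genome = genome, boundaries = bnd, cm = cm,
       truth_bins = bnd$chr1 / 1e4)
})

# compartment checkerboard (500 kb blocks, 3x strength) at 50 kb bins
fx_checker <- function() fixture("checker", function() {
  genome <- genome_spec(c(chr1 = 10e6))
  params <- sim_params(n_pairs = 4e5, alpha = 1, trans_frac = 0,
                       dup_rate = 0, unmapped_rate = 0,
                       comp_block = 5e5, comp_strength = 3, seed = 7)
  sim <- simulate_pairs(genome, params)
  cm <- balance(bin_pairs(process_pairs(sim$pairs, genome), genome, 5e4)$cis$chr1)
  res <- 5e4
  truth_label <- ifelse(
    floor(((seq_len(cm$nbins) - 1) * res) / 5e5) %% 2 == 0, "A", "B")
  orientation <- as.numeric(truth_label == "A")
  list(genome = genome, cm = cm, truth_label = truth_label,
       orientation = orientation)
})

# structure-free power-law worlds for decay-slope recovery
fx_slope <- function(alpha) fixture(paste0("slope", alpha), function() {
  genome <- genome_spec(c(chr1 = 50e6))
  params <- sim_params(n_pairs = 4e5, alpha = alpha, trans_frac = 0,
                       dup_rate = 0, unmapped_rate = 0, seed = 11)
  sim <- simulate_pairs(genome, params)
  cset <- bin_pairs(process_pairs(sim$pairs, genome), genome, 1e4)
  list(genome = genome, sim = sim, cset = cset)
})

# loop-free null for false-positive calibration
fx_null <- function() fixture("null", function() {
  genome <- genome_spec(c(chr1 = 10e6))
  params <- sim_params(n_pairs = 5e5, alpha = 1, trans_frac = 0,
                       dup_rate = 0, unmapped_rate = 0, seed = 5)
  sim <- simulate_pairs(genome, params)
  cm <- balance(bin_pairs(process_pairs(sim$pairs, genome), genome, 1e4)$cis$chr1)
  list(genome = genome, cm = cm)
})

# brute-force interval overlap oracle on BED-style (0-based half-open) frames
overlap_oracle <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i)
    any(y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i]),
    TRUE)
}

# printed read-accounting counts of the study's filtered dataset (Table-1
# style worked example used by the summarize acceptance checks)
published_counts <- c(
  total = 570717912, unmapped = 69526854, mapped = 328428402,
  duplicate = 174768612, nodup = 153659790,
  cis = 107423553, trans = 46236237, valid = 146280218,
  cis_lt_1kb = 7379572, cis_ge_1kb = 100043981, cis_ge_10kb = 78354494)
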