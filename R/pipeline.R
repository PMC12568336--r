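#' Pipeline configuration
#'
#' Bundles every stage's inputs and tunables with full defaulting. Inputs
#' are either in-memory objects (a `genome_spec`, pair records, BED-style
#' data.frames) or file paths (chrom.sizes, .pairs, BED); paths are
#' validated at construction so a missing file fails before any compute.
#' When `pairs` is NULL a synthetic fixture is generated from `sim` and the
#' annotation fixtures are derived from its planted truth.
#'
#' @param genome `genome_spec` or chrom.sizes path (required).
#' @param pairs .pairs path, a `pair_records`-compatible data.frame, or NULL
#'   to simulate from `sim`.
#' @param sim A `sim_params` used when `pairs` is NULL.
#' @param blacklist Blacklist chromosomes (applied when `genome` is a path).
#' @param resolution Working bin size in bp (default 10 kb).
#' @param chimeric_threshold Distance cutoff for the chimeric filter
#'   (default 2000 bp).
#' @param ice_tol,ice_max_iter ICE balancing controls.
#' @param insulation_window Insulation diamond window in bp (default 100 kb).
#' @param delta_threshold Boundary delta threshold (default 0.05).
#' @param expected_strata Equal-occupancy strata for the expected model
#'   (default 100).
#' @param loop_q Loop-call FDR threshold (default 0.1).
#' @param donut_radius,donut_inner Loop-caller neighborhood geometry.
#' @param atac,h3k4me1,h3k4me3,h3k27ac,ctcf,tss,deletions BED paths or
#'   BED-style data.frames; NULL values fall back to generated fixtures when
#'   simulating, or disable the stage otherwise.
#' @param genes Gene list: character vector or one-symbol-per-line file.
#' @param seed Integer seed driving every random choice.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, pairs = NULL, sim = NULL,
                            blacklist = character(),
                            resolution = 1e4, chimeric_threshold = 2000,
                            ice_tol = 1e-5, ice_max_iter = 200,
                            insulation_window = 1e5, delta_threshold = 0.05,
                            expected_strata = 100,
                            loop_q = 0.1, donut_radius = 5, donut_inner = 2,
                            atac = NULL, h3k4me1 = NULL, h3k4me3 = NULL,
                            h3k27ac = NULL, ctcf = NULL, tss = NULL,
                            deletions = NULL, genes = NULL, seed = 1L) {
  stopifnot(resolution > 0, chimeric_threshold >= 0,
            ice_tol > 0, ice_max_iter >= 1,
            insulation_window >= 2 * resolution, delta_threshold >= 0,
            expected_strata >= 1, loop_q > 0, loop_q < 1,
            donut_radius > donut_inner, donut_inner >= 1)
  if (is.null(pairs) && is.null(sim))
    stop("either pairs or sim must be given")
  cfg <- list(genome = genome, pairs = pairs, sim = sim,
              blacklist = blacklist, resolution = resolution,
              chimeric_threshold = chimeric_threshold, ice_tol = ice_tol,
              ice_max_iter = ice_max_iter,
              insulation_window = insulation_window,
              delta_threshold = delta_threshold,
              expected_strata = expected_strata, loop_q = loop_q,
              donut_radius = donut_radius, donut_inner = donut_inner,
              atac = atac, h3k4me1 = h3k4me1, h3k4me3 = h3k4me3,
              h3k27ac = h3k27ac, ctcf = ctcf, tss = tss,
              deletions = deletions, genes = genes, seed = as.integer(seed))
  for (nm in c("genome", "pairs", "atac", "h3k4me1", "h3k4me3", "h3k27ac",
               "ctcf", "tss", "deletions", "genes")) {
    v <- cfg[[nm]]
    if (is.character(v) && length(v) == 1 && !file.exists(v))
      stop(sprintf("config error: %s file does not exist: %s", nm, v))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_bed <- function(x) {
  if (is.null(x)) NULL
  else if (is.character(x)) read_bed(x)
  else as.data.frame(x)
}

# per-bin interval density track for E1 orientation
peak_density_track <- function(bed, chrom, nbins, resolution) {
  v <- numeric(nbins)
  if (is.null(bed)) return(v)
  b <- bed[bed$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(b))) {
    lo <- max(0, floor(b$start[r] / resolution))
    hi <- min(nbins - 1, floor((b$end[r] - 1) / resolution))
    v[(lo:hi) + 1] <- v[(lo:hi) + 1] + 1
  }
  v
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- pair QC (parse, chimeric filter, dedup,
#' classification, accounting), contact matrices and balancing, coverage
#' and decay, compartments, insulation/boundaries, distance-stratified
#' significance, loop calling with anchor annotation and deletion overlap,
#' and promoter-anchored interaction extraction -- and returns a report
#' bundle whose every number is recomputable from the returned stage
#' outputs. The run is deterministic for a fixed config and seed. A stage
#' failure aborts with the stage name, preserving partial outputs in the
#' error's `partial` attribute.
#'
#' @param config A `pipeline_config`.
#' @return List of class `pipeline_report`; see the elements `summary`,
#'   `qc`, `matrices`, `coverage`, `decay`, `compartments`, `insulation`,
#'   `boundaries`, `interactions`, `loops`, `loop_histogram`, `anchors`,
#'   `variant_overlap`, `promoters`, `promoter_interactions`, `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                 conditionMessage(e)))
      attr(err, "partial") <- out
      stop(err)
    })
  }

  genome <- stage("genome", {
    if (inherits(config$genome, "genome_spec")) config$genome
    else read_chrom_sizes(config$genome, blacklist = config$blacklist)
  })

  truth <- NULL
  ann <- list(atac = resolve_bed(config$atac),
              h3k4me1 = resolve_bed(config$h3k4me1),
              h3k4me3 = resolve_bed(config$h3k4me3),
              h3k27ac = resolve_bed(config$h3k27ac),
              ctcf = resolve_bed(config$ctcf),
              tss = resolve_bed(config$tss),
              deletions = resolve_bed(config$deletions))
  raw <- stage("input", {
    if (!is.null(config$pairs)) {
      config$pairs
    } else {
      sim <- simulate_pairs(genome, config$sim)
      truth <- sim$truth
      gen <- generate_annotations(genome, truth, seed = config$seed,
                                  deletion_over_loop =
                                    if (nrow(truth$loops) > 0) 1L else NA)
      for (nm in names(gen)) if (is.null(ann[[nm]])) ann[[nm]] <- gen[[nm]]
      sim$pairs
    }
  })

  qc <- stage("pairsio", {
    rec <- parse_pairs(raw, genome)
    rec <- filter_chimeric(rec, config$chimeric_threshold)
    rec <- deduplicate(sort_pairs(rec))
    rec <- classify_pairs(rec)
    list(records = rec, summary = summarize_pairs(rec))
  })
  out$qc <- qc$summary

  cset <- stage("matrixops", {
    cs <- bin_pairs(qc$records, genome, config$resolution)
    balance_all(cs, tol = config$ice_tol, max_iter = config$ice_max_iter)
  })
  out$matrices <- cset
  out$coverage <- stage("coverage", coverage(cset))
  out$decay <- stage("decay", contact_decay(cset))
  out$decay_slope <- stage("decay", tryCatch(
    fit_decay_slope(out$decay), error = function(e) NA_real_))

  out$compartments <- stage("compartments", {
    lapply(names(cset$cis), function(ch) {
      cm <- cset$cis[[ch]]
      orient <- if (!is.null(ann$atac))
        peak_density_track(ann$atac, ch, cm$nbins, config$resolution)
      else rep(1, cm$nbins)
      tryCatch(compartment_eigenvector(cm, orient),
               error = function(e) structure(list(error = conditionMessage(e)),
                                             class = "compartment_track"))
    }) |> stats::setNames(names(cset$cis))
  })

  out$insulation <- stage("domains", lapply(cset$cis, insulation,
                                            window = config$insulation_window))
  out$boundaries <- stage("domains", {
    b <- lapply(out$insulation, call_boundaries,
                delta_threshold = config$delta_threshold)
    do.call(rbind, c(b, make.row.names = FALSE))
  })

  out$interactions <- stage("significance", {
    tabs <- lapply(cset$cis, function(cm) {
      if (sum(cm$counts@x) == 0) return(NULL)
      test_interactions(cm, fit_expected(cm, n_strata = config$expected_strata))
    })
    tab <- do.call(rbind, c(tabs[!vapply(tabs, is.null, TRUE)],
                            make.row.names = FALSE))
    attr(tab, "resolution") <- config$resolution
    class(tab) <- c("interaction_table", "data.frame")
    tab
  })

  out$loops <- stage("loops", call_loops_all(
    cset, q_threshold = config$loop_q, donut_radius = config$donut_radius,
    donut_inner = config$donut_inner))
  out$loop_histogram <- stage("loops", distance_histogram(out$loops))
  out$anchors <- stage("loops", {
    if (!is.null(ann$atac))
      annotate_anchors(out$loops, ann$atac,
                       marks = Filter(Negate(is.null),
                                      list(H3K4me1 = ann$h3k4me1,
                                           H3K4me3 = ann$h3k4me3,
                                           H3K27ac = ann$h3k27ac,
                                           CTCF = ann$ctcf)))
    else NULL
  })
  out$variant_overlap <- stage("loops", {
    if (!is.null(ann$deletions)) overlap_variants(out$loops, ann$deletions)
    else NULL
  })

  out$promoters <- stage("promoters", {
    if (!is.null(ann$tss))
      build_promoters(ann$tss, peaks = ann$atac, genome = genome)
    else NULL
  })
  out$promoter_interactions <- stage("promoters", {
    if (!is.null(out$promoters) && nrow(out$interactions) > 0) {
      pint <- subset_promoter_interactions(out$interactions, out$promoters,
                                           config$resolution)
      genes <- config$genes
      if (is.character(genes) && length(genes) == 1 && file.exists(genes))
        genes <- readLines(genes)
      if (!is.null(genes)) pint <- filter_by_genes(pint, genes)
      pint
    } else NULL
  })

  out$truth <- truth
  out$summary <- stage("report", list(
    accounting = qc$summary,
    decay_slope = out$decay_slope,
    mean_cis_ratio = out$coverage$mean_ratio,
    n_compartment_bins = sum(vapply(out$compartments, function(x)
      if (!is.null(x$E1)) sum(!is.na(x$E1)) else 0L, 1)),
    n_boundaries = nrow(out$boundaries),
    n_loops = nrow(out$loops),
    loop_histogram = out$loop_histogram,
    anchor_summary = if (!is.null(out$anchors)) out$anchors$summary else NULL,
    n_promoter_interactions = if (!is.null(out$promoter_interactions))
      nrow(out$promoter_interactions) else NA_integer_))
  class(out) <- "pipeline_report"
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  decay slope: %.3f | mean cis ratio: %.3f\n",
              x$summary$decay_slope, x$summary$mean_cis_ratio))
  cat(sprintf("  boundaries: %d | loops: %d\n",
              x$summary$n_boundaries, x$summary$n_loops))
  invisible(x)
}
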