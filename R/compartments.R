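#' Observed/expected transform of a cis matrix
#'
#' Divides every diagonal of the dense (optionally balanced) matrix by its
#' mean over unmasked bin pairs, removing the distance-decay expectation.
#'
#' @param cm A `contact_matrix`.
#' @param balanced Use balancing weights (default TRUE).
#' @return Dense symmetric O/E matrix with NA on masked bins.
#' @export
oe_matrix <- function(cm, balanced = TRUE) {
  M <- cm_dense(cm, balanced = balanced)
  n <- nrow(M)
  for (d in 0:(n - 1)) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    mu <- mean(M[idx], na.rm = TRUE)
    v <- if (!is.na(mu) && mu > 0) M[idx] / mu else NA_real_
    M[idx] <- v
    M[idx[, c(2, 1), drop = FALSE]] <- v
  }
  M
}

#' A/B compartment eigenvector (E1)
#'
#' Calls compartments per chromosome from a balanced cis matrix: the O/E
#' matrix is computed by dividing each diagonal by its mean, the Pearson
#' correlation matrix of O/E columns is eigendecomposed, and the eigenvector
#' with the largest-magnitude eigenvalue is taken as E1. Its sign is
#' oriented so that E1 correlates positively with an external activity track
#' (e.g. ATAC or gene density per bin): bins with E1 > 0 are labelled A
#' (transcriptionally active), E1 < 0 B (inactive).
#'
#' @param cm A balanced `contact_matrix`.
#' @param orientation Numeric per-bin activity track, length `nbins`.
#' @param min_bins Minimum usable (unmasked) bins for a stable eigenvector
#'   (default 20); fewer aborts.
#' @return List of class `compartment_track`: `E1` (NA on masked bins),
#'   `label` ("A"/"B"/NA), `orientation_r` (correlation with the track;
#'   |r| < 0.1 is flagged `ambiguous`), `eigenvalue`.
#' @export
compartment_eigenvector <- function(cm, orientation, min_bins = 20) {
  if (!cm$balanced) stop("matrix must be balanced")
  if (length(orientation) != cm$nbins)
    stop("orientation track must have one value per bin")
  usable <- which(!cm$mask)
  if (length(usable) < min_bins)
    stop(sprintf("only %d usable bins (< %d): matrix too sparse for a stable eigenvector",
                 length(usable), min_bins))
  OE <- oe_matrix(cm)[usable, usable]
  sds <- apply(OE, 2, stats::sd, na.rm = TRUE)
  if (all(!is.finite(sds)) || all(sds == 0, na.rm = TRUE))
    stop("degenerate spectrum: O/E matrix has no variance (uniform matrix?)")
  C <- suppressWarnings(stats::cor(OE, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  eig <- eigen(C, symmetric = TRUE)
  k <- which.max(abs(eig$values))
  e1 <- eig$vectors[, k]
  r <- suppressWarnings(stats::cor(e1, orientation[usable],
                                   use = "complete.obs"))
  if (!is.na(r) && r < 0) e1 <- -e1
  E1 <- rep(NA_real_, cm$nbins)
  E1[usable] <- e1
  structure(list(
    E1 = E1,
    label = ifelse(is.na(E1), NA_character_, ifelse(E1 > 0, "A", "B")),
    orientation_r = abs(r),
    ambiguous = is.na(r) || abs(r) < 0.1,
    eigenvalue = eig$values[k]), class = "compartment_track")
}

#' Saddle plot and compartmentalization strength
#'
#' Ranks bins by E1 into quantiles and averages the O/E matrix over every
#' quantile pair, yielding the saddle matrix (B-B in the top-left corner,
#' A-A in the bottom-right). Compartmentalization strength is the ratio of
#' mean same-compartment corner signal to mean cross-compartment corner
#' signal, (AA + BB) / (AB + BA), computed overall and per genomic distance
#' band.
#'
#' @param cm A balanced `contact_matrix`.
#' @param E1 Per-bin E1 values (e.g. from [compartment_eigenvector()]).
#' @param n_quantiles Number of E1 rank quantiles (default 50).
#' @param corner_frac Fraction of extreme quantiles defining the corners
#'   (default 0.2).
#' @param distance_bands Optional list of c(lo, hi) bp windows for the
#'   per-distance strength profile.
#' @return List of class `saddle_result`: `matrix` (n_quantiles^2),
#'   `strength`, `strength_by_band`.
#' @export
saddle <- function(cm, E1, n_quantiles = 50, corner_frac = 0.2,
                   distance_bands = NULL) {
  usable <- which(!is.na(E1) & !cm$mask)
  if (n_quantiles > length(usable))
    stop("more quantiles than usable bins")
  OE <- oe_matrix(cm)
  res <- cm$resolution
  rk <- rep(NA_integer_, cm$nbins)
  rk[usable] <- if (n_quantiles == 1) 1L else
    as.integer(cut(rank(E1[usable], ties.method = "first"),
                   breaks = n_quantiles, labels = FALSE))
  cell_mean <- function(M, sub_idx) {
    S <- matrix(NA_real_, n_quantiles, n_quantiles)
    for (a in seq_len(n_quantiles)) {
      ia <- sub_idx[rk[sub_idx] == a]
      if (!length(ia)) next
      for (b in seq_len(n_quantiles)) {
        ib <- sub_idx[rk[sub_idx] == b]
        if (!length(ib)) next
        S[a, b] <- mean(M[ia, ib], na.rm = TRUE)
      }
    }
    S
  }
  S <- cell_mean(OE, usable)
  nc <- max(1L, round(corner_frac * n_quantiles))
  lo <- seq_len(nc); hi <- n_quantiles + 1 - seq_len(nc)
  strength_of <- function(S) {
    same <- mean(c(S[lo, lo], S[hi, hi]), na.rm = TRUE)
    cross <- mean(c(S[lo, hi], S[hi, lo]), na.rm = TRUE)
    same / cross
  }
  strength_by_band <- NULL
  if (!is.null(distance_bands)) {
    D <- abs(outer(seq_len(cm$nbins), seq_len(cm$nbins), "-")) * res
    strength_by_band <- vapply(distance_bands, function(band) {
      OEb <- OE
      OEb[D < band[1] | D >= band[2]] <- NA
      strength_of(cell_mean(OEb, usable))
    }, 1)
    names(strength_by_band) <- vapply(distance_bands, function(b)
      sprintf("%g-%g", b[1], b[2]), "")
  }
  structure(list(matrix = S, strength = strength_of(S),
                 strength_by_band = strength_by_band),
            class = "saddle_result")
}
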