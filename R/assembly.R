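#' Target-decoy PSM FDR filter
#'
#' Scans every candidate score cut point and retains all PSMs with score
#' at or above the lowest threshold `t` whose estimated FDR meets the
#' target. The estimator follows the concatenated target-decoy
#' convention, `FDR(t) = 2 D(t) / (T(t) + D(t))` (the `D(t)/T(t)` form is
#' available via `estimator`). Ties at the threshold are kept as a block:
#' a cut point either includes all PSMs with that score or none, so tied
#' PSMs are retained only if the tie-inclusive FDR still meets the
#' target. Decoys are excluded from the returned set.
#'
#' @param psms data.frame/data.table with at least `score` (higher is
#'   better) and logical `decoy`.
#' @param fdr_target maximum acceptable FDR, e.g. 0.001.
#' @param estimator "concatenated" (2D/(T+D)) or "ratio" (D/T).
#' @return the retained target PSMs; attributes `threshold` and
#'   `fdr_at_threshold` record the cut.
#' @export
psm_fdr_filter <- function(psms, fdr_target, estimator = c("concatenated", "ratio")) {
  estimator <- match.arg(estimator)
  psms <- as.data.frame(psms)
  stopifnot(is.numeric(psms$score), is.logical(psms$decoy) || all(psms$decoy %in% 0:1))
  decoy <- as.logical(psms$decoy)
  if (!any(decoy)) stop("no decoy PSMs present: FDR is inestimable")

  cuts <- sort(unique(psms$score))  # candidate thresholds, ascending
  ord <- order(psms$score)
  ## T(t), D(t): counts with score >= t, computed by reverse cumsums
  n <- length(ord)
  dec_sorted <- decoy[ord]
  score_sorted <- psms$score[ord]
  d_ge <- rev(cumsum(rev(dec_sorted)))
  t_ge <- rev(cumsum(rev(!dec_sorted)))
  first_idx <- match(cuts, score_sorted)  # lowest index with score >= cut
  D <- d_ge[first_idx]
  Tt <- t_ge[first_idx]
  fdr <- if (estimator == "concatenated") 2 * D / (Tt + D) else D / pmax(Tt, 1)
  fdr[Tt + D == 0] <- 0
  ok <- which(fdr <= fdr_target)
  if (!length(ok)) {
    warning("no score threshold attains the requested FDR; returning no PSMs")
    out <- psms[integer(0), , drop = FALSE]
    attr(out, "threshold") <- Inf
    attr(out, "fdr_at_threshold") <- NA_real_
    return(out)
  }
  thr <- cuts[min(ok)]
  out <- psms[!decoy & psms$score >= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "fdr_at_threshold") <- fdr[min(ok)]
  out
}

## Threshold only (targets and decoys retained above it) -- used by the
## protein-level decoy accounting in two_step_assembly().
psm_fdr_threshold <- function(psms, fdr_target, estimator = "concatenated") {
  filt <- psm_fdr_filter(psms, fdr_target, estimator)
  attr(filt, "threshold")
}

#' Two-step FDR-controlled protein-group assembly
#'
#' Step 1 filters PSMs at a stringent FDR (default 0.1%) and keeps the
#' protein groups with at least `min_peptides` distinct peptides among
#' the surviving PSMs. Step 2 re-filters all PSMs at a relaxed FDR
#' (default 1%) but admits only PSMs mapping to the step-1 groups, which
#' raises spectral coverage without admitting new proteins. Protein-level
#' FDR is estimated by running the identical procedure on the decoy
#' population: (decoy groups surviving both steps) / (target groups).
#'
#' Distinct peptides are counted by exact string equality.
#'
#' @param psms PSM table with `score`, `decoy`, `peptide`, `protein_group`.
#' @param strict_fdr,relaxed_fdr PSM FDR targets for the two steps.
#' @param min_peptides minimum distinct peptides per group at step 1.
#' @return list of class `protein_group_set`: `groups` (data.frame:
#'   protein_group, n_peptides, n_spectra), `psms` (retained step-2
#'   target PSMs), `protein_fdr`, per-step counts, and an `empty` flag.
#' @export
two_step_assembly <- function(psms, strict_fdr = 0.001, min_peptides = 2,
                              relaxed_fdr = 0.01) {
  psms <- as.data.frame(psms)
  decoy <- as.logical(psms$decoy)

  strict <- psm_fdr_filter(psms, strict_fdr)
  strict_thr <- attr(strict, "threshold")
  groups1 <- groups_with_min_peptides(strict, min_peptides)

  if (!length(groups1)) {
    warning("no protein group passes the strict step; empty assembly")
    return(structure(list(groups = data.frame(protein_group = character(0),
                                              n_peptides = integer(0),
                                              n_spectra = integer(0)),
                          psms = psms[integer(0), , drop = FALSE],
                          protein_fdr = NA_real_,
                          strict_threshold = strict_thr,
                          relaxed_threshold = NA_real_,
                          n_groups_strict = 0L, n_spectra_strict = 0L,
                          n_spectra_relaxed = 0L, empty = TRUE),
                     class = "protein_group_set"))
  }

  relaxed <- psm_fdr_filter(psms, relaxed_fdr)
  relaxed_thr <- attr(relaxed, "threshold")
  keep <- relaxed[relaxed$protein_group %in% groups1, , drop = FALSE]

  ## decoy groups pushed through the same two steps
  dec <- psms[decoy, , drop = FALSE]
  dgroups1 <- groups_with_min_peptides(dec[dec$score >= strict_thr, ,
                                           drop = FALSE], min_peptides)
  dec_keep <- dec[dec$score >= relaxed_thr &
                    dec$protein_group %in% dgroups1, , drop = FALSE]
  protein_fdr <- length(unique(dec_keep$protein_group)) / length(groups1)

  tab <- data.frame(protein_group = groups1, stringsAsFactors = FALSE)
  tab$n_peptides <- as.integer(
    tapply(keep$peptide, factor(keep$protein_group, levels = groups1),
           function(p) length(unique(p))))
  tab$n_spectra <- as.integer(
    table(factor(keep$protein_group, levels = groups1)))

  structure(list(groups = tab, psms = keep, protein_fdr = protein_fdr,
                 strict_threshold = strict_thr,
                 relaxed_threshold = relaxed_thr,
                 n_groups_strict = length(groups1),
                 n_spectra_strict = nrow(strict),
                 n_spectra_relaxed = nrow(keep), empty = FALSE),
            class = "protein_group_set")
}

groups_with_min_peptides <- function(psms, min_peptides) {
  if (!nrow(psms)) return(character(0))
  npep <- tapply(psms$peptide, psms$protein_group,
                 function(p) length(unique(p)))
  sort(names(npep)[npep >= min_peptides])
}

#' Filter an abundance matrix by observation fraction
#'
#' Retains features whose non-missing fraction across samples is at least
#' `min_fraction`, preserving row order. This implements the
#' observed-in-at-least-X%-of-tumors gate applied before clustering and
#' correlation analyses; the cut is an explicit parameter because both a
#' 10% (assembly) and a 90% (core matrix) variant are in routine use.
#'
#' @param matrix features x samples numeric matrix (NA = missing).
#' @param min_fraction required non-missing fraction in (0, 1].
#' @return the row-filtered matrix.
#' @export
filter_by_observation <- function(matrix, min_fraction) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(matrix))
  matrix[frac >= min_fraction, , drop = FALSE]
}
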