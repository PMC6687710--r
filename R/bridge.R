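#' Rank-invariant reference normalization
#'
#' Scales a sample vector onto a reference by a single multiplicative
#' factor fitted on a rank-invariant feature set, in the spirit of
#' iterative rank-order normalization of expression intensities: features
#' whose rank differs between sample and reference by no more than a
#' shrinking tolerance form the invariant set; the factor is the
#' geometric mean of reference/sample over that set; the set is re-derived
#' until it stabilizes. The tolerance starts at 5% of the shared-feature
#' count, halves per iteration, and is floored at 1%.
#'
#' @param sample_vec,reference_vec named or positionally matched positive
#'   vectors; only features finite and positive in both are used (at
#'   least 20 required).
#' @param max_iter maximum refinement iterations.
#' @return `sample_vec` multiplied by the fitted factor; attributes
#'   `factor` and `n_invariant`.
#' @export
rank_invariant_normalize <- function(sample_vec, reference_vec,
                                     max_iter = 10) {
  stopifnot(length(sample_vec) == length(reference_vec))
  shared <- which(is.finite(sample_vec) & is.finite(reference_vec) &
                    sample_vec > 0 & reference_vec > 0)
  if (length(shared) < 20)
    stop(sprintf("rank-invariant normalization needs >= 20 shared features, got %d",
                 length(shared)))
  s <- sample_vec[shared]
  r <- reference_vec[shared]
  n <- length(shared)
  if (stats::sd(s) == 0 || stats::sd(r) == 0) {
    warning("degenerate (constant) vector; falling back to median-ratio scaling")
    f <- stats::median(r / s)
    out <- sample_vec * f
    attr(out, "factor") <- f
    attr(out, "n_invariant") <- n
    return(out)
  }
  tol <- ceiling(0.05 * n)
  floor_tol <- max(1, ceiling(0.01 * n))
  rs <- rank(s, ties.method = "average")
  rr <- rank(r, ties.method = "average")
  inv_prev <- integer(0)
  inv <- seq_len(n)
  for (it in seq_len(max_iter)) {
    inv <- which(abs(rs - rr) <= tol)
    if (!length(inv)) inv <- which(abs(rs - rr) <= min(abs(rs - rr)))
    if (identical(inv, inv_prev)) break
    inv_prev <- inv
    tol <- max(floor_tol, ceiling(tol / 2))
  }
  f <- exp(mean(log(r[inv] / s[inv])))
  out <- sample_vec * f
  attr(out, "factor") <- f
  attr(out, "n_invariant") <- length(inv)
  out
}

#' Spectral-to-protein rollup within one plex
#'
#' Computes, for every protein group, (i) the per-channel log2 ratio to
#' the in-plex reference pool channel as the arithmetic mean of the
#' spectrum-level log2 ratios, and (ii) the reference-pool protein
#' abundance as the geometric mean of the unlogged pool-channel spectral
#' intensities. Ratios are defined only for spectra with positive
#' intensity in both the channel and the pool; a protein with no usable
#' spectrum in a channel is missing there, never zero.
#'
#' @param intensities spectra x channels matrix of reporter intensities.
#' @param protein_group protein group id per spectrum.
#' @param pool_channel column index of the reference pool channel.
#' @return list with `log_ratio` (proteins x channels, log2, pool column
#'   dropped is retained as 0s for bookkeeping) and `pool_abundance`
#'   (named vector).
#' @export
rollup_protein <- function(intensities, protein_group, pool_channel = 1L) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == length(protein_group))
  pool <- intensities[, pool_channel]
  usable <- is.finite(pool) & pool > 0
  lr <- log2(intensities / pool)           # spectrum-level log ratios
  lr[!is.finite(lr)] <- NA
  lr[!usable, ] <- NA
  g <- factor(protein_group)
  log_ratio <- apply(lr, 2, function(col)
    tapply(col, g, function(v) if (all(is.na(v))) NA_real_ else
      mean(v, na.rm = TRUE)))
  log_ratio <- matrix(log_ratio, nlevels(g), ncol(intensities),
                      dimnames = list(levels(g), colnames(intensities)))
  logpool <- log2(pool)
  logpool[!usable] <- NA
  pool_abundance <- tapply(logpool, g, function(v)
    if (all(is.na(v))) NA_real_ else 2^mean(v, na.rm = TRUE))
  list(log_ratio = log_ratio,
       pool_abundance = structure(as.numeric(pool_abundance),
                                  names = levels(g)))
}

#' Bridge per-plex rollups into one cohort abundance matrix
#'
#' Internal-reference scaling across plexes: (1) pick the cohort
#' reference pool — the plex whose reference-pool median log2 abundance
#' is the median over all plexes (lexicographically smallest plex id on
#' ties); (2) normalize every plex's pool abundances onto it with
#' [rank_invariant_normalize()]; (3) set the protein scale to the
#' geometric mean of the normalized pool abundances across plexes;
#' (4) reconstruct each channel as `scale * 2^log_ratio`; (5) log2
#' transform; (6) average replicate injections per tumor on the log2
#' scale. Missing stays missing — no imputation anywhere.
#'
#' @param rollups named list (one element per plex, names = plex ids) as
#'   returned by [rollup_protein()], rows aligned on a shared protein
#'   universe beforehand or not (alignment is by rowname union).
#' @param design plex design data.frame ([generate_plex_design()] schema).
#' @param ref_plex optional plex id whose reference pool anchors the
#'   bridge (overrides the median-of-medians choice, mirroring analyses
#'   that fix a named pool as the cohort reference).
#' @return list of class `bridge_result`: `abundance` (proteins x tumors
#'   log2 matrix), `pools` (bridged log2 values of the non-reference pool
#'   channels, for QC), `scale` (per-protein scale), `reference_plex`,
#'   `factors` (per-plex normalization factors).
#' @export
bridge_across_plexes <- function(rollups, design, ref_plex = NULL) {
  plex_ids <- names(rollups)
  if (is.null(plex_ids)) plex_ids <- as.character(seq_along(rollups))
  proteins <- sort(unique(unlist(lapply(rollups, function(r)
    names(r$pool_abundance)))))

  pool_mat <- sapply(rollups, function(r)
    r$pool_abundance[match(proteins, names(r$pool_abundance))])
  rownames(pool_mat) <- proteins
  if (any(colSums(is.finite(pool_mat)) == 0))
    stop("a plex has no reference-pool protein abundances; cannot bridge")

  ## cohort reference pool: median of the per-plex pool medians
  if (is.null(ref_plex)) {
    med <- apply(log2(pool_mat), 2, stats::median, na.rm = TRUE)
    target <- stats::median(med)
    ref_plex <- plex_ids[order(abs(med - target), plex_ids)][1]
  } else {
    ref_plex <- as.character(ref_plex)
    stopifnot(ref_plex %in% plex_ids)
  }

  factors <- stats::setNames(numeric(length(plex_ids)), plex_ids)
  norm_pool <- pool_mat
  for (j in plex_ids) {
    if (j == ref_plex) {
      factors[j] <- 1
      next
    }
    nv <- rank_invariant_normalize(pool_mat[, j], pool_mat[, ref_plex])
    factors[j] <- attr(nv, "factor")
    norm_pool[, j] <- as.numeric(nv)
  }
  lsc <- rowMeans(log2(norm_pool), na.rm = TRUE)
  lsc[!is.finite(lsc)] <- NA
  scale_protein <- 2^lsc  # geometric mean of normalized pool abundances

  ## reconstruct channel-level log2 abundances: log2(scale) + log_ratio
  tumor_slots <- design[design$role == "tumor", ]
  pool_slots <- design[design$role == "pool" & !design$is_ref_pool, ]
  slot_values <- function(slots) {
    out <- matrix(NA_real_, length(proteins), nrow(slots),
                  dimnames = list(proteins, NULL))
    for (k in seq_len(nrow(slots))) {
      j <- as.character(slots$plex[k])
      r <- rollups[[j]]
      lr <- r$log_ratio[match(proteins, rownames(r$log_ratio)),
                        slots$channel[k]]
      out[, k] <- lsc + lr
    }
    out
  }
  tumor_vals <- slot_values(tumor_slots)
  colnames(tumor_vals) <- tumor_slots$sample_id
  pools <- slot_values(pool_slots)
  colnames(pools) <- pool_slots$sample_id

  ## average replicate injections per tumor (log2 scale)
  tumors <- unique(tumor_slots$sample_id)
  abundance <- sapply(tumors, function(t) {
    cols <- which(colnames(tumor_vals) == t)
    if (length(cols) == 1) tumor_vals[, cols] else
      rowMeans(tumor_vals[, cols, drop = FALSE], na.rm = FALSE)
  })
  ## replicate mean with NA-awareness: average over non-missing replicates
  for (t in tumors) {
    cols <- which(colnames(tumor_vals) == t)
    if (length(cols) > 1) {
      v <- rowMeans(tumor_vals[, cols, drop = FALSE], na.rm = TRUE)
      v[!is.finite(v)] <- NA
      abundance[, t] <- v
    }
  }
  rownames(abundance) <- proteins

  structure(list(abundance = abundance, pools = pools,
                 scale = scale_protein, reference_plex = ref_plex,
                 factors = factors),
            class = "bridge_result")
}

#' Run rollup and bridging straight from a PSM table
#'
#' Convenience wrapper: splits retained target PSMs by plex, rolls each
#' plex up against its reference-pool channel, and bridges across plexes.
#'
#' @param psms wide PSM table (`plex`, `protein_group`, `decoy`,
#'   `ch_1`...) — typically the `psms` element of [two_step_assembly()].
#' @param design plex design data.frame.
#' @param ref_plex optional fixed reference plex id.
#' @return a `bridge_result` (see [bridge_across_plexes()]).
#' @export
bridge_psm_table <- function(psms, design, ref_plex = NULL) {
  psms <- as.data.frame(psms)
  psms <- psms[!as.logical(psms$decoy), , drop = FALSE]
  ch_cols <- grep("^ch_", names(psms), value = TRUE)
  rollups <- list()
  for (j in sort(unique(design$plex))) {
    sub <- psms[psms$plex == j, , drop = FALSE]
    if (!nrow(sub)) stop(sprintf("plex %s has no PSMs", j))
    ref_ch <- design$channel[design$plex == j & design$is_ref_pool]
    if (!length(ref_ch)) stop(sprintf("plex %s has no reference pool channel", j))
    rollups[[as.character(j)]] <- rollup_protein(
      as.matrix(sub[, ch_cols, drop = FALSE]),
      sub$protein_group, pool_channel = ref_ch)
  }
  bridge_across_plexes(rollups, design, ref_plex = ref_plex)
}
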