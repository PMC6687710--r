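# Independent brute-force oracles used to validate the statistical
# operations against first principles on small inputs.

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins: sum the hypergeometric probabilities of tables at
# most as probable as the observed one (tolerance for float ties).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, n - r1, c1)
  obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by full enumeration of group assignments
# (no ties assumed), matching the doubled-tail convention.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# PSM score threshold by brute-force scan over every cut point.
oracle_psm_threshold <- function(scores, decoy, target_fdr) {
  cuts <- sort(unique(scores))
  best <- Inf
  for (t in cuts) {
    keep <- scores >= t
    D <- sum(decoy[keep]); Tt <- sum(!decoy[keep])
    fdr <- if (Tt + D == 0) 0 else 2 * D / (Tt + D)
    if (fdr <= target_fdr && t < best) best <- t
  }
  best
}

# Gene-level CNV state by direct interval scan (0-based half-open).
oracle_cnv_states <- function(segments, gene_models, min_probes,
                              min_length) {
  samples <- sort(unique(segments$sample))
  out <- matrix(0, nrow(gene_models), length(samples),
                dimnames = list(gene_models$gene, samples))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    if (s$n_probes < min_probes || (s$end - s$start) <= min_length) next
    for (g in seq_len(nrow(gene_models))) {
      gm <- gene_models[g, ]
      if (gm$chrom == s$chrom && gm$start < s$end && s$start < gm$end) {
        cur <- out[gm$gene, s$sample]
        if (abs(s$log2) > abs(cur)) out[gm$gene, s$sample] <- s$log2
      }
    }
  }
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small, fast cohort configuration for unit tests.
tiny_config <- function(...) {
  args <- list(n_tumors = 16, n_plexes = 4, n_proteins = 240,
               n_genes = 240, n_program = 25, n_hazard_genes = 5,
               n_planted = 3, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}
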