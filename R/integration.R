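#' Feature-paired Spearman correlations between two omic matrices
#'
#' For every feature pair (default: features with the same id in both
#' matrices), computes the Spearman correlation over the shared samples
#' with pairwise-complete observations. Pairs where either vector has
#' fewer than `min_fraction` non-missing values over the shared samples
#' (or fewer than 3 complete pairs, or a constant vector) are skipped.
#' p-values use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`; BH across computed pairs.
#'
#' @param x,y features x samples matrices sharing sample columns.
#' @param pairs data.frame with columns `feature_x`, `feature_y`;
#'   defaults to the identity pairing on shared rownames.
#' @param min_fraction minimum non-missing fraction required in each
#'   vector (default 0.10).
#' @return data.frame: feature_x, feature_y, rho, n_used, p, p_adj,
#'   with attribute `mean_rho` (cohort mean over computed pairs).
#' @export
paired_spearman <- function(x, y, pairs = NULL, min_fraction = 0.10) {
  samples <- intersect(colnames(x), colnames(y))
  if (!length(samples)) stop("no shared sample columns between x and y")
  if (is.null(pairs)) {
    shared <- intersect(rownames(x), rownames(y))
    pairs <- data.frame(feature_x = shared, feature_y = shared,
                        stringsAsFactors = FALSE)
  }
  xs <- x[, samples, drop = FALSE]
  ys <- y[, samples, drop = FALSE]
  ns <- length(samples)
  res <- data.frame(pairs, rho = NA_real_, n_used = NA_integer_,
                    p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    a <- xs[pairs$feature_x[i], ]
    b <- ys[pairs$feature_y[i], ]
    if (mean(!is.na(a)) < min_fraction || mean(!is.na(b)) < min_fraction)
      next
    ok <- !is.na(a) & !is.na(b)
    res$n_used[i] <- sum(ok)
    if (sum(ok) < 3) next
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next
    res$rho[i] <- stats::cor(a[ok], b[ok], method = "spearman")
    res$p[i] <- spearman_t_p(res$rho[i], sum(ok))
  }
  comp <- !is.na(res$rho)
  res$p_adj[comp] <- bh_adjust(res$p[comp])
  attr(res, "mean_rho") <- mean(res$rho, na.rm = TRUE)
  res
}

spearman_t_p <- function(rho, n) {
  if (n < 3 || is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
}

#' Partition correlation records into high and low bands
#'
#' Strict open intervals: "high" means rho > `high`; "low" means
#' `low_band[1] < rho < low_band[2]`. A rho exactly on a boundary falls
#' in neither band.
#'
#' @param records output of [paired_spearman()].
#' @param high lower bound of the highly correlated band.
#' @param low_band bounds of the poorly correlated band.
#' @return list(high, low, n_high, n_low) of feature_x ids.
#' @export
correlation_band_sets <- function(records, high = 0.5,
                                  low_band = c(-0.2, 0.2)) {
  rho <- records$rho
  hi <- !is.na(rho) & rho > high
  lo <- !is.na(rho) & rho > low_band[1] & rho < low_band[2]
  list(high = records$feature_x[hi], low = records$feature_x[lo],
       n_high = sum(hi), n_low = sum(lo))
}

#' Differential co-expression around an anchor feature
#'
#' Correlates every feature with the anchor separately within two sample
#' groups (Spearman, pairwise-complete, 10% support rule) and returns
#' (i) the features significantly co-expressed within each group
#' (rho > `sig_rho` and BH-adjusted p <= `sig_padj`) and (ii) the
#' features whose correlation differs between groups by more than
#' `delta_threshold`.
#'
#' @param matrix features x samples matrix containing the anchor row.
#' @param anchor anchor feature id.
#' @param mask_a,mask_b logical sample masks (each >= 5 samples).
#' @param delta_threshold minimum |rho_A - rho_B| for the difference set.
#' @param sig_rho,sig_padj within-group significance gates.
#' @param min_fraction support rule passed to [paired_spearman()].
#' @return list(table, sig_a, sig_b, diff_set).
#' @export
differential_correlation <- function(matrix, anchor, mask_a, mask_b,
                                     delta_threshold = 0.5, sig_rho = 0.5,
                                     sig_padj = 0.25, min_fraction = 0.10) {
  stopifnot(anchor %in% rownames(matrix))
  mask_a <- as.logical(mask_a); mask_b <- as.logical(mask_b)
  if (sum(mask_a) < 5 || sum(mask_b) < 5)
    stop("both groups need at least 5 samples")
  others <- setdiff(rownames(matrix), anchor)
  one_group <- function(mask) {
    sub <- matrix[, mask, drop = FALSE]
    anchor_mat <- sub[rep(anchor, length(others)), , drop = FALSE]
    rownames(anchor_mat) <- paste0(".anchor.", others)
    paired_spearman(sub[others, , drop = FALSE], anchor_mat,
                    pairs = data.frame(feature_x = others,
                                       feature_y = paste0(".anchor.", others),
                                       stringsAsFactors = FALSE),
                    min_fraction = min_fraction)
  }
  ra <- one_group(mask_a)
  rb <- one_group(mask_b)
  tab <- data.frame(feature = others,
                    rho_a = ra$rho, p_adj_a = ra$p_adj,
                    rho_b = rb$rho, p_adj_b = rb$p_adj,
                    delta = ra$rho - rb$rho,
                    stringsAsFactors = FALSE)
  sig <- function(rho, padj) !is.na(rho) & !is.na(padj) &
    rho > sig_rho & padj <= sig_padj
  list(table = tab,
       sig_a = tab$feature[sig(tab$rho_a, tab$p_adj_a)],
       sig_b = tab$feature[sig(tab$rho_b, tab$p_adj_b)],
       diff_set = tab$feature[!is.na(tab$delta) &
                                abs(tab$delta) > delta_threshold])
}

#' Transcript-protein correlation of TF target sets by subtype
#'
#' For each target set, recomputes the per-gene transcript-protein
#' Spearman correlation within each subtype's samples (and overall) and
#' reports the set means plus a rank-sum p-value comparing the per-gene
#' correlation values between two chosen subtypes. Subtypes with fewer
#' than 5 samples are excluded with a warning; sets with fewer than
#' `min_pairs` measured pairs are skipped.
#'
#' @param rna,protein genes x samples matrices on a shared gene space.
#' @param target_sets named list of gene-id vectors.
#' @param subtype named character/integer vector per sample.
#' @param compare length-2 vector naming the subtypes to contrast
#'   (default: the two largest).
#' @param min_pairs minimum measured pairs per set.
#' @return data.frame: set, n_genes, mean overall and per subtype, p.
#' @export
tf_target_summary <- function(rna, protein, target_sets, subtype,
                              compare = NULL, min_pairs = 10) {
  samples <- intersect(intersect(colnames(rna), colnames(protein)),
                       names(subtype))
  subtype <- subtype[samples]
  sizes <- sort(table(subtype), decreasing = TRUE)
  small <- names(sizes)[sizes < 5]
  if (length(small)) {
    warning(sprintf("subtype(s) with < 5 samples excluded: %s",
                    paste(small, collapse = ", ")))
    sizes <- sizes[!names(sizes) %in% small]
  }
  groups <- names(sizes)
  if (is.null(compare)) compare <- groups[1:2]
  per_gene_rho <- function(genes, cols) {
    r <- paired_spearman(rna[, cols, drop = FALSE],
                         protein[, cols, drop = FALSE],
                         pairs = data.frame(feature_x = genes,
                                            feature_y = genes,
                                            stringsAsFactors = FALSE))
    r$rho
  }
  out <- lapply(names(target_sets), function(nm) {
    genes <- intersect(target_sets[[nm]],
                       intersect(rownames(rna), rownames(protein)))
    overall <- per_gene_rho(genes, samples)
    if (sum(!is.na(overall)) < min_pairs) {
      warning(sprintf("set %s has < %d measured pairs; skipped", nm, min_pairs))
      return(NULL)
    }
    row <- data.frame(set = nm, n_genes = sum(!is.na(overall)),
                      mean_rho_overall = mean(overall, na.rm = TRUE),
                      stringsAsFactors = FALSE)
    rhos <- list()
    for (g in groups) {
      rg <- per_gene_rho(genes, samples[subtype == g])
      rhos[[g]] <- rg
      row[[paste0("mean_rho_", g)]] <- mean(rg, na.rm = TRUE)
    }
    row$p <- suppressWarnings(stats::wilcox.test(
      rhos[[compare[1]]], rhos[[compare[2]]], exact = FALSE)$p.value)
    row
  })
  out <- do.call(rbind, out)
  attr(out, "compare") <- compare
  out
}

#' Vulnerability intersection cascade
#'
#' Intersects three evidence layers on a shared gene namespace:
#' H = genes whose CNV-protein and RNA-protein Spearman correlations both
#' exceed `rho_min` with BH-adjusted p below `padj_max`; E = genes
#' significantly elevated in the focal subtype (from a [wilcoxon_de()]
#' table, positive fold change); D = genes scoring below `rsa_max` in at
#' least one screened cell line. Primary candidates are H n E n D;
#' secondary candidates are (E n D) \ H. Candidates are flagged as
#' confirmed where a Bayes factor exceeds `bf_min` in at least one line.
#'
#' @param cnv_prot,rna_prot [paired_spearman()] records (feature_x =
#'   gene).
#' @param de [wilcoxon_de()] table for the focal subtype vs rest.
#' @param screen data.frame gene, cell_line, rsa, optional bayes_factor.
#' @param rho_min,padj_max,rsa_max,bf_min thresholds.
#' @return list(report, primary, secondary, n_h, n_e, n_d).
#' @export
vulnerability_cascade <- function(cnv_prot, rna_prot, de, screen,
                                  rho_min = 0.5, padj_max = 0.25,
                                  rsa_max = -3, bf_min = 3) {
  genes <- Reduce(intersect, list(cnv_prot$feature_x, rna_prot$feature_x,
                                  de$feature, unique(screen$gene)))
  if (!length(genes))
    stop("no shared gene namespace across correlation, DE and screen inputs")
  pick <- function(rec) {
    i <- match(genes, rec$feature_x)
    ok <- !is.na(rec$rho[i]) & !is.na(rec$p_adj[i]) &
      rec$rho[i] > rho_min & rec$p_adj[i] < padj_max
    ok
  }
  in_h <- pick(cnv_prot) & pick(rna_prot)
  di <- match(genes, de$feature)
  in_e <- !is.na(de$significant[di]) & de$significant[di] &
    de$log2_fc[di] > 0
  rsa_min_gene <- tapply(screen$rsa, screen$gene, min, na.rm = TRUE)
  in_d <- as.vector(rsa_min_gene[genes] < rsa_max)
  confirmed <- rep(FALSE, length(genes))
  if (!is.null(screen$bayes_factor)) {
    bf_max_gene <- tapply(screen$bayes_factor, screen$gene, max, na.rm = TRUE)
    confirmed <- as.vector(bf_max_gene[genes] > bf_min)
  }
  report <- data.frame(gene = genes, in_h = in_h, in_e = in_e, in_d = in_d,
                       tier = ifelse(in_h & in_e & in_d, "primary",
                                     ifelse(in_e & in_d, "secondary", "none")),
                       bf_confirmed = confirmed, stringsAsFactors = FALSE)
  list(report = report,
       primary = genes[in_h & in_e & in_d],
       secondary = genes[in_e & in_d & !in_h],
       n_h = sum(in_h), n_e = sum(in_e), n_d = sum(in_d))
}

#' Collapse CNV segments to a gene x sample state matrix
#'
#' Segments failing either reporting gate — fewer than `min_probes`
#' consecutive probes, or length not strictly greater than `min_length`
#' base pairs — are dropped. Each gene takes the log2 value of the
#' overlapping filtered segment with the largest |log2| (earlier segment
#' start breaks ties); genes with no overlapping segment are neutral (0).
#' Coordinates are 0-based half-open on both sides.
#'
#' @param segments data.frame sample, chrom, start, end, n_probes, log2.
#' @param gene_models data.frame gene, chrom, start, end.
#' @param min_probes probe-count gate (segments with >= this pass).
#' @param min_length length gate in bp (strictly greater passes).
#' @param reduce "max_abs" (default) or "length_weighted" mean of
#'   overlapping segment values.
#' @return list(log2: gene x sample matrix, state: character matrix
#'   gain/loss/neutral, n_segments_used, counts: per-gene gain/loss
#'   tallies).
#' @export
summarize_cnv <- function(segments, gene_models, min_probes = 50,
                          min_length = 400000,
                          reduce = c("max_abs", "length_weighted")) {
  reduce <- match.arg(reduce)
  bad <- which(!(segments$end > segments$start) | segments$n_probes < 1)
  if (length(bad))
    stop(sprintf("malformed CNV segment interval(s) at row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  keep <- segments$n_probes >= min_probes &
    (segments$end - segments$start) > min_length
  seg <- segments[keep, , drop = FALSE]
  samples <- sort(unique(segments$sample))
  genes <- gene_models$gene
  out <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (nrow(seg)) {
    ## 0-based half-open -> 1-based closed for IRanges
    seg_gr <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start + 1, seg$end))
    gene_gr <- GenomicRanges::GRanges(
      gene_models$chrom, IRanges::IRanges(gene_models$start + 1,
                                          gene_models$end))
    hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      df <- data.frame(gene = genes[qh], sample = seg$sample[sh],
                       log2 = seg$log2[sh], start = seg$start[sh],
                       width = seg$end[sh] - seg$start[sh],
                       stringsAsFactors = FALSE)
      key <- paste(df$gene, df$sample, sep = "\r")
      if (reduce == "max_abs") {
        ord <- order(-abs(df$log2), df$start)
        df <- df[ord, ]
        df <- df[!duplicated(key[ord]), ]
        out[cbind(match(df$gene, genes), match(df$sample, samples))] <- df$log2
      } else {
        wmean <- tapply(seq_len(nrow(df)), key, function(i)
          sum(df$log2[i] * df$width[i]) / sum(df$width[i]))
        parts <- strsplit(names(wmean), "\r", fixed = TRUE)
        gi <- match(vapply(parts, `[`, "", 1), genes)
        si <- match(vapply(parts, `[`, "", 2), samples)
        out[cbind(gi, si)] <- as.numeric(wmean)
      }
    }
  }
  state <- matrix("neutral", nrow(out), ncol(out), dimnames = dimnames(out))
  state[out > 0] <- "gain"
  state[out < 0] <- "loss"
  counts <- data.frame(gene = genes,
                       n_gain = rowSums(state == "gain"),
                       n_loss = rowSums(state == "loss"),
                       stringsAsFactors = FALSE)
  list(log2 = out, state = state, n_segments_used = nrow(seg),
       counts = counts)
}
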