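#' Rank-sum differential expression with a fold-change gate
#'
#' Per feature, compares group A (mask TRUE) against group B by the
#' two-sided Wilcoxon rank-sum test: the exact null when the combined
#' non-missing n is at most 25 and there are no ties, the normal
#' approximation with tie correction otherwise. Fold change is
#' `2^(median_A - median_B)` on log2 inputs. A feature is significant
#' when |fold change| passes `fc_threshold` (i.e. FC >= 1.5 or <= 1/1.5)
#' and the BH-adjusted p is at most `alpha`. Features with fewer than 3
#' non-missing values in either group are skipped (NA results, excluded
#' from the BH family).
#'
#' @param matrix features x samples log2 matrix.
#' @param group_mask logical per sample: TRUE = group A.
#' @param fc_threshold fold-change gate on the linear scale.
#' @param alpha adjusted-p cutoff.
#' @return data.frame: feature, n_a, n_b, log2_fc, fold_change, p, p_adj,
#'   significant, tested.
#' @export
wilcoxon_de <- function(matrix, group_mask, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(ncol(matrix) == length(group_mask))
  group_mask <- as.logical(group_mask)
  feat <- rownames(matrix)
  if (is.null(feat)) feat <- as.character(seq_len(nrow(matrix)))
  res <- data.frame(feature = feat,
                    n_a = NA_integer_, n_b = NA_integer_,
                    log2_fc = NA_real_, fold_change = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    significant = FALSE, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(matrix))) {
    a <- matrix[i, group_mask]
    b <- matrix[i, !group_mask]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    res$n_a[i] <- length(a); res$n_b[i] <- length(b)
    if (length(a) < 3 || length(b) < 3) next
    res$tested[i] <- TRUE
    res$log2_fc[i] <- stats::median(a) - stats::median(b)
    res$fold_change[i] <- 2^res$log2_fc[i]
    res$p[i] <- ranksum_p(a, b)
  }
  res$p_adj[res$tested] <- bh_adjust(res$p[res$tested])
  res$significant <- res$tested & !is.na(res$p_adj) &
    (res$fold_change >= fc_threshold | res$fold_change <= 1 / fc_threshold) &
    res$p_adj <= alpha
  res
}

## Two-sided rank-sum p: exact for combined n <= 25 without ties, normal
## approximation with tie correction (no continuity correction) otherwise.
ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  if (stats::sd(pooled) == 0) return(1)
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && length(pooled) <= 25
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)$p.value)
}

#' Two-sided Fisher exact test with conditional-MLE odds ratio
#'
#' The p-value sums the margin-fixed hypergeometric probabilities of all
#' tables at most as probable as the observed one; the odds ratio is the
#' conditional maximum-likelihood estimate under the noncentral
#' hypergeometric model (0 and Inf allowed at boundary tables). A table
#' with a zero row or column margin has no association to test: p = 1 and
#' the odds ratio is reported missing.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list(odds_ratio, p).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(abs(table - round(table)) < 1e-8))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p = 1))
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Cochran-Mantel-Haenszel ordinal (nonzero-correlation) test
#'
#' One-stratum 2 x K test of linear association between a binary group
#' and ordered categories: `M2 = (N - 1) * r^2` where r is the Pearson
#' correlation between the group indicator and the category score over
#' all N individuals; p from chi-square on 1 df. With zero variance in
#' either margin the statistic is 0 and p = 1. The general-association
#' (K - 1 df) variant is available via `variant`.
#'
#' @param table 2 x K matrix of counts (rows = groups, ordered columns).
#' @param scores numeric scores per category (default 0..K-1).
#' @param variant "correlation" (1 df) or "general" (K-1 df).
#' @return list(statistic, df, p).
#' @export
cmh_ordinal_test <- function(table, scores = NULL,
                             variant = c("correlation", "general")) {
  variant <- match.arg(variant)
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) >= 2, all(table >= 0))
  K <- ncol(table)
  if (is.null(scores)) scores <- seq_len(K) - 1
  stopifnot(length(scores) == K)
  N <- sum(table)
  if (N < 2) stop("need at least 2 individuals")
  g <- rep(rep(c(1, 0), K), as.vector(table))       # group indicator
  x <- rep(rep(scores, each = 2), as.vector(table)) # category score
  if (stats::sd(g) == 0 || stats::sd(x) == 0)
    return(list(statistic = 0, df = 1L, p = 1))
  if (variant == "correlation") {
    r <- stats::cor(g, x)
    m2 <- (N - 1) * r^2
    return(list(statistic = m2, df = 1L,
                p = stats::pchisq(m2, 1, lower.tail = FALSE)))
  }
  ## general association: Pearson-type statistic scaled by (N-1)/N
  E <- outer(rowSums(table), colSums(table)) / N
  keep <- colSums(table) > 0
  stat <- (N - 1) / N * sum((table[, keep] - E[, keep])^2 / E[, keep])
  df <- sum(keep) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 by fitting a cubic smoothing spline
#' to `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over the lambda
#' grid and evaluating it at the largest lambda, clipped to (0, 1].
#' q-values are `pi0` times the BH-type step-up quantity. With fewer
#' than 20 p-values the smoother is unreliable and pi0 falls back to 1
#' (with a warning), making q identical to BH.
#'
#' @param p p-values.
#' @param lambda grid for pi0 estimation.
#' @return list(q, pi0).
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ok <- !is.na(p)
  n <- sum(ok)
  if (n < 20) {
    warning("fewer than 20 p-values; pi0 set to 1 (BH fallback)")
    pi0 <- 1
  } else {
    pl <- vapply(lambda, function(l) mean(p[ok] > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pl, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / n), 1)
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- pmin(1, pi0 * stats::p.adjust(p[ok], method = "BH"))
  list(q = q, pi0 = pi0)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric test of overlap between a query gene set and
#' each set of a collection, within a stated universe; BH adjustment
#' across sets. A stand-in for web-service pathway enrichment that keeps
#' the analysis self-contained.
#'
#' @param query character vector (must be a subset of `universe`).
#' @param collection named list of character vectors.
#' @param universe background gene ids.
#' @return data.frame: set, set_size, overlap, p, p_adj.
#' @export
hypergeom_ora <- function(query, collection, universe) {
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  N <- length(unique(universe))
  k <- length(query)
  res <- data.frame(set = names(collection),
                    set_size = NA_integer_, overlap = NA_integer_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(collection)) {
    s <- intersect(collection[[i]], universe)
    ov <- length(intersect(s, query))
    res$set_size[i] <- length(s)
    res$overlap[i] <- ov
    res$p[i] <- if (k == 0) 1 else
      stats::phyper(ov - 1, length(s), N - length(s), k, lower.tail = FALSE)
  }
  res$p_adj <- bh_adjust(res$p)
  res
}
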