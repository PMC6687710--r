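#' Select the most variable features by median absolute deviation
#'
#' Ranks features by MAD (median absolute deviation from the median,
#' unscaled, over non-missing values) and returns the top `n`. Features
#' with fewer than 3 non-missing values are excluded before ranking;
#' ties are broken by feature id so the selection is deterministic.
#'
#' @param matrix features x samples numeric matrix.
#' @param n number of features to return.
#' @return character vector of feature ids, highest MAD first.
#' @export
select_variable_features <- function(matrix, n = 1000) {
  ok <- rowSums(!is.na(matrix)) >= 3
  m <- matrix[ok, , drop = FALSE]
  if (n > nrow(m))
    stop(sprintf("requested %d features but only %d are rankable", n, nrow(m)))
  mads <- apply(m, 1, function(v) stats::mad(v, constant = 1, na.rm = TRUE))
  ord <- order(-mads, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' Consensus clustering by resampled hierarchical clustering
#'
#' For each resample, a fraction `p_item` of samples (and optionally
#' `p_feature` of features) is drawn without replacement and clustered by
#' complete-linkage hierarchical clustering on 1 - Pearson correlation
#' computed over pairwise-complete observations. The same dendrogram is
#' cut at every k in `k_range`. Consensus(i, j) is the fraction of
#' resamples containing both samples in which they co-clustered. Final
#' labels per k come from complete-linkage clustering of 1 - consensus.
#' The CDF of the off-diagonal consensus values and its area are recorded
#' per k for model selection ([select_k()]).
#'
#' Sample pairs whose pairwise-complete correlation is undefined get the
#' maximum observed dissimilarity; pairs never co-sampled get consensus 0
#' (both with a warning).
#'
#' @param matrix features x samples matrix (log2 abundances, NA allowed).
#' @param k_range candidate cluster numbers.
#' @param n_resamples number of subsampling iterations.
#' @param p_item,p_feature subsampling fractions for samples and features.
#' @param seed RNG seed for the resampling stream.
#' @return list of class `consensus_result`: `consensus` (list of
#'   matrices per k), `labels` (matrix samples x k), `area`, `delta_area`,
#'   `k_range`, `cdf` (list per k: sorted consensus values).
#' @export
consensus_cluster <- function(matrix, k_range = 2:9, n_resamples = 1000,
                              p_item = 0.8, p_feature = 1.0, seed = 1234) {
  stopifnot(p_item > 0, p_item <= 1, p_feature > 0, p_feature <= 1)
  n <- ncol(matrix)
  if (n < 2 * max(k_range))
    stop("need at least 2*max(k_range) samples for consensus clustering")
  set.seed(seed)

  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sample <- matrix(0, n, n)

  n_item <- ceiling(p_item * n)
  n_feat <- ceiling(p_feature * nrow(matrix))
  for (b in seq_len(n_resamples)) {
    items <- sort(sample.int(n, n_item))
    feats <- if (p_feature < 1) sample.int(nrow(matrix), n_feat) else
      seq_len(nrow(matrix))
    d <- dissimilarity_pearson(matrix[feats, items, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    co_sample[items, items] <- co_sample[items, items] + 1
    for (k in k_range) {
      lab <- stats::cutree(hc, k)
      same <- outer(lab, lab, "==")
      ck <- as.character(k)
      co_cluster[[ck]][items, items] <- co_cluster[[ck]][items, items] + same
    }
  }

  never <- co_sample == 0 & upper.tri(co_sample)
  if (any(never))
    warning(sprintf("%d sample pairs were never co-sampled; consensus set to 0",
                    sum(never)))

  samples <- colnames(matrix)
  consensus <- list()
  labels <- matrix(NA_integer_, n, length(k_range),
                   dimnames = list(samples, as.character(k_range)))
  area <- numeric(length(k_range))
  cdfs <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    M <- co_cluster[[as.character(k)]] / co_sample
    M[co_sample == 0] <- 0
    diag(M) <- 1
    M <- (M + t(M)) / 2
    dimnames(M) <- list(samples, samples)
    consensus[[as.character(k)]] <- M
    hc <- stats::hclust(stats::as.dist(1 - M), method = "complete")
    labels[, i] <- stats::cutree(hc, k)
    v <- sort(M[upper.tri(M)])
    cdfs[[as.character(k)]] <- v
    area[i] <- cdf_area(v)
  }
  delta <- rel_area_change(area)
  structure(list(consensus = consensus, labels = labels, area = area,
                 delta_area = delta, k_range = k_range, cdf = cdfs),
            class = "consensus_result")
}

## 1 - Pearson over pairwise-complete observations; undefined entries
## become the max observed dissimilarity.
dissimilarity_pearson <- function(x) {
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  d <- 1 - r
  if (anyNA(d)) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- if (is.finite(mx)) mx else 2
  }
  d
}

## Area under the empirical CDF of consensus values on [0, 1]; equals
## 1 - mean(values) plus the histogram discretization used by the
## standard consensus-clustering implementation.
cdf_area <- function(v) {
  if (!length(v)) return(0)
  br <- seq(0, 1, length.out = 101)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  cdf <- cumsum(h$counts) / length(v)
  sum(cdf * diff(br))
}

rel_area_change <- function(area) {
  if (length(area) < 2) return(rep(NA_real_, length(area)))
  c(NA, diff(area) / utils::head(area, -1))
}

#' Choose k by the CDF-area rule
#'
#' Returns the first k whose relative change in consensus-CDF area versus
#' the previous k is below `delta_threshold` (the "<10% change in area"
#' rule). If no k qualifies the largest k is returned with a warning.
#'
#' @param consensus a `consensus_result`.
#' @param delta_threshold relative-change cutoff.
#' @return the chosen k (integer).
#' @export
select_k <- function(consensus, delta_threshold = 0.10) {
  kr <- consensus$k_range
  if (length(kr) < 3) stop("need at least 3 candidate k values")
  rel <- abs(consensus$delta_area)
  hit <- which(!is.na(rel) & rel < delta_threshold)
  if (!length(hit)) {
    warning("no k met the CDF-area rule; returning max k")
    return(kr[length(kr)])
  }
  kr[min(hit)]
}

#' Nearest-centroid classification by Pearson correlation
#'
#' Assigns each sample the label of the centroid with the highest Pearson
#' correlation over the genes shared between the expression matrix and
#' the centroid matrix (pairwise-complete). Samples with fewer than 10
#' non-missing shared genes, or an undefined correlation to every
#' centroid, are labelled `"unclassified"`. Ties go to the earlier
#' centroid column.
#'
#' @param matrix genes x samples expression matrix.
#' @param centroids genes x classes centroid matrix.
#' @return character vector of labels, one per sample.
#' @export
classify_by_centroids <- function(matrix, centroids) {
  shared <- intersect(rownames(matrix), rownames(centroids))
  if (length(shared) < 10)
    stop("need at least 10 genes shared with the centroid matrix")
  m <- matrix[shared, , drop = FALSE]
  ce <- centroids[shared, , drop = FALSE]
  vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    if (sum(!is.na(x)) < 10) return("unclassified")
    r <- suppressWarnings(apply(ce, 2, function(cc)
      stats::cor(x, cc, use = "pairwise.complete.obs")))
    if (all(is.na(r))) return("unclassified")
    colnames(ce)[which.max(r)]
  }, character(1))
}

#' Map fine-grained clusters to named subtypes
#'
#' Applies a total merge map (cluster -> subtype name) to per-sample
#' cluster labels. The map must cover every observed cluster.
#'
#' @param labels integer cluster labels per sample.
#' @param merge_map named character vector, names = cluster ids.
#' @return character vector of subtype names.
#' @export
merge_clusters <- function(labels, merge_map) {
  miss <- setdiff(as.character(unique(labels)), names(merge_map))
  if (length(miss))
    stop(sprintf("merge map does not cover cluster(s): %s",
                 paste(miss, collapse = ", ")))
  unname(merge_map[as.character(labels)])
}

#' Derive a cluster-to-subtype merge map by enrichment labelling
#'
#' Labels each cluster by the gene set most over-represented among its
#' significantly elevated features (cluster vs rest, [wilcoxon_de()]
#' then [hypergeom_ora()]); clusters sharing a top label merge into one
#' subtype. Clusters with no enriched set — typically small splinter
#' groups without differential-expression power — are assigned the label
#' of the labeled cluster whose mean expression profile they correlate
#' with best ([classify_by_centroids()]); if no cluster at all earns a
#' label they keep their own cluster ids. This reproduces the common
#' practice of collapsing fine-grained consensus clusters into
#' biologically named subtypes by pathway similarity, without
#' hard-coding any biology into the pipeline.
#'
#' @param matrix features x samples matrix used for clustering.
#' @param labels integer cluster labels per sample (columns of `matrix`).
#' @param collection named list of feature sets (e.g. program signatures
#'   or pathway gene sets).
#' @param fc_threshold,alpha differential-expression gates.
#' @param ora_alpha maximum adjusted ORA p for a cluster to take a label.
#' @return named character vector usable as `merge_map` (names = cluster
#'   ids).
#' @export
derive_merge_map <- function(matrix, labels, collection,
                             fc_threshold = 1.5, alpha = 0.05,
                             ora_alpha = 0.05) {
  clusters <- sort(unique(labels))
  universe <- rownames(matrix)
  map <- stats::setNames(as.character(clusters), as.character(clusters))
  labelled <- logical(length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    de <- wilcoxon_de(matrix, labels == cl, fc_threshold = fc_threshold,
                      alpha = alpha)
    up <- de$feature[de$significant & de$log2_fc > 0]
    if (!length(up)) next
    ora <- hypergeom_ora(up, collection, universe)
    best <- which.min(ora$p_adj)
    if (length(best) && ora$p_adj[best] <= ora_alpha) {
      map[as.character(cl)] <- ora$set[best]
      labelled[i] <- TRUE
    }
  }
  ## splinter clusters without an enrichment label inherit the label of
  ## the most similar labelled centroid
  if (any(labelled) && any(!labelled)) {
    centroid <- sapply(clusters, function(cl)
      rowMeans(matrix[, labels == cl, drop = FALSE], na.rm = TRUE))
    colnames(centroid) <- as.character(clusters)
    ref <- centroid[, labelled, drop = FALSE]
    colnames(ref) <- map[as.character(clusters[labelled])]
    for (cl in clusters[!labelled]) {
      hit <- classify_by_centroids(
        centroid[, as.character(cl), drop = FALSE], ref)
      if (hit != "unclassified") map[as.character(cl)] <- hit
    }
  }
  map
}
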