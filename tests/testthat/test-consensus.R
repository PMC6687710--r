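test_that("MAD feature selection ranks and excludes as documented", {
  m <- rbind(const = rep(5, 10),
             spiky = c(1, 2, 3, 4, 100, 3, 3, 3, 3, 3),
             wide = seq(0, 90, by = 10))
  colnames(m) <- paste0("s", 1:10)
  # both "const" and "spiky" have MAD 0 (spiky: median deviation 0);
  # ties broken by feature id, widest row first
  expect_equal(select_variable_features(m, 3), c("wide", "const", "spiky"))
  expect_equal(unname(stats::mad(c(1, 2, 3, 4, 100), constant = 1)), 1)
  sparse <- rbind(m, thin = c(1, NA, NA, NA, NA, NA, NA, NA, NA, 2))
  expect_equal(sort(select_variable_features(sparse, 3)),
               sort(rownames(m)))  # <3 observations excluded
  expect_error(select_variable_features(m, 4), "only 3")
})

make_blobs <- function(n_per = 20, sep = 4, p = 60, seed = 1) {
  set.seed(seed)
  sig <- rep(c(sep, -sep), each = p / 2)  # anti-correlated signatures
  m <- cbind(matrix(rnorm(p * n_per), p) + sig,
             matrix(rnorm(p * n_per), p) - sig)
  dimnames(m) <- list(paste0("f", seq_len(p)),
                      paste0("s", seq_len(2 * n_per)))
  m
}

test_that("duplicate samples always reach consensus 1", {
  m <- make_blobs()
  m[, 2] <- m[, 1]  # exact duplicate pair
  cons <- consensus_cluster(m, k_range = 2:4, n_resamples = 50, seed = 3)
  for (k in c("2", "3", "4"))
    expect_equal(cons$consensus[[k]]["s1", "s2"], 1)
})

test_that("well-separated blobs give block-structured consensus", {
  m <- make_blobs()
  cons <- consensus_cluster(m, k_range = 2:4, n_resamples = 100, seed = 9)
  M <- cons$consensus[["2"]]
  within <- c(M[1:20, 1:20][upper.tri(M[1:20, 1:20])],
              M[21:40, 21:40][upper.tri(M[21:40, 21:40])])
  between <- M[1:20, 21:40]
  expect_gte(mean(within), 0.95)
  expect_lte(mean(between), 0.05)
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(M, t(M))
})

test_that("a single resample reproduces plain hierarchical clustering", {
  m <- make_blobs(n_per = 10)
  cons <- consensus_cluster(m, k_range = 2:4, n_resamples = 1,
                            p_item = 1.0, seed = 5)
  d <- 1 - cor(m, use = "pairwise.complete.obs")
  ref <- cutree(hclust(as.dist(d), method = "complete"), 2)
  expect_equal(ari(cons$labels[, "2"], ref), 1)
})

test_that("consensus is invariant to sample permutation up to relabeling", {
  m <- make_blobs(n_per = 12)
  set.seed(77)
  perm <- sample(ncol(m))
  c1 <- consensus_cluster(m, k_range = 2:4, n_resamples = 80, seed = 11)
  c2 <- consensus_cluster(m[, perm], k_range = 2:4, n_resamples = 80,
                          seed = 11)
  expect_equal(ari(c1$labels[, "2"][colnames(m)[perm]], c2$labels[, "2"]), 1)
})

test_that("the CDF-area rule picks the first flat point", {
  fake <- structure(list(k_range = 2:4, area = c(0.5, 0.9, 0.905),
                         delta_area = c(NA, 0.8, 0.905 / 0.9 - 1)),
                    class = "consensus_result")
  expect_equal(select_k(fake), 4)
  expect_equal(select_k(fake, delta_threshold = 1.0), 3)
  grow <- structure(list(k_range = 2:6, area = 0.4 * 1.2^(0:4),
                         delta_area = c(NA, rep(0.2, 4))),
                    class = "consensus_result")
  expect_warning(k <- select_k(grow), "max k")
  expect_equal(k, 6)
})

test_that("select_k is monotone in the threshold", {
  set.seed(2)
  area <- cumsum(runif(8, 0, 0.1)) + 0.4
  fake <- structure(list(k_range = 2:9, area = area,
                         delta_area = c(NA, diff(area) / head(area, -1))),
                    class = "consensus_result")
  ks <- vapply(seq(0.02, 0.9, by = 0.02), function(th)
    suppressWarnings(select_k(fake, th)), numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("subtypes are recovered exactly at the true cluster number", {
  co <- generate_cohort(tiny_config(n_tumors = 36, n_plexes = 9))
  br <- bridge_psm_table(two_step_assembly(co$psm)$psms, co$design)
  core <- filter_by_observation(br$abundance, 0.9)
  feats <- select_variable_features(core, min(150, nrow(core)))
  cons <- consensus_cluster(core[feats, ], k_range = 2:6,
                            n_resamples = 100, seed = 1234)
  truth <- co$truth$subtype[colnames(core)]
  expect_equal(ari(cons$labels[, "3"], truth), 1)
})

test_that("centroid classification follows maximal correlation", {
  set.seed(8)
  ce <- matrix(rnorm(60), 30, 2,
               dimnames = list(paste0("g", 1:30), c("alpha", "beta")))
  m <- cbind(ce[, 1], -ce[, 1], rep(1, 30))
  dimnames(m) <- list(rownames(ce), c("same", "anti", "flat"))
  # anti-correlated centroids: -alpha classifies as beta only if beta
  # correlates negatively with alpha; build that explicitly
  ce[, "beta"] <- -ce[, "alpha"] + rnorm(30, 0, 0.1)
  lab <- classify_by_centroids(m, ce)
  expect_equal(lab, c("alpha", "beta", "unclassified"))
  expect_error(classify_by_centroids(m[1:5, , drop = FALSE], ce),
               "at least 10")
})

test_that("merge maps must cover every cluster", {
  expect_equal(merge_clusters(c(1, 2, 2), c("1" = "A", "2" = "B")),
               c("A", "B", "B"))
  expect_error(merge_clusters(c(1, 3), c("1" = "A")), "cluster")
})
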