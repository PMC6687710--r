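sample_names <- function(n) paste0("s", seq_len(n))

test_that("paired Spearman matches hand-ranked values and identities", {
  x <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("a", sample_names(5)))
  y <- matrix(c(2, 1, 4, 3, 5), 1, dimnames = list("a", sample_names(5)))
  r <- paired_spearman(x, y)
  expect_equal(r$rho, 0.8)
  self <- paired_spearman(y, y)
  expect_equal(self$rho, 1)
  # strictly monotone transforms leave rho untouched
  r2 <- paired_spearman(x, exp(y / 2))
  expect_equal(r2$rho, r$rho)
})

test_that("the 10% support rule and constant vectors are respected", {
  set.seed(3)
  x <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("a", "b"), sample_names(20)))
  y <- x + rnorm(40, 0, 0.1)
  y["b", 2:20] <- NA  # 1/20 observed -> below the 10% support rule
  r <- paired_spearman(x, y)
  expect_false(is.na(r$rho[r$feature_x == "a"]))
  expect_true(is.na(r$rho[r$feature_x == "b"]))
  x["a", ] <- 7  # constant
  r2 <- paired_spearman(x, y)
  expect_true(is.na(r2$rho[r2$feature_x == "a"]))
})

test_that("generated cohorts reproduce the target transcript-protein rho", {
  # cohort-scale sample size: small-n rank attenuation would bias the
  # estimate at toy sizes
  co <- generate_cohort(tiny_config(n_tumors = 108, n_plexes = 27,
                                    n_proteins = 2000, n_genes = 2000))
  br <- bridge_psm_table(two_step_assembly(co$psm)$psms, co$design)
  r <- paired_spearman(co$rna, br$abundance)
  expect_lt(abs(attr(r, "mean_rho") - 0.38), 0.05)
})

test_that("correlation bands use strict open intervals", {
  rec <- data.frame(feature_x = paste0("g", 1:5),
                    feature_y = paste0("g", 1:5),
                    rho = c(0.5, 0.51, 0, -0.2, 0.19))
  bands <- correlation_band_sets(rec)
  expect_equal(bands$high, "g2")      # 0.5 exactly is in neither set
  expect_equal(sort(bands$low), c("g3", "g5"))
  set.seed(9)
  rnd <- data.frame(feature_x = paste0("r", 1:200),
                    feature_y = paste0("r", 1:200),
                    rho = runif(200, -1, 1))
  b2 <- correlation_band_sets(rnd)
  expect_equal(b2$n_high, sum(rnd$rho > 0.5))
  expect_equal(b2$n_low, sum(rnd$rho > -0.2 & rnd$rho < 0.2))
})

test_that("differential correlation finds constructed group differences", {
  set.seed(17)
  n <- 50
  anchor <- rnorm(2 * n)
  grp_a <- seq_len(n)
  hit <- 0.9 * anchor + 0.1 * rnorm(2 * n)
  hit[-grp_a] <- rnorm(n)             # correlated only in group A
  flat <- rnorm(2 * n)
  m <- rbind(anchor = anchor, hit = hit, flat = flat)
  colnames(m) <- sample_names(2 * n)
  mask_a <- seq_len(2 * n) %in% grp_a
  res <- differential_correlation(m, "anchor", mask_a, !mask_a)
  expect_true("hit" %in% res$diff_set)
  expect_true("hit" %in% res$sig_a)
  expect_false("flat" %in% res$diff_set)
  # identical groups -> empty difference set
  res2 <- differential_correlation(cbind(m, m), "anchor",
                                   rep(c(TRUE, FALSE), each = 2 * n),
                                   rep(c(FALSE, TRUE), each = 2 * n))
  expect_equal(length(res2$diff_set), 0)
  # impossible significance gate
  res3 <- differential_correlation(m, "anchor", mask_a, !mask_a,
                                   sig_padj = 0)
  expect_equal(length(res3$sig_a), 0)
})

test_that("TF target summaries detect subtype-specific decoupling", {
  set.seed(23)
  n <- 60; g <- 40
  subtype <- structure(rep(c("X", "Y"), each = n / 2),
                       names = sample_names(n))
  prot <- matrix(rnorm(g * n), g, n,
                 dimnames = list(paste0("g", 1:g), sample_names(n)))
  rna <- 0.9 * prot + 0.45 * rnorm(g * n)
  # decouple targets in subtype Y
  targets <- paste0("g", 1:20)
  rna[targets, subtype == "Y"] <- rnorm(20 * n / 2)
  sets <- list(tf = targets, ctrl = paste0("g", 21:40))
  out <- tf_target_summary(rna, prot, sets, subtype, compare = c("X", "Y"))
  expect_lt(out$mean_rho_Y[out$set == "tf"],
            out$mean_rho_X[out$set == "tf"] - 0.3)
  expect_lt(out$p[out$set == "tf"], 0.01)
  expect_gt(out$p[out$set == "ctrl"], 0.05)
})

test_that("the vulnerability cascade recovers exactly the planted genes", {
  # full default cohort: the planted-candidate contract is stated at
  # cohort scale, where the DE gate has proper power despite the
  # dosage-driven within-subtype variance of planted genes
  co <- generate_cohort(cohort_config())
  br <- bridge_psm_table(two_step_assembly(co$psm)$psms, co$design)
  cnv <- summarize_cnv(co$cnv, co$gene_models)
  rna_prot <- paired_spearman(co$rna, br$abundance)
  cnv_prot <- paired_spearman(cnv$log2, br$abundance)
  truth <- co$truth$subtype[colnames(br$abundance)]
  de <- wilcoxon_de(br$abundance, truth == 2)
  casc <- vulnerability_cascade(cnv_prot, rna_prot, de, co$screen)
  expect_setequal(casc$primary, co$truth$planted)
  expect_true(all(casc$report$bf_confirmed[
    casc$report$gene %in% co$truth$planted]))
})

test_that("relaxing cascade thresholds never shrinks the candidate set", {
  set.seed(41)
  genes <- paste0("g", 1:100)
  rec <- function() data.frame(feature_x = genes, feature_y = genes,
                               rho = runif(100, -1, 1),
                               p_adj = runif(100))
  de <- data.frame(feature = genes, log2_fc = rnorm(100),
                   significant = runif(100) < 0.5)
  screen <- data.frame(gene = rep(genes, 2),
                       cell_line = rep(c("l1", "l2"), each = 100),
                       rsa = rnorm(200, -2, 1.5))
  c1 <- rec(); c2 <- rec()
  tight <- vulnerability_cascade(c1, c2, de, screen)
  loose <- vulnerability_cascade(c1, c2, de, screen,
                                 rho_min = 0.3, padj_max = 0.5,
                                 rsa_max = -2)
  expect_true(all(tight$primary %in% loose$primary))
})

test_that("CNV summarization applies both gates and the overlap rule", {
  gm <- data.frame(gene = c("gA", "gB", "gC"),
                   chrom = c("chr1", "chr1", "chr2"),
                   start = c(1e6, 5e6, 1e6),
                   end = c(1.2e6, 5.2e6, 1.2e6))
  segs <- data.frame(
    sample = "s1",
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0.9e6, 0.95e6, 4.9e6, 0.5e6),
    end = c(1.5e6, 1.5e6, 5.3e6, 0.9e6),
    n_probes = c(700, 49, 60, 800),
    log2 = c(0.6, -2, -0.8, 1))
  # 49 probes fails the probe gate; 60 probes but 0.4 Mb fails length
  segs$end[3] <- segs$start[3] + 399999
  res <- summarize_cnv(segs, gm)
  expect_equal(res$log2["gA", "s1"], 0.6)
  expect_equal(res$log2["gB", "s1"], 0)     # segment dropped by length
  expect_equal(res$log2["gC", "s1"], 0)     # no overlap (end < gene start)
  expect_equal(res$state["gA", "s1"], "gain")
  # exact-length 400 kb fails the strict > gate
  seg400 <- data.frame(sample = "s1", chrom = "chr1", start = 1e6,
                       end = 1.4e6, n_probes = 500, log2 = 1)
  expect_equal(summarize_cnv(seg400, gm)$log2["gA", "s1"], 0)
})

test_that("gene states match the brute-force overlap oracle", {
  set.seed(53)
  gm <- data.frame(gene = paste0("g", 1:3), chrom = "chr1",
                   start = c(1e6, 3e6, 6e6), end = c(2e6, 4e6, 7e6))
  for (rep in 1:10) {
    segs <- data.frame(
      sample = sample(c("sA", "sB"), 4, TRUE),
      chrom = "chr1",
      start = round(runif(4, 0, 6e6)),
      n_probes = sample(c(30, 100, 800), 4, TRUE),
      log2 = round(rnorm(4), 2))
    segs$end <- segs$start + round(runif(4, 2e5, 3e6))
    res <- summarize_cnv(segs, gm)
    ora <- oracle_cnv_states(segs, gm, 50, 400000)
    expect_equal(res$log2[, colnames(ora), drop = FALSE], ora)
  }
  # segment order must not matter
  segs2 <- segs[rev(seq_len(nrow(segs))), ]
  expect_equal(summarize_cnv(segs2, gm)$log2, summarize_cnv(segs, gm)$log2)
})

test_that("malformed segments are rejected with their row number", {
  gm <- data.frame(gene = "g", chrom = "chr1", start = 0, end = 10)
  bad <- data.frame(sample = "s", chrom = "chr1", start = 10, end = 10,
                    n_probes = 100, log2 = 1)
  expect_error(summarize_cnv(bad, gm), "row")
})
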