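test_that("pure scale offsets are removed exactly", {
  set.seed(5)
  ref <- 2^rnorm(100, 10)
  out <- rank_invariant_normalize(ref * 2, ref)
  expect_equal(attr(out, "factor"), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(out), as.numeric(ref), tolerance = 1e-9)
  same <- rank_invariant_normalize(ref, ref)
  expect_equal(attr(same, "factor"), 1, tolerance = 1e-12)
})

test_that("a large outlier barely moves the fitted factor", {
  set.seed(6)
  ref <- 2^rnorm(200, 10, 0.5)
  smp <- ref * 1.7
  smp[1] <- smp[1] * 1000
  out <- rank_invariant_normalize(smp, ref)
  trimmed <- exp(mean(log(ref[-1] / smp[-1])))  # outlier-free oracle
  expect_lt(abs(attr(out, "factor") / trimmed - 1), 0.01)
})

test_that("degenerate and undersized inputs are handled explicitly", {
  expect_error(rank_invariant_normalize(1:10, 1:10), ">= 20")
  expect_warning(out <- rank_invariant_normalize(rep(2, 30), rep(4, 30)),
                 "median-ratio")
  expect_equal(attr(out, "factor"), 2)
})

test_that("spectral rollup averages log ratios and geomeans the pool", {
  # spectra at 2x and 8x the pool -> protein ratio 4x (log2 = 2)
  intens <- rbind(c(100, 200), c(100, 800))
  r <- rollup_protein(intens, c("P1", "P1"), pool_channel = 1)
  expect_equal(unname(r$log_ratio["P1", 2]), 2)
  # symmetric ratios +1/-1 cancel
  intens2 <- rbind(c(100, 200), c(100, 50))
  r2 <- rollup_protein(intens2, c("P1", "P1"))
  expect_equal(unname(r2$log_ratio["P1", 2]), 0)
  # pool abundance = geometric mean of pool-channel spectra
  expect_equal(unname(r2$pool_abundance["P1"]), sqrt(100 * 100))
  # all channels equal to pool -> all ratios 0
  r3 <- rollup_protein(matrix(100, 3, 4), rep("P1", 3))
  expect_true(all(r3$log_ratio == 0))
  # zero intensity -> missing, never zero
  r4 <- rollup_protein(rbind(c(100, 0)), "P1")
  expect_true(is.na(r4$log_ratio["P1", 2]))
})

test_that("a single plex collapses to pool abundance plus log ratio", {
  cfg <- cohort_config(n_tumors = 4, n_plexes = 1, n_proteins = 200,
                       n_genes = 200, n_program = 20, n_hazard_genes = 5,
                       noise_sd = 0, psm_sd = 0, channel_shift_sd = 0,
                       plex_shift_sd = 0, missing_rate = 0,
                       incorrect_target_rate = 0, seed = 21)
  co <- generate_cohort(cfg)
  br <- bridge_psm_table(co$psm, co$design)
  # with one plex the scale is the pool itself, so the bridged value is
  # log2(pool) + (mu - pool) = mu exactly
  expect_equal(br$abundance,
               co$truth$mu[rownames(br$abundance), colnames(br$abundance)],
               tolerance = 1e-9)
})

test_that("zero-noise bridging recovers truth after per-protein centering", {
  cfg <- tiny_config(noise_sd = 0, psm_sd = 0, channel_shift_sd = 0,
                     plex_shift_sd = 1, missing_rate = 0,
                     incorrect_target_rate = 0)
  co <- generate_cohort(cfg)
  br <- bridge_psm_table(two_step_assembly(co$psm)$psms, co$design)
  ab <- br$abundance
  truth <- co$truth$mu[rownames(ab), colnames(ab)]
  truth[is.na(ab)] <- NA
  cen <- function(m) m - rowMeans(m, na.rm = TRUE)
  expect_gt(mean(!is.na(ab)), 0.9)
  expect_lt(max(abs(cen(ab) - cen(truth)), na.rm = TRUE), 1e-9)
})

test_that("replicate injections are averaged on the log2 scale", {
  design <- data.frame(plex = c(1, 1, 1, 2, 2, 2),
                       channel = c(1, 2, 3, 1, 2, 3),
                       sample_id = c("pool_1_1", "TA", "TB",
                                     "pool_2_1", "TA", "TC"),
                       role = c("pool", "tumor", "tumor",
                                "pool", "tumor", "tumor"),
                       is_ref_pool = c(TRUE, FALSE, FALSE,
                                       TRUE, FALSE, FALSE))
  prot <- sprintf("P%02d", 1:30)
  pool <- 2^rnorm(30, 10)
  mk <- function(ratio_a, ratio_c) {
    intens <- cbind(pool, pool * ratio_a, pool * ratio_c)
    rollup_protein(intens, prot, 1)
  }
  # TA measured at 2^5-fold in plex 1 and 2^7-fold in plex 2 vs pool
  rollups <- list("1" = mk(2^5, 2^1), "2" = mk(2^7, 2^1))
  br <- bridge_across_plexes(rollups, design)
  expect_equal(unname(br$abundance[, "TA"] - log2(pool) - 6),
               rep(0, 30), tolerance = 1e-9)
})

test_that("bridging removes per-plex batch effects from pool profiles", {
  cfg <- tiny_config(plex_shift_sd = 1, noise_sd = 0, psm_sd = 0,
                     channel_shift_sd = 0)
  co <- generate_cohort(cfg)
  asm <- two_step_assembly(co$psm)
  psms <- as.data.frame(asm$psms)
  # raw pool profiles: per-plex reference-pool rollup before bridging
  rollups <- lapply(split(psms, psms$plex), function(sub)
    rollup_protein(as.matrix(sub[, grep("^ch_", names(sub))]),
                   sub$protein_group, 1))
  shared <- Reduce(intersect, lapply(rollups, function(r)
    names(r$pool_abundance)[!is.na(r$pool_abundance)]))
  raw <- sapply(rollups, function(r) log2(r$pool_abundance[shared]))
  br <- bridge_across_plexes(rollups, co$design)
  var_before <- mean(apply(raw, 1, var))
  norm_pool <- sweep(raw, 2, log2(br$factors[colnames(raw)]), "+")
  var_after <- mean(apply(norm_pool, 1, var))
  expect_lt(var_after, 0.01 * var_before)
})

test_that("bridged output is invariant to rescaling one plex", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg)
  asm <- two_step_assembly(co$psm)
  br1 <- bridge_psm_table(asm$psms, co$design, ref_plex = 1)
  psms2 <- as.data.frame(asm$psms)
  chc <- grep("^ch_", names(psms2))
  psms2[psms2$plex == 2, chc] <- psms2[psms2$plex == 2, chc] * 37
  br2 <- bridge_psm_table(psms2, co$design, ref_plex = 1)
  expect_equal(br1$abundance, br2$abundance, tolerance = 1e-9)
})
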