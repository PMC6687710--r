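test_that("plex design respects the tumors-plus-pools layout", {
  cfg <- cohort_config(n_tumors = 108, n_plexes = 29)
  d <- generate_plex_design(cfg)
  expect_equal(nrow(d), 29 * 6)                       # 174 channel-slots
  expect_equal(sum(d$role == "pool"), 58)             # 58 pool slots
  expect_equal(sum(d$role == "tumor"), 116)           # 116 tumor slots
  expect_true(all(tapply(d$role == "pool", d$plex, sum) == 2))
  expect_true(all(d$channel[d$is_ref_pool] == 1))
  expect_equal(length(unique(d$plex[d$is_ref_pool])), 29)
  counts <- table(d$sample_id[d$role == "tumor"])
  expect_equal(length(counts), 108)                   # every tumor placed
  expect_true(all(counts >= 1))
  expect_equal(sum(counts - 1), 8)                    # 8 replicate slots
})

test_that("exact-capacity and surplus designs assign tumors as expected", {
  d1 <- generate_plex_design(cohort_config(n_tumors = 4, n_plexes = 1,
                                           n_proteins = 200, n_genes = 200,
                                           n_program = 20,
                                           n_hazard_genes = 5))
  expect_true(all(table(d1$sample_id[d1$role == "tumor"]) == 1))

  d2 <- generate_plex_design(cohort_config(n_tumors = 7, n_plexes = 2,
                                           n_proteins = 200, n_genes = 200,
                                           n_program = 20,
                                           n_hazard_genes = 5))
  counts <- table(d2$sample_id[d2$role == "tumor"])
  expect_equal(sort(unname(as.integer(counts)), decreasing = TRUE),
               c(2, rep(1, 6)))
})

test_that("over-capacity cohorts raise a sizing error naming the slots", {
  cfg <- cohort_config(n_tumors = 10, n_plexes = 2, n_proteins = 200,
                       n_genes = 200, n_program = 20, n_hazard_genes = 5)
  expect_error(generate_plex_design(cfg), "10 tumors.*8 tumor channel-slots")
})

test_that("the generator is bit-reproducible given seed and config", {
  cfg <- tiny_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$psm, b$psm)
  expect_identical(a$rna, b$rna)
  expect_identical(a$cnv, b$cnv)
  expect_identical(a$truth$subtype, b$truth$subtype)
  c2 <- generate_cohort(tiny_config(seed = 43))
  expect_false(identical(a$psm, c2$psm))
})

test_that("pool channels carry the mean of the tumor expectations", {
  cfg <- tiny_config(noise_sd = 0, psm_sd = 0, channel_shift_sd = 0,
                     plex_shift_sd = 0, missing_rate = 0)
  co <- generate_cohort(cfg)
  # at zero noise every pool-channel intensity equals 2^mean(truth)
  pool_slots <- co$design[co$design$role == "pool", ]
  psm <- as.data.frame(co$psm)[!co$psm$decoy, ]
  for (k in sample(nrow(pool_slots), 3)) {
    pl <- pool_slots$plex[k]; ch <- pool_slots$channel[k]
    sub <- psm[psm$plex == pl, ]
    obs <- log2(sub[[paste0("ch_", ch)]])
    expect_equal(obs, unname(rowMeans(co$truth$mu)[sub$protein_group]),
                 tolerance = 1e-12)
  }
})

test_that("marginal missingness tracks the configured rate", {
  cfg <- tiny_config(n_proteins = 2000, n_genes = 2000, missing_rate = 0.10)
  co <- generate_cohort(cfg)
  psm <- as.data.frame(co$psm)[!co$psm$decoy, ]
  obs_pairs <- nrow(unique(psm[, c("protein_group", "plex")]))
  total <- cfg$n_proteins * cfg$n_plexes
  expect_lt(abs((1 - obs_pairs / total) - 0.10), 0.02)
})

test_that("transcript-protein coupling lands near the target correlation", {
  cfg <- tiny_config(n_proteins = 2000, n_genes = 2000)
  co <- generate_cohort(cfg)
  tumors <- colnames(co$truth$mu)
  idx <- seq_len(500)  # a representative slice keeps the check fast
  rho <- vapply(idx, function(i)
    cor(co$rna[i, tumors], co$truth$mu[i, tumors], method = "spearman"),
    numeric(1))
  expect_lt(abs(mean(rho) - 0.38), 0.05)
})

test_that("configured mutation odds are recovered across seeds", {
  odds <- default_mutation_odds()[1, ]  # the OR = 20 KEAP1-like model
  n_ok <- 0
  for (s in 1:200) {
    set.seed(s)
    subtype <- structure(sample(rep(1:3, c(43, 51, 14))),
                         names = sprintf("T%03d", 1:108))
    mut <- generate_mutations(subtype, odds)
    m <- mut$status == 1
    in2 <- subtype[mut$sample] == 2
    tab <- table(factor(in2, c(TRUE, FALSE)), factor(m, c(TRUE, FALSE)))
    if (any(tab == 0)) tab <- tab + 0.5
    or_hat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    if (or_hat > 20 / 3 && or_hat < 20 * 3) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / 200, 0.9)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(subtype_proportions = c(0.5, 0.6)),
               "sum to 1")
  expect_error(cohort_config(tumors_per_plex = 5), "must equal")
  expect_error(cohort_config(missing_rate = 1.5), "\\[0,1\\]")
})
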