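surv_df <- function(time, event, sample = NULL) {
  data.frame(sample = sample %||% paste0("s", seq_along(time)),
             time_years = time, event = event, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the log-rank statistic matches a hand computation", {
  # A events at 1,2,3; B events at 4,5,6; all uncensored
  rec <- surv_df(c(1, 2, 3, 4, 5, 6), rep(1, 6))
  g <- rep(c("A", "B"), each = 3)
  # hand calculation: O-E for group A over the 6 event times
  at_risk_a <- c(3, 2, 1, 0, 0, 0)
  at_risk <- c(6, 5, 4, 3, 2, 1)
  e_a <- at_risk_a / at_risk
  o_a <- c(1, 1, 1, 0, 0, 0)
  oe <- sum(o_a - e_a)
  v <- sum(e_a * (1 - at_risk_a / at_risk) * 1)  # one event per time
  expect_equal(km_logrank(rec, g)$chi2, oe^2 / v, tolerance = 1e-9)
})

test_that("identical groups and rescaled times behave as expected", {
  set.seed(61)
  t1 <- rexp(20); e1 <- rbinom(20, 1, 0.7)
  rec <- surv_df(c(t1, t1), c(e1, e1))
  g <- rep(c("A", "B"), each = 20)
  r <- km_logrank(rec, g)
  expect_equal(r$chi2, 0, tolerance = 1e-9)
  expect_equal(r$p, 1, tolerance = 1e-9)
  # positive time rescaling leaves the statistic unchanged
  rec2 <- surv_df(runif(40, 0.1, 5), rbinom(40, 1, 0.6))
  g2 <- rep(c("A", "B"), 20)
  a <- km_logrank(rec2, g2)
  rec3 <- rec2; rec3$time_years <- rec3$time_years * 7.3
  expect_equal(km_logrank(rec3, g2)$chi2, a$chi2, tolerance = 1e-9)
  # no events -> warning and p = 1
  expect_warning(r0 <- km_logrank(surv_df(1:4, rep(0, 4)),
                                  rep(c("A", "B"), 2)), "no events")
  expect_equal(r0$p, 1)
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(67)
  rec <- surv_df(rexp(60), rbinom(60, 1, 0.7))
  ps <- replicate(200, km_logrank(rec, sample(rep(c("A", "B"), 30)))$p)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cox estimates are well calibrated under the null", {
  set.seed(71)
  cover <- 0
  for (r in 1:200) {
    x <- rnorm(200)
    t_ev <- rexp(200, log(2) / 3)
    cens <- runif(200, 2, 8)
    rec <- surv_df(pmin(t_ev, cens), as.integer(t_ev <= cens))
    fit <- cox_univariate(rec, x)
    if (abs(fit$log_hr) <= 2 * fit$se) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.93)
})

test_that("monotone likelihoods are flagged and ties match across methods", {
  # covariate equal to event order, no censoring: beta diverges
  rec <- surv_df(1:20, rep(1, 20))
  fit <- suppressWarnings(cox_univariate(rec, 20:1))
  expect_true(fit$flagged)
  expect_true(is.na(fit$se))
  # without ties Breslow and Efron coincide
  set.seed(73)
  rec2 <- surv_df(sort(runif(50, 0.1, 10)), rbinom(50, 1, 0.8))
  x <- rnorm(50)
  b <- cox_univariate(rec2, x, ties = "breslow")
  e <- cox_univariate(rec2, x, ties = "efron")
  expect_equal(b$log_hr, e$log_hr, tolerance = 1e-8)
  expect_error(cox_univariate(rec2, rep(1, 50)), "constant")
})

test_that("random-effects pooling matches closed-form expectations", {
  mi <- data.frame(gene = "g", omic = 1:3,
                   log_hr = c(0.4, 0.4, 0.4), se = rep(0.1, 3))
  r <- random_effects_meta(mi)
  expect_equal(r$pooled_log_hr, 0.4, tolerance = 1e-8)
  expect_equal(r$tau2, 0, tolerance = 1e-8)
  # symmetric disagreement: pooled ~ 0 with positive heterogeneity
  mi2 <- data.frame(gene = "g", omic = 1:2,
                    log_hr = c(1, -1), se = c(0.1, 0.1))
  r2 <- random_effects_meta(mi2)
  expect_equal(r2$pooled_log_hr, 0, tolerance = 1e-6)
  expect_gt(r2$tau2, 0)
  # pooled estimate always inside the input range; pooled se bounded
  set.seed(79)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    y <- rnorm(k); s <- runif(k, 0.05, 0.5)
    ri <- random_effects_meta(data.frame(gene = "g", omic = seq_len(k),
                                         log_hr = y, se = s))
    expect_gte(ri$pooled_log_hr, min(y) - 1e-9)
    expect_lte(ri$pooled_log_hr, max(y) + 1e-9)
    expect_gte(ri$tau2, 0)
    if (ri$tau2 == 0) expect_lte(ri$pooled_se, max(s) + 1e-9)
  }
})

test_that("empirical-Bayes tau2 recovers simulated heterogeneity", {
  set.seed(83)
  tau2 <- 0.25
  rows <- lapply(1:500, function(g) {
    theta <- rnorm(1, 0, 1)
    se <- runif(3, 0.15, 0.35)
    data.frame(gene = g, omic = 1:3,
               log_hr = theta + rnorm(3, 0, sqrt(tau2)) + rnorm(3, 0, se),
               se = se)
  })
  fit <- random_effects_meta(do.call(rbind, rows))
  expect_gte(median(fit$tau2, na.rm = TRUE), 0.15)
  expect_lte(median(fit$tau2, na.rm = TRUE), 0.35)
})

test_that("multi-omic Cox feeds the meta-analysis end to end", {
  co <- generate_cohort(tiny_config(n_tumors = 40, n_plexes = 10))
  genes <- paste0("g", sprintf("%04d", 1:30))
  z <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(genes, co$survival$sample))
  mi <- multi_omic_cox(co$survival, list(a = z, b = z + rnorm(1200, 0, 0.5)),
                       genes = genes[1:20])
  expect_true(all(mi$omic %in% c("a", "b")))
  expect_true(all(mi$se > 0))
  fit <- random_effects_meta(mi)
  expect_equal(nrow(fit), 20)
  expect_true(all(fit$q >= fit$p * 0, na.rm = TRUE))
})
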