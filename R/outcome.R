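#' Log-rank test between survival groups
#'
#' Standard log-rank statistic over the pooled event times, chi-square
#' p on (groups - 1) df. With no events in any group the test is
#' undefined and p = 1 is returned with a warning.
#'
#' @param records data.frame sample, time_years, event (1 = event).
#' @param groups group label per record.
#' @return list(chi2, df, p).
#' @export
km_logrank <- function(records, groups) {
  stopifnot(nrow(records) == length(groups), all(records$time_years > 0))
  if (sum(records$event) == 0) {
    warning("no events observed; log-rank test undefined, p = 1")
    return(list(chi2 = 0, df = length(unique(groups)) - 1L, p = 1))
  }
  sd <- survival::survdiff(
    survival::Surv(records$time_years, records$event) ~ factor(groups))
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Newton-Raphson, Breslow tie handling by
#' default, Efron available), standard error from the observed
#' information, two-sided Wald p. Non-convergence or a monotone partial
#' likelihood (infinite coefficient) yields a flagged result with a
#' missing standard error.
#'
#' @param records data.frame sample, time_years, event.
#' @param covariate numeric vector aligned with `records`.
#' @param ties "breslow" (default) or "efron".
#' @param standardize center and scale the covariate first (so the log
#'   hazard ratio is per SD) — useful before cross-omic meta-analysis.
#' @return list(log_hr, se, p, n, n_events, flagged).
#' @export
cox_univariate <- function(records, covariate,
                           ties = c("breslow", "efron"),
                           standardize = FALSE) {
  ties <- match.arg(ties)
  stopifnot(nrow(records) == length(covariate))
  ok <- !is.na(covariate) & !is.na(records$time_years) & !is.na(records$event)
  x <- covariate[ok]
  if (length(unique(x)) < 2) stop("covariate is constant")
  if (sum(records$event[ok]) < 5)
    warning("fewer than 5 events; estimate will be unstable")
  if (standardize) x <- as.vector(scale(x))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(records$time_years[ok], records$event[ok]) ~ x,
      ties = ties, control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) flagged <- TRUE
  if (flagged) se <- NA_real_
  p <- if (is.na(se)) NA_real_ else
    2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  list(log_hr = beta, se = se, p = p, n = sum(ok),
       n_events = sum(records$event[ok]), flagged = flagged)
}

#' Random-effects meta-analysis across omic layers
#'
#' Per gene, pools the per-omic log hazard ratios with a random-effects
#' model whose between-omic heterogeneity tau^2 is estimated by the
#' iterative empirical-Bayes (Paule-Mandel-type) scheme — the weighted
#' residual statistic is equated to its expectation, tau^2 >= 0 — via
#' `metafor::rma(method = "EB")`. The pooled estimate is the
#' inverse-variance weighted mean with weights `1 / (se^2 + tau2)`;
#' genes where the estimator fails fall back to DerSimonian-Laird and
#' are flagged. Storey q-values are computed across genes and genes with
#' q at or below `q_threshold` are marked selected.
#'
#' @param meta_input data.frame gene, omic, log_hr, se (se > 0); genes
#'   need at least 2 usable omic estimates.
#' @param q_threshold Storey-q selection cutoff.
#' @return data.frame: gene, k, pooled_log_hr, pooled_se, tau2, p, q,
#'   selected, fallback.
#' @export
random_effects_meta <- function(meta_input, q_threshold = 0.3) {
  stopifnot(all(c("gene", "log_hr", "se") %in% names(meta_input)))
  use <- !is.na(meta_input$log_hr) & !is.na(meta_input$se) & meta_input$se > 0
  mi <- meta_input[use, , drop = FALSE]
  genes <- unique(mi$gene)
  out <- data.frame(gene = genes, k = NA_integer_,
                    pooled_log_hr = NA_real_, pooled_se = NA_real_,
                    tau2 = NA_real_, p = NA_real_,
                    fallback = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- mi[mi$gene == genes[i], , drop = FALSE]
    out$k[i] <- nrow(g)
    if (nrow(g) < 2) next
    fit <- tryCatch(
      suppressWarnings(metafor::rma(yi = g$log_hr, sei = g$se,
                                    method = "EB",
                                    control = list(tol = 1e-8,
                                                   maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        suppressWarnings(metafor::rma(yi = g$log_hr, sei = g$se,
                                      method = "DL")),
        error = function(e) NULL)
      out$fallback[i] <- TRUE
    }
    if (is.null(fit)) next
    out$pooled_log_hr[i] <- as.numeric(fit$b)
    out$pooled_se[i] <- fit$se
    out$tau2[i] <- fit$tau2
    out$p[i] <- fit$pval
  }
  est <- !is.na(out$p)
  if (sum(est) >= 2) {
    sq <- storey_qvalue(out$p[est])
    out$q <- NA_real_
    out$q[est] <- sq$q
    attr(out, "pi0") <- sq$pi0
  } else {
    out$q <- out$p
  }
  out$selected <- !is.na(out$q) & out$q <= q_threshold
  out
}

#' Assemble per-gene multi-omic Cox inputs
#'
#' Fits a univariate Cox model per gene within each omic matrix
#' (standardized covariates by default, so log hazard ratios are per SD
#' and comparable across layers) and stacks the estimates in the shape
#' [random_effects_meta()] expects. Genes must be present in all
#' supplied matrices; flagged or failed fits are dropped per gene.
#'
#' @param records survival records (sample, time_years, event).
#' @param omics named list of genes x samples matrices (e.g. cnv, rna,
#'   protein).
#' @param genes genes to fit; default: intersection of all rownames.
#' @param standardize passed to [cox_univariate()].
#' @return data.frame gene, omic, log_hr, se.
#' @export
multi_omic_cox <- function(records, omics, genes = NULL,
                           standardize = TRUE) {
  if (is.null(genes))
    genes <- Reduce(intersect, lapply(omics, rownames))
  rows <- list()
  for (om in names(omics)) {
    m <- omics[[om]][, records$sample, drop = FALSE]
    for (g in genes) {
      x <- m[g, ]
      if (length(unique(x[!is.na(x)])) < 2) next
      fit <- tryCatch(
        suppressWarnings(cox_univariate(records, x,
                                        standardize = standardize)),
        error = function(e) NULL)
      if (is.null(fit) || fit$flagged || is.na(fit$se)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, omic = om, log_hr = fit$log_hr, se = fit$se,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
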