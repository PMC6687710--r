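#' Generate a synthetic proteogenomic cohort with known ground truth
#'
#' Simulates every input of the downstream pipeline from one seeded
#' configuration: a PSM-level reporter-intensity table (targets plus
#' score-shifted decoys), a gene-level log2 RNA matrix coupled to the
#' protein truth, a mutation table with subtype-dependent odds, per-sample
#' CNV segment tables, a dependency-screen score table with planted
#' essential genes, survival records with gene-linked hazards, and the
#' ground truth needed to test recovery.
#'
#' Protein abundances are generated on the log2 scale — baseline +
#' subtype-program effect + tumor-level biological spread (+ CNV dosage
#' for planted genes) — then shifted by per-plex and per-channel batch
#' terms and spectrum-level offsets, and exponentiated into reporter
#' intensities. Pool channels carry the cohort-average profile (mean of
#' the tumor expectations per protein). Missingness acts at the
#' protein-by-plex level: all channels of a plex drop together.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `psm` (wide
#'   data.table: plex, spectrum_id, peptide, protein_group, decoy, score,
#'   ch_1..ch_C), `design`, `rna` (genes x tumors log2 matrix),
#'   `mutations`, `cnv` (BED-like segments, 0-based half-open),
#'   `gene_models`, `screen`, `survival`, and `truth` (subtype labels,
#'   program membership, expected log2 matrix `mu`, pool profile, planted
#'   vulnerabilities, mutation/CNV/hazard truth — for tests only).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  design <- generate_plex_design(config)  # seeds with config$seed
  set.seed(stage_seed(config$seed, "cohort"))

  P <- config$n_proteins
  G <- config$n_genes
  S <- length(config$subtype_proportions)
  tumors <- sprintf("T%03d", seq_len(config$n_tumors))
  genes <- sprintf("g%04d", seq_len(G))
  proteins <- genes[seq_len(P)]

  ## --- latent subtype labels (largest-remainder apportionment) ----------
  raw <- config$subtype_proportions * config$n_tumors
  counts <- floor(raw)
  rem <- config$n_tumors - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  subtype <- sample(rep(seq_len(S), counts))
  names(subtype) <- tumors

  ## --- protein truth ----------------------------------------------------
  program <- lapply(seq_len(S), function(s)
    proteins[((s - 1) * config$n_program + 1):(s * config$n_program)])
  ## planted picks are spaced across the program so their focal CNV
  ## segments cannot overlap a neighboring planted gene
  planted <- program[[min(2, S)]][
    round(seq(1, config$n_program, length.out = config$n_planted))]
  mut_idx <- S * config$n_program + seq_len(nrow(config$mutation_odds))
  mut_genes <- structure(genes[mut_idx], names = config$mutation_odds$label)
  haz_genes <- genes[max(mut_idx) + seq_len(config$n_hazard_genes)]

  base <- stats::rnorm(P, 10, 1)
  mu <- matrix(base, P, config$n_tumors,
               dimnames = list(proteins, tumors))
  for (s in seq_len(S))
    mu[program[[s]], subtype == s] <- mu[program[[s]], subtype == s] +
      config$de_effect_log2
  mu <- mu + matrix(stats::rnorm(P * config$n_tumors, 0, config$bio_sd),
                    P, config$n_tumors)

  ## planted vulnerability genes: CNV dosage drives protein abundance
  dosage <- matrix(0L, config$n_planted, config$n_tumors,
                   dimnames = list(planted, tumors))
  p_focal <- c(0.15, 0.35, 0.50)  # gains enriched in the focal subtype
  p_other <- c(0.25, 0.50, 0.25)
  for (g in seq_len(config$n_planted))
    dosage[g, ] <- vapply(subtype, function(s)
      sample(c(-1L, 0L, 1L), 1,
             prob = if (s == min(2, S)) p_focal else p_other), integer(1))
  mu[planted, ] <- mu[planted, ] + config$cnv_coef * dosage

  pool_profile <- rowMeans(mu)

  ## --- PSM-level reporter table -----------------------------------------
  psm <- simulate_psms(config, design, mu, pool_profile)

  ## --- RNA matrix coupled to protein truth ------------------------------
  rho_p <- 2 * sin(pi * config$rna_protein_rho_target / 6)  # rank -> linear
  coupling <- rep(rho_p, G)
  names(coupling) <- genes
  coupling[planted] <- 0.95
  rna <- matrix(stats::rnorm(G * config$n_tumors), G, config$n_tumors,
                dimnames = list(genes, tumors))
  zmu <- t(scale(t(mu)))
  rna[seq_len(P), ] <- coupling[seq_len(P)] * zmu +
    sqrt(1 - coupling[seq_len(P)]^2) * rna[seq_len(P), ]
  rna <- rna + stats::rnorm(G, 5, 2)  # gene-level expression offsets

  ## --- remaining layers --------------------------------------------------
  mutations <- generate_mutations(subtype, config$mutation_odds, mut_genes)
  gene_models <- make_gene_models(genes)
  cnv <- generate_cnv_segments(tumors, gene_models, planted, dosage)
  screen <- generate_screen(genes, planted, config$n_cell_lines)
  hazard_log <- structure(rep(0, G), names = genes)
  hazard_log[haz_genes] <- config$hazard_log
  survival <- generate_survival(t(zmu)[, haz_genes, drop = FALSE],
                                rep(config$hazard_log, length(haz_genes)),
                                config$median_survival_years,
                                config$censor_years)

  truth <- list(
    subtype = subtype,
    programs = program,
    de_proteins = program,
    mu = mu,
    pool_profile = pool_profile,
    planted = planted,
    dosage = dosage,
    mutation_genes = mut_genes,
    mutant_samples = split(mutations$sample[mutations$status == 1],
                           mutations$gene[mutations$status == 1]),
    hazard_log = hazard_log,
    coupling = coupling
  )
  structure(list(psm = psm, design = design, rna = rna,
                 mutations = mutations, cnv = cnv,
                 gene_models = gene_models, screen = screen,
                 survival = survival, truth = truth, config = config),
            class = "synthetic_cohort")
}

## Reporter-intensity simulation. One wide row per spectrum; channel
## intensities are 2^(expected log2 + plex shift + channel shift +
## spectrum offset + noise). Decoys are score-shifted null spectra.
simulate_psms <- function(config, design, mu, pool_profile) {
  P <- nrow(mu)
  J <- config$n_plexes
  C <- config$channels_per_plex
  proteins <- rownames(mu)

  ## expected log2 value per protein for every (plex, channel) slot
  slot_val <- matrix(NA_real_, P, J * C)
  for (k in seq_len(nrow(design))) {
    col <- (design$plex[k] - 1) * C + design$channel[k]
    slot_val[, col] <- if (design$role[k] == "pool") pool_profile
                       else mu[, design$sample_id[k]]
  }

  n_psm <- matrix(pmax(1L, stats::rpois(P * J, config$psm_rate)), P, J)
  observed <- matrix(stats::runif(P * J) >= config$missing_rate, P, J)
  n_psm[!observed] <- 0L
  total <- sum(n_psm)

  prot_i <- rep(rep(seq_len(P), J), as.vector(n_psm))
  plex_i <- rep(rep(seq_len(J), each = P), as.vector(n_psm))
  within <- sequence(as.vector(n_psm))  # index within each protein x plex

  n_pep <- 2L + stats::rpois(P, 1)
  pep_i <- ((within - 1L) %% n_pep[prot_i]) + 1L

  plex_shift <- stats::rnorm(J, 0, config$plex_shift_sd)
  chan_shift <- matrix(stats::rnorm(J * C, 0, config$channel_shift_sd), J, C)
  chan_shift[, 1] <- 0  # shifts are relative to the reference-pool channel
  delta <- stats::rnorm(total, 0, config$psm_sd)

  intens <- matrix(NA_real_, total, C)
  for (c in seq_len(C)) {
    ev <- slot_val[cbind(prot_i, (plex_i - 1L) * C + c)]
    noise <- if (config$noise_sd > 0)
      stats::rnorm(total, 0, config$noise_sd) else 0
    intens[, c] <- 2^(ev + plex_shift[plex_i] + chan_shift[cbind(plex_i, c)] +
                        delta + noise)
  }

  correct <- stats::runif(total) >= config$incorrect_target_rate
  score <- ifelse(correct, stats::rnorm(total, 4, 1), stats::rnorm(total, 0, 1))

  tgt <- data.table::data.table(
    plex = plex_i,
    spectrum_id = sprintf("sp%07d", seq_len(total)),
    peptide = sprintf("pep_%s_%02d", proteins[prot_i], pep_i),
    protein_group = proteins[prot_i],
    decoy = FALSE,
    score = score
  )
  ch_cols <- sprintf("ch_%d", seq_len(C))
  tgt[, (ch_cols) := data.table::as.data.table(intens)]

  n_dec <- round(config$decoy_fraction * total)
  if (n_dec > 0) {
    dp <- sample(seq_len(P), n_dec, replace = TRUE)
    dec <- data.table::data.table(
      plex = sample(seq_len(J), n_dec, replace = TRUE),
      spectrum_id = sprintf("spD%06d", seq_len(n_dec)),
      peptide = sprintf("dpep_%s_%02d", proteins[dp],
                        sample(3L, n_dec, replace = TRUE)),
      protein_group = paste0("DECOY_", proteins[dp]),
      decoy = TRUE,
      score = stats::rnorm(n_dec, 0, 1)
    )
    dec[, (ch_cols) := data.table::as.data.table(
      matrix(2^stats::rnorm(n_dec * C, 8, 1), n_dec, C))]
    tgt <- data.table::rbindlist(list(tgt, dec), use.names = TRUE)
  }
  tgt[]
}

#' Draw mutation indicators with subtype-dependent odds
#'
#' For each configured gene the mutation probability outside the enriched
#' subtype is `base_rate`; inside it the odds are multiplied by `or`.
#'
#' @param subtype named integer vector of subtype labels per tumor.
#' @param odds data.frame as in [default_mutation_odds()].
#' @param gene_ids named character vector mapping odds labels to gene ids
#'   (defaults to the labels themselves).
#' @return data.frame sample, gene, status (0/1).
#' @export
generate_mutations <- function(subtype, odds = default_mutation_odds(),
                               gene_ids = NULL) {
  if (is.null(gene_ids))
    gene_ids <- structure(odds$label, names = odds$label)
  out <- lapply(seq_len(nrow(odds)), function(i) {
    p0 <- odds$base_rate[i]
    odd <- p0 / (1 - p0) * ifelse(subtype == odds$subtype[i], odds$or[i], 1)
    p <- odd / (1 + odd)
    data.frame(sample = names(subtype),
               gene = gene_ids[[odds$label[i]]],
               status = as.integer(stats::runif(length(subtype)) < p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## Toy genome: five 100-Mb chromosomes, genes in order, 0-based half-open.
make_gene_models <- function(genes) {
  n <- length(genes)
  per_chrom <- ceiling(n / 5)
  idx <- seq_len(n) - 1L
  start <- (idx %% per_chrom) * 45000
  data.frame(gene = genes,
             chrom = paste0("chr", idx %/% per_chrom + 1L),
             start = start, end = start + 20000,
             stringsAsFactors = FALSE)
}

#' Simulate per-sample CNV segment tables
#'
#' Background segments (lognormal lengths, ~800 bp probe spacing, random
#' gain/loss log2 values; a share deliberately below the 50-probe/400-kb
#' reporting gates) plus focal segments covering planted genes wherever
#' their designed dosage is non-zero.
#'
#' @param samples sample ids.
#' @param gene_models toy gene models (0-based half-open BED-like).
#' @param planted planted gene ids.
#' @param dosage planted-gene dosage matrix (genes x samples, -1/0/1).
#' @return data.frame sample, chrom, start, end, n_probes, log2.
#' @export
generate_cnv_segments <- function(samples, gene_models,
                                  planted = character(0), dosage = NULL) {
  chroms <- unique(gene_models$chrom)
  chrom_len <- 1e8
  segs <- lapply(samples, function(s) {
    n <- stats::rpois(1, 20)
    if (n == 0) return(NULL)
    len <- round(stats::rlnorm(n, log(1.2e6), 1.0))
    start <- floor(stats::runif(n, 0, chrom_len - len))
    data.frame(sample = s,
               chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + len,
               n_probes = pmax(1L, round(len / 800 * stats::runif(n, .8, 1.2))),
               log2 = round(sample(c(-1, 1), n, TRUE) * stats::runif(n, .3, 1), 3),
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  if (length(planted)) {
    ## planted loci are owned by their focal alteration: background
    ## segments never overlap them, so the planted dosage is the state
    gm <- gene_models[match(planted, gene_models$gene), ]
    clash <- rep(FALSE, nrow(segs))
    for (g in seq_len(nrow(gm)))
      clash <- clash | (segs$chrom == gm$chrom[g] &
                          segs$start < gm$end[g] + 1e6 &
                          gm$start[g] - 1e6 < segs$end)
    segs <- segs[!clash, , drop = FALSE]
  }
  if (length(planted) && !is.null(dosage)) {
    gm <- gene_models[match(planted, gene_models$gene), ]
    hit <- which(dosage != 0, arr.ind = TRUE)
    if (nrow(hit)) {
      g <- hit[, 1]; s <- hit[, 2]
      start <- pmax(0, gm$start[g] - 4e5)
      end <- gm$end[g] + 4e5
      segs <- rbind(segs, data.frame(
        sample = samples[s], chrom = gm$chrom[g],
        start = start, end = end,
        n_probes = pmax(50L, round((end - start) / 800)),
        log2 = 0.58 * dosage[hit],
        stringsAsFactors = FALSE))
    }
  }
  rownames(segs) <- NULL
  segs[order(segs$sample, segs$chrom, segs$start), ]
}

#' Simulate a dependency-screen score table
#'
#' RSA-like scores (log scale, lower = more essential) per gene and cell
#' line, with planted genes scoring far below the -3 significance
#' threshold and carrying confirmatory Bayes factors above 3.
#'
#' @param genes gene ids.
#' @param planted planted essential gene ids.
#' @param n_cell_lines number of screened lines.
#' @return data.frame gene, cell_line, rsa, bayes_factor.
#' @export
generate_screen <- function(genes, planted = character(0), n_cell_lines = 4) {
  lines <- sprintf("line_%d", seq_len(n_cell_lines))
  out <- expand.grid(gene = genes, cell_line = lines,
                     stringsAsFactors = FALSE)
  out$rsa <- stats::rnorm(nrow(out), -0.5, 1)
  out$bayes_factor <- stats::rnorm(nrow(out), 0, 1)
  hit <- out$gene %in% planted
  out$rsa[hit] <- stats::rnorm(sum(hit), -5, 0.3)
  out$bayes_factor[hit] <- stats::rnorm(sum(hit), 10, 1)
  out
}

#' Simulate survival records from gene-linked hazards
#'
#' Event times are exponential with rate
#' `log(2)/median_survival_years * exp(z %*% beta)`; censoring is
#' uniform administrative.
#'
#' @param z samples x genes matrix of standardized covariates.
#' @param beta log hazard ratios, one per column of `z`.
#' @param median_survival_years baseline median survival.
#' @param censor_years range of uniform censoring times.
#' @return data.frame sample, time_years, event.
#' @export
generate_survival <- function(z, beta, median_survival_years = 3,
                              censor_years = c(5, 10)) {
  n <- nrow(z)
  lp <- if (length(beta)) drop(z %*% beta) else rep(0, n)
  rate <- log(2) / median_survival_years * exp(lp)
  t_ev <- stats::rexp(n, rate)
  t_cn <- stats::runif(n, censor_years[1], censor_years[2])
  data.frame(sample = rownames(z),
             time_years = pmax(1e-6, pmin(t_ev, t_cn)),
             event = as.integer(t_ev <= t_cn),
             stringsAsFactors = FALSE)
}

## Deterministic per-stage child seeds below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100000L) * 17681L + h %% 17681L
}
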