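#' Synthetic cohort configuration
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults reproduce the design of a 29-plex TMT
#' 6-plex tumor cohort: four tumors plus two aliquots of a common tumor
#' pool per plex (174 channel-slots, 58 of them pools for 108 distinct
#' tumors), three latent proteomic subtypes in proportions 40/47/13,
#' subtype-specific protein programs, per-plex multiplicative batch
#' effects, transcript-protein coupling targeting a cohort mean Spearman
#' correlation of 0.38, mutation-subtype enrichment (including a
#' KEAP1-like gene at odds ratio 20 in the redox-like subtype), CNV
#' segments, dependency-screen scores with planted vulnerabilities, and
#' exponential survival with gene-linked log-hazards.
#'
#' @param n_tumors number of distinct tumors.
#' @param n_plexes number of TMT plexes.
#' @param channels_per_plex reporter channels per plex.
#' @param tumors_per_plex tumor channels per plex.
#' @param pools_per_plex pool-replicate channels per plex; channel 1 of
#'   every plex is the fixed reference pool (the "ch-126" analog).
#' @param n_proteins,n_genes feature space sizes; proteins are matched to
#'   the first `n_proteins` genes by shared identifier.
#' @param subtype_proportions simplex vector of latent subtype weights.
#' @param n_program proteins in each subtype's expression program.
#' @param de_effect_log2 log2 shift of program proteins in their subtype.
#' @param bio_sd tumor-to-tumor biological spread per protein (log2).
#' @param noise_sd reporter-level measurement noise (log2).
#' @param psm_sd spectrum-to-spectrum ionization spread (log2).
#' @param psm_rate Poisson mean of spectra per protein per plex (min 1).
#' @param plex_shift_sd per-plex multiplicative batch effect scale (log2).
#' @param channel_shift_sd per-channel loading/mixing spread (log2).
#' @param rna_protein_rho_target target cohort-mean Spearman correlation
#'   between matched transcript and protein profiles.
#' @param mutation_odds data.frame with columns `label`, `subtype`
#'   (0 = none), `or`, `base_rate` describing per-gene mutation models.
#' @param decoy_fraction decoy PSMs as a fraction of target PSMs.
#' @param incorrect_target_rate fraction of target PSMs drawn from the
#'   null (decoy-like) score distribution.
#' @param missing_rate probability that a protein is unobserved in a plex
#'   (all channels of that plex missing together).
#' @param n_planted planted vulnerability genes (CNV-driven, elevated in
#'   the focal subtype, essential in the dependency screen).
#' @param cnv_coef log2 protein response per unit CNV dosage for planted
#'   genes; the default makes their CNV-protein rank correlation clear
#'   the cascade gates with margin, which is these genes' design role
#'   (strongly dosage-driven vulnerabilities).
#' @param n_cell_lines cell lines in the synthetic dependency screen.
#' @param n_hazard_genes,hazard_log genes with non-zero survival effect
#'   and their common log hazard ratio per SD of protein abundance.
#' @param median_survival_years baseline median survival.
#' @param censor_years range of uniform administrative censoring times.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   same seed and configuration.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumors = 108,
                          n_plexes = 29,
                          channels_per_plex = 6,
                          tumors_per_plex = 4,
                          pools_per_plex = 2,
                          n_proteins = 2000,
                          n_genes = 2000,
                          subtype_proportions = c(0.40, 0.47, 0.13),
                          n_program = 100,
                          de_effect_log2 = 1.0,
                          bio_sd = 0.5,
                          noise_sd = 0.25,
                          psm_sd = 0.5,
                          psm_rate = 3,
                          plex_shift_sd = 0.3,
                          channel_shift_sd = 0.1,
                          rna_protein_rho_target = 0.38,
                          mutation_odds = default_mutation_odds(),
                          decoy_fraction = 0.3,
                          incorrect_target_rate = 0.05,
                          missing_rate = 0.05,
                          n_planted = 5,
                          cnv_coef = 1.2,
                          n_cell_lines = 4,
                          n_hazard_genes = 10,
                          hazard_log = 0.5,
                          median_survival_years = 3,
                          censor_years = c(5, 10),
                          seed = 1234) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Default mutation models for the synthetic cohort
#'
#' One row per mutated gene: `subtype` is the enriched subtype (0 for no
#' enrichment), `or` the odds ratio of mutation in that subtype versus the
#' rest, and `base_rate` the mutation probability outside the enriched
#' subtype. The KEAP1-like entry emulates a strongly subtype-linked tumor
#' suppressor (OR 20 in the redox-like subtype at a low background rate).
#'
#' @return data.frame with columns label, subtype, or, base_rate.
#' @export
default_mutation_odds <- function() {
  data.frame(
    label = c("KEAP1like", "NFE2L2like", "APClike", "TP53like"),
    subtype = c(2L, 2L, 3L, 0L),
    or = c(20, 3.9, 5.5, 1),
    base_rate = c(0.0175, 0.14, 0.05, 0.55),
    stringsAsFactors = FALSE
  )
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with(cfg, {
    if (abs(sum(subtype_proportions) - 1) > 1e-9)
      stop("subtype_proportions must sum to 1 (tolerance 1e-9)")
    if (any(subtype_proportions < 0))
      stop("subtype_proportions must be non-negative")
    if (tumors_per_plex + pools_per_plex != channels_per_plex)
      stop("tumors_per_plex + pools_per_plex must equal channels_per_plex")
    for (nm in c("decoy_fraction", "incorrect_target_rate", "missing_rate")) {
      v <- get(nm)
      if (v < 0 || v > 1) stop(sprintf("%s must lie in [0,1]", nm))
    }
    if (rna_protein_rho_target < 0 || rna_protein_rho_target >= 0.95)
      stop("rna_protein_rho_target must lie in [0, 0.95)")
    if (n_proteins > n_genes)
      stop("n_proteins must not exceed n_genes (proteins are gene-matched)")
    if (length(subtype_proportions) * n_program + nrow(mutation_odds) +
        n_hazard_genes > n_proteins)
      stop("n_proteins too small for the configured programs and gene roles")
    if (pools_per_plex < 1) stop("each plex needs at least one pool channel")
  })
  invisible(cfg)
}

#' Lay out tumors and pool replicates across TMT plexes
#'
#' Every plex carries `pools_per_plex` pool channels — one fixed in
#' channel 1 (the reference-pool channel present in every plex, analogous
#' to reporter m/z 126) and the rest in varying channels — plus
#' `tumors_per_plex` tumor channels. Each tumor is assigned to at least
#' one channel-slot; surplus tumor slots become replicate injections of
#' randomly chosen tumors.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `plex`, `channel`, `sample_id`,
#'   `role` ("tumor"/"pool"), `is_ref_pool`.
#' @export
generate_plex_design <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_slots <- config$n_plexes * config$tumors_per_plex
  if (config$n_tumors > n_slots)
    stop(sprintf(
      "cohort does not fit: %d tumors but only %d tumor channel-slots (%d plexes x %d tumors/plex)",
      config$n_tumors, n_slots, config$n_plexes, config$tumors_per_plex))

  tumors <- sprintf("T%03d", seq_len(config$n_tumors))
  surplus <- n_slots - config$n_tumors
  assignment <- c(tumors,
                  if (surplus > 0) sample(tumors, surplus, replace = surplus > config$n_tumors))
  assignment <- sample(assignment)  # scatter tumors and replicates over slots

  rows <- vector("list", config$n_plexes)
  slot <- 0L
  for (j in seq_len(config$n_plexes)) {
    ch <- seq_len(config$channels_per_plex)
    pool_ch <- 1L
    if (config$pools_per_plex > 1)
      pool_ch <- c(1L, sample(ch[-1], config$pools_per_plex - 1L))
    tumor_ch <- setdiff(ch, pool_ch)
    ids <- character(config$channels_per_plex)
    ids[pool_ch] <- sprintf("pool_%02d_%d", j, pool_ch)
    ids[tumor_ch] <- assignment[slot + seq_along(tumor_ch)]
    slot <- slot + length(tumor_ch)
    rows[[j]] <- data.frame(
      plex = j, channel = ch, sample_id = ids,
      role = ifelse(ch %in% pool_ch, "pool", "tumor"),
      is_ref_pool = ch == 1L,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
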