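#' Build a pipeline configuration
#'
#' One validated list drives the whole workflow: the synthetic-cohort
#' generator (or paths to user-supplied inputs), assembly and bridging
#' parameters, consensus-clustering settings, association thresholds,
#' integration gates, and survival/meta settings. Load from YAML with
#' [read_pipeline_config()].
#'
#' @param cohort a [cohort_config()] (ignored if `input_dir` is given).
#' @param input_dir optional directory of cohort TSVs ([write_cohort()]
#'   schema) to ingest instead of simulating.
#' @param strict_fdr,min_peptides,relaxed_fdr two-step assembly settings.
#' @param observation_min_fraction observed-fraction gate for the core
#'   matrix.
#' @param n_variable_features,k_range,n_resamples,p_item,p_feature,cluster_seed,delta_threshold
#'   consensus clustering and k selection.
#' @param merge_map optional named vector mapping clusters to subtype
#'   names.
#' @param label_sets optional named list of feature sets used to derive
#'   a merge map by enrichment labelling ([derive_merge_map()]) when
#'   `merge_map` is not given.
#' @param fc_threshold,alpha differential-expression gates.
#' @param rho_high,rho_low_band correlation band bounds.
#' @param cascade_rho_min,cascade_padj_max,cascade_rsa_max,cascade_bf_min
#'   vulnerability cascade gates.
#' @param cnv_min_probes,cnv_min_length CNV segment reporting gates.
#' @param meta_q_threshold Storey-q selection cutoff.
#' @param seed master seed; per-stage seeds derive from it by a stable
#'   hash of the stage name.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            input_dir = NULL,
                            strict_fdr = 0.001, min_peptides = 2,
                            relaxed_fdr = 0.01,
                            observation_min_fraction = 0.9,
                            n_variable_features = 1000,
                            k_range = 2:9, n_resamples = 1000,
                            p_item = 0.8, p_feature = 1.0,
                            cluster_seed = 1234,
                            delta_threshold = 0.10,
                            merge_map = NULL,
                            label_sets = NULL,
                            fc_threshold = 1.5, alpha = 0.05,
                            rho_high = 0.5, rho_low_band = c(-0.2, 0.2),
                            cascade_rho_min = 0.5, cascade_padj_max = 0.25,
                            cascade_rsa_max = -3, cascade_bf_min = 3,
                            cnv_min_probes = 50, cnv_min_length = 400000,
                            meta_q_threshold = 0.3,
                            seed = 1234) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  issues <- validate_config(cfg)
  if (length(issues))
    stop(paste(c("invalid pipeline configuration:", issues),
               collapse = "\n  "))
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns every violated constraint as a character vector (empty when
#' the configuration is valid) rather than stopping at the first
#' problem.
#'
#' @param config a `pipeline_config` (or plain list with its fields).
#' @return character vector of violations.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  need <- c("strict_fdr", "relaxed_fdr", "min_peptides",
            "observation_min_fraction", "k_range", "n_resamples",
            "p_item", "fc_threshold", "alpha", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing))
    return(sprintf("required field missing: %s", missing))
  chk <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  chk(config$p_item > 0 && config$p_item <= 1,
      "p_item must lie in (0,1]")
  chk(is.null(config$p_feature) ||
        (config$p_feature > 0 && config$p_feature <= 1),
      "p_feature must lie in (0,1]")
  chk(config$strict_fdr > 0 && config$strict_fdr < 1,
      "strict_fdr must lie in (0,1)")
  chk(config$relaxed_fdr >= config$strict_fdr && config$relaxed_fdr < 1,
      "relaxed_fdr must lie in [strict_fdr, 1)")
  chk(config$observation_min_fraction > 0 &&
        config$observation_min_fraction <= 1,
      "observation_min_fraction must lie in (0,1]")
  chk(config$min_peptides >= 1, "min_peptides must be >= 1")
  chk(length(config$k_range) >= 3, "k_range needs at least 3 values")
  chk(config$n_resamples >= 1, "n_resamples must be >= 1")
  chk(config$fc_threshold >= 1, "fc_threshold must be >= 1")
  chk(config$alpha > 0 && config$alpha <= 1, "alpha must lie in (0,1]")
  chk(is.numeric(config$seed) && config$seed == round(config$seed),
      "seed must be an integer")
  if (!is.null(config$input_dir))
    chk(dir.exists(config$input_dir),
        sprintf("input_dir does not exist: %s", config$input_dir))
  issues
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields in the YAML override [pipeline_config()] defaults;
#' nested `cohort:` fields override [cohort_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort
  y$cohort <- NULL
  cohort <- do.call(cohort_config, cohort_args %||% list())
  do.call(pipeline_config, c(list(cohort = cohort), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full proteogenomic pipeline
#'
#' Executes cohort simulation (or ingestion), two-step FDR assembly,
#' cross-plex bridging, observation filtering, consensus-clustering
#' subtype discovery, per-subtype differential expression and
#' mutation-association tests, cross-omic correlation and the
#' vulnerability cascade, survival log-rank by subtype, and the
#' three-omic random-effects meta-analysis. Artifacts are written
#' write-once under `out_dir`; a manifest (JSON, no timestamps, so
#' identical configs give byte-identical manifests) records parameters,
#' seeds and per-stage row counts. If the screen table is absent the
#' cascade stage is skipped and the manifest notes it.
#'
#' @param config a `pipeline_config`.
#' @param out_dir artifact directory.
#' @return list with the principal in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  issues <- validate_config(config)
  if (length(issues))
    stop(paste(c("invalid pipeline configuration:", issues),
               collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "proteogx",
                   version = as.character(utils::packageVersion("proteogx")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## --- cohort -----------------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(config$input_dir)) read_cohort_dir(config$input_dir)
    else generate_cohort(config$cohort)
  })
  manifest$stages$cohort <- list(
    n_tumors = length(unique(
      cohort$design$sample_id[cohort$design$role == "tumor"])),
    n_psm_rows = nrow(cohort$psm))

  ## --- assembly ---------------------------------------------------------
  assembly <- stage("assembly", two_step_assembly(
    cohort$psm, strict_fdr = config$strict_fdr,
    min_peptides = config$min_peptides, relaxed_fdr = config$relaxed_fdr))
  manifest$stages$assembly <- list(
    n_groups = nrow(assembly$groups),
    n_spectra = assembly$n_spectra_relaxed,
    protein_fdr = assembly$protein_fdr)
  data.table::fwrite(assembly$groups,
                     file.path(out_dir, "protein_groups.tsv"), sep = "\t")

  ## --- bridge -----------------------------------------------------------
  bridge <- stage("bridge", bridge_psm_table(assembly$psms, cohort$design))
  core <- stage("bridge", filter_by_observation(
    bridge$abundance, config$observation_min_fraction))
  manifest$stages$bridge <- list(
    reference_plex = bridge$reference_plex,
    n_proteins = nrow(bridge$abundance),
    n_core_proteins = nrow(core))
  write_matrix_tsv(round(bridge$abundance, 6),
                   file.path(out_dir, "abundance.tsv"), "protein")
  jsonlite::write_json(
    list(reference_plex = bridge$reference_plex,
         factors = as.list(round(bridge$factors, 6))),
    file.path(out_dir, "bridge_report.json"), auto_unbox = TRUE,
    digits = NA)

  ## --- subtype discovery -------------------------------------------------
  feats <- stage("subtype", select_variable_features(
    core, min(config$n_variable_features, nrow(core))))
  cons <- stage("subtype", consensus_cluster(
    core[feats, , drop = FALSE], k_range = config$k_range,
    n_resamples = config$n_resamples, p_item = config$p_item,
    p_feature = config$p_feature, seed = config$cluster_seed))
  k <- stage("subtype", select_k(cons, config$delta_threshold))
  clusters <- cons$labels[, as.character(k)]
  merge_map <- config$merge_map
  if (is.null(merge_map) && !is.null(config$label_sets))
    merge_map <- stage("subtype", derive_merge_map(
      core, clusters, config$label_sets,
      fc_threshold = config$fc_threshold, alpha = config$alpha))
  subtype <- if (!is.null(merge_map))
    merge_clusters(clusters, merge_map) else as.character(clusters)
  names(subtype) <- colnames(core)
  manifest$stages$subtype <- list(chosen_k = k,
                                  sizes = as.list(table(subtype)))
  data.table::fwrite(
    data.frame(sample = colnames(core), cluster = clusters,
               subtype = subtype),
    file.path(out_dir, "subtypes.tsv"), sep = "\t")
  data.table::fwrite(
    data.frame(k = cons$k_range, area = cons$area,
               delta_area = cons$delta_area),
    file.path(out_dir, "consensus_areas.tsv"), sep = "\t")

  ## --- association -------------------------------------------------------
  de_tables <- stage("associate", {
    ## DE over the full matrix (missing values ignored); the core matrix
    ## is reserved for clustering
    lapply(sort(unique(subtype)), function(s)
      wilcoxon_de(bridge$abundance[, names(subtype), drop = FALSE],
                  subtype == s, fc_threshold = config$fc_threshold,
                  alpha = config$alpha))
  })
  names(de_tables) <- sort(unique(subtype))
  mut_tests <- stage("associate", {
    genes <- unique(cohort$mutations$gene)
    do.call(rbind, lapply(genes, function(g) {
      mut <- cohort$mutations$sample[cohort$mutations$gene == g &
                                       cohort$mutations$status == 1]
      do.call(rbind, lapply(sort(unique(subtype)), function(s) {
        in_s <- names(subtype)[subtype == s]
        tab <- matrix(c(sum(in_s %in% mut), sum(!in_s %in% mut),
                        sum(!names(subtype) %in% in_s &
                              names(subtype) %in% mut),
                        sum(!names(subtype) %in% in_s &
                              !names(subtype) %in% mut)),
                      2, 2, byrow = TRUE)
        ft <- fisher_exact(tab)
        data.frame(gene = g, subtype = s, n_mut_in = tab[1, 1],
                   odds_ratio = ft$odds_ratio, p = ft$p,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  manifest$stages$associate <- list(
    n_de_significant = vapply(de_tables, function(d) sum(d$significant),
                              integer(1)),
    n_mut_tests = nrow(mut_tests))
  for (s in names(de_tables))
    data.table::fwrite(de_tables[[s]],
                       file.path(out_dir, sprintf("de_%s.tsv", s)),
                       sep = "\t")
  data.table::fwrite(mut_tests, file.path(out_dir, "mutation_tests.tsv"),
                     sep = "\t")

  ## --- integration -------------------------------------------------------
  cnv_gene <- stage("integrate", summarize_cnv(
    cohort$cnv, cohort$gene_models, min_probes = config$cnv_min_probes,
    min_length = config$cnv_min_length))
  rna_prot <- stage("integrate", paired_spearman(cohort$rna,
                                                 bridge$abundance))
  bands <- correlation_band_sets(rna_prot, high = config$rho_high,
                                 low_band = config$rho_low_band)
  cnv_prot <- stage("integrate", paired_spearman(cnv_gene$log2,
                                                 bridge$abundance))
  manifest$stages$integrate <- list(
    mean_rna_protein_rho = round(attr(rna_prot, "mean_rho"), 4),
    n_high = bands$n_high, n_low = bands$n_low,
    n_cnv_segments_used = cnv_gene$n_segments_used)
  data.table::fwrite(rna_prot, file.path(out_dir, "rna_protein_cor.tsv"),
                     sep = "\t")

  cascade <- NULL
  if (!is.null(cohort$screen)) {
    focal <- names(which.max(vapply(
      de_tables, function(d) sum(d$significant & d$log2_fc > 0),
      integer(1))))
    cascade <- stage("integrate", vulnerability_cascade(
      cnv_prot, rna_prot, de_tables[[focal]], cohort$screen,
      rho_min = config$cascade_rho_min,
      padj_max = config$cascade_padj_max,
      rsa_max = config$cascade_rsa_max, bf_min = config$cascade_bf_min))
    manifest$stages$integrate$focal_subtype <- focal
    manifest$stages$integrate$n_primary <- length(cascade$primary)
    data.table::fwrite(cascade$report,
                       file.path(out_dir, "cascade_report.tsv"),
                       sep = "\t")
  } else {
    manifest$stages$integrate$cascade <- "skipped: no screen table"
  }

  ## --- outcome -----------------------------------------------------------
  surv <- cohort$survival[match(names(subtype), cohort$survival$sample), ]
  lr <- stage("outcome", km_logrank(surv, subtype))
  meta_genes <- Reduce(intersect, list(rownames(cnv_gene$log2),
                                       rownames(cohort$rna),
                                       rownames(bridge$abundance)))
  meta_fit <- NULL
  if (length(meta_genes)) {
    mi <- stage("outcome", multi_omic_cox(
      surv, list(cnv = cnv_gene$log2, rna = cohort$rna,
                 protein = bridge$abundance), genes = meta_genes))
    meta_fit <- stage("outcome", random_effects_meta(
      mi, q_threshold = config$meta_q_threshold))
    data.table::fwrite(meta_fit, file.path(out_dir, "meta_analysis.tsv"),
                       sep = "\t")
  }
  manifest$stages$outcome <- list(
    logrank_chi2 = round(lr$chi2, 4), logrank_p = lr$p,
    n_meta_genes = if (is.null(meta_fit)) 0L else nrow(meta_fit),
    n_selected = if (is.null(meta_fit)) 0L else sum(meta_fit$selected))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, assembly = assembly, bridge = bridge,
                 core = core, consensus = cons, k = k, subtype = subtype,
                 de = de_tables, mutation_tests = mut_tests,
                 rna_protein = rna_prot, cnv = cnv_gene,
                 cascade = cascade, logrank = lr, meta = meta_fit,
                 manifest = manifest))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory of TSVs (and truth.json, if present).
#' @return list shaped like a `synthetic_cohort` (truth omitted unless
#'   present).
#' @export
read_cohort_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(
    psm = read_psm_table(p("psms.tsv")),
    design = as.data.frame(data.table::fread(p("plex_design.tsv"))),
    rna = read_matrix_tsv(p("rna.tsv")),
    mutations = as.data.frame(data.table::fread(p("mutations.tsv"))),
    cnv = as.data.frame(data.table::fread(p("cnv_segments.tsv"))),
    gene_models = as.data.frame(data.table::fread(p("gene_models.tsv"))),
    screen = if (file.exists(p("screen.tsv")))
      as.data.frame(data.table::fread(p("screen.tsv"))) else NULL,
    survival = as.data.frame(data.table::fread(p("survival.tsv"))))
  class(out) <- "synthetic_cohort"
  out
}
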