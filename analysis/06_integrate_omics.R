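#!/usr/bin/env Rscript
# Stage 6 — cross-omic integration and the vulnerability cascade.
#
# Computes transcript-protein Spearman correlations (10% support rule),
# splits them into highly (rho > 0.5) and poorly (-0.2 < rho < 0.2)
# correlated bands, collapses CNV segments (>= 50 probes, > 400 kb) to
# gene states, summarizes transcript-protein coupling of the program
# signatures per subtype, and intersects CNV-protein / RNA-protein
# correlation, subtype-elevated DE and dependency-screen essentiality
# into primary vulnerability candidates.

suppressPackageStartupMessages(library(proteogx))

abundance <- read_matrix_tsv("results/bridge/abundance.tsv")
rna <- read_matrix_tsv("results/cohort/rna.tsv")
labels <- as.data.frame(data.table::fread("results/subtypes/labels.tsv"))
subtype <- structure(labels$subtype, names = labels$sample)
cnv_segments <- as.data.frame(data.table::fread("results/cohort/cnv_segments.tsv"))
gene_models <- as.data.frame(data.table::fread("results/cohort/gene_models.tsv"))
screen <- as.data.frame(data.table::fread("results/cohort/screen.tsv"))
programs <- read_gmt("results/cohort/programs.gmt")

dir.create("results/integration", recursive = TRUE, showWarnings = FALSE)

rna_prot <- paired_spearman(rna, abundance)
bands <- correlation_band_sets(rna_prot)
data.table::fwrite(rna_prot, "results/integration/rna_protein_cor.tsv",
                   sep = "\t")
message(sprintf(
  "transcript-protein coupling: mean rho %.3f over %d pairs; %d highly (rho>0.5) and %d poorly (-0.2<rho<0.2) correlated",
  attr(rna_prot, "mean_rho"), sum(!is.na(rna_prot$rho)),
  bands$n_high, bands$n_low))

cnv <- summarize_cnv(cnv_segments, gene_models, min_probes = 50,
                     min_length = 400000)
data.table::fwrite(cnv$counts, "results/integration/cnv_gene_counts.tsv",
                   sep = "\t")
message(sprintf("CNV: %d segments pass the 50-probe/>400kb gates",
                cnv$n_segments_used))

tf <- tf_target_summary(rna, abundance, programs, subtype)
data.table::fwrite(tf, "results/integration/program_correlations.tsv",
                   sep = "\t")

# the cascade is run once per subtype; candidate vulnerabilities are
# expected where CNV-driven, screen-essential biology concentrates
cnv_prot <- paired_spearman(cnv$log2, abundance)
summary <- list()
for (f in list.files("results/associations", "^de_", full.names = TRUE)) {
  s_name <- sub("de_(.*)\\.tsv", "\\1", basename(f))
  de <- as.data.frame(data.table::fread(f))
  casc <- vulnerability_cascade(cnv_prot, rna_prot, de, screen,
                                rho_min = 0.5, padj_max = 0.25,
                                rsa_max = -3, bf_min = 3)
  data.table::fwrite(casc$report,
                     sprintf("results/integration/cascade_%s.tsv", s_name),
                     sep = "\t")
  summary[[s_name]] <- list(n_h = casc$n_h, n_e = casc$n_e,
                            n_d = casc$n_d, primary = casc$primary,
                            secondary = casc$secondary)
  message(sprintf(
    "cascade (%s): |H|=%d, |E|=%d, |D|=%d; primary candidates: %s",
    s_name, casc$n_h, casc$n_e, casc$n_d,
    paste(casc$primary, collapse = ", ")))
}
jsonlite::write_json(summary, "results/integration/cascade_summary.json",
                     auto_unbox = TRUE, digits = NA)
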