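#!/usr/bin/env Rscript
# Stage 3 — pool-referenced cross-plex bridging.
#
# Rolls spectra up to protein-level log2 ratios against each plex's
# fixed reference-pool channel, picks the cohort reference pool (median
# of the per-plex pool medians), rank-invariant-normalizes every pool
# onto it, and reconstructs one cohort-wide log2 abundance matrix
# (scale x 2^ratio, replicate injections averaged). Writes the matrix,
# the >90%-observed core matrix, and a bridge report.

suppressPackageStartupMessages(library(proteogx))

psms <- data.table::fread("results/assembly/retained_psms.tsv")
design <- as.data.frame(data.table::fread("results/cohort/plex_design.tsv"))
br <- bridge_psm_table(psms, design)
core <- filter_by_observation(br$abundance, 0.9)

dir.create("results/bridge", recursive = TRUE, showWarnings = FALSE)
proteogx:::write_matrix_tsv(round(br$abundance, 6),
                            "results/bridge/abundance.tsv", "protein")
proteogx:::write_matrix_tsv(round(core, 6),
                            "results/bridge/abundance_core.tsv", "protein")
jsonlite::write_json(
  list(reference_plex = br$reference_plex,
       factors = as.list(round(br$factors, 6)),
       n_proteins = nrow(br$abundance), n_core = nrow(core)),
  "results/bridge/bridge_report.json", auto_unbox = TRUE, digits = NA)

pool_sd <- apply(br$pools, 1, stats::sd, na.rm = TRUE)
message(sprintf(
  "bridge: reference plex %s; %d proteins (%d observed in >90%% of tumors); median bridged pool SD %.3f log2 units",
  br$reference_plex, nrow(br$abundance), nrow(core),
  stats::median(pool_sd, na.rm = TRUE)))
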