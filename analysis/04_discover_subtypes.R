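#!/usr/bin/env Rscript
# Stage 4 — consensus-clustering subtype discovery.
#
# Clusters the top-1000 most variable core proteins (MAD) by resampled
# complete-linkage hierarchical clustering on 1 - Pearson (pItem 0.8,
# 250 resamples, seed 1234), chooses k by the first <10% relative change
# in consensus-CDF area, labels clusters by program enrichment
# (rank-sum DE -> hypergeometric ORA against results/cohort/programs.gmt)
# and merges them into named subtypes.

suppressPackageStartupMessages(library(proteogx))

core <- read_matrix_tsv("results/bridge/abundance_core.tsv")
feats <- select_variable_features(core, 1000)
cons <- consensus_cluster(core[feats, ], k_range = 2:9, n_resamples = 250,
                          p_item = 0.8, seed = 1234)
k <- select_k(cons, delta_threshold = 0.10)
clusters <- cons$labels[, as.character(k)]
programs <- read_gmt("results/cohort/programs.gmt")
map <- derive_merge_map(core, clusters, programs)
subtype <- merge_clusters(clusters, map)

dir.create("results/subtypes", recursive = TRUE, showWarnings = FALSE)
data.table::fwrite(
  data.frame(sample = colnames(core), cluster = clusters,
             subtype = subtype),
  "results/subtypes/labels.tsv", sep = "\t")
data.table::fwrite(
  data.frame(k = cons$k_range, area = round(cons$area, 4),
             delta_area = round(cons$delta_area, 4)),
  "results/subtypes/consensus_areas.tsv", sep = "\t")
for (kk in cons$k_range)
  proteogx:::write_matrix_tsv(round(cons$consensus[[as.character(kk)]], 3),
                              sprintf("results/subtypes/consensus_k%d.tsv", kk),
                              "sample")

message(sprintf(
  "subtypes: chose k = %d (CDF-area rule); merge map [%s]; subtype sizes %s",
  k, paste(names(map), map, sep = "->", collapse = ", "),
  paste(names(table(subtype)), table(subtype), sep = ":", collapse = " ")))
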