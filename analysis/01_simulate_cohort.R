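#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 108 tumors across 29 TMT
# 6-plexes (four tumors + two pool replicates each, 174 channel-slots),
# three latent proteomic subtypes (40/47/13%), 2000 proteins matched to
# 2000 genes, mutation models including a KEAP1-like gene at OR 20 in
# the redox-like subtype, CNV segments with five planted dosage-driven
# vulnerability genes, a 4-line dependency screen, and survival records.
# Writes every downstream input as plain TSV/JSON under results/cohort/.

suppressPackageStartupMessages(library(proteogx))

cfg <- cohort_config()  # seed 1234; all study conditions are defaults
co <- generate_cohort(cfg)
write_cohort(co, "results/cohort")

# the program signatures double as the pathway collection used later to
# label clusters; store them in standard GMT form
gmt <- vapply(seq_along(co$truth$programs), function(s)
  paste(c(sprintf("program_%d", s), "synthetic subtype program",
          co$truth$programs[[s]]), collapse = "\t"), character(1))
writeLines(gmt, "results/cohort/programs.gmt")

counts <- table(co$truth$subtype)
message(sprintf(
  "cohort: %d tumors in %d plexes; subtype sizes %s; %d PSM rows (%.0f%% decoys); planted vulnerabilities: %s",
  cfg$n_tumors, cfg$n_plexes, paste(counts, collapse = "/"),
  nrow(co$psm), 100 * mean(co$psm$decoy),
  paste(co$truth$planted, collapse = ", ")))
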