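## Readers and writers for the pipeline's plain-text interchange formats.
## Missing values are empty TSV cells, never sentinel numbers.

#' Write a synthetic cohort to a directory of TSV/JSON files
#'
#' Emits the long-format PSM table (plex, channel, spectrum_id, peptide,
#' protein_group, decoy, score, intensity), the plex design, the RNA
#' matrix, mutations, BED-like CNV segments (0-based half-open), gene
#' models, screen scores, survival records, and the ground truth (JSON).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(psm_wide_to_long(cohort$psm),
                     file.path(dir, "psms.tsv"), sep = "\t")
  data.table::fwrite(cohort$design, file.path(dir, "plex_design.tsv"),
                     sep = "\t")
  write_matrix_tsv(cohort$rna, file.path(dir, "rna.tsv"), "gene")
  data.table::fwrite(cohort$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$cnv, file.path(dir, "cnv_segments.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$gene_models, file.path(dir, "gene_models.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$screen, file.path(dir, "screen.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t")
  tr <- cohort$truth
  truth <- list(
    subtype = as.list(tr$subtype),
    programs = stats::setNames(tr$programs,
                               sprintf("program_%d", seq_along(tr$programs))),
    planted = tr$planted,
    dosage = apply(tr$dosage, 1, as.list, simplify = FALSE),
    mutation_genes = as.list(tr$mutation_genes),
    mutant_samples = tr$mutant_samples,
    hazard_genes = as.list(tr$hazard_log[tr$hazard_log != 0]))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

psm_wide_to_long <- function(psm) {
  dt <- data.table::as.data.table(psm)
  ch_cols <- grep("^ch_", names(dt), value = TRUE)
  long <- data.table::melt(dt, measure.vars = ch_cols,
                           variable.name = "channel",
                           value.name = "intensity")
  long[, channel := as.integer(sub("ch_", "", channel))]
  data.table::setcolorder(long, c("plex", "channel", "spectrum_id",
                                  "peptide", "protein_group", "decoy",
                                  "score", "intensity"))
  long[order(plex, spectrum_id, channel)]
}

#' Read a long-format PSM TSV back into the wide in-memory layout
#'
#' @param path TSV written by [write_cohort()] (or any file with columns
#'   plex, channel, spectrum_id, peptide, protein_group, decoy, score,
#'   intensity).
#' @return wide data.table with one row per spectrum and ch_* columns.
#' @export
read_psm_table <- function(path) {
  long <- data.table::fread(path, sep = "\t")
  wide <- data.table::dcast(long,
                            plex + spectrum_id + peptide + protein_group +
                              decoy + score ~ channel,
                            value.var = "intensity")
  ch <- setdiff(names(wide), c("plex", "spectrum_id", "peptide",
                               "protein_group", "decoy", "score"))
  data.table::setnames(wide, ch, paste0("ch_", ch))
  wide[]
}

write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
}

#' Read a features x samples TSV matrix (empty cell = missing)
#'
#' @param path TSV with the feature id in the first column.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line — name, description, then member genes,
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
    unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}
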