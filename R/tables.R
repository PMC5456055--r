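#' @include utils.R
NULL

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "plastomeCompare")
  if (!nzchar(p)) stop("bundled table not found: ", file)
  p
}

#' Bundled published comparison tables
#'
#' Transcriptions of the published 11-genome comparison tables shipped
#' as plain TSV: partition/size/GC per genome, per-region divergence for
#' the variable coding and noncoding (>150 bp) regions, and the SSR locus
#' table. They serve as regression fixtures for the divergence formulas
#' and summaries.
#'
#' @return data.frame (see columns in the respective TSV)
#' @name bundledTables
NULL

#' @rdname bundledTables
#' @export
loadPartitionTable <- function() readTsv(extdataPath("table1_partitions.tsv"))

#' @rdname bundledTables
#' @export
loadCodingDivergenceTable <- function()
  readTsv(extdataPath("table2_coding_divergence.tsv"))

#' @rdname bundledTables
#' @export
loadNoncodingDivergenceTable <- function()
  readTsv(extdataPath("table3_noncoding_divergence.tsv"))

#' @rdname bundledTables
#' @export
loadSSRLocusTable <- function() readTsv(extdataPath("table4_ssr_loci.tsv"))

#' Audit a divergence table against the summary-statistic identities
#'
#' Recomputes percent variability P = round2(100 (S + I) / L) and
#' variable positions V = S + G from the table's substitution (S), indel
#' event (I), aligned length (L) and indel length (G) columns, and
#' compares with the printed values. The V identity assumes
#' non-overlapping indel events (gap columns = total indel length).
#'
#' @param tab data.frame with columns aligned_length, substitutions,
#'   n_indels, indel_length, variable_positions, percent_variability
#' @return `tab` with added columns p_recomputed, p_matches,
#'   v_recomputed, v_matches
#' @export
auditDivergenceTable <- function(tab) {
  tab$p_recomputed <- percentVariability(tab$substitutions, tab$n_indels,
                                         tab$aligned_length)
  tab$p_matches <- abs(tab$p_recomputed - tab$percent_variability) < 1e-9
  tab$v_recomputed <- tab$substitutions + tab$indel_length
  tab$v_matches <- tab$v_recomputed == tab$variable_positions
  tab
}
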