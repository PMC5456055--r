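#' Round half-up to two decimals
#'
#' Divergence percentages are conventionally reported with half-up rounding
#' (2.857 -> 2.86), which differs from R's banker's rounding in `round()`.
#'
#' @param x numeric vector
#' @return `x` rounded half-up to 2 decimal places
#' @keywords internal
roundHalfUp2 <- function(x) floor(x * 100 + 0.5) / 100

#' Percent variability of a region
#'
#' The per-region divergence score: 100 * (substitutions + indel events) /
#' aligned length, rounded half-up to two decimals.
#'
#' @param S number of substitution columns (gap-free polymorphic columns)
#' @param I number of indel events (distinct maximal gap runs)
#' @param L aligned length in columns
#' @return percent variability (numeric, 2 decimals)
#' @export
#' @examples
#' percentVariability(5, 0, 1527)   # 0.33
#' percentVariability(4, 1, 175)    # 2.86
percentVariability <- function(S, I, L) {
  stopifnot(all(L > 0))
  roundHalfUp2(100 * (S + I) / L)
}

reverseComplementChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
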