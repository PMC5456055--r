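#' @include AllClasses.R
NULL

#' Extract a subsequence from a (circular) genome
#'
#' Coordinates are 0-based half-open on the plus strand. On a circular
#' genome the interval may wrap the origin, given either as `end > start`
#' with `end > length` or as `end < start` (interpreted modulo the genome
#' length). With `strand = "-"` the extracted plus-strand sequence is
#' reverse-complemented.
#'
#' @param record a [GenomeRecord-class]
#' @param start,end 0-based half-open interval
#' @param strand `"+"` or `"-"`
#' @return character scalar DNA sequence
#' @export
extractSubsequence <- function(record, start, end, strand = "+") {
  n <- genomeLength(record)
  s <- as.character(record@seq)
  if (end <= start) {
    if (!record@circular)
      stop("wrapping interval on a linear genome")
    end <- end + n
  }
  if (start < 0 || start >= n)
    stop("interval start outside [0, genome length)")
  if (end > n && !record@circular)
    stop("interval end beyond a linear genome")
  out <- if (end <= n) substr(s, start + 1L, end)
  else paste0(substr(s, start + 1L, n), substr(s, 1L, end - n))
  if (strand == "-") out <- reverseComplementChr(out)
  out
}

#' Extract the transcript-order sequence of a feature
#'
#' Parts are concatenated in ascending plus-strand order; for minus-strand
#' features the concatenation is reverse-complemented, giving the sequence
#' in transcription order.
#'
#' @param record a [GenomeRecord-class]
#' @param feature one row of the record's feature table (or its index)
#' @return character scalar DNA sequence
#' @export
extractFeatureSeq <- function(record, feature) {
  if (is.numeric(feature) || is.character(feature)) {
    ft <- genomeFeatures(record)
    i <- if (is.character(feature)) match(feature, ft$name) else feature
    if (is.na(i)) stop("no feature named '", feature, "'")
    feature <- ft[i, , drop = FALSE]
  }
  p <- feature$parts[[1]]
  pieces <- vapply(seq_len(nrow(p)), function(i)
    extractSubsequence(record, p[i, 1], p[i, 2], "+"), character(1))
  out <- paste(pieces, collapse = "")
  if (feature$strand[1] == "-") out <- reverseComplementChr(out)
  out
}

#' GC content of a DNA sequence, in percent
#'
#' 100 * (#G + #C) / (#A + #C + #G + #T); N and other ambiguity codes are
#' excluded from the denominator. Reported to two decimals.
#'
#' @param seq character DNA sequence or [Biostrings::DNAString]
#' @return percent GC, rounded half-up to 2 decimals
#' @export
#' @examples
#' gcContent("ATAT")  # 0
#' gcContent("GCGC")  # 100
gcContent <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  if (length(seq) == 0L) stop("empty sequence")
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0L) stop("sequence has no unambiguous bases")
  roundHalfUp2(100 * (f[["C"]] + f[["G"]]) / denom)
}

# rotate a circular record so that `offset` becomes position 0
rotateRecord <- function(record, offset) {
  n <- genomeLength(record)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(record)
  if (!record@circular) stop("cannot rotate a linear genome")
  s <- as.character(record@seq)
  newseq <- paste0(substr(s, offset + 1L, n), substr(s, 1L, offset))
  ft <- record@features
  if (nrow(ft)) {
    ft$parts <- lapply(ft$parts, function(p) {
      widths <- p[, 2] - p[, 1] # wrap-aware: end > n encodes the wrap
      p[, 1] <- (p[, 1] - offset) %% n
      p[, 2] <- p[, 1] + widths
      p[order(p[, 1]), , drop = FALSE]
    })
  }
  GenomeRecord(id = record@id, seq = newseq, features = ft,
               circular = TRUE, organism = record@organism,
               metadata = record@metadata)
}
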