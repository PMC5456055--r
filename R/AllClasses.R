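#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importClassesFrom Biostrings DNAString
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' GenomeRecord: an annotated (circular) plastome
#'
#' Holds one chloroplast genome: its sequence, circularity flag, and an
#' ordered table of gene features. Internal coordinates are 0-based
#' half-open; GenBank input/output converts from/to 1-based inclusive.
#'
#' The `features` slot is a data.frame with columns `name` (gene symbol;
#' tRNAs carry their anticodon, e.g. `"trnL (UAA)"`), `kind` (one of
#' `"CDS"`, `"tRNA"`, `"rRNA"`), `strand` (`"+"`/`"-"`) and `parts` (a list
#' column of two-column integer matrices `start`,`end`, 0-based half-open,
#' in ascending plus-strand order). A part of a circular genome may wrap
#' the origin, encoded as `end > length(genome)` with the excess read from
#' position 0.
#'
#' @slot id accession or taxon label
#' @slot organism free-text organism name
#' @slot seq a [Biostrings::DNAString] over A,C,G,T,N
#' @slot circular logical, is the molecule circular
#' @slot features data.frame of gene features (see Details)
#' @slot metadata list of free-form metadata (voucher, source, ...)
#' @export
setClass("GenomeRecord",
  representation(
    id = "character",
    organism = "character",
    seq = "DNAString",
    circular = "logical",
    features = "data.frame",
    metadata = "list"
  )
)

validGenomeRecord <- function(object) {
  msgs <- character()
  n <- length(object@seq)
  if (n < 1L) msgs <- c(msgs, "sequence is empty")
  ft <- object@features
  needed <- c("name", "kind", "strand", "parts")
  if (!all(needed %in% names(ft))) {
    msgs <- c(msgs, paste("features must have columns:",
                          paste(needed, collapse = ", ")))
    return(msgs)
  }
  if (nrow(ft)) {
    if (!all(ft$kind %in% c("CDS", "tRNA", "rRNA")))
      msgs <- c(msgs, "feature kind must be CDS, tRNA or rRNA")
    if (!all(ft$strand %in% c("+", "-")))
      msgs <- c(msgs, "feature strand must be '+' or '-'")
    for (i in seq_len(nrow(ft))) {
      p <- ft$parts[[i]]
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 1L) {
        msgs <- c(msgs, sprintf("feature '%s': parts must be an n x 2 matrix",
                                ft$name[i]))
        next
      }
      if (any(p[, 1] < 0L) || any(p[, 1] >= n))
        msgs <- c(msgs, sprintf(
          "feature '%s': part start outside [0, genome length)", ft$name[i]))
      if (any(p[, 2] <= p[, 1]))
        msgs <- c(msgs, sprintf("feature '%s': empty or reversed part",
                                ft$name[i]))
      wraps <- p[, 2] > n
      if (any(wraps) && !object@circular)
        msgs <- c(msgs, sprintf(
          "feature '%s': origin-wrapping part on a linear genome", ft$name[i]))
      if (any(p[, 2] > 2L * n))
        msgs <- c(msgs, sprintf("feature '%s': part longer than the genome",
                                ft$name[i]))
    }
    starts <- vapply(ft$parts, function(p) p[1, 1], numeric(1))
    if (is.unsorted(starts))
      msgs <- c(msgs, "features must be sorted by start of first part")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("GenomeRecord", validGenomeRecord)

#' Construct a GenomeRecord
#'
#' @param id accession or taxon label
#' @param seq DNA sequence (character or [Biostrings::DNAString]); it is
#'   uppercased and U is mapped to T
#' @param features feature table (see [GenomeRecord-class]); defaults empty
#' @param circular logical, default TRUE (plastomes are circular)
#' @param organism organism name
#' @param metadata list of metadata strings
#' @return a [GenomeRecord-class] object
#' @export
GenomeRecord <- function(id, seq, features = emptyFeatureTable(),
                         circular = TRUE, organism = "", metadata = list()) {
  if (is.character(seq)) {
    seq <- chartr("u", "t", seq)
    seq <- chartr("U", "T", toupper(seq))
    seq <- DNAString(seq)
  }
  features <- features[order(vapply(features$parts, function(p) p[1, 1],
                                    numeric(1))), , drop = FALSE]
  rownames(features) <- NULL
  new("GenomeRecord", id = id, organism = organism, seq = seq,
      circular = circular, features = features, metadata = metadata)
}

#' An empty feature table
#' @return zero-row feature data.frame with the canonical columns
#' @export
emptyFeatureTable <- function() {
  data.frame(name = character(), kind = character(), strand = character(),
             parts = I(list()), stringsAsFactors = FALSE)
}

#' Build a feature table row-wise
#'
#' @param name gene symbols
#' @param kind feature kinds (CDS/tRNA/rRNA), recycled
#' @param strand strands, recycled
#' @param parts list of n x 2 integer matrices (0-based half-open)
#' @return feature data.frame
#' @export
featureTable <- function(name, kind, strand, parts) {
  stopifnot(length(parts) == length(name))
  data.frame(name = name, kind = rep_len(kind, length(name)),
             strand = rep_len(strand, length(name)),
             parts = I(parts), stringsAsFactors = FALSE)
}

#' PlastomePartition: quadripartite intervals of one genome
#'
#' LSC/IRb/SSC/IRa intervals (0-based half-open) on the canonically
#' oriented sequence: position 0 is the first LSC base downstream of IRa,
#' so the layout is LSC, IRb, SSC, IRa.
#'
#' @slot lsc,irb,ssc,ira integer(2) start/end intervals
#' @slot genomeLength total genome length in bp
#' @export
setClass("PlastomePartition",
  representation(lsc = "integer", irb = "integer", ssc = "integer",
                 ira = "integer", genomeLength = "integer")
)

setValidity("PlastomePartition", function(object) {
  msgs <- character()
  iv <- list(lsc = object@lsc, irb = object@irb, ssc = object@ssc,
             ira = object@ira)
  for (nm in names(iv)) {
    if (length(iv[[nm]]) != 2L || iv[[nm]][2] <= iv[[nm]][1])
      msgs <- c(msgs, sprintf("%s interval malformed", nm))
  }
  if (!length(msgs)) {
    w <- vapply(iv, diff, numeric(1))
    if (w[["irb"]] != w[["ira"]]) msgs <- c(msgs, "|IRb| != |IRa|")
    if (w[["lsc"]] + w[["ssc"]] + w[["irb"]] + w[["ira"]] !=
        object@genomeLength)
      msgs <- c(msgs, "LSC + SSC + 2*IR != genome length")
    if (w[["lsc"]] <= w[["ssc"]])
      msgs <- c(msgs, "LSC must be longer than SSC")
    if (!(object@lsc[1] == 0L && object@lsc[2] == object@irb[1] &&
          object@irb[2] == object@ssc[1] && object@ssc[2] == object@ira[1] &&
          object@ira[2] == object@genomeLength))
      msgs <- c(msgs, "intervals must tile the genome as LSC,IRb,SSC,IRa")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a canonical PlastomePartition from segment lengths
#'
#' @param lscLen,irLen,sscLen segment lengths in bp
#' @return a [PlastomePartition-class] tiling LSC, IRb, SSC, IRa
#' @export
PlastomePartition <- function(lscLen, irLen, sscLen) {
  lscLen <- as.integer(lscLen); irLen <- as.integer(irLen)
  sscLen <- as.integer(sscLen)
  n <- lscLen + sscLen + 2L * irLen
  new("PlastomePartition",
      lsc = c(0L, lscLen),
      irb = c(lscLen, lscLen + irLen),
      ssc = c(lscLen + irLen, lscLen + irLen + sscLen),
      ira = c(lscLen + irLen + sscLen, n),
      genomeLength = n)
}
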