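#' @include AllClasses.R
NULL

# affine-gap global pairwise alignment at the package's fixed scores:
# match +1, mismatch -1, gap open -4, gap extend -1
pairAlign <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(b), Biostrings::DNAString(a), type = "global",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
  list(center = as.character(Biostrings::alignedSubject(pa)),
       other = as.character(Biostrings::alignedPattern(pa)))
}

# decompose a pairwise alignment (center row with gaps, other row) into
# per-center-position pieces: ins[[i+1]] = other-row characters inserted
# before center base i (i = 0..Lc), and ach[i] = other-row character
# aligned to center base i (i = 1..Lc)
decomposeAgainstCenter <- function(centerRow, otherRow) {
  cc <- strsplit(centerRow, "")[[1]]
  oc <- strsplit(otherRow, "")[[1]]
  Lc <- sum(cc != "-")
  ins <- character(Lc + 1L)
  ach <- character(Lc)
  pos <- 0L
  buf <- character(0)
  for (k in seq_along(cc)) {
    if (cc[k] == "-") {
      buf <- c(buf, oc[k])
    } else {
      ins[pos + 1L] <- paste(buf, collapse = "")
      buf <- character(0)
      pos <- pos + 1L
      ach[pos] <- oc[k]
    }
  }
  ins[Lc + 1L] <- paste(buf, collapse = "")
  list(ins = ins, ach = ach, Lc = Lc)
}

# center-star progressive multiple alignment: every sequence is aligned
# to the center (longest sequence; ties by input order) and the pairwise
# insertions are merged into a common gap pattern
centerStarAlign <- function(seqs) {
  nm <- names(seqs)
  ci <- which.max(nchar(seqs))
  center <- seqs[[ci]]
  others <- setdiff(seq_along(seqs), ci)
  decs <- lapply(others, function(j) {
    pa <- pairAlign(center, seqs[[j]])
    decomposeAgainstCenter(pa$center, pa$other)
  })
  Lc <- nchar(center)
  masterIns <- integer(Lc + 1L)
  for (d in decs) masterIns <- pmax(masterIns, nchar(d$ins))
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  buildRow <- function(ins, ach) {
    pieces <- character(2L * Lc + 1L)
    for (i in 0:Lc) pieces[2L * i + 1L] <- pad(ins[i + 1L], masterIns[i + 1L])
    if (Lc) pieces[2L * seq_len(Lc)] <- ach
    paste(pieces, collapse = "")
  }
  cc <- strsplit(center, "")[[1]]
  rows <- character(length(seqs))
  rows[ci] <- buildRow(rep("", Lc + 1L), cc)
  for (k in seq_along(others)) {
    d <- decs[[k]]
    rows[others[k]] <- buildRow(d$ins, d$ach)
  }
  stats::setNames(rows, nm)
}

#' Align one region across taxa
#'
#' The default built-in aligner is a deterministic progressive
#' (center-star) method built on affine-gap global pairwise alignment
#' (match +1, mismatch -1, gap open -4, gap extend -1; Biostrings dynamic
#' programming), adequate for the low-divergence regions of congeneric
#' plastomes. `method = "mafft"` shells out to an external `mafft`
#' binary (`--auto --quiet`) when one is installed.
#'
#' @param seqs named character vector, one unaligned sequence per taxon
#' @param name region label carried into the result
#' @param method "builtin" (default) or "mafft"
#' @return a `RegionAlignment`: list with `name`, `rows` (named
#'   equal-length gapped sequences) and `L` (alignment columns)
#' @export
alignRegion <- function(seqs, name = NA_character_,
                        method = c("builtin", "mafft")) {
  method <- match.arg(method)
  if (length(seqs) < 1L || any(!nzchar(seqs))) stop("empty input sequence")
  if (length(unique(nchar(seqs))) == 1L &&
      length(unique(seqs)) == 1L) {
    rows <- seqs # identical sequences need no work
  } else if (method == "mafft") {
    rows <- mafftAlign(seqs)
  } else {
    rows <- centerStarAlign(seqs)
  }
  aln <- structure(list(name = name, rows = rows,
                        L = nchar(rows[[1]])), class = "RegionAlignment")
  stopifnot(all(nchar(rows) == aln$L))
  stopifnot(identical(unname(gsub("-", "", rows)), unname(seqs)))
  aln
}

mafftAlign <- function(seqs) {
  if (Sys.which("mafft") == "") stop("mafft binary not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeFastaSeqs(seqs, fin)
  status <- system2("mafft", c("--auto", "--quiet", fin), stdout = fout)
  if (status != 0L) stop("mafft failed with status ", status)
  out <- Biostrings::readBStringSet(fout)
  stats::setNames(toupper(as.character(out)), names(out))[names(seqs)]
}

#' Align every region of a RegionSet
#'
#' @param regionSet a `RegionSet` from [extractRegions()]
#' @param method passed to [alignRegion()]
#' @return named list of `RegionAlignment` objects
#' @export
alignRegions <- function(regionSet, method = "builtin") {
  out <- lapply(names(regionSet$seqs), function(nm)
    alignRegion(regionSet$seqs[[nm]], name = nm, method = method))
  names(out) <- names(regionSet$seqs)
  out
}

#' @export
print.RegionAlignment <- function(x, ...) {
  cat(sprintf("RegionAlignment '%s': %d taxa x %d columns\n",
              x$name, length(x$rows), x$L))
  invisible(x)
}
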