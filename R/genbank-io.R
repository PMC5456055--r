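#' @include AllClasses.R
NULL

# ---- location strings ------------------------------------------------------

# Internal parts matrix (0-based half-open, wrap encoded as end > n) to a
# GenBank location string (1-based inclusive, join/complement).
partsToLocation <- function(parts, strand, n) {
  spans <- character(0)
  for (i in seq_len(nrow(parts))) {
    s <- parts[i, 1]; e <- parts[i, 2]
    if (e > n) { # origin wrap -> two printed spans
      spans <- c(spans, sprintf("%d..%d", s + 1L, n),
                 sprintf("%d..%d", 1L, e - n))
    } else {
      spans <- c(spans, sprintf("%d..%d", s + 1L, e))
    }
  }
  loc <- if (length(spans) > 1L)
    paste0("join(", paste(spans, collapse = ","), ")") else spans
  if (strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

# GenBank location string to list(parts, strand). Supports nested
# complement(join(...)) and join(complement(...)) forms.
locationToParts <- function(loc, n, circular) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  spans <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (any(grepl("complement", spans))) {
    strand <- "-"
    spans <- sub("^complement\\((.*)\\)$", "\\1", spans)
  }
  mat <- t(vapply(spans, function(sp) {
    ab <- as.integer(strsplit(sp, "\\.\\.")[[1]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    c(ab[1] - 1L, ab[2]) # to 0-based half-open
  }, integer(2)))
  dimnames(mat) <- NULL
  # merge a trailing-origin + leading span pair back into one wrapping part
  if (circular && nrow(mat) > 1L) {
    keep <- rep(TRUE, nrow(mat))
    for (i in seq_len(nrow(mat) - 1L)) {
      if (mat[i, 2] == n && mat[i + 1L, 1] == 0L) {
        mat[i, 2] <- n + mat[i + 1L, 2]
        keep[i + 1L] <- FALSE
      }
    }
    mat <- mat[keep, , drop = FALSE]
  }
  mat <- mat[order(mat[, 1]), , drop = FALSE]
  list(parts = mat, strand = strand)
}

# ---- GenBank write ---------------------------------------------------------

#' Write a GenomeRecord as a GenBank flat file
#'
#' Emits LOCUS/DEFINITION/SOURCE headers, a `source` feature, one feature
#' per gene (key = kind), and the ORIGIN sequence block. Coordinates are
#' converted to 1-based inclusive; origin-wrapping parts are printed as two
#' joined spans.
#'
#' @param record a [GenomeRecord-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeGenBank <- function(record, path) {
  n <- genomeLength(record)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %-16s %7d bp    DNA     %-8s PLN 01-JAN-2000",
     record@id, n, if (record@circular) "circular" else "linear")
  wl("DEFINITION  %s chloroplast, complete genome.",
     if (nzchar(record@organism)) record@organism else record@id)
  wl("ACCESSION   %s", record@id)
  wl("SOURCE      %s", record@organism)
  wl("  ORGANISM  %s", record@organism)
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", n)
  wl("                     /organism=\"%s\"", record@organism)
  ft <- record@features
  for (i in seq_len(nrow(ft))) {
    loc <- partsToLocation(ft$parts[[i]], ft$strand[i], n)
    wl("     %-15s %s", ft$kind[i], loc)
    wl("                     /gene=\"%s\"", ft$name[i])
  }
  wl("ORIGIN")
  s <- tolower(as.character(record@seq))
  for (off in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    wl("%9d %s", off, paste(blocks, collapse = " "))
  }
  wl("//")
  invisible(path)
}

# ---- GenBank read ----------------------------------------------------------

#' Parse a GenBank flat file into a GenomeRecord
#'
#' Reads the LOCUS line (length, circular flag), ORGANISM, the feature
#' table and the ORIGIN sequence. Only CDS/tRNA/rRNA features are
#' retained; `gene`, `source` and other keys are skipped with a notice.
#' 1-based inclusive locations (including `complement(join(...))`) are
#' converted to 0-based half-open internal coordinates.
#'
#' @param path GenBank flat file
#' @param quiet suppress the skipped-feature notice
#' @return a [GenomeRecord-class]
#' @export
readGenBank <- function(path, quiet = TRUE) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  circular <- grepl("circular", locus[1], ignore.case = TRUE)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (!is.na(a) && nzchar(a)) id <- a
  }
  org <- grep("^  ORGANISM", lines, value = TRUE)
  organism <- if (length(org)) trimws(sub("^  ORGANISM", "", org[1])) else ""

  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("GenBank file has no ORIGIN sequence: ", path)
  endi <- grep("^//", lines)
  endi <- if (length(endi)) endi[endi > oi[1]][1] else length(lines) + 1L
  seqlines <- lines[(oi[1] + 1L):(endi - 1L)]
  seq <- gsub("[^A-Za-z]", "", paste(seqlines, collapse = ""))
  if (!nzchar(seq)) stop("GenBank file has an empty ORIGIN block: ", path)
  seq <- chartr("Uu", "Tt", seq)
  n <- nchar(seq)

  fi <- grep("^FEATURES", lines)
  name <- kind <- strand <- character(0)
  parts <- list()
  skipped <- character(0)
  if (length(fi)) {
    block <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    # a new feature starts at column 6; continuation/qualifier lines at 22
    starts <- grep("^     \\S", block)
    bounds <- c(starts, length(block) + 1L)
    for (k in seq_along(starts)) {
      chunk <- block[starts[k]:(bounds[k + 1L] - 1L)]
      key <- sub("^\\s*(\\S+).*$", "\\1", chunk[1])
      rest <- trimws(sub("^\\s*\\S+\\s*", "", chunk[1]))
      qual1 <- grep("^\\s+/", chunk)
      locEnd <- if (length(qual1)) qual1[1] - 1L else length(chunk)
      loc <- paste0(rest, paste(trimws(chunk[seq_len(locEnd)][-1]),
                                collapse = ""))
      if (!key %in% c("CDS", "tRNA", "rRNA")) {
        if (!key %in% c("source")) skipped <- c(skipped, key)
        next
      }
      gq <- grep("/gene=", chunk, value = TRUE)
      if (!length(gq)) gq <- grep("/product=|/label=", chunk, value = TRUE)
      gname <- if (length(gq))
        sub('^.*="?([^"]*)"?.*$', "\\1", gq[1]) else sprintf("feat%d", k)
      lp <- locationToParts(loc, n, circular)
      ends <- ifelse(lp$parts[, 2] > n, lp$parts[, 2] - n, lp$parts[, 2])
      if (any(lp$parts[, 1] >= n) || any(ends > n))
        stop(sprintf("feature '%s' has coordinates beyond sequence length %d",
                     gname, n))
      name <- c(name, gname); kind <- c(kind, key)
      strand <- c(strand, lp$strand)
      parts <- c(parts, list(lp$parts))
    }
  }
  if (length(skipped) && !quiet)
    message("readGenBank: skipped non-gene feature keys: ",
            paste(unique(skipped), collapse = ", "))
  GenomeRecord(id = id, seq = seq,
               features = featureTable(name, kind, strand, parts),
               circular = circular, organism = organism)
}

# ---- FASTA -----------------------------------------------------------------

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over Biostrings returning/accepting named character
#' vectors; output wrapped at 70 columns.
#'
#' @param path file path
#' @return `readFastaSeqs`: named character vector of sequences
#' @export
readFastaSeqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname readFastaSeqs
#' @param seqs named character vector (or DNAStringSet)
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (is.character(seqs)) {
    # gapped alignment rows must keep their "-" characters
    if (any(grepl("-", seqs, fixed = TRUE)))
      x <- Biostrings::BStringSet(seqs)
    else x <- Biostrings::DNAStringSet(seqs)
  } else x <- seqs
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
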