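#' @include AllClasses.R quadripartite.R
NULL

# Annotation map of one genome on the IRa-stripped coordinate space
# [0, ira_start): gene bodies, introns (inter-part gaps), and intergenic
# spacers between consecutive features. Incomplete IR duplicates
# ("_like" names) are not used as spacer delimiters.
contextMap <- function(record, partition) {
  n <- genomeLength(partition)
  cut <- partition@ira[1]
  ft <- genomeFeatures(record)
  ft <- ft[!grepl("_like$", ft$name), , drop = FALSE]
  # drop the IRa duplicate copies: features whose parts all start in IRa
  startsInIRa <- vapply(ft$parts, function(p)
    all(p[, 1] >= cut), logical(1))
  ft <- ft[!startsInIRa, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ft))) {
    p <- ft$parts[[i]]
    nm <- ft$name[i]; strand <- ft$strand[i]
    for (k in seq_len(nrow(p)))
      rows[[length(rows) + 1L]] <- data.frame(
        start = p[k, 1], end = p[k, 2], name = nm,
        category = "gene", kind = ft$kind[i], strand = strand,
        stringsAsFactors = FALSE)
    if (nrow(p) > 1L) {
      nIntron <- nrow(p) - 1L
      for (j in seq_len(nIntron)) { # gap j by ascending coordinate
        # introns numbered 5'->3' in transcription order
        num <- if (strand == "+") j else nIntron - j + 1L
        iname <- if (nIntron == 1L) paste(nm, "intron")
        else paste0(nm, " intron", num)
        rows[[length(rows) + 1L]] <- data.frame(
          start = p[j, 2], end = p[j + 1L, 1], name = iname,
          category = "intron", kind = ft$kind[i], strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  map <- do.call(rbind, rows)
  if (is.null(map)) stop("genome has no annotated features")
  # spacers between consecutive gene spans
  sp <- featureSpans(record)
  sp <- sp[!grepl("_like$", sp$name), , drop = FALSE]
  sp <- sp[sp$start < cut, , drop = FALSE]
  sp <- sp[order(sp$start), , drop = FALSE]
  spacers <- list()
  if (nrow(sp) > 1L) {
    for (i in seq_len(nrow(sp) - 1L)) {
      a <- sp$end[i]; b <- sp$start[i + 1L]
      if (b <= a) next # overlapping/abutting genes yield no spacer
      spacers[[length(spacers) + 1L]] <- data.frame(
        start = a, end = b,
        name = paste0(sp$name[i], "-", sp$name[i + 1L]),
        category = "spacer", kind = "spacer", strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  map <- rbind(map, do.call(rbind, spacers))
  map <- map[order(map$start, map$end), , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Extract homologous regions across genomes
#'
#' Builds the region inventory of each genome with the IRa copy removed,
#' and matches regions across genomes by name. Coding regions are the
#' exon-concatenated CDS of each unique protein-coding gene (transcript
#' order, stop codon included); introns are the inter-part gaps of
#' multi-exon genes, numbered 5' to 3'; spacers are the gaps between
#' consecutive gene spans on the IRa-stripped genome, named
#' "upstreamGene-downstreamGene" in genome order. tRNA/rRNA gene bodies
#' delimit spacers but are not themselves emitted as regions.
#'
#' @param records list of annotated, canonically oriented
#'   [GenomeRecord-class] objects
#' @param partitions list of matching [PlastomePartition-class] objects
#' @return a `RegionSet`: list with `info` (data.frame name, category),
#'   `seqs` (per-region named character vectors, one sequence per genome)
#'   and `excluded` (region names absent from at least one genome)
#' @export
extractRegions <- function(records, partitions) {
  stopifnot(length(records) == length(partitions), length(records) >= 1L)
  taxa <- vapply(records, genomeId, character(1))
  perGenome <- vector("list", length(records))
  for (gi in seq_along(records)) {
    rec <- records[[gi]]; part <- partitions[[gi]]
    map <- contextMap(rec, part)
    ft <- genomeFeatures(rec)
    ft <- ft[!grepl("_like$", ft$name), , drop = FALSE]
    seqs <- character(0); cats <- character(0)
    # coding: unique CDS genes, exon-concatenated
    cds <- ft[ft$kind == "CDS", , drop = FALSE]
    cds <- cds[!duplicated(cds$name), , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      seqs[[cds$name[i]]] <- extractFeatureSeq(rec, cds[i, , drop = FALSE])
      cats[[cds$name[i]]] <- "coding"
    }
    # introns and spacers from the map
    ns <- map[map$category %in% c("intron", "spacer"), , drop = FALSE]
    ns <- ns[!duplicated(ns$name), , drop = FALSE]
    for (i in seq_len(nrow(ns))) {
      s <- extractSubsequence(rec, ns$start[i], ns$end[i], ns$strand[i])
      seqs[[ns$name[i]]] <- s
      cats[[ns$name[i]]] <- ns$category[i]
    }
    perGenome[[gi]] <- list(seqs = seqs, cats = cats)
  }
  common <- Reduce(intersect, lapply(perGenome, function(x) names(x$seqs)))
  allNames <- unique(unlist(lapply(perGenome, function(x) names(x$seqs))))
  excluded <- setdiff(allNames, common)
  if (length(excluded))
    warning("regions absent from at least one genome were excluded: ",
            paste(excluded, collapse = ", "))
  common <- common[vapply(common, function(nm)
    all(vapply(perGenome, function(x) nzchar(x$seqs[[nm]]), logical(1))),
    logical(1))]
  info <- data.frame(
    name = common,
    category = vapply(common, function(nm) perGenome[[1]]$cats[[nm]],
                      character(1)),
    stringsAsFactors = FALSE)
  rownames(info) <- NULL
  seqs <- lapply(common, function(nm)
    stats::setNames(vapply(perGenome, function(x) x$seqs[[nm]],
                           character(1)), taxa))
  names(seqs) <- common
  structure(list(info = info, seqs = seqs, excluded = excluded),
            class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet: %d regions (%s) across %d genomes\n",
              nrow(x$info),
              paste(sprintf("%s: %d", names(table(x$info$category)),
                            table(x$info$category)), collapse = ", "),
              length(x$seqs[[1]]) %||% 0L))
  invisible(x)
}

#' Write each region of a RegionSet as a multi-FASTA file
#'
#' @param regionSet a `RegionSet` from [extractRegions()]
#' @param dir output directory (created if needed)
#' @return character vector of file paths, invisibly
#' @export
writeRegionFastas <- function(regionSet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(regionSet$seqs), function(nm) {
    safe <- gsub("[^A-Za-z0-9._-]+", "_", nm)
    p <- file.path(dir, paste0(safe, ".fa"))
    writeFastaSeqs(regionSet$seqs[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
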