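#' @include align.R
NULL

alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  rows <- if (inherits(aln, "RegionAlignment")) aln$rows else aln
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  m
}

# distinct maximal gap runs keyed by (start, end) column coordinates; a
# run shared by several taxa at identical coordinates counts once
indelEvents <- function(m) {
  ev <- character(0)
  lens <- integer(0)
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    key <- sprintf("%d:%d", starts[gi], ends[gi])
    new <- !(key %in% ev)
    ev <- c(ev, key[new])
    lens <- c(lens, r$lengths[gi][new])
  }
  list(keys = ev, lengths = lens)
}

#' Divergence statistics of one region alignment
#'
#' Computes the standard per-region divergence row: aligned length L,
#' nucleotide substitutions S (gap-free columns with at least two base
#' states), indel events I (distinct maximal gap runs, identical
#' coordinates counted once), total indel length G (sum of event
#' lengths), variable positions V = S + number of columns containing at
#' least one gap, and percent variability P = 100 (S + I) / L rounded
#' half-up to two decimals. Columns containing any gap are excluded from
#' substitution counting.
#'
#' @param aln a `RegionAlignment` (or named character vector of aligned
#'   rows)
#' @param name optional region label
#' @param category optional region category label
#' @return one-row data.frame with columns region, category, length_min,
#'   length_max, aligned_length, variable_positions, substitutions,
#'   n_indels, indel_length, percent_variability
#' @export
divergenceStats <- function(aln, name = NULL, category = NA_character_) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2L) stop("divergence statistics require >= 2 sequences")
  if (is.null(name))
    name <- if (inherits(aln, "RegionAlignment")) aln$name else NA_character_
  L <- ncol(m)
  hasGap <- colSums(m == "-") > 0L
  nStates <- apply(m, 2, function(col) length(unique(col)))
  S <- sum(!hasGap & nStates >= 2L)
  ev <- indelEvents(m)
  I <- length(ev$keys)
  G <- sum(ev$lengths)
  V <- S + sum(hasGap)
  raw <- nchar(gsub("-", "", apply(m, 1, paste, collapse = "")))
  data.frame(region = name, category = category,
             length_min = min(raw), length_max = max(raw),
             aligned_length = L, variable_positions = V,
             substitutions = S, n_indels = I, indel_length = G,
             percent_variability = percentVariability(S, I, L),
             stringsAsFactors = FALSE)
}

#' Divergence table over a list of region alignments
#'
#' Applies [divergenceStats()] to each alignment and keeps regions whose
#' aligned length exceeds `minAlignedLength` (the >150 bp filter of the
#' standard workflow; applied to aligned, not raw, length).
#'
#' @param alignments named list of `RegionAlignment` objects
#' @param categories optional named category vector (by region name)
#' @param minAlignedLength minimum aligned length, exclusive (default 150)
#' @return data.frame, one row per retained region
#' @export
divergenceTable <- function(alignments, categories = NULL,
                            minAlignedLength = 150L) {
  rows <- lapply(alignments, function(a)
    divergenceStats(a, category =
                      if (!is.null(categories)) categories[[a$name]]
                    else NA_character_))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$aligned_length > minAlignedLength, , drop = FALSE]
}

#' Screen mutational hotspots
#'
#' Regions whose percent variability strictly exceeds the threshold,
#' ordered by decreasing variability.
#'
#' @param stats data.frame from [divergenceTable()] (needs columns
#'   `region` and `percent_variability`)
#' @param threshold percent threshold, strict (default 2.0)
#' @return the qualifying rows, sorted by percent variability descending
#' @export
hotspotScreen <- function(stats, threshold = 2.0) {
  if (is.null(stats) || !nrow(stats))
    return(stats[0, , drop = FALSE])
  hot <- stats[stats$percent_variability > threshold, , drop = FALSE]
  hot <- hot[order(-hot$percent_variability, hot$region), , drop = FALSE]
  rownames(hot) <- NULL
  hot
}

#' Mean pairwise sequence identity of an alignment, in percent
#'
#' For every unordered taxon pair, identical columns / gap-free columns
#' for that pair; averaged over pairs, times 100, one decimal.
#'
#' @param aln a `RegionAlignment` or named character vector of rows
#' @return percent identity (1 decimal)
#' @export
overallIdentity <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2L) stop("identity requires >= 2 taxa")
  vals <- c()
  for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    vals <- c(vals, sum(m[i, ok] == m[j, ok]) / sum(ok))
  }
  round(100 * mean(vals), 1)
}
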