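#' @include AllClasses.R regions.R
NULL

#' Default perfect-microsatellite unit minima
#'
#' Minimum repeat-unit counts by motif length: mononucleotide >= 10,
#' dinucleotide >= 6, trinucleotide >= 4, tetranucleotide >= 4,
#' penta-/hexanucleotide >= 3.
#'
#' @return named integer vector, names "1".."6"
#' @export
ssrThresholds <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 4L, `4` = 4L, `5` = 3L, `6` = 3L)
}

# is the motif a power of a shorter unit (e.g. "AA", "ATAT")?
isPrimitiveMotif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (strrep(substr(motif, 1L, d), u %/% d) == motif) return(FALSE)
  }
  TRUE
}

# overlap policy shared by the finder and its test oracle: process loci in
# increasing unit length then start; a locus overlapping an accepted locus
# is trimmed to the part after that locus, then re-checked
resolveSsrOverlaps <- function(cand, s, minUnits) {
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$unit_len, cand$start), , drop = FALSE]
  acc <- cand[0, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    cur <- cand[i, , drop = FALSE]
    repeat {
      ov <- which(acc$start < cur$end & cur$start < acc$end)
      if (!length(ov)) break
      cur$start <- max(acc$end[ov])
      if (cur$start >= cur$end) break
      u <- cur$unit_len
      len <- cur$end - cur$start
      cur$n_units <- len %/% u
      cur$length <- len
      cur$motif <- substr(s, cur$start + 1L, cur$start + u)
    }
    if (cur$start >= cur$end) next
    if (cur$n_units < minUnits[[as.character(cur$unit_len)]]) next
    if (!isPrimitiveMotif(cur$motif)) next
    acc <- rbind(acc, cur)
  }
  acc[order(acc$start), , drop = FALSE]
}

#' Find perfect microsatellites (cpSSRs) in a sequence
#'
#' Detects maximal perfect tandem repeats of unit length 1-6 on the given
#' (plus) strand. A run generated by a smaller unit is reported only under
#' its smallest unit (the motif must not be a power of a shorter string);
#' the motif is reported in observed phase (the first unit of the run), so
#' e.g. ATT and TTA runs are distinct labels. Runs containing N are broken
#' at the N. A trailing partial unit is included in `length` but not in
#' `n_units`. Overlaps between loci of different unit lengths are resolved
#' in favour of the smaller unit, the larger-unit run being trimmed and
#' re-checked against the minima.
#'
#' @param seq character DNA sequence
#' @param thresholds named minimum unit counts per unit length, as
#'   [ssrThresholds()]
#' @return data.frame of loci sorted by start: motif, unit_len, start,
#'   end (0-based half-open), n_units, length
#' @export
findSSRs <- function(seq, thresholds = ssrThresholds()) {
  s <- toupper(as.character(seq))
  sv <- strsplit(s, "")[[1]]
  n <- length(sv)
  empty <- data.frame(motif = character(), unit_len = integer(),
                      start = integer(), end = integer(),
                      n_units = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  valid <- sv %in% c("A", "C", "G", "T")
  cand <- list()
  for (u in as.integer(names(thresholds))) {
    if (n <= u) next
    eq <- sv[seq_len(n - u)] == sv[(u + 1L):n] &
      valid[seq_len(n - u)] & valid[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k] + u          # repeat tract length in bp
      if (len %/% u < thresholds[[as.character(u)]]) next
      st <- starts[k] - 1L             # 0-based tract start
      motif <- substr(s, st + 1L, st + u)
      if (!isPrimitiveMotif(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        motif = motif, unit_len = u, start = st, end = st + len,
        n_units = len %/% u, length = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  out <- resolveSsrOverlaps(do.call(rbind, cand), s, thresholds)
  rownames(out) <- NULL
  out
}

#' Classify SSR loci by quadripartite region and genic context
#'
#' Loci are detected on the canonically oriented genome; loci starting in
#' the IRa copy are dropped (IR-duplicated loci are thereby collapsed to
#' the IRb record). Each locus is assigned its region (LSC/IR/SSC by the
#' interval containing its start) and context: the containing gene body,
#' named intron, or named spacer.
#'
#' @param loci data.frame from [findSSRs()] run on the full genome
#' @param record the annotated canonical [GenomeRecord-class]
#' @param partition the genome's [PlastomePartition-class]
#' @return `loci` with added columns region, context, context_category,
#'   and boundary flag (locus crossing a quadripartite boundary)
#' @export
classifySSRs <- function(loci, record, partition) {
  map <- contextMap(record, partition)
  iraStart <- partition@ira[1]
  loci <- loci[loci$start < iraStart, , drop = FALSE]
  regOf <- function(p) {
    if (p < partition@lsc[2]) "LSC"
    else if (p < partition@irb[2]) "IR"
    else if (p < partition@ssc[2]) "SSC"
    else "IR"
  }
  n <- nrow(loci)
  loci$region <- vapply(loci$start, function(p) regOf(p), character(1))
  loci$boundary <- vapply(seq_len(n), function(i)
    regOf(loci$start[i]) != regOf(loci$end[i] - 1L), logical(1))
  ctx <- character(n); ctxCat <- character(n)
  for (i in seq_len(n)) {
    hit <- which(map$start <= loci$start[i] & loci$start[i] < map$end)
    if (length(hit)) {
      hit <- hit[1]
      ctx[i] <- map$name[hit]
      ctxCat[i] <- map$category[hit]
    } else {
      ctx[i] <- NA_character_; ctxCat[i] <- NA_character_
    }
  }
  loci$context <- ctx
  loci$context_category <- ctxCat
  rownames(loci) <- NULL
  loci
}

#' Cross-species SSR table and summary counts
#'
#' Matches classified loci across genomes by (context, motif, occurrence
#' rank within context) and builds a per-locus row with the range of
#' repeat lengths across species, plus summary counts by unit length,
#' mononucleotide motif composition, and per-region counts/proportions.
#'
#' @param lociPerGenome named list (by taxon) of data.frames from
#'   [classifySSRs()]
#' @return list with `table` (cross-species locus table) and `summary`
#' @export
summarizeSSRs <- function(lociPerGenome) {
  rows <- lapply(names(lociPerGenome), function(tx) {
    d <- lociPerGenome[[tx]]
    if (!nrow(d)) return(NULL)
    d$taxon <- tx
    # occurrence rank of the (context, motif) pair within this genome
    key <- paste(d$context, d$motif)
    d$rank <- stats::ave(seq_along(key), key, FUN = seq_along)
    d
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all))
    return(list(table = data.frame(), summary = summarizeSSRTable(
      data.frame(motif = character(), region = character()))))
  sp <- split(all, paste(all$context, all$motif, all$rank, sep = "\r"))
  tab <- do.call(rbind, lapply(sp, function(d) {
    lens <- sort(unique(d$length))
    data.frame(
      motif = d$motif[1], location = d$context[1],
      region = d$region[1],
      repeat_length = if (length(lens) == 1L) as.character(lens)
      else paste0(min(lens), "-", max(lens)),
      n_species = nrow(d), stringsAsFactors = FALSE)
  }))
  tab <- tab[order(match(tab$region, c("LSC", "IR", "SSC")), tab$location), ,
             drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, summary = summarizeSSRTable(tab))
}

#' Summary counts for an SSR locus table
#'
#' Works on any table with `motif` and `region` columns (one row per
#' locus), e.g. the cross-species table of [summarizeSSRs()] or a
#' transcribed published locus table.
#'
#' @param tab data.frame with columns motif and region
#' @return list of counts: total, by unit length, mononucleotide motif
#'   composition (with A/T shares in percent), per-region counts and
#'   proportions
#' @export
summarizeSSRTable <- function(tab) {
  unit <- nchar(tab$motif)
  mono <- tab$motif[unit == 1L]
  monoTab <- table(mono)
  nMono <- length(mono)
  regionCounts <- table(factor(tab$region, levels = c("LSC", "IR", "SSC")))
  list(
    total = nrow(tab),
    by_unit_len = table(unit),
    n_mono = nMono,
    mono_composition = monoTab,
    a_share_pct = if (nMono) roundHalfUp2(100 * sum(mono == "A") / nMono)
    else NA_real_,
    t_share_pct = if (nMono) roundHalfUp2(100 * sum(mono == "T") / nMono)
    else NA_real_,
    region_counts = regionCounts,
    region_pct = if (nrow(tab))
      roundHalfUp2(100 * as.numeric(regionCounts) / nrow(tab))
    else numeric(3))
}
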