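#' @include AllClasses.R sequence-utils.R
NULL

# longest m in [0, cap] with substr(a, i, i+m-1) == substr(b, j, j+m-1)
# (1-based string indices; monotone, so binary search over block equality)
longestCommonStretch <- function(a, b, i, j, cap) {
  if (cap <= 0L) return(0L)
  lo <- 0L; hi <- cap
  while (lo < hi) {
    mid <- as.integer((lo + hi + 1L) %/% 2L)
    if (substr(a, i, i + mid - 1L) == substr(b, j, j + mid - 1L))
      lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Detect the inverted repeat and partition a plastome
#'
#' Finds the longest pair of disjoint intervals whose sequences are exact
#' reverse complements of each other (the IR pair), labels the two
#' single-copy arcs LSC (longer) and SSC (shorter), and rotates the
#' sequence to the canonical orientation: position 0 is the first LSC base
#' downstream of IRa, so the layout is LSC, IRb, SSC, IRa.
#'
#' Detection is seed-and-extend: probe k-mers tiled along the genome are
#' matched against the reverse complement and maximal exact matches are
#' grown around each hit. The match is exact (0 mismatches); extension
#' stops at the first mismatch.
#'
#' @param record a circular [GenomeRecord-class]
#' @param minIrLen minimum IR length in bp (default 1000)
#' @return list with elements `record` (the canonically rotated
#'   [GenomeRecord-class]) and `partition` (a [PlastomePartition-class])
#' @export
detectIR <- function(record, minIrLen = 1000L) {
  if (!record@circular) stop("IR detection requires a circular genome")
  n <- genomeLength(record)
  if (2L * minIrLen >= n) stop("genome shorter than two IR copies")
  s <- as.character(record@seq)
  r <- reverseComplementChr(s)
  S2 <- paste0(s, s)
  R2 <- paste0(r, r)
  w <- 31L
  step <- max(1L, as.integer(minIrLen %/% 2L) - w)
  cap <- as.integer(n %/% 2L)
  rsubj <- Biostrings::DNAString(R2)

  best <- NULL # list(astart, bstart, len), 0-based starts mod n
  for (p in seq(0L, n - 1L, by = step)) {
    if (!is.null(best)) {
      # skip probes inside an already-found copy; they extend to the same IR
      inA <- ((p - best$astart) %% n) < best$len
      inB <- ((p - best$bstart) %% n) < best$len
      if (inA || inB) next
    }
    probe <- substr(S2, p + 1L, p + w)
    if (grepl("N", probe, fixed = TRUE)) next
    hits <- Biostrings::matchPattern(probe, rsubj)
    if (length(hits) == 0L) next
    for (q0 in BiocGenerics::start(hits) - 1L) {
      if (q0 >= n) next # duplicate hit in the doubled subject
      q <- q0
      right <- longestCommonStretch(S2, R2, p + w + 1L, q + w + 1L,
                                    min(cap - w, n - 1L))
      # leftward extension, binary search on circular coordinates: an
      # extension by m means s[p-m .. p) matches r[q-m .. q)
      left <- {
        lo <- 0L; hi <- min(cap - w - right, n - 1L)
        lcheck <- function(m) {
          if (m == 0L) return(TRUE)
          i <- ((p - m) %% n) + 1L
          j <- ((q - m) %% n) + 1L
          substr(S2, i, i + m - 1L) == substr(R2, j, j + m - 1L)
        }
        while (lo < hi) {
          mid <- as.integer((lo + hi + 1L) %/% 2L)
          if (lcheck(mid)) lo <- mid else hi <- mid - 1L
        }
        lo
      }
      len <- w + left + right
      if (len > cap) len <- cap
      astart <- (p - left) %% n
      # map the reverse-complement interval back to plus-strand coordinates:
      # r[j, j+len) corresponds to s[n - j - len, n - j)
      rj <- (q - left) %% n
      bstart <- (n - rj - len) %% n
      # disjointness on the circle (reject palindromic self-matches)
      d1 <- (bstart - astart) %% n
      d2 <- (astart - bstart) %% n
      if (d1 < len || d2 < len) next
      if (is.null(best) || len > best$len)
        best <- list(astart = astart, bstart = bstart, len = len)
    }
  }
  if (is.null(best) || best$len < minIrLen)
    stop("no quadripartite structure: no inverted repeat of length >= ",
         minIrLen)

  a <- best$astart; b <- best$bstart; len <- best$len
  gapAB <- (b - (a + len)) %% n # arc from end of A to start of B
  gapBA <- (a - (b + len)) %% n
  if (gapAB == gapBA)
    stop("no quadripartite structure: single-copy arcs have equal length")
  if (gapAB > gapBA) {
    # LSC lies between A and B: layout IRa=A, LSC, ... wait: LSC follows A
    iraStart <- a; lscLen <- gapAB; sscLen <- gapBA
  } else {
    iraStart <- b; lscLen <- gapBA; sscLen <- gapAB
  }
  offset <- (iraStart + len) %% n # first LSC base downstream of IRa
  canonical <- rotateRecord(record, offset)
  part <- PlastomePartition(lscLen, len, sscLen)
  list(record = canonical, partition = part)
}

# gene span [start, end) with wrap encoded as end > n; excludes nothing
featureSpans <- function(record) {
  ft <- genomeFeatures(record)
  if (!nrow(ft)) return(data.frame(name = character(), kind = character(),
                                   strand = character(), start = integer(),
                                   end = integer()))
  data.frame(
    name = ft$name, kind = ft$kind, strand = ft$strand,
    start = vapply(ft$parts, function(p) p[1, 1], numeric(1)),
    end = vapply(ft$parts, function(p) max(p[, 2]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Profile the four quadripartite junctions
#'
#' For each junction (J_LB = LSC/IRb, J_SB = IRb/SSC, J_SA = SSC/IRa,
#' J_LA = IRa/LSC) reports the spanning gene with its side lengths, or the
#' flanking genes with their gaps when no gene spans. Incomplete IR
#' duplicates of junction genes (names with the `_like` suffix) are
#' reported with their within-IR length.
#'
#' @param record canonically oriented annotated [GenomeRecord-class]
#' @param partition the genome's [PlastomePartition-class]
#' @return data.frame with one row per junction (columns: junction,
#'   position, spanning_gene, left_bp, right_bp, upstream_gene,
#'   upstream_gap, downstream_gene, downstream_gap); attribute
#'   `like_features` holds the `_like` duplicate lengths
#' @export
junctionReport <- function(record, partition) {
  sp <- featureSpans(record)
  if (!nrow(sp)) stop("junctionReport requires an annotated genome")
  n <- genomeLength(partition)
  juncs <- c(J_LB = partition@irb[1], J_SB = partition@ssc[1],
             J_SA = partition@ira[1], J_LA = n)
  rows <- lapply(names(juncs), function(jn) {
    j <- juncs[[jn]]
    spans <- which(sp$start < j & j < sp$end)
    if (!length(spans)) # wrap-aware: a gene crossing the origin spans J_LA
      spans <- which(sp$start < j - n & j - n < sp$end - n)
    if (length(spans)) {
      i <- spans[which.max(sp$end[spans] - sp$start[spans])]
      data.frame(junction = jn, position = j,
                 spanning_gene = sp$name[i],
                 left_bp = j - sp$start[i], right_bp = sp$end[i] - j,
                 upstream_gene = NA_character_, upstream_gap = NA_real_,
                 downstream_gene = NA_character_, downstream_gap = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      upGap <- (j - sp$end) %% n
      dnGap <- (sp$start - j) %% n
      iu <- which.min(upGap); idn <- which.min(dnGap)
      data.frame(junction = jn, position = j,
                 spanning_gene = NA_character_,
                 left_bp = NA_real_, right_bp = NA_real_,
                 upstream_gene = sp$name[iu], upstream_gap = upGap[iu],
                 downstream_gene = sp$name[idn], downstream_gap = dnGap[idn],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  likes <- sp[grepl("_like$", sp$name), , drop = FALSE]
  if (nrow(likes)) {
    likes$length <- likes$end - likes$start
    likes$ir <- ifelse(likes$start >= partition@ira[1] |
                         likes$end > partition@ira[1], "IRa",
                       ifelse(likes$start >= partition@irb[1] &
                                likes$end <= partition@irb[2], "IRb", "IR"))
    attr(out, "like_features") <-
      likes[, c("name", "length", "ir"), drop = FALSE]
  } else {
    attr(out, "like_features") <-
      data.frame(name = character(), length = numeric(), ir = character())
  }
  out
}

#' Census of unique genes in a plastome
#'
#' Counts unique genes by kind. Genes fully duplicated within the two IR
#' copies are counted once and flagged as duplicated; incomplete
#' duplicates (`_like` names) are excluded from the unique count. A gene
#' annotated with k exon parts has k - 1 introns.
#'
#' @param record annotated [GenomeRecord-class]
#' @param partition the genome's [PlastomePartition-class]
#' @return list with counts (`total`, `n_cds`, `n_trna`, `n_rrna`),
#'   duplicated-in-IR gene names, and an intron table
#' @export
geneCensus <- function(record, partition) {
  ft <- genomeFeatures(record)
  ft <- ft[!grepl("_like$", ft$name), , drop = FALSE]
  if (!nrow(ft))
    return(list(total = 0L, n_cds = 0L, n_trna = 0L, n_rrna = 0L,
                duplicated_in_ir = character(),
                introns = data.frame(name = character(), kind = character(),
                                     n_introns = integer()),
                n_single_intron = 0L, n_two_intron = 0L))
  inIR <- function(p) {
    within <- function(iv) all(p[, 1] >= iv[1] & p[, 2] <= iv[2])
    within(partition@irb) || within(partition@ira)
  }
  uniq <- !duplicated(ft$name)
  dupNames <- unique(ft$name[duplicated(ft$name)])
  fullDup <- vapply(dupNames, function(nm) {
    copies <- ft$parts[ft$name == nm]
    sum(vapply(copies, inIR, logical(1))) >= 2L
  }, logical(1))
  u <- ft[uniq, , drop = FALSE]
  nIntrons <- vapply(seq_len(nrow(u)), function(i) {
    k <- max(vapply(ft$parts[ft$name == u$name[i]], nrow, integer(1)))
    k - 1L
  }, integer(1))
  introns <- data.frame(name = u$name, kind = u$kind, n_introns = nIntrons,
                        stringsAsFactors = FALSE)
  introns <- introns[introns$n_introns > 0L, , drop = FALSE]
  rownames(introns) <- NULL
  list(total = nrow(u),
       n_cds = sum(u$kind == "CDS"),
       n_trna = sum(u$kind == "tRNA"),
       n_rrna = sum(u$kind == "rRNA"),
       duplicated_in_ir = dupNames[fullDup],
       introns = introns,
       n_single_intron = sum(introns$n_introns == 1L),
       n_two_intron = sum(introns$n_introns == 2L))
}

#' Report CDSs whose start codon is not ATG
#'
#' @param record annotated [GenomeRecord-class]
#' @return data.frame (gene, codon) listing CDS genes with a non-ATG first
#'   in-frame codon
#' @export
checkStartCodons <- function(record) {
  ft <- genomeFeatures(record)
  cds <- ft[ft$kind == "CDS" & !grepl("_like$", ft$name), , drop = FALSE]
  cds <- cds[!duplicated(cds$name), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cds)), function(i) {
    s <- extractFeatureSeq(record, cds[i, , drop = FALSE])
    if (nchar(s) < 3L)
      stop("CDS '", cds$name[i], "' is shorter than one codon")
    data.frame(gene = cds$name[i], codon = substr(s, 1, 3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(gene = character(),
                                      codon = character()))
  out <- out[out$codon != "ATG", , drop = FALSE]
  rownames(out) <- NULL
  out
}
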