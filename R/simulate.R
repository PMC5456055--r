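#' @include regions.R quadripartite.R
NULL

# gene entry constructor for the template gene map
ge <- function(spacer, name, kind, strand, exons, introns = integer(0)) {
  list(spacer = spacer, name = name, kind = kind, strand = strand,
       exons = as.integer(exons), introns = as.integer(introns))
}

# Scaled plastome gene map: real gene names and structure motifs
# (junction-spanning rps19 and ycf1 with their incomplete IR duplicates,
# intron genes incl. two-intron ycf3/clpP, a duplicated IR gene set) at
# about one quarter of real plastome dimensions.
defaultGeneMap <- function() {
  list(
    lsc = list(
      ge(14, "trnH (GUG)", "tRNA", "-", 74),
      ge(120, "psbA", "CDS", "-", 450),
      ge(300, "matK", "CDS", "+", 600),
      ge(250, "rps16", "CDS", "-", c(39, 198), 500),
      ge(300, "trnQ (UUG)", "tRNA", "-", 72),
      ge(200, "psbK", "CDS", "+", 186),
      ge(200, "atpF", "CDS", "-", c(144, 408), 450),
      ge(280, "trnC (GCA)", "tRNA", "+", 71),
      ge(250, "psbM", "CDS", "-", 105),
      ge(240, "trnD (GUC)", "tRNA", "-", 74),
      ge(200, "trnG (UCC)", "tRNA", "+", 71),
      ge(170, "trnfM (CAU)", "tRNA", "-", 73),
      ge(210, "rps14", "CDS", "-", 225),
      ge(300, "ycf3", "CDS", "-", c(124, 230, 153), c(300, 300)),
      ge(260, "trnT (UGU)", "tRNA", "+", 72),
      ge(800, "trnL (UAA)", "tRNA", "+", c(35, 50), 350),
      ge(180, "ndhC", "CDS", "-", 363),
      ge(400, "trnV (UAC)", "tRNA", "-", c(38, 35), 450),
      ge(300, "atpB", "CDS", "-", 600),
      ge(500, "rbcL", "CDS", "+", 600),
      ge(350, "psbB", "CDS", "+", 600),
      ge(172, "psbT", "CDS", "+", 108),
      ge(200, "petB", "CDS", "+", c(6, 642), 350),
      ge(210, "petD", "CDS", "+", c(9, 474), 350),
      ge(207, "rpoA", "CDS", "-", 600),
      ge(300, "rps11", "CDS", "-", 300),
      ge(250, "clpP", "CDS", "-", c(69, 291, 228), c(350, 300)),
      ge(350, "psbI", "CDS", "+", 111)
    ),
    irb = list(
      ge(150, "rpl2", "CDS", "-", c(300, 300), 400),
      ge(120, "rpl23", "CDS", "-", 282),
      ge(200, "trnI (CAU)", "tRNA", "-", 74),
      ge(300, "rrn16", "rRNA", "+", 900),
      ge(180, "trnA (UGC)", "tRNA", "+", c(38, 35), 450),
      ge(150, "rrn5", "rRNA", "+", 121),
      ge(60, "trnR (ACG)", "tRNA", "+", 74),
      ge(120, "trnN (GUU)", "tRNA", "-", 72)
    ),
    ssc = list(
      ge(80, "ndhF", "CDS", "-", 300),
      ge(200, "rpl32", "CDS", "+", 162),
      ge(300, "trnL (UAG)", "tRNA", "-", 74),
      ge(150, "ccsA", "CDS", "+", 300),
      ge(120, "ndhD", "CDS", "-", 300),
      ge(100, "psaC", "CDS", "-", 201),
      ge(200, "ndhE", "CDS", "-", 201),
      ge(180, "ndhG", "CDS", "-", 252)
    ),
    rps19Span = 279L, rps19Overhang = 120L, # rps19 crosses J_LB
    ycf1SscPart = 800L, ycf1Overhang = 1000L # ycf1 crosses J_SA
  )
}

defaultSimTree <- function() {
  paste0(
    "(((A1:0.0016,A2:0.0018):0.0012,(A3:0.0017,(A4:0.0013,A5:0.0014):",
    "0.0009):0.0011):0.0020,((B1:0.0015,B2:0.0017):0.0010,(B3:0.0016,",
    "(B4:0.0012,B5:0.0015):0.0008):0.0012):0.0021,OUT:0.0042);")
}

defaultSSRSeeds <- function() {
  data.frame(
    context = c("trnH (GUG)-psbA", "rps16 intron", "matK-rps16",
                "trnQ (UUG)-psbK", "psbM-trnD (GUC)", "trnG (UCC)-trnfM (CAU)",
                "trnT (UGU)-trnL (UAA)", "ndhC-trnV (UAC)", "clpP intron1",
                "rrn5-trnR (ACG)", "ndhF-rpl32", "ccsA-ndhD",
                "rpl32-trnL (UAG)"),
    motif = c("A", "T", "A", "T", "A", "A", "AT", "TTA", "A", "A", "T", "T",
              "A"),
    units = c(13L, 12L, 12L, 12L, 13L, 12L, 7L, 5L, 12L, 12L, 12L, 13L,
              14L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic annotated plastomes
#'
#' The defaults describe a quarter-scale quadripartite plastome (LSC 20
#' kb, IR 6 kb, SSC 4 kb) annotated with a realistic gene template
#' (junction-spanning rps19/ycf1 with `_like` IR duplicates, single- and
#' two-intron genes, a duplicated IR gene block), evolved along a fixed
#' 11-taxon tree shaped like two five-species clades plus an early
#' diverging lineage. Branch lengths are expected substitutions per site.
#' Designated hotspot spacers carry rate multipliers of 4-6.5; indels and
#' SSR slippage act in noncoding sequence only, and the IR pair evolves
#' as a single locus (every IRb mutation is mirrored into IRa).
#'
#' @param lscLen,irLen,sscLen partition sizes in bp
#' @param tree Newick string with branch lengths
#' @param geneMap gene template (see `defaultGeneMap`)
#' @param multipliers named per-region rate multipliers (region name ->
#'   multiplier); unnamed regions fall back to the category defaults
#' @param codingMult,intronMult,spacerMult category default multipliers
#' @param indelRate indel events per noncoding site per unit branch length
#' @param indelGeomP geometric length parameter for indels (mean 1/p)
#' @param slipRate expected SSR slippage events per repeat unit per
#'   unit branch length
#' @param ssrSeeds data.frame (context, motif, units) of planted SSRs
#' @param seed RNG seed (all randomness derives from it)
#' @return a `SimConfig` list
#' @export
simConfig <- function(lscLen = 20000L, irLen = 6000L, sscLen = 4000L,
                      tree = defaultSimTree(),
                      geneMap = defaultGeneMap(),
                      multipliers = c(
                        "trnG (UCC)-trnfM (CAU)" = 5.0,
                        "trnT (UGU)-trnL (UAA)" = 6.0,
                        "ndhC-trnV (UAC)" = 5.5,
                        "psbB-psbT" = 6.5,
                        "petD-rpoA" = 5.0,
                        "ndhE-ndhG" = 4.0,
                        "rpl32-trnL (UAG)" = 4.5),
                      codingMult = 0.4, intronMult = 0.8, spacerMult = 1.4,
                      indelRate = 0.08, indelGeomP = 0.4,
                      slipRate = 8,
                      ssrSeeds = defaultSSRSeeds(), seed = 20170501L) {
  structure(list(lscLen = as.integer(lscLen), irLen = as.integer(irLen),
                 sscLen = as.integer(sscLen), tree = tree,
                 geneMap = geneMap, multipliers = multipliers,
                 codingMult = codingMult, intronMult = intronMult,
                 spacerMult = spacerMult, indelRate = indelRate,
                 indelGeomP = indelGeomP, slipRate = slipRate,
                 ssrSeeds = ssrSeeds, seed = as.integer(seed)),
            class = "SimConfig")
}

regionMultiplier <- function(config, name, category) {
  if (name %in% names(config$multipliers))
    return(unname(config$multipliers[[name]]))
  switch(category, gene = config$codingMult, coding = config$codingMult,
         intron = config$intronMult, spacer = config$spacerMult, 1)
}

# plant a start codon for a CDS whose exon parts are known; minus-strand
# genes get the reverse complement written at the top end of the last part
plantStartCodon <- function(sv, parts, strand, codon) {
  cd <- strsplit(codon, "")[[1]]
  if (strand == "+") {
    sv[(parts[1, 1] + 1L):(parts[1, 1] + 3L)] <- cd
  } else {
    e <- parts[nrow(parts), 2]
    rc <- rev(chartr("ACGT", "TGCA", cd))
    sv[(e - 2L):e] <- rc
  }
  sv
}

#' Build the ancestral annotated plastome
#'
#' Constructs the circular LSC + IRb + SSC + IRa ancestor from the
#' configured gene map: random sequence, genes placed region by region,
#' IRa generated as the exact reverse complement of IRb with mirrored
#' annotations, junction-spanning rps19/ycf1 and their `_like` partial
#' duplicates, planted unusual start codons (GTG rps19, ATC psbI, ATT
#' psbT, ACG ndhD) and planted SSR seeds.
#'
#' @param config a `SimConfig` from [simConfig()]
#' @return list with `record` (the ancestor [GenomeRecord-class]),
#'   `partition`, and `ssrs` (planted locus table in genome coordinates)
#' @export
buildAncestor <- function(config) {
  gm <- config$geneMap
  l <- config$lscLen; ir <- config$irLen; ssc <- config$sscLen
  n <- l + ssc + 2L * ir
  sv <- sample(c("A", "C", "G", "T"), n, replace = TRUE)

  name <- kind <- strand <- character(0); partsL <- list()
  addFeat <- function(nm, kd, st, p) {
    name <<- c(name, nm); kind <<- c(kind, kd); strand <<- c(strand, st)
    partsL[[length(partsL) + 1L]] <<- p
  }
  placeRegion <- function(entries, origin, limit) {
    cursor <- origin
    for (g in entries) {
      cursor <- cursor + g$spacer
      k <- length(g$exons)
      p <- matrix(0L, k, 2L)
      pos <- cursor
      for (i in seq_len(k)) {
        p[i, ] <- c(pos, pos + g$exons[i])
        pos <- pos + g$exons[i] +
          (if (i < k) g$introns[i] else 0L)
      }
      if (pos > limit)
        stop("gene map exceeds partition capacity at '", g$name, "'")
      addFeat(g$name, g$kind, g$strand, p)
      cursor <- pos
    }
    cursor
  }
  # LSC genes, then rps19 pinned so that it overhangs J_LB into IRb
  rps19Start <- l - (gm$rps19Span - gm$rps19Overhang)
  end <- placeRegion(gm$lsc, 0L, rps19Start)
  addFeat("rps19", "CDS", "+",
          matrix(c(rps19Start, rps19Start + gm$rps19Span), 1L))
  # IRb genes after the rps19 overhang; ycf1_like pinned at the IRb end
  ycf1LikeStart <- l + ir - gm$ycf1Overhang
  placeRegion(gm$irb, l + gm$rps19Overhang, ycf1LikeStart)
  addFeat("ycf1_like", "CDS", "+", matrix(c(ycf1LikeStart, l + ir), 1L))
  # SSC genes; ycf1 pinned at the SSC end, overhanging J_SA into IRa
  sscStart <- l + ir
  ycf1Start <- sscStart + ssc - gm$ycf1SscPart
  placeRegion(gm$ssc, sscStart, ycf1Start)
  addFeat("ycf1", "CDS", "-",
          matrix(c(ycf1Start, ycf1Start + gm$ycf1SscPart + gm$ycf1Overhang),
                 1L))

  # block exact-match extension of the IR beyond its planted boundaries
  sv[1L] <- "A"; sv[l] <- "A"           # J_LA / J_LB flanks
  sv[l + ir + 1L] <- "A"; sv[n - ir] <- "A" # J_SB / J_SA flanks

  # start codons (CDS only); ycf1's codon lies in IRa and is planted by
  # writing ATG at the start of its ycf1_like mirror inside IRb
  unusual <- c(rps19 = "GTG", psbI = "ATC", psbT = "ATT", ndhD = "ACG")
  for (i in seq_along(name)) {
    if (kind[i] != "CDS") next
    if (name[i] == "ycf1") next
    if (name[i] == "ycf1_like") {
      sv[(ycf1LikeStart + 1L):(ycf1LikeStart + 3L)] <-
        c("A", "T", "G") # mirrors to ATG read on ycf1's minus strand
      next
    }
    codon <- if (name[i] %in% names(unusual)) unusual[[name[i]]] else "ATG"
    sv <- plantStartCodon(sv, partsL[[i]], strand[i], codon)
  }

  # mirror IRb into IRa (sequence appended below) and duplicate features
  mirror <- function(p) {
    iraStart <- l + ir + ssc
    out <- cbind(iraStart + (l + ir - p[, 2]), iraStart + (l + ir - p[, 1]))
    out[order(out[, 1]), , drop = FALSE]
  }
  nIR <- length(name)
  for (i in seq_len(nIR)) {
    p <- partsL[[i]]
    if (p[1, 1] >= l && max(p[, 2]) <= l + ir &&
        !grepl("_like$", name[i])) {
      flipped <- if (strand[i] == "+") "-" else "+"
      addFeat(name[i], kind[i], flipped, mirror(p))
    }
  }
  # incomplete duplicate of rps19's IRb segment at the IRa end
  addFeat("rps19_like", "CDS", "-",
          matrix(c(n - gm$rps19Overhang, n), 1L))

  # plant SSR seeds before mirroring the IRa sequence
  ft <- featureTable(name, kind, strand, partsL)
  recTmp <- GenomeRecord("ancestor", paste(sv, collapse = ""), ft)
  part <- PlastomePartition(l, ir, ssc)
  map <- contextMap(recTmp, part)
  seeds <- config$ssrSeeds
  ssrs <- NULL
  for (i in seq_len(nrow(seeds))) {
    row <- map[map$name == seeds$context[i], , drop = FALSE]
    if (!nrow(row)) stop("SSR seed context not found: ", seeds$context[i])
    u <- nchar(seeds$motif[i]); len <- u * seeds$units[i]
    if (row$end[1] - row$start[1] < len + 4L)
      stop("SSR seed does not fit in context: ", seeds$context[i])
    st <- row$start[1] + ((row$end[1] - row$start[1] - len) %/% 2L)
    run <- strsplit(strrep(seeds$motif[i], seeds$units[i]), "")[[1]]
    sv[(st + 1L):(st + len)] <- run
    # blockers: prevent the maximal run from extending past the seed
    if (sv[st] == sv[st + u]) sv[st] <- setdiff(c("A", "C", "G", "T"),
                                                c(sv[st + u]))[2L]
    e <- st + len
    if (e + 1L <= n && sv[e + 1L] == sv[e + 1L - u])
      sv[e + 1L] <- setdiff(c("A", "C", "G", "T"), c(sv[e + 1L - u]))[2L]
    ssrs <- rbind(ssrs, data.frame(
      context = seeds$context[i], motif = seeds$motif[i], unit_len = u,
      start = st, end = st + len, n_units = seeds$units[i],
      stringsAsFactors = FALSE))
  }

  # IRa sequence = exact reverse complement of IRb
  irb <- sv[(l + 1L):(l + ir)]
  sv[(l + ir + ssc + 1L):n] <- rev(chartr("ACGT", "TGCA", irb))

  rec <- GenomeRecord("ancestor", paste(sv, collapse = ""), ft,
                      organism = "synthetic plastome")
  list(record = rec, partition = part, ssrs = ssrs)
}
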