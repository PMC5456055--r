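# build a bare quadripartite genome from planted segment sequences
plantedGenome <- function(lsc = 3000L, ir = 800L, ssc = 600L) {
  segs <- list(lsc = randomDNA(lsc), irb = randomDNA(ir),
               ssc = randomDNA(ssc))
  g <- strsplit(paste0(segs$lsc, segs$irb, segs$ssc,
                       plastomeCompare:::reverseComplementChr(segs$irb)),
                "")[[1]]
  # pin the single-copy bases flanking the IR pair so the maximal exact
  # reverse-complement match is exactly the planted pair
  g[c(1L, lsc, lsc + ir + 1L, lsc + ir + ssc)] <- "A"
  GenomeRecord("planted", paste(g, collapse = ""))
}

test_that("detectIR recovers planted partitions exactly", {
  set.seed(101)
  for (dims in list(c(3000L, 800L, 600L), c(5000L, 1200L, 900L))) {
    rec <- plantedGenome(dims[1], dims[2], dims[3])
    res <- detectIR(rec, minIrLen = 500L)
    expect_equal(lscLength(res$partition), dims[1])
    expect_equal(irLength(res$partition), dims[2])
    expect_equal(sscLength(res$partition), dims[3])
    expect_equal(lscLength(res$partition) + sscLength(res$partition) +
                   2L * irLength(res$partition), genomeLength(rec))
    # the IR pair really is a reverse-complement pair on the canonical seq
    s <- as.character(genomeSeq(res$record))
    irb <- substr(s, dims[1] + 1, dims[1] + dims[2])
    ira <- substr(s, nchar(s) - dims[2] + 1, nchar(s))
    expect_equal(plastomeCompare:::reverseComplementChr(irb), ira)
  }
})

test_that("detectIR is invariant to rotation of the circular input", {
  set.seed(102)
  rec <- plantedGenome()
  ref <- detectIR(rec, minIrLen = 500L)
  for (off in c(1L, 777L, 2500L, 4000L)) {
    rot <- plastomeCompare:::rotateRecord(rec, off)
    res <- detectIR(rot, minIrLen = 500L)
    expect_equal(as.character(genomeSeq(res$record)),
                 as.character(genomeSeq(ref$record)))
    expect_equal(lscLength(res$partition), lscLength(ref$partition))
  }
})

test_that("a genome without an inverted repeat is rejected", {
  set.seed(103)
  rec <- GenomeRecord("norepeat", randomDNA(5000))
  expect_error(detectIR(rec, minIrLen = 1000L), "no quadripartite")
})

test_that("junction report recovers planted junction geometry", {
  set.seed(104)
  anc <- buildAncestor(simConfig())
  jr <- junctionReport(anc$record, anc$partition)
  gm <- defaultGeneMap()
  r <- jr[jr$junction == "J_LB", ]
  expect_equal(r$spanning_gene, "rps19")
  expect_equal(r$right_bp, gm$rps19Overhang)
  expect_equal(r$left_bp + r$right_bp, gm$rps19Span) # sides sum to length
  r <- jr[jr$junction == "J_SA", ]
  expect_equal(r$spanning_gene, "ycf1")
  expect_equal(r$left_bp, gm$ycf1SscPart)
  expect_equal(r$right_bp, gm$ycf1Overhang)
  # incomplete duplicates abut J_SB and J_LA
  r <- jr[jr$junction == "J_SB", ]
  expect_equal(r$upstream_gene, "ycf1_like")
  expect_equal(r$upstream_gap, 0)
  r <- jr[jr$junction == "J_LA", ]
  expect_equal(r$upstream_gene, "rps19_like")
  expect_equal(r$downstream_gene, "trnH (GUG)")
  expect_equal(r$downstream_gap, 14)
  likes <- attr(jr, "like_features")
  expect_setequal(likes$name, c("ycf1_like", "rps19_like"))
  expect_equal(likes$length[likes$name == "ycf1_like"], gm$ycf1Overhang)
  expect_equal(likes$length[likes$name == "rps19_like"], gm$rps19Overhang)
})

test_that("gene census recovers the planted gene inventory", {
  set.seed(105)
  anc <- buildAncestor(simConfig())
  cen <- geneCensus(anc$record, anc$partition)
  gm <- defaultGeneMap()
  entries <- c(gm$lsc, gm$irb, gm$ssc)
  kinds <- vapply(entries, `[[`, character(1), "kind")
  # + rps19 and ycf1 (junction genes); _like duplicates are not unique genes
  expect_equal(cen$total, length(entries) + 2L)
  expect_equal(cen$n_cds, sum(kinds == "CDS") + 2L)
  expect_equal(cen$n_trna, sum(kinds == "tRNA"))
  expect_equal(cen$n_rrna, sum(kinds == "rRNA"))
  expect_setequal(cen$duplicated_in_ir,
                  vapply(gm$irb, `[[`, character(1), "name"))
  nIntrons <- vapply(entries, function(g) length(g$introns), integer(1))
  expect_equal(cen$n_single_intron, sum(nIntrons == 1L))
  expect_equal(cen$n_two_intron, sum(nIntrons == 2L))
  # empty annotation gives a zero census
  bare <- GenomeRecord("bare", randomDNA(100))
  zero <- geneCensus(bare, PlastomePartition(40, 20, 20))
  expect_equal(zero$total, 0L)
})

test_that("non-ATG start codons are reported exactly as planted", {
  set.seed(106)
  anc <- buildAncestor(simConfig())
  sc <- checkStartCodons(anc$record)
  got <- stats::setNames(sc$codon, sc$gene)
  expect_mapequal(as.list(got),
                  list(rps19 = "GTG", psbI = "ATC", psbT = "ATT",
                       ndhD = "ACG"))
  short <- GenomeRecord("s", "ACGTACGT",
                        featureTable("tiny", "CDS", "+",
                                     list(matrix(c(0L, 2L), 1))),
                        circular = FALSE)
  expect_error(checkStartCodons(short), "codon")
})
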