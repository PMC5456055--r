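test_that("GenBank write-then-parse is the identity on planted records", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 5000L
    seq <- randomDNA(n)
    ft <- featureTable(
      name = c("geneA", "trnX (UAA)", "geneB", "rrnY"),
      kind = c("CDS", "tRNA", "CDS", "rRNA"),
      strand = c("+", "-", "-", "+"),
      parts = list(matrix(c(10L, 310L), 1),
                   matrix(c(400L, 475L), 1),
                   matrix(c(600L, 900L, 1100L, 1400L), 2, byrow = TRUE),
                   matrix(c(2000L, 3500L), 1)))
    rec <- GenomeRecord(sprintf("SYN%02d", rep), seq, ft,
                        organism = "Synthetic organism")
    path <- tempfile(fileext = ".gb")
    writeGenBank(rec, path)
    back <- readGenBank(path)
    expect_identical(as.character(genomeSeq(back)), seq)
    expect_identical(genomeId(back), genomeId(rec))
    expect_identical(genomeFeatures(back)$name, ft$name)
    expect_identical(genomeFeatures(back)$kind, ft$kind)
    expect_identical(genomeFeatures(back)$strand, ft$strand)
    expect_identical(lapply(genomeFeatures(back)$parts, unname),
                     lapply(ft$parts, unname))
  }
})

test_that("complement(join(...)) yields one minus-strand feature with ascending parts", {
  gb <- c("LOCUS       X                 100 bp    DNA     circular PLN",
          "FEATURES             Location/Qualifiers",
          "     CDS             complement(join(11..30,41..70))",
          "                     /gene=\"g1\"",
          "ORIGIN",
          paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
          "//")
  path <- tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- readGenBank(path)
  ft <- genomeFeatures(rec)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$strand, "-")
  p <- unname(ft$parts[[1]])
  expect_equal(p, matrix(c(10L, 30L, 40L, 70L), 2, byrow = TRUE))
})

test_that("origin-wrapping features survive a GenBank round trip", {
  seq <- randomDNA(200)
  ft <- featureTable("wrapper", "CDS", "+",
                     list(matrix(c(180L, 230L), 1))) # wraps 200 -> 30
  rec <- GenomeRecord("W1", seq, ft, circular = TRUE)
  path <- tempfile(fileext = ".gb")
  writeGenBank(rec, path)
  back <- readGenBank(path)
  expect_equal(unname(genomeFeatures(back)$parts[[1]]),
               matrix(c(180L, 230L), 1))
})

test_that("malformed GenBank input errors informatively", {
  noseq <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X  100 bp DNA linear", "FEATURES", "//"), noseq)
  expect_error(readGenBank(noseq), "ORIGIN")
  bad <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X                 20 bp    DNA     linear PLN",
               "FEATURES             Location/Qualifiers",
               "     CDS             10..55",
               "                     /gene=\"gX\"",
               "ORIGIN",
               "        1 acgtacgtac acgtacgtac",
               "//"), bad)
  expect_error(readGenBank(bad), "gX")
})

test_that("extractSubsequence handles strands and circular wrap", {
  rec <- GenomeRecord("t", "AACCGGTT", circular = FALSE)
  expect_equal(extractSubsequence(rec, 2, 6), "CCGG")
  expect_equal(extractSubsequence(rec, 1, 5, strand = "-"), "CGGT")
  circ <- GenomeRecord("c", "ACGTACGTAC", circular = TRUE)
  expect_equal(extractSubsequence(circ, 8, 2),
               paste0(substr("ACGTACGTAC", 9, 10), substr("ACGTACGTAC", 1, 2)))
  expect_error(extractSubsequence(rec, 6, 2), "linear")
})

test_that("multi-part features are extracted in transcription order", {
  seq <- paste0(strrep("A", 10), "CCGG", strrep("A", 6), "TTAA",
                strrep("A", 10))
  ft <- featureTable(c("plus", "minus"), "CDS", c("+", "-"),
                     list(matrix(c(10L, 14L, 20L, 24L), 2, byrow = TRUE),
                          matrix(c(10L, 14L, 20L, 24L), 2, byrow = TRUE)))
  rec <- GenomeRecord("m", seq, ft, circular = FALSE)
  expect_equal(extractFeatureSeq(rec, "plus"), "CCGGTTAA")
  expect_equal(extractFeatureSeq(rec, "minus"), "TTAACCGG")
})

test_that("gcContent matches a character-count oracle and its invariants", {
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("GCGC"), 100)
  expect_error(gcContent("NNNN"))
  set.seed(7)
  s <- randomDNA(10000)
  expect_equal(gcContent(s), oracleGC(s))
  expect_equal(gcContent(s), gcContent(reverseComplementChr(s)))
})

test_that("subsequence length equals interval length, wrap included", {
  set.seed(11)
  rec <- GenomeRecord("len", randomDNA(500), circular = TRUE)
  for (i in 1:20) {
    a <- sample(0:499, 1); b <- sample(0:499, 1)
    if (a == b) next
    got <- extractSubsequence(rec, a, b)
    want <- if (b > a) b - a else b - a + 500
    expect_equal(nchar(got), want)
  }
})

test_that("FASTA round trip preserves sequences and names", {
  set.seed(3)
  seqs <- stats::setNames(vapply(1:4, function(i) randomDNA(150 + i),
                                 character(1)), paste0("tax", 1:4))
  p <- tempfile(fileext = ".fa")
  writeFastaSeqs(seqs, p)
  expect_equal(readFastaSeqs(p), seqs)
})
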