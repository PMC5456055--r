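test_that("planted mono- and dinucleotide runs are found with correct bounds", {
  s <- paste0("GG", strrep("A", 11), "CC", strrep("AT", 6), "GG")
  loci <- findSSRs(s)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$motif, c("A", "AT"))
  expect_equal(loci$length, c(11L, 12L))
  expect_equal(loci$start, c(2L, 15L))
  expect_equal(loci$n_units, c(11L, 6L))
})

test_that("runs below the unit-count minima are not reported", {
  expect_equal(nrow(findSSRs(strrep("A", 9))), 0L)
  expect_equal(nrow(findSSRs(strrep("A", 10))), 1L)
  expect_equal(nrow(findSSRs(paste0("G", strrep("AT", 5), "G"))), 0L)
})

test_that("runs are broken at N and non-primitive motifs are suppressed", {
  s <- paste0(strrep("A", 7), "N", strrep("A", 7))
  expect_equal(nrow(findSSRs(s)), 0L)
  # a pure poly-A tract must be reported as unit 1 only
  loci <- findSSRs(paste0("C", strrep("A", 14), "C"))
  expect_equal(loci$motif, "A")
  expect_equal(loci$unit_len, 1L)
})

test_that("findSSRs equals the exhaustive enumerator on random sequences", {
  set.seed(401)
  for (i in 1:40) {
    # SSR-enriched random sequence: splice runs into random background
    s <- randomDNA(500)
    for (k in 1:3) {
      unit <- sample(c("A", "T", "AT", "TA", "ATT", "AAG"), 1)
      run <- strrep(unit, sample(3:14, 1))
      at <- sample(400, 1)
      s <- paste0(substr(s, 1, at), run, substr(s, at + 1, nchar(s)))
    }
    got <- findSSRs(s)
    want <- oracleSSRs(s)
    expect_equal(got, want)
  }
})

test_that("reported loci never overlap", {
  set.seed(402)
  for (i in 1:10) {
    s <- paste0(randomDNA(100), strrep("A", 12), strrep("TA", 7),
                randomDNA(100))
    loci <- findSSRs(s)
    if (nrow(loci) > 1L) {
      loci <- loci[order(loci$start), ]
      expect_true(all(loci$start[-1] >= loci$end[-nrow(loci)]))
    }
  }
})

test_that("published SSR locus table summarizes to the reported census", {
  tab <- loadSSRLocusTable()
  s <- summarizeSSRTable(tab)
  expect_equal(s$total, 58L)
  expect_equal(s$n_mono, 55L)
  expect_equal(as.vector(s$mono_composition[c("A", "T", "C")]),
               c(24L, 30L, 1L))
  expect_equal(sum(nchar(tab$motif) == 2L), 1L) # the AT dinucleotide
  expect_equal(sort(tab$motif[nchar(tab$motif) == 3L]), c("ATT", "TTA"))
  expect_equal(s$a_share_pct, 43.64)
  expect_equal(as.vector(s$region_counts), c(49L, 1L, 8L))
  expect_equal(sum(s$region_pct), 100, tolerance = 0.02)
})

test_that("planted SSRs are classified into their regions and contexts", {
  set.seed(403)
  cfg <- simConfig()
  anc <- buildAncestor(cfg)
  loci <- findSSRs(as.character(genomeSeq(anc$record)))
  cls <- classifySSRs(loci, anc$record, anc$partition)
  for (i in seq_len(nrow(anc$ssrs))) {
    hit <- cls[cls$context == anc$ssrs$context[i] &
                 cls$motif == anc$ssrs$motif[i], , drop = FALSE]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, anc$ssrs$start[i])
  }
  # the IR-context locus is reported once, from the IRb copy
  irLocus <- cls[cls$context == "rrn5-trnR (ACG)", , drop = FALSE]
  expect_equal(nrow(irLocus), 1L)
  expect_equal(irLocus$region, "IR")
  expect_true(all(cls$start < anc$partition@ira[1]))
})

test_that("cross-species SSR matching keys on context, motif and rank", {
  perGenome <- list(
    g1 = data.frame(motif = c("A", "A", "T"), unit_len = 1L,
                    start = c(10L, 50L, 90L), end = c(22L, 61L, 100L),
                    n_units = c(12L, 11L, 10L), length = c(12L, 11L, 10L),
                    region = "LSC", boundary = FALSE,
                    context = c("x-y", "x-y", "y-z"),
                    context_category = "spacer"),
    g2 = data.frame(motif = c("A", "A", "T"), unit_len = 1L,
                    start = c(11L, 52L, 95L), end = c(25L, 62L, 106L),
                    n_units = c(14L, 10L, 11L), length = c(14L, 10L, 11L),
                    region = "LSC", boundary = FALSE,
                    context = c("x-y", "x-y", "y-z"),
                    context_category = "spacer"))
  res <- summarizeSSRs(perGenome)
  expect_equal(nrow(res$table), 3L)
  xy <- res$table[res$table$location == "x-y", ]
  expect_setequal(xy$repeat_length, c("12-14", "10-11"))
  expect_equal(res$summary$total, 3L)
})

test_that("no loci yields empty outputs", {
  expect_equal(nrow(findSSRs("ACGT")), 0L)
  res <- summarizeSSRs(list(g1 = findSSRs("ACGT")))
  expect_equal(res$summary$total, 0L)
})
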