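mkAln <- function(rows) structure(list(name = "x", rows = rows,
                                       L = nchar(rows[[1]])),
                                  class = "RegionAlignment")

test_that("site classification matches the brute-force column classifier", {
  # columns: (A,A,T,T) PI; (A,T,C,G) V only; constant; (A,A,A,T) V only;
  # constant; (G,G,C,C) PI
  rows <- c(t1 = "AAAACG", t2 = "ATAACG", t3 = "TCAACC", t4 = "TGATCC")
  s <- alignmentSummary(mkAln(rows))
  expect_equal(s$variable_positions, 4L)
  expect_equal(s$parsimony_informative, 2L)
  # gaps are not a PI state: {A, A, -, -} is not informative
  rows2 <- c(t1 = "AA", t2 = "AA", t3 = "-A", t4 = "-A")
  expect_equal(alignmentSummary(mkAln(rows2))$parsimony_informative, 0L)
})

test_that("an invariant alignment has all-zero statistics", {
  rows <- stats::setNames(rep("ACGTACGT", 4), paste0("t", 1:4))
  s <- alignmentSummary(mkAln(rows))
  expect_equal(s$variable_positions, 0L)
  expect_equal(s$parsimony_informative, 0L)
  expect_equal(s$percent_variability, 0)
})

test_that("PI sites <= variable sites <= aligned length", {
  set.seed(501)
  for (i in 1:20) {
    rows <- randomAlignment(nrow = sample(4:8, 1), L = 40)
    s <- alignmentSummary(mkAln(rows))
    expect_lte(s$parsimony_informative, s$variable_positions)
    expect_lte(s$variable_positions, s$aligned_length)
  }
})

test_that("JC69 distances match the closed form with pairwise deletion", {
  rows <- stats::setNames(rep("ACGTACGTAC", 2), c("a", "b"))
  expect_equal(unname(jc69Distance(rows)["a", "b"]), 0)
  # p = 0.1 over ten columns
  rows <- c(a = "ACGTACGTAC", b = "ACGTACGTAT")
  expect_equal(unname(jc69Distance(rows)["a", "b"]),
               -0.75 * log(1 - 4 * 0.1 / 3))
  expect_equal(round(unname(jc69Distance(rows)["a", "b"]), 4), 0.1073)
  # gap columns are dropped per pair
  rows <- c(a = "-CGTACGTAC", b = "ACGTACGT-T")
  p <- 1 / 8
  expect_equal(unname(jc69Distance(rows)["a", "b"]),
               -0.75 * log(1 - 4 * p / 3))
  expect_error(jc69Distance(c(a = "AAAA", b = "TTTT")), "undefined")
})

test_that("NJ resolves the additive four-taxon matrix exactly", {
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- njTree(d)
  want <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  expect_equal(ape::dist.topo(tr, ape::unroot(want)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 1))
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(502)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
    d <- ape::cophenetic.phylo(tr)
    rec <- njTree(d)
    expect_equal(ape::dist.topo(tr, rec), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap is reproducible and saturates on clean signal", {
  set.seed(503)
  # strong, consistent split signal: two haplotypes repeated
  block1 <- randomDNA(300); block2 <- strsplit(block1, "")[[1]]
  flip <- seq(1, 300, by = 3)
  block2[flip] <- chartr("ACGT", "TGCA", block2[flip])
  block2 <- paste(block2, collapse = "")
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(300, k)
    v[at] <- chartr("ACGT", "TGCA", v[at])
    paste(v, collapse = "")
  }
  rows <- c(a1 = block1, a2 = mut(block1, 2), b1 = block2,
            b2 = mut(block2, 2))
  aln <- mkAln(rows)
  r1 <- bootstrapNJ(aln, nReps = 50, seed = 9)
  r2 <- bootstrapNJ(aln, nReps = 50, seed = 9)
  expect_identical(r1$supports, r2$supports)
  expect_true(all(r1$supports >= 99))
  expect_error(bootstrapNJ(aln, nReps = 0), "nReps")
})

test_that("concatenation joins regions and keeps taxa aligned", {
  a1 <- mkAln(c(x = "AAAA", y = "AAAT", z = "AAAA"))
  a2 <- mkAln(c(x = "GG-G", y = "GGGG", z = "GGGG"))
  cc <- concatenateAlignments(list(a1, a2))
  expect_equal(cc$L, 8L)
  expect_equal(unname(cc$rows[["x"]]), "AAAAGG-G")
  a3 <- mkAln(c(x = "TT", w = "TT", z = "TT"))
  expect_error(concatenateAlignments(list(a1, a3)), "missing")
})

test_that("PHYLIP export writes a parseable relaxed matrix", {
  aln <- mkAln(c("tax one" = "ACGT-CGT", tax2 = "ACGTACGT"))
  p <- tempfile(fileext = ".phy")
  writePhylipAlignment(aln, p)
  lines <- readLines(p)
  expect_match(lines[1], "^ 2 8$")
  expect_match(lines[2], "^tax_one ACGT-CGT$")
})
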