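test_that("the ancestor satisfies the quadripartite identities by construction", {
  set.seed(601)
  cfg <- simConfig()
  anc <- buildAncestor(cfg)
  expect_equal(lscLength(anc$partition) + sscLength(anc$partition) +
                 2L * irLength(anc$partition), genomeLength(anc$record))
  res <- detectIR(anc$record, 1000L)
  expect_equal(lscLength(res$partition), cfg$lscLen)
  expect_equal(irLength(res$partition), cfg$irLen)
  expect_equal(sscLength(res$partition), cfg$sscLen)
})

test_that("a gene map that does not fit its partition is rejected", {
  cfg <- simConfig(lscLen = 2000L)
  expect_error(buildAncestor(cfg), "capacity")
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- simConfig(seed = 99L)
  s1 <- simulatePlastomes(cfg)
  s2 <- simulatePlastomes(cfg)
  for (tx in names(s1$records))
    expect_identical(as.character(genomeSeq(s1$records[[tx]])),
                     as.character(genomeSeq(s2$records[[tx]])))
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulatedDataset(s1, d1)
  writeSimulatedDataset(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("zero branch lengths leave every leaf identical to the ancestor", {
  cfg <- simConfig(tree = "(L1:0,L2:0,L3:0);")
  sim <- simulatePlastomes(cfg)
  for (rec in sim$records)
    expect_identical(as.character(genomeSeq(rec)),
                     as.character(genomeSeq(sim$ancestor$record)))
})

test_that("the IR pair stays a perfect reverse-complement at every leaf", {
  sim <- simulatePlastomes(simConfig(seed = 5L))
  for (tx in names(sim$records)) {
    p <- sim$truth$partitions[[tx]]
    s <- as.character(genomeSeq(sim$records[[tx]]))
    irb <- substr(s, p$lsc + 1, p$lsc + p$ir)
    ira <- substr(s, p$lsc + p$ir + p$ssc + 1, nchar(s))
    expect_identical(plastomeCompare:::reverseComplementChr(irb), ira)
  }
})

test_that("replaying recorded branch actions reproduces each genome", {
  sim <- simulatePlastomes(simConfig(seed = 6L))
  for (lbl in names(sim$truth$actions)) {
    if (!lbl %in% names(sim$records)) next
    got <- replayBranchActions(sim$truth$parent_seqs[[lbl]],
                               sim$truth$actions[[lbl]])
    expect_identical(got, as.character(genomeSeq(sim$records[[lbl]])))
  }
})

test_that("realized substitution counts are Poisson-consistent", {
  # one branch, many replicates: the total count over replicates is
  # Poisson with summed mean; check it lies in the 99% interval
  cfg <- simConfig()
  anc <- buildAncestor(cfg)
  state0 <- plastomeCompare:::stateFromAncestor(anc)
  bl <- 0.002
  region <- "trnT (UGU)-trnL (UAA)" # hotspot spacer, multiplier 6
  map <- plastomeCompare:::contextMap(anc$record, anc$partition)
  row <- map[map$name == region, ]
  # subtract the slippage-only SSR tract inside the spacer
  ssrIn <- anc$ssrs[anc$ssrs$context == region, , drop = FALSE]
  effWidth <- (row$end - row$start) -
    sum(ssrIn$end - ssrIn$start + 2L)
  lambda1 <- bl * effWidth *
    plastomeCompare:::regionMultiplier(cfg, region, "spacer")
  R <- 40L
  set.seed(607)
  total <- 0L
  for (r in seq_len(R)) {
    res <- plastomeCompare:::evolveBranch(state0, bl, cfg)
    total <- total + sum(vapply(res$actions, function(a)
      a$type == "sub" && a$region == region, logical(1)))
  }
  expect_gte(total, stats::qpois(0.005, R * lambda1))
  expect_lte(total, stats::qpois(0.995, R * lambda1))
})

test_that("the written dataset parses back to the simulated genomes", {
  sim <- simulatePlastomes(simConfig(tree = "(X:0.001,Y:0.002,Z:0.001);"))
  d <- tempfile()
  writeSimulatedDataset(sim, d)
  for (tx in names(sim$records)) {
    back <- readGenBank(file.path(d, paste0(tx, ".gb")))
    expect_identical(as.character(genomeSeq(back)),
                     as.character(genomeSeq(sim$records[[tx]])))
    expect_identical(genomeFeatures(back)$name,
                     genomeFeatures(sim$records[[tx]])$name)
  }
  expect_true(file.exists(file.path(d, "truth.json")))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_setequal(unlist(truth$taxa), names(sim$records))
})
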