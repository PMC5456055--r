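#' @include evolve.R phylo.R ssr.R tables.R
NULL

#' Run the full comparative-plastome analysis
#'
#' End-to-end orchestration over a set of annotated genomes (or a
#' simulation configuration): quadripartite partitioning and junction
#' profiling, homologous region extraction (IRa removed), per-region
#' alignment and divergence statistics with hotspot screening, cpSSR
#' detection/classification, IR-stripped concatenation statistics, and a
#' JC69 neighbor-joining tree with bootstrap supports. Writes the full
#' report bundle as TSV/Newick plus a run log.
#'
#' @param records list of annotated [GenomeRecord-class] objects (NULL to
#'   simulate)
#' @param config a `SimConfig` used when `records` is NULL
#' @param outDir output directory (created); NULL skips file output
#' @param minIrLen minimum IR length for [detectIR()]
#' @param minAlignedLength region filter, aligned length strictly greater
#'   (default 150)
#' @param hotspotThreshold percent-variability hotspot cutoff, strict
#' @param ssrMinima SSR unit-count minima, as [ssrThresholds()]
#' @param bootstrapReps bootstrap replicates for the NJ tree
#' @param seed seed for the bootstrap resampling
#' @param alignMethod passed to [alignRegions()]
#' @return list with all computed tables and objects, invisibly when
#'   written to disk
#' @export
runPipeline <- function(records = NULL, config = simConfig(),
                        outDir = NULL, minIrLen = 1000L,
                        minAlignedLength = 150L, hotspotThreshold = 2.0,
                        ssrMinima = ssrThresholds(), bootstrapReps = 100L,
                        seed = 1L, alignMethod = "builtin") {
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- NULL
  if (is.null(records)) {
    say("simulating %d-leaf dataset (seed %d)",
        length(ape::read.tree(text = config$tree)$tip.label), config$seed)
    sim <- stage("simulate", simulatePlastomes(config))
    records <- sim$records
  }
  if (length(records) < 3L) stop("need at least 3 genomes")
  taxa <- vapply(records, genomeId, character(1))

  say("partitioning %d genomes", length(records))
  parts <- list(); canon <- list()
  table1 <- do.call(rbind, lapply(records, function(rec) {
    res <- stage(paste0("partition:", genomeId(rec)),
                 detectIR(rec, minIrLen))
    canon[[genomeId(rec)]] <<- res$record
    parts[[genomeId(rec)]] <<- res$partition
    data.frame(taxon = genomeId(rec),
               genome_size = genomeLength(res$record),
               lsc_length = lscLength(res$partition),
               ssc_length = sscLength(res$partition),
               ir_length = irLength(res$partition),
               gc_percent = gcContent(genomeSeq(res$record)),
               stringsAsFactors = FALSE)
  }))

  say("profiling junctions")
  junctions <- do.call(rbind, lapply(taxa, function(tx) {
    j <- stage(paste0("junctions:", tx),
               junctionReport(canon[[tx]], parts[[tx]]))
    cbind(taxon = tx, j)
  }))

  say("extracting and aligning regions")
  regions <- stage("regions", extractRegions(canon[taxa], parts[taxa]))
  alns <- stage("align", alignRegions(regions, method = alignMethod))
  cats <- stats::setNames(regions$info$category, regions$info$name)
  divAll <- stage("divergence",
                  divergenceTable(alns, categories = cats,
                                  minAlignedLength = minAlignedLength))
  codingTab <- divAll[divAll$category == "coding", , drop = FALSE]
  noncodingTab <- divAll[divAll$category %in% c("spacer", "intron"), ,
                         drop = FALSE]
  hotspots <- hotspotScreen(noncodingTab, hotspotThreshold)
  say("%d coding and %d noncoding regions pass the %d bp filter; %d hotspots",
      nrow(codingTab), nrow(noncodingTab), minAlignedLength, nrow(hotspots))

  say("detecting SSRs")
  lociPerGenome <- lapply(taxa, function(tx) {
    loci <- stage(paste0("ssr:", tx),
                  findSSRs(as.character(genomeSeq(canon[[tx]])), ssrMinima))
    classifySSRs(loci, canon[[tx]], parts[[tx]])
  })
  names(lociPerGenome) <- taxa
  ssr <- stage("ssr-summary", summarizeSSRs(lociPerGenome))

  say("concatenation statistics and NJ tree (%d bootstrap replicates)",
      bootstrapReps)
  concat <- stage("concat", concatenateAlignments(alns))
  concatSummary <- stage("concat-summary", alignmentSummary(concat))
  boot <- stage("tree", bootstrapNJ(concat, nReps = bootstrapReps,
                                    seed = seed))

  out <- list(table1 = table1, junctions = junctions, regions = regions,
              alignments = alns, coding = codingTab,
              noncoding = noncodingTab, hotspots = hotspots,
              ssr_loci = lociPerGenome, ssr = ssr, concat = concat,
              concat_summary = concatSummary, tree = boot$tree,
              bootstrap = boot, sim = sim, log = log)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(table1, file.path(outDir, "table1.tsv"))
    writeTsv(junctions, file.path(outDir, "junctions.tsv"))
    writeTsv(codingTab, file.path(outDir, "table2.tsv"))
    writeTsv(noncodingTab, file.path(outDir, "table3.tsv"))
    writeTsv(hotspots, file.path(outDir, "hotspots.tsv"))
    writeTsv(ssr$table, file.path(outDir, "table4.tsv"))
    writeTsv(concatSummary, file.path(outDir, "concat_summary.tsv"))
    writeNewickTree(boot$tree, file.path(outDir, "tree.nwk"))
    writePhylipAlignment(concat, file.path(outDir, "concat.phy"))
    log <- c(sprintf("plastomeCompare %s | R %s",
                     as.character(utils::packageVersion("plastomeCompare")),
                     paste(R.version$major, R.version$minor, sep = ".")),
             sprintf("thresholds: region>%d bp, hotspot>%s%%, bootstrap %d, seed %d",
                     minAlignedLength, format(hotspotThreshold),
                     bootstrapReps, seed), log)
    writeLines(log, file.path(outDir, "run.log"))
    return(invisible(out))
  }
  out
}
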