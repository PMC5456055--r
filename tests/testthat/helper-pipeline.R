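# one full pipeline run on the default simulated dataset, shared across
# test files (it is the expensive fixture: simulate + align + tree)
.sharedRun <- new.env(parent = emptyenv())

getSharedPipelineRun <- function() {
  if (is.null(.sharedRun$out)) {
    .sharedRun$cfg <- simConfig()
    .sharedRun$dir <- file.path(tempdir(), "sharedPipelineRun")
    .sharedRun$out <- suppressMessages(
      runPipeline(config = .sharedRun$cfg, outDir = .sharedRun$dir,
                  bootstrapReps = 50, seed = 7))
  }
  list(cfg = .sharedRun$cfg, out = .sharedRun$out, dir = .sharedRun$dir)
}
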