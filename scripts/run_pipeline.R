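#!/usr/bin/env Rscript

## Thin command-line wrapper over netpharm::runPipeline().
## Usage: Rscript scripts/run_pipeline.R <config.yaml> [--validate-only]

suppressPackageStartupMessages(library(netpharm))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  cat("usage: Rscript scripts/run_pipeline.R <config.yaml>",
      "[--validate-only]\n")
  quit(status = 1)
}
cfg <- args[1]
problems <- validateConfig(cfg)
if (length(problems)) {
  cat("config problems:\n", paste(" -", problems, collapse = "\n"), "\n")
  quit(status = 1)
}
if ("--validate-only" %in% args) {
  cat("config OK\n")
  quit(status = 0)
}
invisible(runPipeline(cfg))
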