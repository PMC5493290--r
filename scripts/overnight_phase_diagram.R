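#!/usr/bin/env Rscript
# Full-scale activity/shape-factor phase diagrams with open and fixed
# boundaries (N = 1000 cells, 100k-250k steps per state point).  This is an
# overnight computation; the desk-scale counterpart of the comparison lives
# in the test suite.  Usage:
#   Rscript scripts/overnight_phase_diagram.R --out results/phase --seed 1

suppressPackageStartupMessages(library(avm))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
outDir <- getArg("--out", "results/phase")
seed <- as.integer(getArg("--seed", "1"))
dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

p0Grid <- seq(3.0, 4.2, by = 0.1)
faGrid <- c(0.01, 0.02, 0.03, 0.05, 0.1, 0.2, 0.3)

for (mode in c("fixed", "free")) {
  res <- sweepPhase(p0Grid, faGrid, seeds = seed, N = 1000, Gamma = 1,
                    Dr = taurInverse(0.01), nSteps = 100000, dt = 0.025,
                    snapshotEvery = 500,
                    bnd = BoundaryParams(mode = mode, lambda = 0, l0 = 1))
  write.table(res, file.path(outDir, paste0("phase_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("done; tables in", outDir, "\n")
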