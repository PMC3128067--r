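#!/usr/bin/env Rscript
# Regenerates the packaged seed catalogues under inst/extdata/seeds/.
# Deterministic: every design call derives its RNG seed from the cell's
# (regime, type, k, weight). Run from the repository root after installing
# the package. This takes a while (hill climbing over ~170 cells).

suppressPackageStartupMessages(library(oligoSeeds))

weights <- 7:20
regimes <- list(`50mer` = AlignmentModel(50, 0.85),
                `70mer` = AlignmentModel(70, 0.85))
# hill-climbing restarts: the designer's default (20) everywhere except the
# 16-seed cells, whose larger sets are individually less restart-sensitive
# and dominate build time
restartsFor <- function(k) if (k >= 16) 6L else 20L

cellSeed <- function(regimeIdx, typeIdx, k, w)
  ((regimeIdx * 1000L + typeIdx) * 100L + k) * 100L + w

for (ri in seq_along(regimes)) {
  regime <- names(regimes)[ri]
  model <- regimes[[ri]]
  dir <- file.path("inst", "extdata", "seeds", regime)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in weights) {
    writeSeedFile(contiguousSeed(w),
                  file.path(dir, sprintf("contiguous_w%d_k1.txt", w)),
                  header = sprintf("contiguous seed, weight %d", w))
    # single spaced seed
    set <- designSeedSet(1, w, span = min(w + 7L, 22L), model = model,
                         restarts = 20L, rngSeed = cellSeed(ri, 2L, 1L, w))
    writeSeedFile(set, file.path(dir, sprintf("1seed_w%d_k1.txt", w)),
                  header = sprintf("spaced seed, weight %d, %s", w, regime))
    # transition-constrained seed (two @ positions, like the YASS seed)
    set <- designSeedSet(1, w, span = min(w + 6L, 22L), model = model,
                         nTransition = 2L, restarts = 20L,
                         rngSeed = cellSeed(ri, 3L, 1L, w))
    writeSeedFile(set, file.path(dir, sprintf("transition_w%d_k1.txt", w)),
                  header = sprintf("transition seed, weight %d, %s", w, regime))
    for (k in c(2L, 4L, 8L, 16L)) {
      set <- designSeedSet(k, w, span = min(w + 7L, 22L), model = model,
                           restarts = restartsFor(k),
                           rngSeed = cellSeed(ri, 4L, k, w))
      writeSeedFile(set, file.path(dir, sprintf("%dseed_w%d_k%d.txt", k, w, k)),
                    header = sprintf("%d spaced seeds, weight %d, %s",
                                     k, w, regime))
      message(sprintf("%s w=%d k=%d done", regime, w, k))
    }
    message(sprintf("%s w=%d singles done", regime, w))
  }
}
message("catalogues written")
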