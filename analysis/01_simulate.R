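#!/usr/bin/env Rscript
# Step 1: simulate the two study designs with known ground truth.
#
# aging4:     Young/Middle/Old/HGPS fibroblast groups (15/25/16/26 samples)
#             over 7 pseudo-datasets, with 13 pathways planted equivalent in
#             {Middle, Old, HGPS}, 12 more in {Middle, HGPS}, 5 null
#             pathways and 35 distinct per-group profiles.
# senescence: one culture series at 30/50/70/80 passages (3/4/3/2 samples)
#             with planted monotone, non-monotonic and flat passage trends.

suppressPackageStartupMessages(library(pasdrift))
seed <- as.integer(Sys.getenv("PASDRIFT_SEED", "42"))

for (preset in c("aging4", "senescence")) {
  st <- make_paper_like_study(preset, seed = seed)
  dir <- file.path("results", "data", preset)
  write_study(st, dir)
  cat(sprintf("[01] %s (seed %d): %d datasets, %d samples, %d pathways -> %s\n",
              preset, seed, length(st$matrices), nrow(st$annotation),
              length(st$collection$pathways), dir))
  print(table(st$annotation$group))
}
cat("[01] done\n")
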