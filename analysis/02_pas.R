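#!/usr/bin/env Rscript
# Step 2: score every sample with Pathway Activation Strength (PAS).
#
# Each dataset is scored against its own reference group (Young samples in
# the donor-age datasets, healthy controls in the progeria datasets, the
# 30-passage group in the senescence series). Case groups use filtered mode
# (|FC| >= 1.5, BH-FDR < 0.05); reference groups are scored unfiltered,
# since against their own mean every gene fails the filter and PAS would be
# identically zero.

suppressPackageStartupMessages(library(pasdrift))

for (preset in c("aging4", "senescence")) {
  study <- load_study(file.path("results", "data", preset))
  pas <- suppressWarnings(compute_pas_matrix(
    study$matrices, study$groups, study$collection, study$reference_groups,
    mode = "filtered", score_groups = study$score_groups))
  out <- file.path("results", paste0("pas_", preset, ".tsv"))
  write_pas_matrix(pas, out)
  cat(sprintf("[02] %s: PAS for %d pathways x %d samples -> %s\n",
              preset, nrow(pas$values), ncol(pas$values), out))
  grand <- tapply(colMeans(pas$values), pas$sample_info$group, mean)
  cat("[02] grand mean PAS per group:\n")
  print(round(grand, 2))
}
cat("[02] done\n")
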