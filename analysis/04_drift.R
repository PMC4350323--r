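#!/usr/bin/env Rscript
# Step 4: drift summaries.
#
# aging4:     Pearson correlation of PAS profiles with hierarchical
#             clustering (distance 1 - r, complete linkage) and a 3-component
#             PCA embedding; the progeria group is expected to sit close to
#             Middle/Old and away from Young.
# senescence: passage-ordered trend classification of every pathway.

suppressPackageStartupMessages(library(pasdrift))

pas <- read_pas_matrix(file.path("results", "pas_aging4.tsv"))

cm <- correlation_cluster(pas)
utils::write.table(
  data.frame(sample_id = rownames(cm$cor), cm$cor, check.names = FALSE),
  file.path("results", "correlation_aging4.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(cm$order, file.path("results", "correlation_leaf_order.txt"))
cat(sprintf("[04] mean between-group r: (HGPS,Old) %.3f vs (HGPS,Young) %.3f\n",
            mean_between_group_cor(cm, "HGPS", "Old"),
            mean_between_group_cor(cm, "HGPS", "Young")))

emb <- pca_embed(pas)
utils::write.table(
  data.frame(emb$sample_info, emb$scores, check.names = FALSE),
  file.path("results", "pca_aging4.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("[04] PC1-3 explain %.1f%% of variance\n",
            100 * sum(emb$explained[1:3])))
cat(sprintf("[04] centroid distance: d(Old,HGPS) %.1f vs d(Young,HGPS) %.1f\n",
            centroid_distance(emb, "Old", "HGPS"),
            centroid_distance(emb, "Young", "HGPS")))

sen <- read_pas_matrix(file.path("results", "pas_senescence.tsv"))
dp <- passage_drift(sen, c("P30", "P50", "P70", "P80"))
utils::write.table(dp, file.path("results", "drift_senescence.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("[04] senescence trend labels:\n")
print(table(dp$trend))
cat("[04] done; tables under results/\n")
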