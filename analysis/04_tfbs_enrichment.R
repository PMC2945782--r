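#!/usr/bin/env Rscript
# Stage 4: motif over-representation in the recovered cluster 1.
#
# For every PWM and conservation mode, the score threshold is optimized
# to maximize the fold enrichment of cluster-1 promoters over all other
# promoters, subject to the Bonferroni-corrected hypergeometric p being
# below 0.01; motifs with best-mode fold below 1.8 are discarded. The
# planted motif should be reported; its column-shuffled decoys should
# not.

suppressMessages(library(adipomotif))

scores <- as_promoter_scores(
  data.table::fread("scratch/analysis/scan/scores.tsv",
                    data.table = FALSE)
)
clusters <- read.delim("scratch/analysis/clusters/clusters.tsv")
universe_ids <- dimnames(scores$score)[[1]]
cl1 <- intersect(
  clusters$gene_id[!is.na(clusters$cluster) & clusters$cluster == 1L],
  universe_ids
)
message(length(cl1), " cluster-1 genes inside the promoter universe")

enrichment <- enrich_clusters(scores, cl1, alpha = 0.01, min_fold = 1.8)
write.table(enrichment, "results/04_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(enrichment)) {
  message("motifs enriched in cluster 1 (Bonferroni p < 0.01, fold >= 1.8):")
  print(enrichment[, c("motif_id", "conservation", "threshold", "k", "n",
                       "fold", "p_raw", "p_bonferroni")], row.names = FALSE)
} else {
  message("no motif passed the enrichment criteria")
}
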