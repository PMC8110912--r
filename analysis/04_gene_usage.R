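#!/usr/bin/env Rscript
# TRBV usage frequencies across the inflamed samples, PCA of V-gene usage,
# and the per-gene early-vs-late node comparison with Sidak correction.

library(clonotrace)

manifest <- read_manifest("results/cohort/manifest.tsv")
inflamed <- manifest[manifest$condition == "inflamed", ]
reps <- lapply(seq_len(nrow(inflamed)), function(i)
  read_airr(inflamed$path[i], sample_id = inflamed$sample_id[i],
            subject_id = inflamed$subject_id[i], tissue = inflamed$tissue[i],
            phase = inflamed$phase[i], condition = inflamed$condition[i]))
names(reps) <- inflamed$sample_id

um <- usage_matrix(reps, segment = "V", weighting = "reads")
write.table(cbind(sample_id = rownames(um), as.data.frame(unclass(um))),
            "results/v_usage.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

pca <- usage_pca(um, n_components = 2)
labels <- paste(inflamed$tissue, inflamed$phase, sep = ".")[
  match(rownames(um), inflamed$sample_id)]
scores <- data.frame(sample_id = rownames(um), group = labels, pca$scores)
write.table(scores, "results/v_usage_pca_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sil <- group_silhouette(pca$scores[, 1],
                        ifelse(labels == "pLN.late", "late_node", "rest"),
                        group = "late_node")
message(sprintf("PC1 explains %.0f%% of V-usage variance; late-node silhouette on PC1 = %.2f",
                100 * pca$explained_variance_fraction[1], sil))

cmp <- compare_gene_usage(um[labels == "pLN.early", ],
                          um[labels == "pLN.late", ])
write.table(cmp, "results/v_usage_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("genes enriched in late nodes after Sidak correction: %s",
                paste(cmp$gene[cmp$significant & cmp$mean_b > cmp$mean_a],
                      collapse = ", ")))
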