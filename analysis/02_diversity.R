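#!/usr/bin/env Rscript
# Per-sample clonality, D50 and clonal-space homeostasis on the simulated
# cohort, with the early-vs-late and inflamed-vs-control group comparisons.

library(clonotrace)

manifest <- read_manifest("results/cohort/manifest.tsv")
reps <- lapply(seq_len(nrow(manifest)), function(i)
  read_airr(manifest$path[i], sample_id = manifest$sample_id[i],
            subject_id = manifest$subject_id[i], tissue = manifest$tissue[i],
            phase = manifest$phase[i], condition = manifest$condition[i]))
names(reps) <- manifest$sample_id

div <- diversity_table(reps)
write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

by_group <- function(tissue, phase, what)
  div[[what]][div$tissue == tissue & div$phase == phase &
                div$condition == "inflamed"]

for (what in c("clonality", "d50")) {
  cmp <- welch_t(by_group("pLN", "early", what), by_group("pLN", "late", what))
  message(sprintf("node %s early %.1f vs late %.1f (Welch p = %.3g)", what,
                  mean(by_group("pLN", "early", what)),
                  mean(by_group("pLN", "late", what)), cmp$p_value))
}
cmp_j <- welch_t(by_group("joint", "early", "d50"),
                 by_group("joint", "late", "d50"))
message(sprintf("joint D50 early %.2f vs late %.2f (Welch p = %.3g) - stable",
                mean(by_group("joint", "early", "d50")),
                mean(by_group("joint", "late", "d50")), cmp_j$p_value))
message(sprintf("joint top-10 read share: early %.1f%%, late %.1f%%",
                100 * mean(by_group("joint", "early", "top10")),
                100 * mean(by_group("joint", "late", "top10"))))

# clones above the control node's median read count, the antigen-driven
# expansion readout
ctrl_pln <- reps[manifest$sample_id[manifest$tissue == "pLN" &
                                      manifest$condition == "control"]]
threshold <- min(sapply(ctrl_pln, median_clone_frequency))
counts <- sapply(reps, count_clones_at_least, min_reads = max(2, threshold))
write.table(data.frame(sample_id = names(counts), n_expanded_clones = counts),
            "results/expanded_clone_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("clone counts at reads >= %d written for %d samples",
                max(2, threshold), length(counts)))
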