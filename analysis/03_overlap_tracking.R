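#!/usr/bin/env Rscript
# Node/joint CDR3 amino-acid overlap per phase, the same-animal paired
# diagonal, and the cross-site rank tracking of each joint's top 10 clones.

library(clonotrace)

manifest <- read_manifest("results/cohort/manifest.tsv")
reps <- lapply(seq_len(nrow(manifest)), function(i)
  read_airr(manifest$path[i], sample_id = manifest$sample_id[i],
            subject_id = manifest$subject_id[i], tissue = manifest$tissue[i],
            phase = manifest$phase[i], condition = manifest$condition[i]))
names(reps) <- manifest$sample_id

inflamed <- manifest[manifest$condition == "inflamed", ]
for (ph in c("early", "late")) {
  sub <- inflamed[inflamed$phase == ph, ]
  m <- overlap_matrix(reps[sub$sample_id[sub$tissue == "pLN"]],
                      reps[sub$sample_id[sub$tissue == "joint"]])
  write.table(overlap_long(m), sprintf("results/overlap_%s.tsv", ph),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pairing <- setNames(paste0(unique(sub$subject_id), "_joint"),
                      paste0(unique(sub$subject_id), "_pLN"))
  diag <- paired_diagonal(m, pairing)
  write.table(diag, sprintf("results/overlap_diagonal_%s.tsv", ph),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s phase: mean paired overlap index %.3g", ph,
                  mean(diag$value)))
}

rows <- lapply(unique(inflamed$subject_id), function(subj) {
  cs <- cross_site_ranks(reps[[paste0(subj, "_joint")]],
                         reps[[paste0(subj, "_pLN")]], n = 10)
  data.frame(subject_id = subj,
             phase = inflamed$phase[inflamed$subject_id == subj][1],
             rho = cs$rho, p_value = cs$p_value, n_absent = cs$n_absent)
})
tracking <- do.call(rbind, rows)
write.table(tracking, "results/tracking.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("joint top-10 vs node rank: early mean rho %.2f (%.1f absent), late mean rho %.2f (%.1f absent)",
                mean(tracking$rho[tracking$phase == "early"]),
                mean(tracking$n_absent[tracking$phase == "early"]),
                mean(tracking$rho[tracking$phase == "late"]),
                mean(tracking$n_absent[tracking$phase == "late"])))
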