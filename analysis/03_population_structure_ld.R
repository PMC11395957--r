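#!/usr/bin/env Rscript
# Population structure and linkage disequilibrium: VanRaden GRM, principal
# components (full-sib families appear as clusters), binned LD-decay curve
# and the distance at which mean r^2 falls to 0.05.

library(sturgeonGP)

gm <- read_dosage_table("results/qc/genotypes_qc.tsv")
grm <- build_grm(gm)
print(grm)

dir.create("results/structure", showWarnings = FALSE, recursive = TRUE)
pcs <- compute_pcs(grm, k = 10)
cat("variance explained by PC1-3:",
    paste(sprintf("%.1f%%", 100 * pcs$var_explained[1:3]), collapse = ", "), "\n")
write.table(data.frame(sample_id = grm$sample_ids, pcs$vectors),
            "results/structure/pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_grm(grm, "results/structure/grm.txt.gz")

curve <- ld_decay(gm, max_dist = 1e5, bin_width = 2000)
write.table(curve, "results/structure/ld_decay.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mean adjacent-pair r^2:", round(mean_adjacent_r2(gm), 3), "\n")
cat("LD decays to r^2 = 0.05 at ~",
    find_decay_distance(curve, 0.05) / 1000, "kb\n")
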