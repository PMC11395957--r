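#!/usr/bin/env Rscript
# Marker quality control: drop SNPs with MAF < 0.05, then SNPs failing the
# exact Hardy-Weinberg test at p < 1e-7. Writes the per-marker QC table and
# the filtered genotypes used by all later scripts.

library(sturgeonGP)

gm <- read_vcf("results/fixture/genotypes.vcf")
qc <- apply_qc(gm, maf_min = 0.05, hwe_alpha = 1e-7)
print(qc$report)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write.table(qc$report$per_marker, "results/qc/qc_markers.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_genotypes(qc$genotypes, "results/qc/genotypes_qc.tsv", "dosage_table")
cat("retained", qc$report$n_retained, "of", qc$report$n_input_markers,
    "markers\n")
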