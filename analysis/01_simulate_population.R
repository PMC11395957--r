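#!/usr/bin/env Rscript
# Build the synthetic study population: 673 fish in 26 full-sib families,
# 5,000 biallelic SNPs with distance-decaying LD (r^2 = 0.05 at 20 kb), and
# three traits -- caviar yield (h2 0.50), ordinal 1-4 caviar colour
# (h2 0.61, mean ~2.45) and body weight (h2 0.63). The real study's
# genotypes are not public, so this population stands in for them in every
# downstream script.

library(sturgeonGP)

out <- "results/fixture"
paths <- make_fixture("sturgeon", out, seed = 20240901)

gm <- read_vcf(paths$vcf)
ph <- read_phenotypes(paths$phenotypes)
cat("samples:", nrow(gm$dosages), " markers:", ncol(gm$dosages), "\n")
cat("traits:", paste(setdiff(names(ph), "sample_id"), collapse = ", "), "\n")
cat("caviar colour score mean:", round(mean(ph$caviar_color), 3),
    "(target ~2.45)\n")
cat("files under", out, ":", paste(basename(unlist(paths)), collapse = ", "), "\n")
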