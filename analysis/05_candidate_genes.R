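#!/usr/bin/env Rscript
# Candidate-gene mapping: merge significant and suggestive SNPs into
# regions, extend by 20 kb on both sides, and report genes overlapping each
# window from the (toy) GFF3 annotation.

library(sturgeonGP)

genes <- load_gff("results/fixture/genes.gff3")
cat("annotation:", nrow(genes), "genes\n")
dir.create("results/genes", showWarnings = FALSE, recursive = TRUE)

for (f in list.files("results/gwas", pattern = "^gwas_.*\\.tsv$",
                     full.names = TRUE)) {
  trait <- sub("^gwas_(.*)\\.tsv$", "\\1", basename(f))
  gw <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  hits <- gw[gw$class != "none", ]
  reg <- build_regions(hits, flank = 20000)
  reg <- map_candidate_genes(reg, genes)
  write.table(as.data.frame(reg),
              sprintf("results/genes/candidate_regions_%s.tsv", trait),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-14s %d hit(s) -> %d region(s); genes: %s\n", trait,
              nrow(hits), nrow(reg),
              if (nrow(reg) == 0) "-" else
                paste(unique(unlist(strsplit(reg$genes[reg$genes != ""], ","))),
                      collapse = ", ")))
}
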