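test_that("VCF genotypes decode to alt-allele dosages", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=10000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "A", "B", "C"), collapse = "\t"),
           paste(c("chr1", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
                   "0/0", "0/1", "1/1"), collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f)
  expect_equal(unname(gm$dosages[, 1]), c(0, 1, 2))
  expect_equal(gm$map$pos, 100L)
  expect_equal(rownames(gm$dosages), c("A", "B", "C"))
})

test_that("non-biallelic-SNP records are skipped and counted", {
  rows <- c("chr1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
            "chr1\t200\ts2\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t1/2",  # triallelic
            "chr1\t300\ts3\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/0",
            "chr1\t400\ts4\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",   # indel
            "chr1\t500\ts5\tG\tA\t.\tPASS\t.\tGT\t0/1\t./.")
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "A", "B"), collapse = "\t"), rows)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f)
  expect_equal(ncol(gm$dosages), 3)
  expect_equal(attr(gm, "n_skipped"), 2)
  # ./. becomes a masked cell
  expect_true(gm$missing[2, "s5"])
})

test_that("write/read round trips are exact for both formats", {
  gm <- rand_gm(12, 8, seed = 42)
  for (fmt in c("vcf", "dosage_table")) {
    f <- withr::local_tempfile(fileext = if (fmt == "vcf") ".vcf" else ".tsv")
    write_genotypes(gm, f, fmt)
    back <- if (fmt == "vcf") read_vcf(f) else read_dosage_table(f)
    expect_identical(unname(back$dosages), unname(gm$dosages) * 1.0, label = fmt)
    expect_equal(back$map$pos, gm$map$pos)
    expect_equal(back$map$id, gm$map$id)
  }
  # VCF header declares the contigs present
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(gm, f, "vcf")
  expect_true(any(grepl("##contig=<ID=chr1", readLines(f))))
})

test_that("dosage table rejects out-of-domain entries and honours missing code", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tm1\tm2", "s1\t0\t2", "s2\t3\t1"), f)
  writeLines(c("id\tchrom\tpos\tref\talt", "m1\tchr1\t10\tA\tG",
               "m2\tchr1\t20\tA\tG"), paste0(f, ".map"))
  expect_error(read_dosage_table(f), "s2.*m1|m1.*s2")
  writeLines(c("sample_id\tm1\tm2", "s1\t0\t2", "s2\tNA\t1"), f)
  gm <- read_dosage_table(f)
  expect_true(gm$missing[2, 1])
  expect_false(gm$missing[1, 1])
})

test_that("MAF filter removes strictly below threshold, keeps equality", {
  # 10 samples, one heterozygote: MAF exactly 0.05 -> retained
  dos <- matrix(0, 10, 2)
  dos[1, 1] <- 1               # marker 1: MAF 0.05
  dos[, 2] <- rep(c(0, 1, 2), length.out = 10)  # polymorphic control
  gm <- toy_gm(dos)
  qc <- apply_qc(gm, maf_min = 0.05)
  expect_true("M001" %in% qc$genotypes$map$id)
  # monomorphic marker (MAF 0) is removed
  dos2 <- cbind(dos, 0)
  qc2 <- apply_qc(toy_gm(dos2), maf_min = 0.05)
  expect_equal(qc2$report$n_removed_maf, 1)
  expect_false("M003" %in% qc2$genotypes$map$id)
})

test_that("QC report categories are disjoint and tally", {
  gm <- rand_gm(60, 40, seed = 5, p = runif(40, 0.01, 0.99))
  qc <- apply_qc(gm, maf_min = 0.1, hwe_alpha = 0.05)
  r <- qc$report
  expect_equal(r$n_input_markers, r$n_removed_maf + r$n_removed_hwe + r$n_retained)
  expect_equal(sum(r$per_marker$status == "retained"), r$n_retained)
  # order-independence: permuting marker columns permutes, not changes, the set
  perm <- sample(ncol(gm$dosages))
  gmp <- genotype_matrix(gm$dosages[, perm], gm$map[perm, ])
  qcp <- apply_qc(gmp, maf_min = 0.1, hwe_alpha = 0.05)
  expect_setequal(qcp$genotypes$map$id, qc$genotypes$map$id)
})

test_that("HWE exact test matches brute-force enumeration for n <= 50", {
  # oracle: probability of each het count from the closed-form expression
  hwe_oracle <- function(n_het, n_rare_hom, n_common_hom) {
    n <- n_het + n_rare_hom + n_common_hom
    nr <- 2 * n_rare_hom + n_het
    if (nr > n) nr <- 2 * n - nr
    if (nr == 0) return(1)
    hets <- seq(nr %% 2, nr, by = 2)
    logp <- vapply(hets, function(h) {
      lchoose(n, (nr - h) / 2) + lchoose(n - (nr - h) / 2, h) +
        h * log(2) - lchoose(2 * n, nr)
    }, numeric(1))
    p <- exp(logp - max(logp)); p <- p / sum(p)
    obs <- p[match(n_het, hets)]
    sum(p[p <= obs * (1 + 1e-12)])
  }
  # perfect HWE proportions give p = 1 (modal het count)
  expect_equal(hwe_exact_p(50, 25, 25), 1)
  expect_equal(hwe_oracle(50, 25, 25), 1)
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
    expect_equal(hwe_exact_p(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-10)
  }
})

test_that("phenotype table io and alignment work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ph <- data.frame(sample_id = c("S001", "S002", "S003"),
                   bw = c(10.5, 12.1, 9.8))
  write_phenotypes(ph, f)
  back <- read_phenotypes(f)
  expect_equal(back$bw, ph$bw)
  gm <- rand_gm(3, 4, seed = 2)
  y <- align_phenotype(gm, back, "bw")
  expect_named(y, rownames(gm$dosages))
})
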