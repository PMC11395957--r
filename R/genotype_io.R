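#' Construct a genotype matrix object
#'
#' The central container of the package: an `n_samples x n_markers` matrix of
#' alt-allele dosages (0, 1, 2) together with the marker map (chromosome,
#' 1-based position, ref/alt alleles). Missing genotypes are tracked in an
#' optional logical mask; cells under the mask may hold imputed (possibly
#' non-integer) dosages.
#'
#' @param dosages numeric matrix, samples in rows, markers in columns. Row
#'   names are sample ids, column names marker ids.
#' @param map data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   one row per marker, in column order of `dosages`.
#' @param missing optional logical matrix, same shape as `dosages`, `TRUE`
#'   where the original genotype was missing.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosages, map, missing = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 1L || ncol(dosages) < 1L)
    stop("genotype matrix must have at least one sample and one marker")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample ids")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map)))
    stop("marker map must have columns ", paste(need, collapse = ", "))
  if (nrow(map) != ncol(dosages))
    stop("marker map rows (", nrow(map), ") != dosage columns (", ncol(dosages), ")")
  if (anyDuplicated(map$id)) stop("duplicate marker ids")
  if (any(map$pos < 1)) stop("marker positions must be >= 1 (1-based)")
  if (any(map$ref == map$alt)) stop("ref and alt allele identical for some marker")
  colnames(dosages) <- map$id
  obs <- dosages
  if (!is.null(missing)) {
    missing <- as.matrix(missing)
    stopifnot(identical(dim(missing), dim(dosages)))
    dimnames(missing) <- dimnames(dosages)
    obs <- dosages[!missing]
  }
  bad <- !(obs %in% c(0, 1, 2)) & !is.na(obs)
  if (any(bad))
    stop("non-missing dosages must be in {0,1,2}; first offender value: ",
         obs[bad][1])
  structure(list(dosages = dosages, map = map, missing = missing),
            class = "GenotypeMatrix")
}

#' @exportS3Method base::print
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  if (!is.null(x$missing))
    cat(sprintf("  missing genotypes: %.3f%%\n", 100 * mean(x$missing)))
  invisible(x)
}

#' @exportS3Method
dim.GenotypeMatrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by sample and/or marker ids
#'
#' @param gm a `GenotypeMatrix`.
#' @param samples optional character vector of sample ids to keep.
#' @param markers optional character vector of marker ids to keep.
#' @return A `GenotypeMatrix` restricted to the requested ids (order follows
#'   the request).
#' @export
subset_genotypes <- function(gm, samples = NULL, markers = NULL) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  si <- if (is.null(samples)) seq_len(nrow(gm$dosages)) else {
    i <- match(samples, rownames(gm$dosages))
    if (anyNA(i)) stop("unknown sample id(s): ", paste(samples[is.na(i)], collapse = ", "))
    i
  }
  mi <- if (is.null(markers)) seq_len(ncol(gm$dosages)) else {
    i <- match(markers, gm$map$id)
    if (anyNA(i)) stop("unknown marker id(s): ", paste(markers[is.na(i)][1:min(3, sum(is.na(i)))], collapse = ", "))
    i
  }
  genotype_matrix(gm$dosages[si, mi, drop = FALSE], gm$map[mi, , drop = FALSE],
                 if (!is.null(gm$missing)) gm$missing[si, mi, drop = FALSE])
}

#' Read genotypes from a VCF file
#'
#' Consumes the GT field of a VCF 4.x file via \pkg{vcfR}. Only biallelic
#' SNP records (single-base REF and ALT) are accepted; other records are
#' skipped and counted. Dosage is the count of alt alleles in the genotype.
#'
#' @param path path to a plain-text VCF.
#' @return A `GenotypeMatrix`; the number of skipped records is attached as
#'   attribute `n_skipped`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("VCF contains no records: ", path)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[is_snp, ]
  fix <- fix[is_snp, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (anyDuplicated(colnames(gt))) stop("duplicate sample ids in VCF")
  # count "1" alleles; "." anywhere marks the genotype missing
  alt_count <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(v) {
      if (any(v == "." | is.na(v))) NA_real_ else sum(v == "1")
    }, numeric(1))
  }
  dos <- apply(gt, 2, alt_count)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gt)))
  dos <- t(dos)  # samples x markers
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  map <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  miss <- is.na(dos)
  dos[miss] <- 0
  gm <- genotype_matrix(dos, map, missing = if (any(miss)) miss else NULL)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Read genotypes from a tab-separated dosage table
#'
#' Expects a table with sample ids in the first column (`sample_id`) and one
#' column per marker, plus a sidecar marker map (`<path>.map` by default)
#' with columns id, chrom, pos, ref, alt.
#'
#' @param path path to the dosage table.
#' @param map_path path to the marker map; default `paste0(path, ".map")`.
#' @param missing_code string coding missing dosages (default `"NA"`).
#' @return A `GenotypeMatrix`.
#' @export
read_dosage_table <- function(path, map_path = paste0(path, ".map"),
                              missing_code = "NA") {
  if (!file.exists(path)) stop("cannot read dosage table: ", path)
  if (!file.exists(map_path)) stop("cannot read marker map: ", map_path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0))
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  samples <- tab[[1]]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  miss <- raw == missing_code
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(!miss & (is.na(vals) | !(vals %in% c(0, 1, 2))), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid dosage '", raw[bad[1, 1], bad[1, 2]], "' at sample ",
         samples[bad[1, 1]], ", marker ", colnames(raw)[bad[1, 2]])
  vals[miss] <- 0
  dos <- matrix(vals, nrow = nrow(raw), dimnames = list(samples, colnames(raw)))
  map <- map[match(colnames(dos), map$id), , drop = FALSE]
  if (anyNA(map$id)) stop("marker map is missing entries for some table columns")
  genotype_matrix(dos, map, missing = if (any(miss)) miss else NULL)
}

#' Write genotypes to VCF or dosage-table format
#'
#' Both formats round-trip dosages and marker coordinates exactly. The VCF
#' writer requires integer dosages (imputed fractional dosages cannot be
#' represented as GT calls) and declares a contig header line for every
#' chromosome present.
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output path (dosage-table format writes `path` and
#'   `paste0(path, ".map")`).
#' @param format `"vcf"` or `"dosage_table"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "dosage_table")) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  format <- match.arg(format)
  if (ncol(gm$dosages) == 0L) stop("refusing to write an empty genotype matrix")
  if (format == "vcf") {
    dos <- gm$dosages
    if (any(!(dos %in% c(0, 1, 2)))) stop("VCF output requires integer dosages in {0,1,2}")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##fileformat=VCFv4.2", con)
    for (ch in unique(gm$map$chrom)) {
      len <- max(gm$map$pos[gm$map$chrom == ch])
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, as.integer(len)), con)
    }
    writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t"), con)
    gt_code <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(dos))) {
      g <- gt_code[dos[, j] + 1L]
      if (!is.null(gm$missing)) g[gm$missing[, j]] <- "./."
      writeLines(paste(c(gm$map$chrom[j], gm$map$pos[j], gm$map$id[j],
                         gm$map$ref[j], gm$map$alt[j], ".", "PASS", ".", "GT", g),
                       collapse = "\t"), con)
    }
  } else {
    out <- as.data.frame(gm$dosages, check.names = FALSE)
    if (!is.null(gm$missing)) out[gm$missing] <- NA
    out <- cbind(sample_id = rownames(gm$dosages), out)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gm$map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Per-marker alt-allele frequency and minor allele frequency
#'
#' Missing genotypes are mean-imputed per marker before frequencies are
#' taken, so the frequency equals the mean observed dosage / 2.
#'
#' @param gm a `GenotypeMatrix`.
#' @return data.frame with columns `id`, `freq_alt`, `maf`.
#' @export
marker_frequencies <- function(gm) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  dos <- gm$dosages
  if (!is.null(gm$missing)) dos[gm$missing] <- NA
  p <- colMeans(dos, na.rm = TRUE) / 2
  data.frame(id = gm$map$id, freq_alt = p, maf = pmin(p, 1 - p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional-on-allele-counts exact test: the p-value is the total
#' probability of all heterozygote counts whose conditional probability does
#' not exceed that of the observed count (the enumeration approach used by
#' common SNP QC software). Probabilities are computed by the stable ratio
#' recurrence across heterozygote counts.
#'
#' @param n_het observed heterozygote count.
#' @param n_hom_rare observed count of rare-allele homozygotes.
#' @param n_hom_common observed count of common-allele homozygotes.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom_rare, n_hom_common) {
  stopifnot(n_het >= 0, n_hom_rare >= 0, n_hom_common >= 0)
  n <- n_het + n_hom_rare + n_hom_common
  n_rare <- 2 * n_hom_rare + n_het
  if (n_rare > n) { # ensure "rare" really is the minor allele
    n_rare <- 2 * n - n_rare
  }
  if (n_rare == 0) return(1)
  # heterozygote count shares the parity of the rare allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(hets))
  # start from the midpoint and apply the two-sided recurrence
  mid_i <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n - 1)))
  probs[mid_i] <- 1
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1)) {
      h <- hets[i]
      hr <- (n_rare - h) / 2; hc <- (2 * n - n_rare - h) / 2
      probs[i + 1] <- probs[i] * 4 * hr * hc / ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1) {
    for (i in mid_i:2) {
      h <- hets[i]
      hr <- (n_rare - h) / 2; hc <- (2 * n - n_rare - h) / 2
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  obs_i <- match(n_het, hets)
  if (is.na(obs_i)) stop("heterozygote count has impossible parity for the allele counts")
  min(1, sum(probs[probs <= probs[obs_i] * (1 + 1e-12)]))
}

#' Chi-square test of Hardy-Weinberg equilibrium (1 df)
#' @inheritParams hwe_exact_p
#' @return p-value.
#' @export
hwe_chisq_p <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  p <- (2 * n_hom_rare + n_het) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_hom_rare, n_het, n_hom_common)
  if (any(e == 0)) return(1)
  stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

#' Marker quality control: MAF and Hardy-Weinberg filters
#'
#' Removes markers with minor allele frequency strictly below `maf_min`;
#' among the survivors, removes markers whose Hardy-Weinberg test p-value is
#' strictly below `hwe_alpha`. MAF is tested first so the two removal
#' categories in the report are disjoint. Missing genotypes are mean-imputed
#' per marker (non-integer dosages allowed thereafter); the HWE test uses
#' observed genotype counts only.
#'
#' @param gm a `GenotypeMatrix`.
#' @param maf_min minimum minor allele frequency retained (default 0.05;
#'   equality is kept).
#' @param hwe_alpha Hardy-Weinberg significance cutoff (default 1e-7).
#' @param hwe_method `"exact"` (default) or `"chisq"`.
#' @return list with elements `genotypes` (filtered `GenotypeMatrix`, missing
#'   cells imputed) and `report` (a `QCReport`).
#' @export
apply_qc <- function(gm, maf_min = 0.05, hwe_alpha = 1e-7,
                     hwe_method = c("exact", "chisq")) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  hwe_method <- match.arg(hwe_method)
  dos <- gm$dosages
  obs <- dos
  if (!is.null(gm$missing)) obs[gm$missing] <- NA
  p <- colMeans(obs, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_fun <- if (hwe_method == "exact") hwe_exact_p else hwe_chisq_p
  hwe_p <- vapply(seq_len(ncol(obs)), function(j) {
    x <- obs[, j]; x <- x[!is.na(x)]
    hwe_fun(sum(x == 1), sum(x == 2), sum(x == 0))
  }, numeric(1))
  fail_maf <- maf < maf_min
  fail_hwe <- !fail_maf & hwe_p < hwe_alpha
  keep <- !fail_maf & !fail_hwe
  if (!any(keep)) stop("quality control removed every marker")
  reason <- rep("retained", ncol(obs))
  reason[fail_maf] <- "maf"
  reason[fail_hwe] <- "hwe"
  report <- structure(list(
    n_input_markers = ncol(obs),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_retained = sum(keep),
    imputed_fraction = if (is.null(gm$missing)) 0 else mean(gm$missing),
    per_marker = data.frame(id = gm$map$id, maf = maf, hwe_p = hwe_p,
                            status = reason, row.names = NULL,
                            stringsAsFactors = FALSE)
  ), class = "QCReport")
  # mean-impute missing cells so downstream matrix algebra sees no NAs
  if (!is.null(gm$missing)) {
    mu <- colMeans(obs, na.rm = TRUE)
    idx <- which(gm$missing, arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  out <- structure(list(dosages = dos[, keep, drop = FALSE],
                        map = gm$map[keep, , drop = FALSE],
                        missing = if (!is.null(gm$missing)) gm$missing[, keep, drop = FALSE] else NULL),
                   class = "GenotypeMatrix")
  list(genotypes = out, report = report)
}

#' @exportS3Method base::print
print.QCReport <- function(x, ...) {
  cat("Marker QC:", x$n_input_markers, "in;",
      x$n_removed_maf, "removed (MAF);",
      x$n_removed_hwe, "removed (HWE);",
      x$n_retained, "retained\n")
  invisible(x)
}

#' Read a phenotype table
#'
#' TSV with a header; column 1 is the sample id, subsequent columns are
#' trait values.
#'
#' @param path path to the phenotype TSV.
#' @return data.frame; first column `sample_id`, one column per trait.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read phenotype table: ", path)
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(ph)[1] <- "sample_id"
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample ids in phenotype table")
  ph
}

#' Write a phenotype table
#' @param pheno data.frame with `sample_id` first.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a phenotype vector to the samples of a genotype matrix
#'
#' @param gm a `GenotypeMatrix`.
#' @param pheno phenotype data.frame from [read_phenotypes()].
#' @param trait trait column name.
#' @return named numeric vector in `gm` sample order (samples without a
#'   phenotype are dropped with a warning).
#' @export
align_phenotype <- function(gm, pheno, trait) {
  stopifnot(trait %in% names(pheno))
  i <- match(rownames(gm$dosages), pheno$sample_id)
  if (all(is.na(i))) stop("no phenotype sample id matches the genotype samples")
  if (anyNA(i)) warning(sum(is.na(i)), " genotyped sample(s) lack phenotypes and are dropped")
  y <- pheno[[trait]][i]
  names(y) <- rownames(gm$dosages)
  y[!is.na(y)]
}
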