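#' Load gene records from a GFF3 file
#'
#' Parses the annotation with \pkg{rtracklayer} and keeps `gene`-type
#' features only; coordinates stay 1-based inclusive.
#'
#' @param path path to a GFF3 file.
#' @return data.frame: `gene_id`, `name`, `chrom`, `start`, `end`,
#'   `strand`. A file with no gene features returns an empty frame with a
#'   warning.
#' @export
load_gff <- function(path) {
  if (!file.exists(path)) stop("cannot read GFF3: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) == "gene"
  if (!any(keep)) {
    warning("no gene-type features in ", path)
    return(data.frame(gene_id = character(), name = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  gr <- gr[keep]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  nm[is.na(nm)] <- as.character(gr$ID)[is.na(nm)]
  data.frame(gene_id = as.character(gr$ID), name = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Build candidate regions around significant/suggestive GWAS hits
#'
#' Hits on one chromosome lying within `merge_gap` of each other are merged
#' into a single region; the region spans the member SNP positions extended
#' by `flank` base pairs on both sides (floored at 1) and records the top
#' SNP (minimum p among members).
#'
#' @param hits a `GwasResult` (or data.frame with id, chrom, pos, p),
#'   typically the rows classified genomewide or suggestive.
#' @param flank window half-width in bp (default 20000).
#' @param merge_gap maximum distance between hits merged into one region
#'   (default `2 * flank`, so hits with touching windows share a region).
#' @return data.frame of class `CandidateRegionSet`: chrom, region_start,
#'   region_end, n_snps, snp_ids, top_snp, top_pos, top_p.
#' @export
build_regions <- function(hits, flank = 20000, merge_gap = 2 * flank) {
  cols <- c("id", "chrom", "pos", "p")
  stopifnot(all(cols %in% names(hits)))
  out <- list()
  if (nrow(hits) > 0) {
    for (ch in unique(hits$chrom)) {
      h <- hits[hits$chrom == ch, , drop = FALSE]
      h <- h[order(h$pos), , drop = FALSE]
      grp <- cumsum(c(1, diff(h$pos) > merge_gap))
      for (g in unique(grp)) {
        hg <- h[grp == g, , drop = FALSE]
        top <- which.min(hg$p)
        out[[length(out) + 1]] <- data.frame(
          chrom = ch,
          region_start = max(1, min(hg$pos) - flank),
          region_end = max(hg$pos) + flank,
          n_snps = nrow(hg),
          snp_ids = paste(hg$id, collapse = ","),
          top_snp = hg$id[top], top_pos = hg$pos[top], top_p = hg$p[top],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), region_start = numeric(),
               region_end = numeric(), n_snps = integer(),
               snp_ids = character(), top_snp = character(),
               top_pos = numeric(), top_p = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("CandidateRegionSet", "data.frame")
  res
}

#' Map candidate regions to overlapping genes
#'
#' A gene overlaps a region iff gene.start <= region.end and gene.end >=
#' region.start (1-based inclusive on both sides); strand is ignored.
#' Overlap is computed with \pkg{GenomicRanges}. Chromosomes present in the
#' regions but absent from the annotation are reported in a warning rather
#' than silently dropped.
#'
#' @param regions a `CandidateRegionSet` from [build_regions()].
#' @param genes gene table from [load_gff()].
#' @return `regions` with a `genes` column (comma-separated names sorted by
#'   gene start; empty string when none).
#' @export
map_candidate_genes <- function(regions, genes) {
  stopifnot(inherits(regions, "CandidateRegionSet"))
  regions$genes <- rep("", nrow(regions))
  if (nrow(regions) == 0 || nrow(genes) == 0) return(regions)
  missing_chr <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(missing_chr) > 0)
    warning("chromosome(s) absent from the annotation: ",
            paste(missing_chr, collapse = ", "))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$region_start, regions$region_end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  # findOverlaps warns about disjoint seqlevel sets; the explicit
  # missing-chromosome warning above already covers that case
  ov <- suppressWarnings(GenomicRanges::findOverlaps(rgr, ggr))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  for (i in unique(qh)) {
    gi <- sh[qh == i]
    gi <- gi[order(genes$start[gi])]
    regions$genes[i] <- paste(genes$name[gi], collapse = ",")
  }
  regions
}
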