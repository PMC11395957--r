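#' Build a VanRaden (method 1) genomic relationship matrix
#'
#' G = W W' / (2 * sum_j p_j (1 - p_j)), where W is the dosage matrix
#' centred by twice the in-sample alt-allele frequency. Markers that are
#' monomorphic in-sample contribute nothing and are excluded from the
#' scaling sum.
#'
#' @param gm a `GenotypeMatrix`.
#' @param marker_subset optional character vector of marker ids to use.
#' @return list of class `GRM`: `matrix` (n x n, dimnames = sample ids),
#'   `marker_ids` actually used, `scale_const` = 2 * sum p(1-p).
#' @export
build_grm <- function(gm, marker_subset = NULL) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  if (nrow(gm$dosages) < 2) stop("need at least 2 samples to build a GRM")
  dos <- gm$dosages
  if (!is.null(marker_subset)) {
    if (length(marker_subset) == 0) stop("empty marker subset")
    i <- match(marker_subset, gm$map$id)
    if (anyNA(i)) stop("marker subset contains unknown ids")
    dos <- dos[, i, drop = FALSE]
  }
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic: VanRaden scaling constant is zero")
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(dos, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  structure(list(matrix = G, marker_ids = colnames(dos), scale_const = denom,
                 sample_ids = rownames(dos)),
            class = "GRM")
}

#' @exportS3Method base::print
print.GRM <- function(x, ...) {
  cat("GRM:", nrow(x$matrix), "samples,", length(x$marker_ids),
      "markers, mean diagonal", round(mean(diag(x$matrix)), 3), "\n")
  invisible(x)
}

#' Partition markers into feature and background relationship matrices
#'
#' Builds the two-component covariance structure of genomic-feature BLUP:
#' `G_f` from the feature markers (e.g. FDR-significant GWAS hits) and
#' `G_r` from the background set with any feature markers removed first.
#' Each matrix is scaled by its own subset's 2*sum p(1-p), following the
#' genomic-feature BLUP convention.
#'
#' @param gm a `GenotypeMatrix`.
#' @param feature_ids marker ids of the genomic feature.
#' @param background_ids marker ids of the background set (defaults to all
#'   markers).
#' @return list with elements `feature` and `background`, each a `GRM`, or
#'   an error/fallback condition: an empty feature set raises a condition of
#'   class `empty_feature_set` so callers can fall back to plain GBLUP.
#' @export
partition_feature_grm <- function(gm, feature_ids, background_ids = gm$map$id) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  background_ids <- setdiff(background_ids, feature_ids)
  if (length(feature_ids) == 0)
    stop(structure(class = c("empty_feature_set", "error", "condition"),
                   list(message = "empty feature marker set", call = sys.call())))
  if (length(background_ids) == 0) stop("background marker set is empty after removing feature markers")
  list(feature = build_grm(gm, feature_ids),
       background = build_grm(gm, background_ids))
}

#' Principal components of a genomic relationship matrix
#'
#' Eigen-decomposition of G; used to inspect population structure.
#'
#' @param grm a `GRM`.
#' @param k number of components to return.
#' @return list: `values` (k eigenvalues, descending), `vectors` (n x k,
#'   orthonormal columns), `var_explained` (fraction of trace).
#' @export
compute_pcs <- function(grm, k = 10) {
  stopifnot(inherits(grm, "GRM"))
  n <- nrow(grm$matrix)
  if (k <= 0) stop("k must be positive")
  k <- min(k, n)
  eg <- eigen(grm$matrix, symmetric = TRUE)
  list(values = eg$values[seq_len(k)],
       vectors = eg$vectors[, seq_len(k), drop = FALSE],
       var_explained = eg$values[seq_len(k)] / sum(pmax(eg$values, 0)))
}

#' Export a GRM as gzipped lower-triangle text
#'
#' One row per sample pair (i >= j): `id_i TAB id_j TAB value`.
#'
#' @param grm a `GRM`.
#' @param path output path (".gz" appended if absent).
#' @return the path written, invisibly.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "GRM"))
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  ids <- grm$sample_ids
  n <- length(ids)
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(
    data.frame(id1 = ids[i], id2 = ids[j],
               value = sprintf("%.10g", grm$matrix[cbind(i, j)])),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#' @param path path to the gzipped lower-triangle file.
#' @return a `GRM` (scale constant and marker ids are not stored in this
#'   format and come back as `NA`/`NULL`).
#' @export
read_grm <- function(path) {
  tab <- utils::read.table(gzfile(path), sep = "\t", stringsAsFactors = FALSE)
  ids <- unique(tab[[1]])
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(match(tab[[1]], ids), match(tab[[2]], ids))] <- tab[[3]]
  G[upper.tri(G)] <- t(G)[upper.tri(G)]
  structure(list(matrix = G, marker_ids = NULL, scale_const = NA_real_,
                 sample_ids = ids), class = "GRM")
}

# subset a GRM to a sample index set (internal)
.grm_sub <- function(grm, idx) {
  structure(list(matrix = grm$matrix[idx, idx, drop = FALSE],
                 marker_ids = grm$marker_ids, scale_const = grm$scale_const,
                 sample_ids = grm$sample_ids[idx]), class = "GRM")
}
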