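#' Fit the polygenic null model of a mixed-linear-model GWAS
#'
#' Estimates the polygenic and residual variances once by REML under
#' y = 1 mu + g + e, g ~ N(0, G sigma_a^2), and caches the spectral
#' decomposition of G. All markers are subsequently scored with these
#' variance components held fixed (the standard MLMA strategy), which
#' controls relatedness and population stratification without re-estimating
#' components per marker.
#'
#' @param y phenotype vector, named by sample id when the GRM carries ids.
#' @param grm a `GRM` built over the phenotyped samples.
#' @param ... passed to [reml_fit()].
#' @return list of class `NullModel`: variance components, eigenvalues `d`,
#'   rotation `U`, rotated phenotype/intercept, weights `w` =
#'   1/(sigma_a^2 d + sigma_e^2).
#' @export
fit_null <- function(y, grm, ...) {
  stopifnot(inherits(grm, "GRM"))
  est <- reml_fit(y, grm, ...)
  if (!is.null(names(y)) && !is.null(grm$sample_ids)) y <- y[match(grm$sample_ids, names(y))]
  eg <- eigen(grm$matrix, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  s2a <- unname(est$components[1]); s2e <- unname(est$components[2])
  U <- eg$vectors
  structure(list(sigma2_a = s2a, sigma2_e = s2e, est = est,
                 U = U, d = d,
                 y_rot = as.vector(crossprod(U, y)),
                 one_rot = as.vector(crossprod(U, rep(1, length(y)))),
                 w = 1 / (s2a * d + s2e),
                 sample_ids = grm$sample_ids),
            class = "NullModel")
}

#' Score one SNP under the mixed-model null
#'
#' Generalized least squares of y on [1, x] under V = sigma_a^2 G +
#' sigma_e^2 I, computed through the cached rotation; the p-value is a Wald
#' test of b/se against the standard normal.
#'
#' @param null a `NullModel` from [fit_null()].
#' @param x dosage vector aligned to the null model's samples.
#' @return named numeric vector `c(b, se, p)`.
#' @export
score_snp <- function(null, x) {
  stopifnot(inherits(null, "NullModel"))
  if (length(x) != length(null$y_rot)) stop("dosage vector not aligned to null model")
  if (stats::var(x) == 0) stop("monomorphic marker: association undefined")
  xr <- as.vector(crossprod(null$U, x))
  w <- null$w; o <- null$one_rot; yr <- null$y_rot
  a11 <- sum(w * o^2); a12 <- sum(w * o * xr); a22 <- sum(w * xr^2)
  c1 <- sum(w * o * yr); c2 <- sum(w * xr * yr)
  det <- a11 * a22 - a12^2
  b <- (a11 * c2 - a12 * c1) / det
  se <- sqrt(a11 / det)
  z <- b / se
  c(b = b, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Run a single-marker mixed-linear-model association scan
#'
#' Every polymorphic marker is tested with the model
#' y = 1 mu + b x + g + e, with the polygenic variance structure fixed from
#' the null fit. Monomorphic markers are skipped and counted.
#'
#' @param gm a `GenotypeMatrix`.
#' @param y phenotype vector named by sample id (or in `gm` sample order).
#' @param grm a `GRM`; defaults to VanRaden G over all markers of `gm`.
#' @param null optionally a precomputed `NullModel` (e.g. to share across
#'   marker subsets).
#' @param genomewide,suggestive significance thresholds for
#'   [classify_hits()].
#' @return data.frame of class `GwasResult`: id, chrom, pos, freq_alt,
#'   beta, se, p, class; attributes `lambda` (genomic inflation),
#'   `n_skipped`, `null` (the null model).
#' @export
run_gwas <- function(gm, y, grm = NULL, null = NULL,
                     genomewide = 5e-8, suggestive = 5e-6) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  if (!is.null(names(y))) {
    i <- match(rownames(gm$dosages), names(y))
    if (anyNA(i)) stop("phenotype vector does not cover all genotyped samples")
    y <- y[i]
  }
  if (length(y) != nrow(gm$dosages)) stop("phenotype/genotype sample mismatch")
  if (is.null(grm)) grm <- build_grm(gm)
  if (!identical(grm$sample_ids, rownames(gm$dosages)))
    stop("GRM samples do not align with the genotype matrix")
  if (is.null(null)) null <- fit_null(stats::setNames(y, rownames(gm$dosages)), grm)
  sds <- apply(gm$dosages, 2, stats::sd)
  poly <- sds > 0
  X <- gm$dosages[, poly, drop = FALSE]
  Xr <- crossprod(null$U, X)                       # rotate all markers at once
  w <- null$w; o <- null$one_rot; yr <- null$y_rot
  a11 <- sum(w * o^2); c1 <- sum(w * o * yr)
  a12 <- colSums((w * o) * Xr)
  a22 <- colSums(w * Xr^2)
  c2 <- colSums((w * yr) * Xr)
  det <- a11 * a22 - a12^2
  beta <- (a11 * c2 - a12 * c1) / det
  se <- sqrt(a11 / det)
  p <- 2 * stats::pnorm(-abs(beta / se))
  res <- data.frame(id = gm$map$id[poly], chrom = gm$map$chrom[poly],
                    pos = gm$map$pos[poly],
                    freq_alt = colMeans(X) / 2,
                    beta = beta, se = se, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- classify_hits(res, genomewide = genomewide, suggestive = suggestive)
  attr(res, "lambda") <- genomic_inflation(res$p)
  attr(res, "n_skipped") <- sum(!poly)
  attr(res, "null") <- null
  res
}

#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square statistics implied by the p-values divided
#' by the null median 0.4549; lambda near 1 indicates a calibrated scan.
#'
#' @param pvalues numeric vector of p-values.
#' @return lambda.
#' @export
genomic_inflation <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0) stop("no p-values")
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Classify association hits by significance thresholds
#'
#' `genomewide` if p < 5e-8, else `suggestive` if p < 5e-6, else `none`
#' (strict inequalities, thresholds configurable).
#'
#' @param result a `GwasResult` data.frame with a `p` column.
#' @param genomewide genome-wide significance level.
#' @param suggestive suggestive significance level.
#' @return `result` with a `class` column set/replaced.
#' @export
classify_hits <- function(result, genomewide = 5e-8, suggestive = 5e-6) {
  stopifnot("p" %in% names(result))
  cl <- rep("none", nrow(result))
  cl[result$p < suggestive] <- "suggestive"
  cl[result$p < genomewide] <- "genomewide"
  result$class <- cl
  if (!inherits(result, "GwasResult")) class(result) <- c("GwasResult", class(result))
  result
}

#' Benjamini-Hochberg FDR marker selection
#'
#' Step-up rule: with ordered p-values p(1) <= ... <= p(m), find the largest
#' k with p(k) <= k q / m and select every marker with p <= p(k).
#' Implemented through `stats::p.adjust(..., "BH")`, which is equivalent.
#'
#' @param pvalues numeric p-values.
#' @param q target false discovery rate (default 0.05), in (0, 1).
#' @return integer indices of selected markers (possibly empty).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  which(stats::p.adjust(pvalues, method = "BH") <= q)
}

#' Export Manhattan and QQ plotting tables from a GWAS result
#'
#' @param result a `GwasResult`.
#' @return list with `manhattan` (chrom, pos, p, -log10 p, class, sorted by
#'   chromosome then position) and `qq` (expected vs observed -log10 p,
#'   expected quantiles from uniform order statistics).
#' @export
gwas_plot_data <- function(result) {
  stopifnot(inherits(result, "GwasResult"))
  ord <- order(result$chrom, result$pos)
  man <- data.frame(chrom = result$chrom[ord], pos = result$pos[ord],
                    p = result$p[ord], neglog10p = -log10(result$p[ord]),
                    class = result$class[ord])
  m <- nrow(result)
  po <- sort(result$p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(po))
  list(manhattan = man, qq = qq)
}
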