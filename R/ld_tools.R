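#' Pairwise linkage disequilibrium r-squared between two markers
#'
#' Composite (genotypic) r^2: the squared Pearson correlation of the two
#' dosage vectors. Phase information is not used.
#'
#' @param gm a `GenotypeMatrix`.
#' @param i,j marker ids.
#' @return r^2 in [0, 1].
#' @export
pairwise_r2 <- function(gm, i, j) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  ii <- match(i, gm$map$id); jj <- match(j, gm$map$id)
  if (is.na(ii) || is.na(jj)) stop("unknown marker id")
  x <- gm$dosages[, ii]; y <- gm$dosages[, jj]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("r^2 undefined for a monomorphic marker")
  stats::cor(x, y)^2
}

#' Greedy sliding-window LD pruning
#'
#' Markers must be sorted by (chromosome, position). Windows of `window_kb`
#' kilobases start at every `step`-th marker along each chromosome. Within
#' a window, violating pairs (r^2 > `r2_max`) are resolved by removing the
#' member with the lower MAF; at equal MAF the later-positioned marker is
#' removed. The result is deterministic and every retained pair inside one
#' window satisfies r^2 <= r2_max.
#'
#' @param gm a `GenotypeMatrix`.
#' @param window_kb window span in kb (default 100).
#' @param step window start advance, in markers (default half the mean
#'   marker count per window, minimum 1).
#' @param r2_max maximum tolerated r^2 (default 0.9; strictly greater is
#'   pruned).
#' @return character vector of retained marker ids, in map order.
#' @export
ld_prune <- function(gm, window_kb = 100, step = NULL, r2_max = 0.9) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  m <- ncol(gm$dosages)
  if (m == 0) stop("empty genotype matrix")
  # chromosomes must form contiguous blocks with nondecreasing positions
  # (chromosome naming order itself is irrelevant)
  rl <- rle(gm$map$chrom)
  if (anyDuplicated(rl$values) ||
      any(tapply(gm$map$pos, factor(gm$map$chrom, levels = rl$values),
                 is.unsorted)))
    stop("markers must be sorted by (chromosome, position)")
  maf <- marker_frequencies(gm)$maf
  keep <- rep(TRUE, m)
  window_bp <- window_kb * 1000
  for (ch in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == ch)
    if (length(idx) < 2) next
    pos <- gm$map$pos[idx]
    if (is.null(step)) {
      mean_win <- max(1, length(idx) * window_bp / max(diff(range(pos)), 1))
      st <- max(1L, as.integer(mean_win / 2))
    } else st <- max(1L, as.integer(step))
    starts <- seq(1L, length(idx), by = st)
    for (s in starts) {
      in_win <- which(pos >= pos[s] & pos <= pos[s] + window_bp)
      in_win <- in_win[keep[idx[in_win]]]
      if (length(in_win) < 2) next
      X <- gm$dosages[, idx[in_win], drop = FALSE]
      sds <- apply(X, 2, stats::sd)
      live <- rep(TRUE, length(in_win))
      for (a in seq_along(in_win)) {
        if (!live[a]) next
        for (b in seq_along(in_win)) {
          if (b <= a || !live[b] || !live[a]) next
          if (sds[a] == 0 || sds[b] == 0) next
          r2 <- stats::cor(X[, a], X[, b])^2
          if (r2 > r2_max) {
            ma <- maf[idx[in_win[a]]]; mb <- maf[idx[in_win[b]]]
            drop_b <- if (ma == mb) TRUE else mb < ma
            if (drop_b) live[b] <- FALSE else { live[a] <- FALSE; break }
          }
        }
      }
      keep[idx[in_win[!live]]] <- FALSE
    }
  }
  gm$map$id[keep]
}

#' Prune markers down to (approximately) a target count
#'
#' Bisection over the pruning threshold `r2_max`: lower thresholds prune
#' harder. If even near-zero thresholds leave more markers than the target
#' (mutually independent markers), the retained set is thinned uniformly
#' along the genome. Stops when the retained count is within +-2% of the
#' target.
#'
#' @param gm a `GenotypeMatrix`.
#' @param target_count desired number of retained markers.
#' @param window_kb window span passed to [ld_prune()].
#' @return character vector of retained marker ids.
#' @export
prune_to_target <- function(gm, target_count, window_kb = 100) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  m <- ncol(gm$dosages)
  if (target_count > m) stop("target_count exceeds the number of markers")
  if (target_count == m) return(gm$map$id)
  tol <- max(1, ceiling(0.02 * target_count))
  lo <- 0.001; hi <- 0.999
  best <- gm$map$id
  for (it in 1:18) {
    mid <- (lo + hi) / 2
    ids <- ld_prune(gm, window_kb = window_kb, r2_max = mid)
    if (abs(length(ids) - target_count) <= tol) return(ids)
    if (length(ids) > target_count) { hi <- mid; best <- ids } else lo <- mid
  }
  ids <- if (length(best) >= target_count) best else ld_prune(gm, window_kb = window_kb, r2_max = hi)
  # uniform physical thinning of whatever the mildest pruning retained
  if (length(ids) > target_count) {
    pick <- unique(round(seq(1, length(ids), length.out = target_count)))
    ids <- ids[pick]
  }
  ids
}

#' Binned LD-decay curve
#'
#' All within-chromosome marker pairs up to `max_dist` apart are assigned to
#' distance bins of width `bin_width`; the curve reports the mean r^2 and
#' pair count per bin.
#'
#' @param gm a `GenotypeMatrix`.
#' @param max_dist maximum pair distance in bp (default 100 kb).
#' @param bin_width bin width in bp (default 2 kb).
#' @return data.frame of class `LdDecayCurve`: `bin_start`, `bin_end`,
#'   `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gm, max_dist = 1e5, bin_width = 2000) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  nb <- length(edges) - 1
  sums <- numeric(nb); cnts <- integer(nb)
  for (ch in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == ch)
    if (length(idx) < 2) next
    X <- gm$dosages[, idx, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    pos <- gm$map$pos[idx]
    C <- suppressWarnings(stats::cor(X))
    D <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(D)
    ok <- ut & D <= max_dist & outer(sds > 0, sds > 0, "&")
    if (!any(ok)) next
    b <- findInterval(D[ok], edges, rightmost.closed = TRUE, left.open = TRUE)
    b[b == 0] <- 1
    r2 <- C[ok]^2
    sums <- sums + vapply(seq_len(nb), function(k) sum(r2[b == k]), numeric(1))
    cnts <- cnts + vapply(seq_len(nb), function(k) sum(b == k), integer(1))
  }
  if (sum(cnts) == 0) stop("no marker pairs within max_dist")
  out <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                    bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                    mean_r2 = ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_),
                    n_pairs = cnts)
  class(out) <- c("LdDecayCurve", "data.frame")
  out
}

#' Distance at which mean LD drops to a given r^2 level
#'
#' @param curve an `LdDecayCurve` from [ld_decay()].
#' @param r2_level target r^2 (e.g. 0.05).
#' @return the midpoint (bp) of the first bin whose mean r^2 is at or below
#'   `r2_level`; `NA` if the curve never reaches it.
#' @export
find_decay_distance <- function(curve, r2_level) {
  stopifnot(inherits(curve, "LdDecayCurve"))
  ok <- !is.na(curve$mean_r2) & curve$mean_r2 <= r2_level
  if (!any(ok)) return(NA_real_)
  curve$bin_mid[which(ok)[1]]
}

#' Mean r^2 of physically adjacent marker pairs
#'
#' The genome-wide average of r^2 over all pairs of neighbouring markers
#' (per chromosome), a standard one-number LD summary.
#'
#' @param gm a `GenotypeMatrix`.
#' @return mean adjacent-pair r^2.
#' @export
mean_adjacent_r2 <- function(gm) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  vals <- c()
  for (ch in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == ch)
    if (length(idx) < 2) next
    X <- gm$dosages[, idx, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    for (k in seq_len(length(idx) - 1)) {
      if (sds[k] > 0 && sds[k + 1] > 0)
        vals <- c(vals, stats::cor(X[, k], X[, k + 1])^2)
    }
  }
  if (length(vals) == 0) stop("no adjacent polymorphic pairs")
  mean(vals)
}
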