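# shared builders for small in-code fixtures

`%||%` <- function(a, b) if (is.null(a)) b else a

# GenotypeMatrix from a bare dosage matrix
toy_gm <- function(dos, chrom = NULL, pos = NULL, ids = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("S%03d", seq_len(n))
  map <- data.frame(
    id = ids %||% sprintf("M%03d", seq_len(m)),
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% as.integer(seq_len(m) * 1000L),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}

# iid Binomial(2, p) markers (no LD)
rand_gm <- function(n, m, seed = 1, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  toy_gm(dos)
}

# wrap an arbitrary symmetric PSD matrix as a GRM object
as_grm <- function(M, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  structure(list(matrix = M, marker_ids = NULL, scale_const = 1,
                 sample_ids = ids), class = "GRM")
}

# restricted log-likelihood computed from first principles (dense V,
# independent of reml_fit's internals)
reml_ll_oracle <- function(y, Klist, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Klist)) V <- V + theta[i] * Klist[[i]]
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       log(XtViX[1, 1]) + crossprod(y, P %*% y)))
}

# dense generalized-least-squares BLUP oracle for one or two components
blup_oracle <- function(y_tr, G_list, s2_list, s2e, tr_idx, ridge = 1e-6) {
  nt <- length(tr_idx)
  Vt <- diag(s2e, nt)
  Gsum_tt <- matrix(0, nt, nt)
  for (i in seq_along(G_list)) {
    Gtt <- G_list[[i]][tr_idx, tr_idx]
    Vt <- Vt + s2_list[[i]] * Gtt
    Gsum_tt <- Gsum_tt + s2_list[[i]] * Gtt
  }
  Vt <- Vt + diag(ridge * mean(diag(Gsum_tt)), nt)
  Vi <- solve(Vt)
  one <- rep(1, nt)
  mu <- sum(Vi %*% y_tr) / sum(Vi %*% one)
  resid <- Vi %*% (y_tr - mu)
  lapply(seq_along(G_list), function(i)
    as.vector(s2_list[[i]] * G_list[[i]][, tr_idx] %*% resid))
}
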