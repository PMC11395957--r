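test_that("with an identity G the scan reduces to ordinary least squares", {
  ids <- sprintf("S%03d", 1:5)
  y <- setNames(c(1, 2, 3, 4, 5), ids)
  x <- c(0, 0, 1, 1, 2)
  null <- suppressWarnings(fit_null(y, as_grm(diag(5), ids)))
  sc <- score_snp(null, x)
  # OLS slope of y on x: cov/var = 1.4/0.56... closed form 5/2.8
  expect_equal(unname(sc["b"]), 5 / 2.8, tolerance = 1e-8)
  expect_equal(unname(sc["b"]), unname(coef(lm(y ~ x))[2]), tolerance = 1e-8)
})

test_that("score_snp equals a dense generalized-least-squares solve", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 20
    ids <- sprintf("S%03d", 1:n)
    K <- tcrossprod(matrix(rnorm(n * 40), n)) / 40
    y <- setNames(as.vector(chol(K + diag(n)) %*% rnorm(n)), ids)
    null <- suppressWarnings(fit_null(y, as_grm(K, ids)))
    x <- rbinom(n, 2, 0.4)
    if (var(x) == 0) next
    sc <- score_snp(null, x)
    V <- null$sigma2_a * K + null$sigma2_e * diag(n)
    Vi <- solve(V)
    X <- cbind(1, x)
    XtViX_inv <- solve(crossprod(X, Vi %*% X))
    bhat <- XtViX_inv %*% crossprod(X, Vi %*% y)
    expect_equal(unname(sc["b"]), as.numeric(bhat[2, 1]), tolerance = 1e-8)
    expect_equal(unname(sc["se"]), sqrt(XtViX_inv[2, 2]), tolerance = 1e-8)
  }
})

test_that("allele-coding swap flips the sign of b but not the p-value", {
  set.seed(73)
  n <- 60
  gm <- rand_gm(n, 30, seed = 73)
  y <- setNames(rnorm(n), rownames(gm$dosages))
  null <- fit_null(y, build_grm(gm))
  x <- gm$dosages[, 5]
  a <- score_snp(null, x)
  b <- score_snp(null, 2 - x)
  expect_equal(unname(a["b"]), -unname(b["b"]), tolerance = 1e-10)
  expect_equal(unname(a["p"]), unname(b["p"]), tolerance = 1e-10)
})

test_that("the scan covers exactly the polymorphic markers in input order", {
  set.seed(79)
  gm <- rand_gm(80, 25, seed = 79)
  gm$dosages[, 10] <- 1   # monomorphic
  y <- setNames(rnorm(80), rownames(gm$dosages))
  gw <- run_gwas(gm, y)
  expect_equal(nrow(gw), 24)
  expect_equal(attr(gw, "n_skipped"), 1)
  expect_false("M010" %in% gw$id)
  # permuting markers permutes rows only
  perm <- sample(25)
  gmp <- genotype_matrix(gm$dosages[, perm], gm$map[perm, ])
  gwp <- run_gwas(gmp, y)
  m <- match(gw$id, gwp$id)
  expect_equal(gwp$p[m], gw$p, tolerance = 1e-10)
})

test_that("a planted large-effect QTL ranks at the top of the scan", {
  for (s in 1:3) {
    cfg <- sim_config(n_samples = 400, n_markers = 500,
                      chrom_lengths = rep(2e6, 2), n_qtl = 1,
                      h2_target = 0.4, seed = 300 + s)
    gm <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(gm, cfg)
    y <- setNames(sim$phenotypes$trait, rownames(gm$dosages))
    gw <- run_gwas(gm, y)
    rank_q <- rank(gw$p)[gw$id == sim$truth$qtl_ids]
    expect_lte(rank_q, ceiling(0.01 * nrow(gw)))
  }
})

test_that("genomic inflation follows the median chi-square definition", {
  expect_equal(genomic_inflation(0.5), 1.0, tolerance = 1e-10)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 10001)
  expect_equal(genomic_inflation(grid), 1.0, tolerance = 1e-3)
  expect_gt(genomic_inflation(rep(1e-8, 5)), 10)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
})

test_that("hit classification uses strict thresholds", {
  res <- data.frame(id = c("a", "b", "c", "d"), chrom = "1",
                    pos = 1:4, p = c(4.23e-8, 5e-6, 1e-6, 0.2))
  cl <- classify_hits(res)
  expect_equal(cl$class, c("genomewide", "none", "suggestive", "none"))
})

test_that("BH selection matches an exhaustive threshold search", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.5), q = 0.05), 1:3)
  expect_length(bh_fdr(rep(1, 10)), 0)
  # oracle: try every observed p as the cut and apply the step-up criterion
  bh_oracle <- function(p, q) {
    m <- length(p)
    ps <- sort(p)
    ok <- ps <= seq_len(m) * q / m
    if (!any(ok)) return(integer(0))
    thr <- ps[max(which(ok))]
    which(p <= thr)
  }
  set.seed(83)
  for (rep in 1:1000) {
    p <- runif(sample(3:25, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    expect_identical(bh_fdr(p, q), bh_oracle(p, q))
  }
  # monotone: lowering q never adds markers
  set.seed(89)
  p <- runif(50)^2
  expect_true(all(bh_fdr(p, 0.01) %in% bh_fdr(p, 0.1)))
  expect_error(bh_fdr(p, 1.2), "q must be")
})

test_that("null-model caching reconstructs G and a zero-h2 null hits the bound", {
  set.seed(97)
  gm <- rand_gm(150, 300, seed = 97)
  y <- setNames(rnorm(150), rownames(gm$dosages))
  g <- build_grm(gm)
  null <- fit_null(y, g)
  recon <- null$U %*% diag(null$d) %*% t(null$U)
  expect_equal(recon, g$matrix, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(null$sigma2_a / (null$sigma2_a + null$sigma2_e), 0.15)
  # a predictor orthogonal to y (given the intercept) in the rotated,
  # weighted space has b = 0 and p = 1
  w <- null$w; o <- null$one_rot; yr <- null$y_rot
  xr <- rnorm(150)
  for (v in list(o, yr)) xr <- xr - sum(w * xr * v) / sum(w * v^2) * v
  # re-orthogonalise yr against o the same way score_snp's GLS does implicitly
  yr_go <- yr - sum(w * yr * o) / sum(w * o^2) * o
  xr <- xr - sum(w * xr * yr_go) / sum(w * yr_go^2) * yr_go
  sc <- score_snp(null, as.vector(null$U %*% xr))
  expect_lt(abs(unname(sc["b"])), 1e-8 * sd(y))
  expect_gt(unname(sc["p"]), 0.999)
})
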