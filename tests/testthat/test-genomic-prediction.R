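test_that("evaluation metrics follow their definitions", {
  y <- c(1, 2, 3, 2.5, 4)
  m <- evaluate_prediction(y, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$bias, 0)
  expect_equal(m$mse, 0)
  expect_equal(m$mae, 0)
  m2 <- evaluate_prediction(2 * y, y * 4)     # slope of (2y) on (4y) is 0.5
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$bias, 0.5)
  m3 <- evaluate_prediction(c(1, 2, 3), c(1, 1, 2))
  expect_equal(round(m3$accuracy, 3), 0.866)
  expect_equal(m3$bias, 0.5)
  m4 <- evaluate_prediction(y, rep(1, 5))
  expect_true(m4$degenerate)
  expect_true(is.na(m4$accuracy))
  expect_error(evaluate_prediction(1:2, 1:2), "at least 3")
})

test_that("accuracy is affine-invariant but dispersion bias is not", {
  set.seed(101)
  y <- rnorm(50); g <- 0.6 * y + rnorm(50, sd = 0.5)
  a <- evaluate_prediction(y, g)
  b <- evaluate_prediction(y, 3 * g + 2)
  expect_equal(a$accuracy, b$accuracy, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$bias, b$bias)))
})

test_that("GBLUP matches the dense GLS oracle and its noiseless limit", {
  set.seed(103)
  n <- 15
  gm <- rand_gm(n, 200, seed = 103)
  G <- build_grm(gm)
  ids <- G$sample_ids
  y <- setNames(as.vector(chol(G$matrix + diag(n) + diag(1e-6, n)) %*% rnorm(n)), ids)
  train <- ids[1:10]; test <- ids[11:15]
  est <- structure(list(components = c(sigma2_g = 0.8, sigma2_e = 0.4),
                        h2 = c(h2_g = 2 / 3, total = 2 / 3)),
                   class = "VarianceEstimate")
  pred <- gblup_predict(y[train], G, train, test, est = est)
  oracle <- blup_oracle(y[train], list(G$matrix), list(0.8), 0.4,
                        match(train, ids))[[1]]
  expect_equal(unname(pred$gebv), oracle, tolerance = 1e-8)
  # sigma_e -> 0: training GEBVs converge to the centred phenotypes
  est0 <- structure(list(components = c(sigma2_g = 1, sigma2_e = 1e-10)),
                    class = "VarianceEstimate")
  p0 <- gblup_predict(y[train], G, train, test, est = est0, ridge = 1e-12)
  expect_equal(unname(p0$gebv[train]), unname(y[train] - p0$mu), tolerance = 1e-4)
  # leakage guard: train/test must be disjoint
  expect_error(gblup_predict(y[train], G, train, c(test, train[1])), "overlap")
})

test_that("GFBLUP matches the two-component GLS oracle and nests GBLUP", {
  set.seed(107)
  n <- 15
  gm <- rand_gm(n, 100, seed = 107)
  feat <- gm$map$id[1:20]
  part <- partition_feature_grm(gm, feat)
  ids <- part$feature$sample_ids
  y <- setNames(rnorm(n), ids)
  train <- ids[1:11]; test <- ids[12:15]
  est <- structure(list(components = c(sigma2_f = 0.5, sigma2_r = 0.3,
                                       sigma2_e = 0.6)),
                   class = "VarianceEstimate")
  pred <- gfblup_predict(y[train], part$feature, part$background, train, test,
                         est = est)
  oracle <- blup_oracle(y[train], list(part$feature$matrix, part$background$matrix),
                        list(0.5, 0.3), 0.6, match(train, ids))
  expect_equal(unname(pred$gebv_f), oracle[[1]], tolerance = 1e-8)
  expect_equal(unname(pred$gebv_r), oracle[[2]], tolerance = 1e-8)
  expect_equal(pred$gebv, pred$gebv_f + pred$gebv_r, tolerance = 1e-12)
  # sigma_f = 0 collapses GFBLUP onto GBLUP over the background matrix
  est_f0 <- structure(list(components = c(sigma2_f = 0, sigma2_r = 0.3,
                                          sigma2_e = 0.6)),
                      class = "VarianceEstimate")
  est_g <- structure(list(components = c(sigma2_g = 0.3, sigma2_e = 0.6)),
                     class = "VarianceEstimate")
  pf <- gfblup_predict(y[train], part$feature, part$background, train, test,
                       est = est_f0, ridge = 0)
  pg <- gblup_predict(y[train], part$background, train, test, est = est_g,
                      ridge = 0)
  expect_equal(pf$gebv, pg$gebv, tolerance = 1e-10)
})

test_that("holdout accuracy is well above chance for a heritable trait", {
  accs <- vapply(1:2, function(s) {
    cfg <- sim_config(n_samples = 400, n_markers = 800,
                      chrom_lengths = rep(3e6, 2), n_qtl = 50,
                      h2_target = 0.6, seed = 400 + s)
    gm <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(gm, cfg)
    ids <- rownames(gm$dosages)
    y <- setNames(sim$phenotypes$trait, ids)
    test <- ids[1:100]; train <- setdiff(ids, test)
    pred <- gblup_predict(y[train], build_grm(gm), train, test)
    cor(y[test], pred$gebv[test])
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
})

test_that("fold plans partition samples with near-equal sizes", {
  ids <- sprintf("S%04d", 1:673)
  plan <- make_fold_plan(ids, k = 10, replicates = 3, seed = 5)
  for (r in 1:3) {
    sizes <- lengths(plan[[r]])
    expect_true(all(sizes %in% c(67, 68)))
    expect_equal(sum(sizes), 673)
    expect_setequal(unlist(plan[[r]]), ids)
  }
  # same seed, same plan
  plan2 <- make_fold_plan(ids, k = 10, replicates = 3, seed = 5)
  expect_identical(plan, plan2)
  expect_error(make_fold_plan(ids[1:5], k = 10), "more folds")
})

test_that("cross-validation bookkeeping and determinism hold", {
  cfg <- sim_config(n_samples = 120, n_markers = 150, chrom_lengths = rep(1e6, 2),
                    n_qtl = 10, h2_target = 0.6, seed = 109)
  gm <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(gm, cfg)
  y <- setNames(sim$phenotypes$trait, rownames(gm$dosages))
  cv1 <- crossvalidate(gm, y, "gblup", k = 4, replicates = 3, seed = 7)
  expect_equal(nrow(cv1$per_fold), 12)   # every validation set evaluated once
  expect_equal(nrow(cv1$per_replicate), 3)
  cv2 <- crossvalidate(gm, y, "gblup", k = 4, replicates = 3, seed = 7)
  expect_identical(cv1$per_fold, cv2$per_fold)
  # gldblup runs on a fixed pruned subset
  cvl <- crossvalidate(gm, y, "gldblup", k = 4, replicates = 1, seed = 7,
                       prune_target = 100)
  expect_lte(length(cvl$pruned_ids), 110)
})

test_that("validation phenotypes cannot influence training", {
  set.seed(113)
  gm <- rand_gm(60, 100, seed = 113)
  ids <- rownames(gm$dosages)
  y <- setNames(rnorm(60), ids)
  train <- ids[1:45]; test <- ids[46:60]
  G <- build_grm(gm)
  p1 <- gblup_predict(y[train], G, train, test)
  y2 <- y; y2[test] <- 0   # mangle validation phenotypes
  p2 <- gblup_predict(y2[train], G, train, test)
  expect_identical(p1$gebv, p2$gebv)
  expect_identical(p1$est$components, p2$est$components)
})

test_that("gfblup cross-validation selects features per training fold", {
  cfg <- sim_config(n_samples = 150, n_markers = 200, chrom_lengths = rep(1e6, 2),
                    n_qtl = 5, h2_target = 0.7, seed = 127)
  gm <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(gm, cfg)
  y <- setNames(sim$phenotypes$trait, rownames(gm$dosages))
  cv <- crossvalidate(gm, y, "gfblup", k = 3, replicates = 1, seed = 11)
  expect_s3_class(cv, "PredictionReport")
  expect_equal(nrow(cv$per_fold), 3)
  expect_true(all(is.finite(cv$per_fold$accuracy)))
})
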