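#' GBLUP breeding values for all samples from a training subset
#'
#' Variance components are estimated by REML on the training samples only;
#' GEBVs for every sample (training and validation) then come from
#' g_hat = sigma_g^2 G[, train] V_train^-1 (y_train - mu_hat), the BLUP
#' solution of the mixed-model equations. Validation phenotypes are never
#' touched. A small ridge (1e-6 x mean diagonal) stabilises the solve.
#'
#' @param y_train named phenotype vector for the training samples.
#' @param grm a `GRM` covering training and validation samples.
#' @param train_ids,test_ids disjoint sample-id sets.
#' @param est optional precomputed `VarianceEstimate` (training samples).
#' @param ridge relative ridge added to the training covariance diagonal.
#' @return list: `gebv` (named vector over all GRM samples), `est`, `mu`.
#' @export
gblup_predict <- function(y_train, grm, train_ids, test_ids, est = NULL,
                          ridge = 1e-6) {
  stopifnot(inherits(grm, "GRM"))
  if (length(intersect(train_ids, test_ids)) > 0)
    stop("train and test sample sets overlap")
  tr <- match(train_ids, grm$sample_ids)
  if (anyNA(tr)) stop("training ids missing from GRM")
  y_train <- y_train[train_ids]
  if (anyNA(y_train)) stop("training phenotypes missing")
  if (is.null(est)) est <- reml_fit(y_train, .grm_sub(grm, tr))
  s2g <- sum(est$components[-length(est$components)])
  s2e <- est$components[length(est$components)]
  Gtt <- grm$matrix[tr, tr, drop = FALSE]
  V <- s2g * Gtt + diag(s2e + ridge * mean(diag(Gtt)) * s2g, length(tr))
  Vi <- chol2inv(chol(V))
  one <- rep(1, length(tr))
  mu <- sum(Vi %*% y_train) / sum(Vi %*% one)
  resid <- as.vector(Vi %*% (y_train - mu))
  gebv <- as.vector(s2g * grm$matrix[, tr, drop = FALSE] %*% resid)
  names(gebv) <- grm$sample_ids
  list(gebv = gebv, est = est, mu = mu)
}

#' Genomic-feature BLUP with feature and background components
#'
#' Two genomic random effects: f ~ N(0, G_f sigma_f^2) over the feature
#' markers and r ~ N(0, G_r sigma_r^2) over the background markers; the
#' total GEBV is f_hat + r_hat. Components are estimated by two-matrix REML
#' on the training samples.
#'
#' @param y_train named phenotype vector for the training samples.
#' @param grm_f,grm_r feature and background `GRM`s over all samples (from
#'   [partition_feature_grm()]).
#' @param train_ids,test_ids disjoint sample-id sets.
#' @param est optional precomputed two-component `VarianceEstimate`.
#' @param ridge relative ridge on the training covariance diagonal.
#' @return list: `gebv` (= `gebv_f + gebv_r`), `gebv_f`, `gebv_r`, `est`,
#'   `mu`.
#' @export
gfblup_predict <- function(y_train, grm_f, grm_r, train_ids, test_ids,
                           est = NULL, ridge = 1e-6) {
  stopifnot(inherits(grm_f, "GRM"), inherits(grm_r, "GRM"))
  if (length(intersect(train_ids, test_ids)) > 0)
    stop("train and test sample sets overlap")
  tr <- match(train_ids, grm_f$sample_ids)
  if (anyNA(tr)) stop("training ids missing from GRM")
  y_train <- y_train[train_ids]
  if (is.null(est))
    est <- reml_fit(y_train, list(f = .grm_sub(grm_f, tr), r = .grm_sub(grm_r, tr)))
  s2f <- unname(est$components["sigma2_f"])
  s2r <- unname(est$components["sigma2_r"])
  s2e <- unname(est$components["sigma2_e"])
  Ftt <- grm_f$matrix[tr, tr, drop = FALSE]
  Rtt <- grm_r$matrix[tr, tr, drop = FALSE]
  V <- s2f * Ftt + s2r * Rtt +
    diag(s2e + ridge * mean(diag(s2f * Ftt + s2r * Rtt)), length(tr))
  Vi <- chol2inv(chol(V))
  one <- rep(1, length(tr))
  mu <- sum(Vi %*% y_train) / sum(Vi %*% one)
  resid <- as.vector(Vi %*% (y_train - mu))
  gebv_f <- as.vector(s2f * grm_f$matrix[, tr, drop = FALSE] %*% resid)
  gebv_r <- as.vector(s2r * grm_r$matrix[, tr, drop = FALSE] %*% resid)
  names(gebv_f) <- names(gebv_r) <- grm_f$sample_ids
  list(gebv = gebv_f + gebv_r, gebv_f = gebv_f, gebv_r = gebv_r,
       est = est, mu = mu)
}

#' Cross-validation metrics for genomic prediction
#'
#' Accuracy is the Pearson correlation r(y, GEBV); dispersion bias is
#' |1 - b| where b is the slope of y regressed on GEBV; MSE and MAE are
#' computed after mean-centring both y and GEBV.
#'
#' @param y_valid validation phenotypes.
#' @param gebv_valid predicted GEBVs for the same samples.
#' @return list: `accuracy`, `bias`, `mse`, `mae`, `degenerate` (TRUE when
#'   the GEBVs are constant, in which case accuracy and bias are NA).
#' @export
evaluate_prediction <- function(y_valid, gebv_valid) {
  stopifnot(length(y_valid) == length(gebv_valid))
  if (length(y_valid) < 3) stop("need at least 3 validation samples")
  yc <- y_valid - mean(y_valid)
  gc <- gebv_valid - mean(gebv_valid)
  degenerate <- stats::var(gebv_valid) == 0
  acc <- if (degenerate) NA_real_ else stats::cor(y_valid, gebv_valid)
  bias <- if (degenerate) NA_real_ else abs(1 - sum(yc * gc) / sum(gc^2))
  list(accuracy = acc, bias = bias,
       mse = mean((yc - gc)^2), mae = mean(abs(yc - gc)),
       degenerate = degenerate)
}

#' Build a replicated k-fold plan
#'
#' Within each replicate the folds partition all samples exactly once; the
#' plan depends only on the ids, k, number of replicates and seed, so the
#' same plan can be shared across prediction methods.
#'
#' @param sample_ids character sample ids.
#' @param k folds per replicate.
#' @param replicates number of replicates.
#' @param seed root seed.
#' @return list of class `FoldPlan`: one element per replicate, each a list
#'   of k character vectors of validation ids.
#' @export
make_fold_plan <- function(sample_ids, k = 10, replicates = 20, seed = 1) {
  n <- length(sample_ids)
  if (k > n) stop("more folds than samples")
  plan <- lapply(seq_len(replicates), function(r) {
    set.seed(substream_seed(seed, paste0("folds:", r)))
    idx <- sample.int(n)
    fold_of <- rep(seq_len(k), length.out = n)  # sizes differ by at most 1
    lapply(seq_len(k), function(f) sample_ids[idx[fold_of == f]])
  })
  structure(plan, class = "FoldPlan", k = k, replicates = replicates, seed = seed)
}

#' Replicated k-fold cross-validation of genomic prediction
#'
#' Implements three prediction strategies over one shared fold plan:
#' \describe{
#'   \item{gblup}{G from all markers.}
#'   \item{gldblup}{G from an LD-pruned subset of about `prune_target`
#'     markers, fixed once (pruning uses no phenotypes).}
#'   \item{gfblup}{two components: the feature set is re-selected inside
#'     every training fold by a reference-only GWAS followed by
#'     Benjamini-Hochberg FDR at `fdr_q`; the background set is the pruned
#'     subset minus the feature markers. A fold whose training GWAS yields
#'     no FDR-significant marker falls back to GBLUP on the background
#'     matrix (the event is counted in `n_fallback`).}
#' }
#' Variance components are re-estimated within every training fold; the
#' replicate-level metric is the mean over its k folds.
#'
#' @param gm a `GenotypeMatrix`.
#' @param y phenotype vector named by sample id (or in `gm` sample order).
#' @param method `"gblup"`, `"gldblup"` or `"gfblup"`.
#' @param k folds (default 10).
#' @param replicates replicates (default 20).
#' @param seed root seed controlling the fold plan.
#' @param prune_target marker count for the pruned subset used by gldblup
#'   and as the gfblup background pool (default `min(2000, n_markers)`).
#' @param fdr_q FDR level for gfblup feature selection (default 0.05).
#' @param fold_plan optional `FoldPlan` to reuse across methods (overrides
#'   `k`, `replicates`, `seed`).
#' @param feature_ids optional fixed feature set for gfblup (bypasses the
#'   per-fold GWAS; used for negative controls).
#' @return list of class `PredictionReport`: `per_fold`, `per_replicate`,
#'   `summary` (mean and sd over replicates of the four metrics), `method`,
#'   `fold_plan`, `n_fallback`.
#' @export
crossvalidate <- function(gm, y, method = c("gblup", "gldblup", "gfblup"),
                          k = 10, replicates = 20, seed = 1,
                          prune_target = NULL, fdr_q = 0.05,
                          fold_plan = NULL, feature_ids = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(gm, "GenotypeMatrix"))
  ids <- rownames(gm$dosages)
  if (is.null(names(y))) names(y) <- ids
  y <- y[ids]
  if (anyNA(y)) stop("phenotypes missing for some genotyped samples")
  if (is.null(fold_plan)) fold_plan <- make_fold_plan(ids, k, replicates, seed)
  if (is.null(prune_target)) prune_target <- min(2000L, ncol(gm$dosages))

  pruned_ids <- if (method %in% c("gldblup", "gfblup"))
    prune_to_target(gm, prune_target) else NULL
  G_full <- build_grm(gm)
  G_pruned <- if (method == "gldblup") build_grm(gm, pruned_ids) else NULL

  n_fallback <- 0L
  rows <- list()
  for (r in seq_along(fold_plan)) {
    for (f in seq_along(fold_plan[[r]])) {
      test_ids <- fold_plan[[r]][[f]]
      train_ids <- setdiff(ids, test_ids)
      y_train <- y[train_ids]
      if (method == "gblup") {
        pred <- gblup_predict(y_train, G_full, train_ids, test_ids)
      } else if (method == "gldblup") {
        pred <- gblup_predict(y_train, G_pruned, train_ids, test_ids)
      } else {
        feat <- feature_ids
        if (is.null(feat)) {
          # reference-only GWAS: training samples, training-subset GRM
          gm_tr <- subset_genotypes(gm, samples = train_ids)
          tr_idx <- match(train_ids, G_full$sample_ids)
          gw <- run_gwas(gm_tr, y_train, grm = .grm_sub(G_full, tr_idx))
          feat <- gw$id[bh_fdr(gw$p, q = fdr_q)]
        }
        feat <- intersect(feat, gm$map$id)
        bg <- setdiff(pruned_ids, feat)
        if (length(feat) == 0) {
          n_fallback <- n_fallback + 1L
          pred <- gblup_predict(y_train, build_grm(gm, bg), train_ids, test_ids)
        } else {
          part <- partition_feature_grm(gm, feat, background_ids = pruned_ids)
          pred <- gfblup_predict(y_train, part$feature, part$background,
                                 train_ids, test_ids)
        }
      }
      met <- evaluate_prediction(y[test_ids], pred$gebv[test_ids])
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, fold = f, n_valid = length(test_ids),
        accuracy = met$accuracy, bias = met$bias, mse = met$mse, mae = met$mae)
    }
  }
  per_fold <- do.call(rbind, rows)
  per_replicate <- do.call(rbind, lapply(split(per_fold, per_fold$replicate),
    function(d) data.frame(replicate = d$replicate[1],
                           accuracy = mean(d$accuracy), bias = mean(d$bias),
                           mse = mean(d$mse), mae = mean(d$mae))))
  rownames(per_replicate) <- NULL
  summary <- data.frame(
    metric = c("accuracy", "bias", "mse", "mae"),
    mean = vapply(c("accuracy", "bias", "mse", "mae"),
                  function(m) mean(per_replicate[[m]]), numeric(1)),
    sd = vapply(c("accuracy", "bias", "mse", "mae"),
                function(m) stats::sd(per_replicate[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(method = method, per_fold = per_fold,
                 per_replicate = per_replicate, summary = summary,
                 fold_plan = fold_plan, n_fallback = n_fallback,
                 pruned_ids = pruned_ids),
            class = "PredictionReport")
}

#' @exportS3Method base::print
print.PredictionReport <- function(x, ...) {
  cat("Genomic prediction CV:", x$method, "-",
      attr(x$fold_plan, "replicates"), "replicates x",
      attr(x$fold_plan, "k"), "folds\n")
  print(x$summary, row.names = FALSE)
  if (x$n_fallback > 0)
    cat("  folds falling back to background-only GBLUP:", x$n_fallback, "\n")
  invisible(x)
}
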