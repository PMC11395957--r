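#' Descriptive statistics for a trait
#'
#' @param values numeric trait vector (NAs dropped).
#' @return list of class `TraitSummary`: `n`, `mean`, `sd` (n-1
#'   denominator), `cv` (sd/mean as a percentage), `min`, `max`.
#' @export
descriptive_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 observations")
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for mean 0")
  s <- stats::sd(values)
  structure(list(n = length(values), mean = m, sd = s, cv = 100 * s / m,
                 min = min(values), max = max(values)),
            class = "TraitSummary")
}

#' @exportS3Method base::print
print.TraitSummary <- function(x, ...) {
  cat(sprintf("n = %d  mean = %.4g  SD = %.4g  CV = %.2f%%  range = [%.4g, %.4g]\n",
              x$n, x$mean, x$sd, x$cv, x$min, x$max))
  invisible(x)
}

#' SNP heritability from variance components
#'
#' h^2 = V(G) / (V(G) + V(e)).
#'
#' @param v_g genetic (genomic) variance, >= 0.
#' @param v_e residual variance, >= 0.
#' @return heritability in [0, 1].
#' @export
heritability <- function(v_g, v_e) {
  stopifnot(v_g >= 0, v_e >= 0)
  if (v_g + v_e == 0) stop("both variance components are zero")
  v_g / (v_g + v_e)
}

#' REML variance components for one or two genomic relationship matrices
#'
#' Fits y = X b + sum_i u_i + e with u_i ~ N(0, K_i sigma_i^2) and
#' e ~ N(0, I sigma_e^2) by average-information REML. When an AI update
#' leaves the parameter space or decreases the restricted likelihood, the
#' iteration falls back to an EM step (which cannot decrease it). Variances
#' are constrained to >= 1e-6 * var(y); convergence is declared when the
#' restricted log-likelihood changes by < `tol`.
#'
#' @param y numeric phenotype vector. If named, samples are matched against
#'   the GRM sample ids.
#' @param grms a single `GRM` or a named list of `GRM`s (all over the same
#'   samples). One matrix gives the GBLUP variance structure; two give the
#'   feature/background structure of genomic-feature BLUP.
#' @param X fixed-effect design matrix; default intercept only.
#' @param max_iter maximum iterations (default 100).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param init optional numeric vector of starting values (genomic
#'   components then residual).
#' @return list of class `VarianceEstimate`: `components` (named variances,
#'   residual last), `h2` (per genomic component and `total`), `loglik`,
#'   `n_iter`, `converged`, `beta` (fixed-effect GLS estimates).
#' @export
reml_fit <- function(y, grms, X = NULL, max_iter = 100, tol = 1e-6, init = NULL) {
  if (inherits(grms, "GRM")) grms <- list(g = grms)
  stopifnot(length(grms) >= 1, all(vapply(grms, inherits, logical(1), "GRM")))
  if (is.null(names(grms)) || any(names(grms) == ""))
    names(grms) <- if (length(grms) == 1) "g" else c("f", "r")[seq_along(grms)]
  ids <- grms[[1]]$sample_ids
  if (!is.null(names(y)) && !is.null(ids)) {
    i <- match(ids, names(y))
    if (anyNA(i)) stop("sample ids of y and GRM do not align")
    y <- y[i]
  }
  n <- length(y)
  if (n != nrow(grms[[1]]$matrix)) stop("length(y) does not match GRM dimension")
  if (n < 30) warning("REML with n < 30 samples is fragile")
  K <- lapply(grms, function(g) g$matrix)
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)
  vy <- stats::var(y)
  lb <- 1e-6 * vy
  k <- length(K)
  theta <- if (!is.null(init)) pmax(init, lb) else rep(vy / (k + 1), k + 1)

  eval_fit <- function(theta) {
    V <- diag(theta[k + 1], n)
    for (i in seq_len(k)) V <- V + theta[i] * K[[i]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    M <- solve(XtViX)
    P <- Vi - ViX %*% M %*% t(ViX)
    u <- as.vector(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(R))) + determinant(XtViX, logarithm = TRUE)$modulus[1] +
                    sum(y * u))
    list(P = P, u = u, ll = ll, Vi = Vi, M = M, ViX = ViX)
  }

  Ku <- function(i, u) if (i <= k) as.vector(K[[i]] %*% u) else u
  fit <- eval_fit(theta)
  if (is.null(fit)) stop("singular covariance matrix at starting values")
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    # scores and AI matrix at current theta
    trPK <- vapply(seq_len(k + 1), function(i) {
      if (i <= k) sum(fit$P * K[[i]]) else sum(diag(fit$P))
    }, numeric(1))
    uK <- lapply(seq_len(k + 1), function(i) Ku(i, fit$u))
    score <- vapply(seq_len(k + 1), function(i)
      -0.5 * (trPK[i] - sum(fit$u * uK[[i]])), numeric(1))
    AI <- matrix(0, k + 1, k + 1)
    PuK <- lapply(uK, function(v) as.vector(fit$P %*% v))
    for (i in seq_len(k + 1)) for (j in i:(k + 1)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(uK[[i]] * PuK[[j]])
    }
    # active-set AI update: components pinned at the bound with a negative
    # score stay fixed; the remaining components move jointly
    free <- which(!(theta <= lb * (1 + 1e-8) & score < 0))
    new_theta <- NULL
    if (length(free) > 0) {
      step <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                       error = function(e) NULL)
      if (!is.null(step)) {
        new_theta <- theta
        new_theta[free] <- pmax(theta[free] + step, lb)
      }
    }
    new_fit <- if (!is.null(new_theta)) eval_fit(new_theta) else NULL
    if (is.null(new_fit) || new_fit$ll < fit$ll - 1e-10) {
      # EM fallback: guaranteed ascent direction
      new_theta <- pmax(theta + theta^2 * (vapply(seq_len(k + 1), function(i)
        sum(fit$u * uK[[i]]), numeric(1)) - trPK) / n, lb)
      new_fit <- eval_fit(new_theta)
      if (is.null(new_fit)) break
    }
    # boundary shortcut: EM approaches a zero component geometrically, so
    # also try clamping down-trending components straight to the bound
    clamp <- new_theta
    clamp[score < 0 & new_theta < 0.05 * vy] <- lb
    if (!identical(clamp, new_theta)) {
      clamp_fit <- eval_fit(clamp)
      if (!is.null(clamp_fit) && clamp_fit$ll > new_fit$ll) {
        new_theta <- clamp
        new_fit <- clamp_fit
      }
    }
    delta <- abs(new_fit$ll - fit$ll)
    theta <- new_theta
    fit <- new_fit
    if (delta < tol) { converged <- TRUE; break }
  }
  beta <- as.vector(fit$M %*% crossprod(X, as.vector(fit$Vi %*% y)))
  names(theta) <- c(paste0("sigma2_", names(grms)), "sigma2_e")
  gsum <- sum(theta[seq_len(k)])
  h2 <- c(theta[seq_len(k)] / (gsum + theta[k + 1]),
          total = unname(gsum / (gsum + theta[k + 1])))
  names(h2)[seq_len(k)] <- paste0("h2_", names(grms))
  structure(list(components = theta, h2 = h2, loglik = fit$ll,
                 n_iter = iter, converged = converged, beta = beta,
                 sample_ids = ids),
            class = "VarianceEstimate")
}

#' @exportS3Method base::print
print.VarianceEstimate <- function(x, ...) {
  cat("REML variance components",
      if (x$converged) sprintf("(converged in %d iterations)\n", x$n_iter)
      else sprintf("(NOT converged after %d iterations)\n", x$n_iter))
  for (nm in names(x$components)) cat(sprintf("  %-10s %.6g\n", nm, x$components[nm]))
  cat(sprintf("  h2 (total) %.4f   logL %.4f\n", x$h2["total"], x$loglik))
  invisible(x)
}

#' Format a variance report like a heritability table
#'
#' @param est a `VarianceEstimate`.
#' @param trait trait label.
#' @return one-row data.frame with columns Trait, V_G, V_e, h2 (two-GRM fits
#'   report the summed genomic variance as V_G).
#' @export
variance_table <- function(est, trait = "trait") {
  stopifnot(inherits(est, "VarianceEstimate"))
  k <- length(est$components) - 1
  data.frame(Trait = trait,
             V_G = sum(est$components[seq_len(k)]),
             V_e = est$components[k + 1],
             h2 = unname(est$h2["total"]))
}
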