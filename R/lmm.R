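# Per-feature linear mixed model scan, EMMA-style:
# one eigendecomposition of the grouping covariance shared across features,
# then per-feature 1-D REML profile optimization of the variance ratio
# lambda = sigma_g^2 / sigma_e^2. For exchangeable family blocks the
# eigendecomposition of Z Z' is closed-form (per-family mean vector with
# eigenvalue = family size; Helmert complement with eigenvalue 0), built
# sparse, so the rotation costs sum(s_f^2) rather than n^2.

# sparse orthonormal rotation U and eigenvalues d for family blocks
family_decomposition <- function(family_ids) {
  f <- factor(family_ids)
  idx_by_fam <- split(seq_along(f), f)
  n <- length(f)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  d <- numeric(n)
  col <- 0L
  for (idx in idx_by_fam) {
    s <- length(idx)
    col <- col + 1L
    ii <- c(ii, idx); jj <- c(jj, rep(col, s)); xx <- c(xx, rep(1 / sqrt(s), s))
    d[col] <- s
    if (s > 1) {
      for (j in 2:s) {
        col <- col + 1L
        ii <- c(ii, idx[1:j])
        jj <- c(jj, rep(col, j))
        xx <- c(xx, c(rep(1, j - 1), -(j - 1)) / sqrt(j * (j - 1)))
        d[col] <- 0
      }
    }
  }
  U <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  list(U = U, d = d)
}

grouping_decomposition <- function(n, family = NULL, kinship = NULL) {
  if (!is.null(kinship)) {
    stopifnot(is.matrix(kinship), nrow(kinship) == n, ncol(kinship) == n)
    if (max(abs(kinship - t(kinship))) > 1e-8) abort("Kinship matrix must be symmetric.")
    eg <- eigen((kinship + t(kinship)) / 2, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
      abort("Kinship matrix must be positive semi-definite.")
    }
    list(U = eg$vectors, d = pmax(eg$values, 0))
  } else if (!is.null(family)) {
    stopifnot(length(family) == n)
    family_decomposition(family)
  } else {
    list(U = Matrix::Diagonal(n), d = rep(1, n))
  }
}

# negative REML profile criterion for one feature at variance ratio lambda
reml_neg <- function(lambda, d, Xs, ys) {
  v <- lambda * d + 1
  w <- 1 / v
  Xw <- Xs * w
  XtWX <- crossprod(Xw, Xs)
  XtWy <- crossprod(Xw, ys)
  R <- chol(XtWX)
  b <- backsolve(R, forwardsolve(t(R), XtWy))
  rss <- sum(ys^2 * w) - sum(b * XtWy)
  np <- length(ys) - ncol(Xs)
  np * log(max(rss / np, 1e-300)) + sum(log(v)) + 2 * sum(log(diag(R)))
}

lmm_beta_se <- function(lambda, d, Xs, ys, term = 2L) {
  v <- lambda * d + 1
  w <- 1 / v
  Xw <- Xs * w
  XtWX <- crossprod(Xw, Xs)
  XtWy <- crossprod(Xw, ys)
  XtWXi <- solve(XtWX)
  b <- XtWXi %*% XtWy
  rss <- sum(ys^2 * w) - sum(b * XtWy)
  np <- length(ys) - ncol(Xs)
  s2e <- rss / np
  list(beta = b[term, 1], se = sqrt(s2e * XtWXi[term, term]),
       sigma2_e = s2e, sigma2_g = lambda * s2e)
}

# vectorized REML criterion across features for one shared lambda
reml_neg_grid <- function(lambda, d, Xs, Ys) {
  v <- lambda * d + 1
  w <- 1 / v
  Xw <- Xs * w
  XtWX <- crossprod(Xw, Xs)
  R <- chol(XtWX)
  XtWY <- crossprod(Xw, Ys)
  B <- backsolve(R, forwardsolve(t(R), XtWY))
  rss <- colSums(Ys^2 * w) - colSums(B * XtWY)
  np <- nrow(Ys) - ncol(Xs)
  np * log(pmax(rss / np, 1e-300)) + sum(log(v)) + 2 * sum(log(diag(R)))
}

# Y: features x subjects; X: subjects x p design (term 2 = exposure of
# interest). Returns per-feature beta, se, Wald z / normal p, variance
# components. lambda_grid brackets the per-feature Brent refinement.
lmm_scan <- function(Y, X, family = NULL, kinship = NULL,
                     force_ols = FALSE,
                     lambda_grid = c(0, 10^seq(-3, 3, by = 0.25))) {
  Y <- rbind(Y)
  n <- ncol(Y)
  stopifnot(nrow(X) == n)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  dec <- grouping_decomposition(n, family = family, kinship = kinship)
  Xs <- as.matrix(Matrix::crossprod(dec$U, X))
  Ys <- as.matrix(Matrix::crossprod(dec$U, t(Y)))
  d <- dec$d
  m <- nrow(Y)

  if (force_ols || all(d == d[1])) {
    # constant eigenvalues (e.g. all-singleton families): GLS == OLS exactly
    lam_hat <- rep(0, m)
    fits <- lapply(seq_len(m), function(i) lmm_beta_se(0, d, Xs, Ys[, i]))
    conv <- rep(TRUE, m)
  } else {
    crit <- vapply(lambda_grid, function(l) reml_neg_grid(l, d, Xs, Ys),
                   numeric(m))
    crit <- rbind(crit)
    best <- apply(crit, 1, which.min)
    lam_hat <- numeric(m)
    conv <- rep(TRUE, m)
    fits <- vector("list", m)
    lg <- length(lambda_grid)
    for (i in seq_len(m)) {
      bi <- best[i]
      lo <- lambda_grid[max(1L, bi - 1L)]
      hi <- lambda_grid[min(lg, bi + 1L)]
      lam <- if (lo == hi) lo else {
        op <- optimize(reml_neg, c(lo, hi), d = d, Xs = Xs, ys = Ys[, i],
                       tol = 1e-6)
        # keep the boundary value if it beats the interior optimum (lambda = 0)
        if (bi == 1L && reml_neg(lambda_grid[1], d, Xs, Ys[, i]) <= op$objective)
          lambda_grid[1] else op$minimum
      }
      lam_hat[i] <- lam
      fits[[i]] <- lmm_beta_se(lam, d, Xs, Ys[, i])
    }
  }
  beta <- vapply(fits, `[[`, 0, "beta")
  se <- vapply(fits, `[[`, 0, "se")
  bad <- !is.finite(beta) | !is.finite(se) | se <= 0
  if (any(bad)) {
    for (i in which(bad)) {
      fits[[i]] <- lmm_beta_se(0, d, Xs, Ys[, i])
      lam_hat[i] <- 0
    }
    beta <- vapply(fits, `[[`, 0, "beta")
    se <- vapply(fits, `[[`, 0, "se")
    conv[bad] <- FALSE
  }
  z <- beta / se
  tibble::tibble(
    feature = rownames(Y) %||% as.character(seq_len(m)),
    beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
    n = n, converged = conv,
    sigma2_g = vapply(fits, `[[`, 0, "sigma2_g"),
    sigma2_e = vapply(fits, `[[`, 0, "sigma2_e"),
    lambda = lam_hat
  )
}

#' Mixed-model association of one feature with delta age
#'
#' Fits `y = beta * delta_age + X gamma + u + e` where `u` has family-block
#' (or kinship-proportional) covariance `sigma_g^2` and `e` is i.i.d.
#' `sigma_e^2`, by REML on the variance ratio after a single rotation by the
#' eigenvectors of the grouping covariance. The reported p is a two-sided
#' Wald test of `beta = 0`. With all subjects unrelated (or `force_ols`),
#' estimates coincide exactly with ordinary least squares.
#'
#' @param y numeric feature vector (one value per subject).
#' @param delta_age numeric exposure vector, years.
#' @param covariates data frame (or NULL) of adjustment columns; factors are
#'   expanded via [stats::model.matrix()]; constant columns are dropped.
#' @param family family identifiers (exchangeable within-family covariance).
#' @param kinship alternatively, an `n x n` symmetric PSD relatedness matrix.
#' @param force_ols force `sigma_g^2 = 0` (plain OLS).
#' @return A one-row tibble: `feature`, `beta`, `se`, `z`, `p`, `n`,
#'   `converged`, `sigma2_g`, `sigma2_e`, `lambda`.
#' @export
fit_feature_lmm <- function(y, delta_age, covariates = NULL,
                            family = NULL, kinship = NULL, force_ols = FALSE) {
  stopifnot(length(y) == length(delta_age))
  X <- build_design(delta_age, covariates, n = length(y))
  keep <- is.finite(y)
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    if (!is.null(family)) family <- family[keep]
    if (!is.null(kinship)) kinship <- kinship[keep, keep, drop = FALSE]
  }
  lmm_scan(matrix(y, 1), X, family = family, kinship = kinship,
           force_ols = force_ols)
}

# design: intercept, delta_age (term 2), then covariates
build_design <- function(delta_age, covariates, n) {
  X <- cbind(`(Intercept)` = 1, delta_age = delta_age)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    mm <- model.matrix(~., data = covariates)[, -1, drop = FALSE]
    const <- apply(mm, 2, function(col) var(col) == 0)
    mm <- mm[, !const, drop = FALSE]
    if (ncol(mm)) X <- cbind(X, mm)
  }
  X
}
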