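# Voxel-wise three-step mediation scan.

#' Standardized OLS coefficient with t-test
#'
#' All variables (outcome, predictor of interest, covariates) are z-scored
#' with the sample SD; the model is fitted by OLS with intercept and the
#' standardized coefficient of the predictor of interest is returned with its
#' two-sided t-test p-value.
#'
#' @param y outcome vector.
#' @param x predictor of interest.
#' @param covariates optional vector or matrix of covariates.
#' @return list with `beta_std`, `se`, `t`, `p`, `df`.
#' @export
standardized_ols <- function(y, x, covariates = NULL) {
  n <- length(y)
  if (length(x) != n) stop("length mismatch between y and x")
  Z <- cbind(1, zscore(x))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match n")
    Z <- cbind(Z, apply(covariates, 2, zscore))
  }
  if (n <= ncol(Z)) stop("too few observations for the design")
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("collinear design")
  zy <- zscore(y)
  beta <- qr.coef(qz, zy)
  res <- zy - Z %*% beta
  df <- n - ncol(Z)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qz))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- beta[2] / se
  list(beta_std = unname(beta[2]), se = unname(se), t = unname(tval),
       p = unname(2 * stats::pt(-abs(tval), df)), df = df)
}

# residualize the columns of M on design X (with intercept); returns residuals
resid_on <- function(M, X) {
  X <- cbind(1, X)
  M - X %*% qr.coef(qr(X), M)
}

#' Voxel-wise three-step mediation scan
#'
#' Tests, at every voxel of a ReHo stack, whether the voxel's regional
#' homogeneity mediates the gene-score -> trait association. The three steps
#' are: (1) X -> Y (once, globally), (2) X -> M per voxel (coefficient `a`),
#' (3) M -> Y controlling X per voxel (coefficient `b`). All regressions are
#' standardized OLS with gender as covariate. A voxel is flagged significant
#' only if all three p-values fall below `alpha` (a conservative
#' intersection with joint null rate `alpha^3`). The per-voxel mediation
#' effect is `a * b`.
#'
#' Per-voxel coefficients are computed by Frisch--Waugh partialling, which is
#' algebraically identical to running [standardized_ols] at each voxel.
#'
#' @param X gene-score vector (length n).
#' @param Y trait vector (length n).
#' @param gender covariate vector (length n).
#' @param reho_stack n x V matrix of per-subject voxel values.
#' @param alpha per-step significance level (default 0.05).
#' @return object of class `mediation_map`: list with per-voxel `a`, `p_a`,
#'   `b`, `p_b`, `ab`, logical `sig`, global `c`, `p_c`, `alpha`, `n`.
#' @export
mediation_scan <- function(X, Y, gender, reho_stack, alpha = 0.05) {
  n <- length(X)
  reho_stack <- as.matrix(reho_stack)
  if (nrow(reho_stack) != n) stop("reho_stack must have one row per subject")
  V <- ncol(reho_stack)
  zx <- zscore(X); zy <- zscore(Y); zg <- zscore(gender)

  step1 <- standardized_ols(Y, X, gender)

  # standardize voxels; constant voxels are flagged and excluded
  sds <- apply(reho_stack, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  ZM <- sweep(sweep(reho_stack, 2, colMeans(reho_stack)), 2,
              ifelse(const, 1, sds), "/")

  # a-path: zm ~ zx + zg.  Partial out [1, zg] from both sides.
  ex <- resid_on(matrix(zx), matrix(zg))
  EM <- resid_on(ZM, matrix(zg))
  sxx <- sum(ex^2)
  a <- drop(crossprod(ex, EM)) / sxx
  res_a <- EM - ex %*% rbind(a)
  df_a <- n - 3
  se_a <- sqrt(colSums(res_a^2) / df_a / sxx)
  p_a <- 2 * stats::pt(-abs(a / se_a), df_a)

  # b-path: zy ~ zx + zm + zg.  Partial out [1, zx, zg] from zy and zm.
  D <- cbind(zx, zg)
  ey <- resid_on(matrix(zy), D)
  EM2 <- resid_on(ZM, D)
  smm <- colSums(EM2^2)
  smm[smm == 0] <- NA_real_
  b <- drop(crossprod(ey, EM2)) / smm
  rss <- drop(sum(ey^2) - b^2 * smm)
  df_b <- n - 4
  se_b <- sqrt(rss / df_b / smm)
  p_b <- 2 * stats::pt(-abs(b / se_b), df_b)

  a[const] <- 0; b[const] <- 0
  p_a[const | !is.finite(p_a)] <- 1
  p_b[const | !is.finite(p_b)] <- 1
  b[!is.finite(b)] <- 0

  sig <- step1$p < alpha & p_a < alpha & p_b < alpha
  structure(list(a = a, p_a = p_a, b = b, p_b = p_b, ab = a * b,
                 sig = sig, c = step1$beta_std, p_c = step1$p,
                 alpha = alpha, n = n, n_voxels = V),
            class = "mediation_map")
}

#' @export
print.mediation_map <- function(x, ...) {
  cat(sprintf("<mediation_map> %d voxels, n = %d; step 1: c = %.3f (p = %.3g); %d significant voxel(s) at alpha = %g per step\n",
              x$n_voxels, x$n, x$c, x$p_c, sum(x$sig), x$alpha))
  invisible(x)
}
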