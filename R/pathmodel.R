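# ROI-level path (mediation/suppression) model and its methods.

#' Mean ReHo over a cluster mask
#'
#' Arithmetic mean over the member voxels of a cluster, per subject.
#'
#' @param map_stack subjects x voxels matrix (columns = in-analysis voxels).
#' @param cluster_mask logical vector or column indices selecting member
#'   voxels.
#' @return per-subject mean vector.
#' @export
extract_roi_mean <- function(map_stack, cluster_mask) {
  map_stack <- as.matrix(map_stack)
  cols <- if (is.logical(cluster_mask)) which(cluster_mask) else cluster_mask
  if (!length(cols)) stop("empty cluster mask")
  if (max(cols) > ncol(map_stack)) stop("cluster mask exceeds analyzed voxels")
  rowMeans(map_stack[, cols, drop = FALSE])
}

#' Fit the ROI-level path model
#'
#' Single-mediator path model with covariates, fitted by standardized OLS:
#' \deqn{M = a X + (covariates), \quad Y = c' X + b M + (covariates),
#'       \quad Y = c X + (covariates)}
#' All coefficients are standardized regression weights; the indirect effect
#' is `ab = a * b`, the decomposition `c = c' + ab` holds to machine
#' precision, and the suppression/mediation ratio is `100 * ab / c` (percent
#' of the total effect). `r2_y` is the squared multiple correlation of the
#' full outcome equation.
#'
#' The model can be specified with a formula, `outcome ~ exposure + covariates`
#' with the mediator named separately, e.g.
#' `path_model(sps ~ gene_score + gender, mediator = "reho_pcc", data = d)`:
#' the first right-hand term is the exposure, the rest are covariates.
#'
#' @param formula model formula `outcome ~ exposure (+ covariates)`.
#' @param mediator column name (in `data`) or numeric vector for the
#'   mediator.
#' @param data data frame holding the variables.
#' @return an object of class `path_model` with components `paths` (a data
#'   frame of standardized coefficients, SEs and p-values), `ab`,
#'   `suppression_pct`, `r2_y`, `effect_type`, the unstandardized outcome fit
#'   used by [predict.path_model()], and the model frame.
#' @seealso [classify_effect()], [bootstrap_paths()], [loo_validate()]
#' @export
path_model <- function(formula, mediator, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  yname <- all.vars(formula[[2]])
  rhs <- attr(stats::terms(formula), "term.labels")
  if (!length(rhs)) stop("formula needs at least an exposure term")
  xname <- rhs[1]
  covnames <- rhs[-1]
  mname <- if (is.character(mediator)) mediator else deparse(substitute(mediator))
  M <- if (is.character(mediator)) {
    if (!mediator %in% names(data)) stop("mediator column '", mediator, "' not in data")
    data[[mediator]]
  } else as.numeric(mediator)
  Y <- mf[[yname]]
  X <- mf[[xname]]
  covs <- if (length(covnames)) as.matrix(mf[covnames]) else NULL
  fit <- fit_paths(X, M, Y, covs, xname = xname, mname = mname,
                   covnames = covnames)
  n <- length(Y)
  if (n < 10) stop("path model needs at least 10 complete cases")

  # unstandardized outcome equation (with intercept) for prediction
  df_out <- data.frame(Y = Y, X = X, M = M)
  if (!is.null(covs)) df_out <- cbind(df_out, as.data.frame(covs))
  lm_y <- stats::lm(Y ~ ., data = df_out)

  structure(c(fit, list(
    call = match.call(), n = n,
    vars = list(y = yname, x = xname, m = mname, covariates = covnames),
    lm_y = lm_y, frame = df_out)),
    class = "path_model")
}

# core standardized estimation shared by the fit, the bootstrap and LOO;
# X, M, Y vectors, covs NULL or matrix
fit_paths <- function(X, M, Y, covs = NULL, xname = "X", mname = "M",
                      covnames = NULL) {
  fa <- standardized_ols(M, X, covs)
  # outcome equation: need coefficients of both X and M
  fb <- standardized_ols(Y, M, cbind(X, covs))
  fcp <- standardized_ols(Y, X, cbind(M, covs))
  fc <- standardized_ols(Y, X, covs)
  ab <- fa$beta_std * fb$beta_std
  paths <- data.frame(
    path = c("a (X->M)", "b (M->Y|X)", "c' (X->Y|M)", "c (X->Y)"),
    estimate = c(fa$beta_std, fb$beta_std, fcp$beta_std, fc$beta_std),
    se = c(fa$se, fb$se, fcp$se, fc$se),
    t = c(fa$t, fb$t, fcp$t, fc$t),
    p = c(fa$p, fb$p, fcp$p, fc$p))
  # covariate (e.g. gender) paths in the two structural equations
  if (!is.null(covs)) {
    for (j in seq_len(ncol(covs))) {
      cn <- covnames[j] %||% paste0("cov", j)
      others <- covs[, -j, drop = FALSE]
      gm <- standardized_ols(M, covs[, j], cbind(X, others))
      gy <- standardized_ols(Y, covs[, j], cbind(X, M, others))
      paths <- rbind(paths, data.frame(
        path = paste0(cn, c(" (->M)", " (->Y)")),
        estimate = c(gm$beta_std, gy$beta_std),
        se = c(gm$se, gy$se), t = c(gm$t, gy$t), p = c(gm$p, gy$p)))
    }
  }
  # R^2 of the full (standardized) outcome equation
  zy <- zscore(Y)
  D <- cbind(1, zscore(X), zscore(M))
  if (!is.null(covs)) D <- cbind(D, apply(covs, 2, zscore))
  res <- zy - D %*% qr.coef(qr(D), zy)
  r2_y <- 1 - sum(res^2) / sum(zy^2)
  list(paths = paths, a = fa$beta_std, b = fb$beta_std,
       c_prime = fcp$beta_std, c = fc$beta_std, ab = ab,
       suppression_pct = 100 * ab / fc$beta_std, r2_y = r2_y,
       p_a = fa$p, p_b = fb$p, p_c = fc$p, p_c_prime = fcp$p)
}

#' Classify the indirect effect
#'
#' Suppression when the indirect (`ab`) and direct (`c'`) effects have
#' opposite signs (the total effect is smaller in magnitude than the direct
#' effect, so adjusting for the mediator strengthens the X--Y association);
#' mediation when they share a sign and both constituent paths are
#' significant; otherwise none.
#'
#' @param fit a `path_model`.
#' @param alpha significance level for the constituent paths (default 0.05).
#' @return one of `"suppression"`, `"mediation"`, `"none"`.
#' @export
classify_effect <- function(fit, alpha = 0.05) {
  if (fit$p_a >= alpha || fit$p_b >= alpha) return("none")
  if (sign(fit$ab) == -sign(fit$c_prime) && fit$ab != 0) "suppression"
  else if (sign(fit$ab) == sign(fit$c_prime)) "mediation"
  else "none"
}

#' Bootstrap confidence intervals for the path model
#'
#' Nonparametric case resampling: subjects are drawn with replacement,
#' the standardized path model is refitted per resample, and percentile
#' (default) or bias-corrected percentile intervals are formed for every
#' path and for the indirect effect `ab`. Resamples in which any variable is
#' degenerate (zero variance, e.g. a single-gender draw) are redrawn and
#' counted; a warning is given if more than 1% of draws were redrawn.
#'
#' @param fit a `path_model`.
#' @param n_boot number of resamples (default 5000).
#' @param ci_level confidence level (default 0.95).
#' @param type `"percentile"` or `"bc"` (bias-corrected).
#' @param seed RNG seed.
#' @return object of class `path_boot`: list with `ci` (data frame), the
#'   resampled draws, `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_paths <- function(fit, n_boot = 5000, ci_level = 0.95,
                            type = c("percentile", "bc"), seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  fr <- fit$frame
  n <- nrow(fr)
  covnames <- fit$vars$covariates
  X <- fr$X; M <- fr$M; Y <- fr$Y
  covs <- if (length(covnames)) as.matrix(fr[covnames]) else NULL
  draws <- matrix(NA_real_, n_boot, 5,
                  dimnames = list(NULL, c("a", "b", "c_prime", "c", "ab")))
  n_redrawn <- 0L
  for (bb in seq_len(n_boot)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      ok <- stats::sd(X[i]) > 0 && stats::sd(M[i]) > 0 && stats::sd(Y[i]) > 0 &&
        (is.null(covs) || all(apply(covs[i, , drop = FALSE], 2, stats::sd) > 0))
      if (ok) break
      n_redrawn <- n_redrawn + 1L
    }
    f <- fit_paths_fast(X[i], M[i], Y[i],
                        if (is.null(covs)) NULL else covs[i, , drop = FALSE])
    draws[bb, ] <- c(f$a, f$b, f$c_prime, f$c, f$a * f$b)
  }
  if (n_redrawn > 0.01 * n_boot)
    warning(sprintf("%d degenerate resamples redrawn (> 1%% of draws)", n_redrawn))
  alpha2 <- (1 - ci_level) / 2
  est <- c(a = fit$a, b = fit$b, c_prime = fit$c_prime, c = fit$c, ab = fit$ab)
  ci <- t(vapply(colnames(draws), function(nm) {
    v <- draws[, nm]
    if (type == "bc") {
      z0 <- stats::qnorm(mean(v < est[nm]))
      lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha2))
      hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha2))
      stats::quantile(v, c(lo, hi), names = FALSE, type = 6)
    } else stats::quantile(v, c(alpha2, 1 - alpha2), names = FALSE, type = 6)
  }, numeric(2)))
  out <- data.frame(term = rownames(ci), estimate = unname(est),
                    lower = ci[, 1], upper = ci[, 2])
  rownames(out) <- NULL
  structure(list(ci = out, draws = draws, n_boot = n_boot,
                 ci_level = ci_level, type = type, n_redrawn = n_redrawn),
            class = "path_boot")
}

# minimal standardized refit (a, b, c', c only) used inside bootstrap loops
fit_paths_fast <- function(X, M, Y, covs = NULL) {
  zx <- zscore(X); zm <- zscore(M); zy <- zscore(Y)
  ZC <- if (is.null(covs)) NULL else apply(covs, 2, zscore)
  ba <- qr.coef(qr(cbind(1, zx, ZC)), zm)
  bo <- qr.coef(qr(cbind(1, zx, zm, ZC)), zy)
  bc <- qr.coef(qr(cbind(1, zx, ZC)), zy)
  list(a = unname(ba[2]), b = unname(bo[3]), c_prime = unname(bo[2]),
       c = unname(bc[2]))
}

#' @export
print.path_boot <- function(x, ...) {
  cat(sprintf("Bootstrap %s CIs (%d resamples, level %.2f)\n",
              x$type, x$n_boot, x$ci_level))
  print(x$ci, digits = 4)
  invisible(x)
}

#' Leave-one-out validation of the outcome equation
#'
#' For each subject, the unstandardized outcome equation
#' `Y ~ X + M + covariates` (with intercept) is refitted on the remaining
#' subjects and used to predict the held-out subject's score; the summary
#' statistic is the Pearson correlation between predicted and observed
#' scores.
#'
#' @param fit a `path_model`.
#' @return list with `predicted`, `observed`, and `r`.
#' @export
loo_validate <- function(fit) {
  fr <- fit$frame
  n <- nrow(fr)
  D <- stats::model.matrix(~ ., data = fr[setdiff(names(fr), "Y")])
  Y <- fr$Y
  pred <- vapply(seq_len(n), function(i) {
    beta <- qr.coef(qr(D[-i, , drop = FALSE]), Y[-i])
    drop(D[i, ] %*% beta)
  }, numeric(1))
  list(predicted = pred, observed = Y, r = stats::cor(pred, Y))
}

#' Cohort descriptive statistics for the trait
#'
#' Per-gender mean, SD (n-1), skewness and excess kurtosis with small-sample
#' corrections (the legacy statistical-package convention; `corrected =
#' FALSE` gives the simple moment estimators), a one-sample
#' Kolmogorov--Smirnov test against a normal with sample-estimated mean and
#' SD reported as `Z = sqrt(n) * D` with the asymptotic Kolmogorov p-value
#' (the classical test, not the Lilliefors-corrected one -- with estimated
#' parameters the p-value is conservative), and a pooled-variance two-sample
#' t-test across gender.
#'
#' @param y trait vector.
#' @param gender 0/1 vector.
#' @param corrected use small-sample-corrected moment estimators.
#' @return list with a per-group data frame `by_gender`, overall `mean` and
#'   `sd`, and `t_test` (`NULL` with a warning for single-gender input).
#' @export
describe_phenotype <- function(y, gender, corrected = TRUE) {
  stats_one <- function(v) {
    n <- length(v)
    m <- mean(v); s <- stats::sd(v)
    z <- (v - m) / s
    if (corrected && n > 3) {
      g1 <- n / ((n - 1) * (n - 2)) * sum(z^3)
      g2 <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
        3 * (n - 1)^2 / ((n - 2) * (n - 3))
    } else {
      g1 <- mean(z^3)
      g2 <- mean(z^4) - 3
    }
    D <- suppressWarnings(stats::ks.test(v, "pnorm", m, s)$statistic)
    Z <- sqrt(n) * D
    list(n = n, mean = m, sd = s, skewness = g1, kurtosis = g2,
         ks_z = unname(Z), ks_p = kolmogorov_p(Z))
  }
  groups <- sort(unique(gender))
  by_gender <- do.call(rbind, lapply(groups, function(gv) {
    as.data.frame(c(gender = gv, stats_one(y[gender == gv])))
  }))
  tt <- NULL
  if (length(groups) >= 2) {
    tt <- stats::t.test(y[gender == groups[1]], y[gender == groups[2]],
                        var.equal = TRUE)
  } else warning("single-gender input: t-test omitted")
  list(by_gender = by_gender, mean = mean(y), sd = stats::sd(y), t_test = tt)
}

# asymptotic Kolmogorov distribution tail: Q(z) = 2 sum (-1)^{k-1} exp(-2 k^2 z^2)
kolmogorov_p <- function(z) {
  if (z < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
  min(max(p, 0), 1)
}

# --- methods ---------------------------------------------------------------

#' @export
print.path_model <- function(x, digits = 3, ...) {
  cat("Path (mediation/suppression) model\n")
  cat(sprintf("  n = %d;  %s ~ %s with mediator %s\n", x$n, x$vars$y,
              paste(c(x$vars$x, x$vars$covariates), collapse = " + "),
              x$vars$m))
  cat(sprintf("  a = %.*f, b = %.*f, c' = %.*f, c = %.*f, ab = %.*f\n",
              digits, x$a, digits, x$b, digits, x$c_prime, digits, x$c,
              digits + 1, x$ab))
  cat(sprintf("  indirect/total = %.2f%%  (%s);  outcome R^2 = %.3f\n",
              x$suppression_pct, classify_effect(x), x$r2_y))
  invisible(x)
}

#' @export
summary.path_model <- function(object, ...) {
  structure(list(fit = object), class = "summary.path_model")
}

#' @export
print.summary.path_model <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nStandardized paths:\n")
  print(f$paths, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.path_model <- function(object, ...) {
  c(a = object$a, b = object$b, c_prime = object$c_prime, c = object$c,
    ab = object$ab)
}

#' @export
#' @param parm which terms (subset of `a, b, c_prime, c, ab`).
#' @param level confidence level.
#' @param n_boot,type,seed passed to [bootstrap_paths()].
#' @rdname bootstrap_paths
confint.path_model <- function(object, parm, level = 0.95, n_boot = 5000,
                               type = "percentile", seed = NULL, ...) {
  bs <- bootstrap_paths(object, n_boot = n_boot, ci_level = level,
                        type = type, seed = seed)
  ci <- bs$ci
  m <- as.matrix(ci[, c("lower", "upper")])
  rownames(m) <- ci$term
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
predict.path_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm_y))
  nd <- newdata
  nm <- object$vars
  if (!"X" %in% names(nd) && nm$x %in% names(nd)) nd$X <- nd[[nm$x]]
  if (!"M" %in% names(nd) && nm$m %in% names(nd)) nd$M <- nd[[nm$m]]
  stats::predict(object$lm_y, newdata = nd)
}

#' @export
residuals.path_model <- function(object, ...) stats::residuals(object$lm_y)

#' @export
fitted.path_model <- function(object, ...) stats::fitted(object$lm_y)

#' @export
simulate.path_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  covnames <- object$vars$covariates
  covs <- if (length(covnames)) as.matrix(fr[covnames]) else NULL
  lm_m <- stats::lm(M ~ . - Y, data = fr)
  sd_m <- stats::sd(stats::residuals(lm_m))
  sd_y <- stats::sd(stats::residuals(object$lm_y))
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    nd <- fr
    nd$M <- stats::fitted(lm_m) + stats::rnorm(nrow(fr), 0, sd_m)
    nd$Y <- stats::predict(object$lm_y, newdata = nd) +
      stats::rnorm(nrow(fr), 0, sd_y)
    out[[s]] <- nd
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.path_model <- function(x, digits = 3, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 10), ylim = c(0, 6), asp = NA)
  box_at <- function(cx, cy, lab) {
    graphics::rect(cx - 1.4, cy - 0.5, cx + 1.4, cy + 0.5)
    graphics::text(cx, cy, lab)
  }
  star <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else ""
  box_at(2, 1.5, x$vars$x)
  box_at(8, 1.5, x$vars$y)
  box_at(5, 4.5, x$vars$m)
  graphics::arrows(3.0, 2.0, 4.2, 4.1, length = 0.1)
  graphics::arrows(5.8, 4.1, 7.0, 2.0, length = 0.1)
  graphics::arrows(3.4, 1.5, 6.6, 1.5, length = 0.1)
  graphics::text(3.1, 3.2, sprintf("a = %.*f%s", digits, x$a, star(x$p_a)), adj = 1)
  graphics::text(6.9, 3.2, sprintf("b = %.*f%s", digits, x$b, star(x$p_b)), adj = 0)
  graphics::text(5, 1.15, sprintf("c' = %.*f%s   (c = %.*f%s)", digits,
                                  x$c_prime, star(x$p_c_prime), digits, x$c,
                                  star(x$p_c)))
  graphics::title(sprintf("%s: ab = %.*f (%.2f%% of total), R² = %.3f",
                          classify_effect(x), digits + 1, x$ab,
                          x$suppression_pct, x$r2_y))
  invisible(x)
}
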