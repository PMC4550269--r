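test_that("standardized OLS matches the closed-form normal equations", {
  # 6-point toy dataset, solved by hand via solve(t(X)X) on z-scored data
  y <- c(2.1, 3.0, 4.2, 3.9, 5.5, 6.0)
  x <- c(1, 2, 3, 4, 5, 6)
  g <- c(0, 1, 0, 1, 0, 1)
  zs <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(1, zs(x), zs(g))
  beta <- solve(crossprod(X), crossprod(X, zs(y)))
  res <- zs(y) - X %*% beta
  se <- sqrt(drop(crossprod(res)) / 3 * solve(crossprod(X))[2, 2])
  fit <- standardized_ols(y, x, g)
  expect_equal(fit$beta_std, beta[2], tolerance = 1e-10)
  expect_equal(fit$t, beta[2] / se, tolerance = 1e-10)
  expect_equal(fit$p, 2 * pt(-abs(beta[2] / se), 3), tolerance = 1e-10)
})

test_that("standardized OLS endpoints: identity slope 1, orthogonal slope 0", {
  x <- rnorm(50, 10, 3)
  f <- standardized_ols(x, x)
  expect_equal(f$beta_std, 1, tolerance = 1e-12)
  expect_lt(f$p, 1e-12)
  set.seed(10)
  y0 <- rnorm(100)
  x0 <- rnorm(100)
  y0 <- y0 - x0 * sum(y0 * (x0 - mean(x0))) / sum((x0 - mean(x0))^2)
  y0 <- residuals(lm(y0 ~ x0))  # exact orthogonalization
  expect_lt(abs(standardized_ols(y0, x0)$beta_std), 1e-10)
  expect_error(standardized_ols(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("mediation scan equals per-voxel standardized OLS (exhaustive 4x4x4)", {
  set.seed(12)
  n <- 40; V <- 64
  X <- rnorm(n); G <- rbinom(n, 1, 0.4); Y <- 0.5 * X + rnorm(n)
  stack <- matrix(rnorm(n * V), n, V)
  stack[, 5] <- -0.4 * X + rnorm(n, 0, 0.5)
  scan <- mediation_scan(X, Y, G, stack)
  for (v in seq_len(V)) {
    fa <- standardized_ols(stack[, v], X, G)
    fb <- standardized_ols(Y, stack[, v], cbind(X, G))
    expect_equal(scan$a[v], fa$beta_std, tolerance = 1e-10)
    expect_equal(scan$p_a[v], fa$p, tolerance = 1e-10)
    expect_equal(scan$b[v], fb$beta_std, tolerance = 1e-10)
    expect_equal(scan$p_b[v], fb$p, tolerance = 1e-10)
    expect_equal(scan$ab[v], fa$beta_std * fb$beta_std, tolerance = 1e-10)
  }
  s1 <- standardized_ols(Y, X, G)
  expect_equal(scan$c, s1$beta_std)
  expect_equal(scan$p_c, s1$p)
})

test_that("a constant voxel is flagged non-significant, not an error", {
  set.seed(13)
  n <- 30
  stack <- matrix(rnorm(n * 3), n, 3)
  stack[, 2] <- 1
  scan <- mediation_scan(rnorm(n), rnorm(n), rbinom(n, 1, 0.5), stack)
  expect_false(scan$sig[2])
  expect_equal(scan$ab[2], 0)
})

test_that("the three-way conjunction gates on the global first step", {
  set.seed(14)
  n <- 200
  X <- rnorm(n); Y <- rnorm(n); G <- rbinom(n, 1, 0.3)
  # force step 1 non-significant by orthogonalizing Y against X and gender
  Y <- residuals(lm(Y ~ X + G))
  stack <- matrix(rnorm(n * 50), n, 50)
  stack[, 1] <- X + rnorm(n, 0, 0.1)          # strong a path
  stack[, 2] <- Y + rnorm(n, 0, 0.1)          # strong b path
  scan <- mediation_scan(X, Y, G, stack)
  expect_gte(scan$p_c, 0.05)
  expect_equal(sum(scan$sig), 0)
})

test_that("planted-cluster scan concentrates hits in the cluster with few false positives", {
  # With the planted total effect, step 1 is essentially always significant,
  # so the out-of-cluster joint rate is bounded by alpha^2 = 0.0025.
  V <- 4000; cluster <- 1:20
  hits_out <- 0; hits_in <- 0; n_out <- 0
  for (r in 1:5) {
    ps <- planted_stack(298, V, cluster, seed = r)
    scan <- mediation_scan(ps$X, ps$Y, ps$gender, ps$stack)
    hits_in <- hits_in + sum(scan$sig[cluster])
    hits_out <- hits_out + sum(scan$sig[-cluster])
    n_out <- n_out + (V - length(cluster))
  }
  expect_gt(hits_in / (5 * 20), 0.9)
  expect_lte(hits_out, qbinom(0.999, n_out, 0.0025))
})

test_that("shuffled gene scores flag voxels at the joint null rate", {
  set.seed(16)
  n <- 150; V <- 800; reps <- 40
  total <- 0
  for (r in 1:reps) {
    X <- rnorm(n); Y <- rnorm(n); G <- rbinom(n, 1, 0.32)
    scan <- mediation_scan(X, Y, G, matrix(rnorm(n * V), n, V))
    total <- total + sum(scan$sig)
  }
  # observed count within a 99% binomial band around rate alpha^3
  expect_lte(total, qbinom(0.995, reps * V, 0.000125))
})

test_that("cluster labeling handles isolated voxels, blocks and diagonal contact", {
  d <- c(6, 6, 6)
  m <- array(FALSE, d); m[1, 1, 1] <- TRUE; m[6, 6, 6] <- TRUE
  tab <- label_clusters(m)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$size_vox, c(1L, 1L))

  blk <- array(FALSE, d); blk[2:3, 2:3, 2:3] <- TRUE
  for (conn in c(6, 18, 26)) {
    tb <- label_clusters(blk, conn)
    expect_equal(nrow(tb), 1)
    expect_equal(tb$size_vox, 8L)
  }

  diag2 <- array(FALSE, d); diag2[2, 2, 2] <- TRUE; diag2[3, 3, 3] <- TRUE
  expect_equal(nrow(label_clusters(diag2, 26)), 1)
  expect_equal(nrow(label_clusters(diag2, 6)), 2)

  empty <- label_clusters(array(FALSE, d))
  expect_equal(nrow(empty), 0)
})

test_that("cluster peaks maximise |value| and map through the affine", {
  d <- c(5, 5, 5)
  m <- array(FALSE, d); m[2:4, 3, 3] <- TRUE
  vals <- array(0, d); vals[2, 3, 3] <- 0.1; vals[3, 3, 3] <- -0.9; vals[4, 3, 3] <- 0.2
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-6, -6, -6)
  tab <- label_clusters(m, values = vals, affine = aff, voxel_mm = c(3, 3, 3))
  expect_equal(tab$peak_value, -0.9)
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z), c(0, 0, 0))
  expect_equal(tab$size_mm3, 3 * 27)
})

test_that("Monte-Carlo threshold honours its degenerate and independent-voxel limits", {
  one <- cluster_threshold_mc(200, fwhm = 0, voxel_p = 1, n_iter = 5,
                              sided = 1, seed = 1)
  expect_equal(one$threshold, 200L)
  iso <- cluster_threshold_mc(10000, fwhm = 0, voxel_p = 0.001, n_iter = 300,
                              connectivity = 6, seed = 2)
  expect_lte(iso$threshold, 2L)
})

test_that("Monte-Carlo threshold is monotone in smoothness and voxel threshold", {
  t_lo <- cluster_threshold_mc(6000, fwhm = 3, voxel_p = 0.001, n_iter = 300,
                               seed = 3)$threshold
  t_hi <- cluster_threshold_mc(6000, fwhm = 9, voxel_p = 0.001, n_iter = 300,
                               seed = 3)$threshold
  expect_gte(t_hi, t_lo)
  p_lo <- cluster_threshold_mc(6000, fwhm = 6, voxel_p = 1e-4, n_iter = 300,
                               seed = 4)$threshold
  p_hi <- cluster_threshold_mc(6000, fwhm = 6, voxel_p = 5e-3, n_iter = 300,
                               seed = 4)$threshold
  expect_gte(p_hi, p_lo)
})

test_that("permutation threshold: null ceiling, exchangeability, degenerate quantile", {
  set.seed(17)
  n <- 80; d <- c(8, 8, 8); V <- prod(d)
  mask <- array(TRUE, d)
  pool <- gen_genotypes(n = n, maf = seq(0.05, 0.5, length.out = 98),
                        locus_prefix = "P", seed = 18)
  Y <- rnorm(n); G <- rbinom(n, 1, 0.32)
  stack <- matrix(rnorm(n * V), n, V)
  pt <- cluster_threshold_perm(pool, Y, G, stack, mask, n_perm = 200, seed = 19)
  expect_lte(pt$threshold, 3L)

  # planting signal driven by loci NOT in the pool leaves the null threshold alone
  truth <- gen_genotypes(n = n, maf = rep(0.3, 10), locus_prefix = "T", seed = 20)
  score_true <- compute_gene_score(truth, setNames(rep(1, 10), colnames(truth)))
  stack2 <- stack
  stack2[, 1:12] <- stack2[, 1:12] - 0.5 * scale(score_true)[, 1]
  Y2 <- Y + 0.4 * scale(score_true)[, 1]
  pt2 <- cluster_threshold_perm(pool, Y2, G, stack2, mask, n_perm = 200, seed = 19)
  expect_lte(abs(pt2$threshold - pt$threshold), 1L)

  expect_equal(cluster_threshold_perm(pool, Y, G, stack, mask, n_perm = 120,
                                      alpha = 1, seed = 21)$threshold, 0L)
})

test_that("permutation and Monte-Carlo thresholds agree on matched smooth null data", {
  set.seed(22)
  n <- 60; d <- c(12, 12, 12); V <- prod(d)
  mask <- array(TRUE, d)
  fwhm <- 6
  stack <- t(vapply(seq_len(n), function(i)
    as.vector(gaussian_smooth(array(rnorm(V), d), fwhm, voxel_mm = c(3, 3, 3))),
    numeric(V)))
  pool <- gen_genotypes(n = n, maf = seq(0.05, 0.5, length.out = 98),
                        locus_prefix = "P", seed = 23)
  Y <- rnorm(n); G <- rbinom(n, 1, 0.32)
  est <- estimate_fwhm(lapply(1:4, function(i) array(stack[i, ], d)),
                       mask, c(3, 3, 3))
  # the permutation scan thresholds at the joint rate, so match voxel_p to it
  pt <- cluster_threshold_perm(pool, Y, G, stack, mask, n_perm = 250, seed = 24)
  mc <- cluster_threshold_mc(V, fwhm = est, voxel_p = 0.05^3, n_iter = 500,
                             seed = 25)
  expect_lte(abs(pt$threshold - mc$threshold), 2L)
})
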