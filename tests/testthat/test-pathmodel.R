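test_that("ROI mean extraction is the arithmetic mean over member voxels", {
  stack <- rbind(c(1, 2, 6), c(2, 4, 12))
  expect_equal(extract_roi_mean(stack, 1:3), c(3, 6))
  expect_equal(extract_roi_mean(stack, 2), stack[, 2])
  expect_equal(extract_roi_mean(matrix(5, 4, 3), c(TRUE, TRUE, TRUE)), rep(5, 4))
  expect_error(extract_roi_mean(stack, integer(0)), "empty")
})

test_that("path model recovers exact standardized structure a=-0.3, b=0.5, c'=0.4", {
  # data built on a sample-orthonormal basis so the standardized structural
  # coefficients hold exactly in-sample, not just in expectation
  set.seed(30)
  n <- 120
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4] * sqrt(n - 1)
  X <- Q[, 1]
  M <- -0.3 * X + sqrt(1 - 0.3^2) * Q[, 2]
  Y <- 0.4 * X + 0.5 * M + sqrt(0.71) * Q[, 3]  # var(Y) = 1 exactly
  fit <- path_model(y ~ x, mediator = "m", data = data.frame(y = Y, x = X, m = M))
  expect_equal(fit$a, -0.3, tolerance = 1e-10)
  expect_equal(fit$b, 0.5, tolerance = 1e-10)
  expect_equal(fit$c_prime, 0.4, tolerance = 1e-10)
  expect_equal(fit$c, 0.25, tolerance = 1e-10)
  expect_equal(fit$suppression_pct, 100 * (-0.15) / 0.25, tolerance = 1e-8)
  expect_equal(fit$r2_y, 0.29, tolerance = 1e-10)
})

test_that("c = c' + ab holds to machine precision on arbitrary data", {
  for (r in 1:25) {
    set.seed(r)
    n <- 30 + r
    d <- data.frame(y = rnorm(n), x = rnorm(n), g = rbinom(n, 1, 0.5),
                    m = rnorm(n))
    fit <- path_model(y ~ x + g, mediator = "m", data = d)
    expect_lt(abs(fit$c - (fit$c_prime + fit$ab)), 1e-10)
    expect_gte(fit$r2_y, 0); expect_lte(fit$r2_y, 1)
  }
})

test_that("an independent mediator leaves the total effect direct", {
  set.seed(31)
  n <- 10000
  X <- rnorm(n); M <- rnorm(n); g <- rbinom(n, 1, 0.3)
  Y <- 0.4 * X + rnorm(n)
  fit <- path_model(y ~ x + g, mediator = "m",
                    data = data.frame(y = Y, x = X, g = g, m = M))
  expect_lt(abs(fit$a), 3 / sqrt(n) * 2)
  expect_lt(abs(fit$b), 3 / sqrt(n) * 2)
  expect_equal(fit$c, fit$c_prime, tolerance = 0.01)
  expect_lt(abs(fit$suppression_pct), 2)
})

test_that("effect classification follows the sign and significance rules", {
  d <- synthetic_s1_cohort(seed = 2)
  fit <- path_model(sps_total ~ gene_score + gender, mediator = "reho_pcc",
                    data = d)
  expect_equal(classify_effect(fit), "suppression")
  # a same-sign indirect path with significant constituents -> mediation
  set.seed(37)
  n2 <- 2000
  X2 <- rnorm(n2); M2 <- 0.3 * X2 + rnorm(n2)
  Y2 <- 0.4 * X2 + 0.5 * M2 + rnorm(n2)
  fit2 <- path_model(y ~ x, mediator = "m",
                     data = data.frame(y = Y2, x = X2, m = M2))
  expect_equal(classify_effect(fit2), "mediation")
  # destroy the b path -> none
  set.seed(32)
  d3 <- d; d3$reho_pcc <- rnorm(nrow(d))
  fit3 <- path_model(sps_total ~ gene_score + gender, mediator = "reho_pcc",
                     data = d3)
  expect_equal(classify_effect(fit3), "none")
})

test_that("bootstrap CIs are deterministic under a seed and shrink with n", {
  d <- synthetic_s1_cohort(seed = 3)
  fit <- path_model(sps_total ~ gene_score + gender, mediator = "reho_pcc",
                    data = d)
  b1 <- bootstrap_paths(fit, n_boot = 400, seed = 99)
  b2 <- bootstrap_paths(fit, n_boot = 400, seed = 99)
  expect_identical(b1$ci, b2$ci)

  make_noiseless <- function(n) {
    X <- rnorm(n); M <- 0.5 * X + 0.1 * rnorm(n); Y <- 0.3 * X + 0.4 * M
    data.frame(y = Y, x = X, m = M)
  }
  set.seed(33)
  f50 <- path_model(y ~ x, mediator = "m", data = make_noiseless(50))
  f1000 <- path_model(y ~ x, mediator = "m", data = make_noiseless(1000))
  w50 <- with(bootstrap_paths(f50, 300, seed = 1)$ci, upper - lower)
  w1000 <- with(bootstrap_paths(f1000, 300, seed = 1)$ci, upper - lower)
  expect_true(all(w1000 < w50))
})

test_that("leave-one-out prediction is exact for noiseless data and bounded by the in-sample fit", {
  n <- 60
  set.seed(34)
  X <- rnorm(n); g <- rbinom(n, 1, 0.4); M <- -0.2 * X + rnorm(n, 0, 0.5)
  Y <- 2 + 0.3 * X + 0.5 * M + 0.2 * g
  fit <- path_model(y ~ x + g, mediator = "m",
                    data = data.frame(y = Y, x = X, g = g, m = M))
  expect_equal(loo_validate(fit)$r, 1, tolerance = 1e-8)

  for (r in 1:10) {
    set.seed(100 + r)
    d <- data.frame(y = rnorm(80), x = rnorm(80), g = rbinom(80, 1, 0.3),
                    m = rnorm(80))
    f <- path_model(y ~ x + g, mediator = "m", data = d)
    expect_lte(loo_validate(f)$r, sqrt(f$r2_y) + 1e-10)
  }

  set.seed(35)
  dn <- data.frame(y = rnorm(200), x = rnorm(200), g = rbinom(200, 1, 0.3),
                   m = rnorm(200))
  fn <- path_model(y ~ x + g, mediator = "m", data = dn)
  expect_lt(abs(loo_validate(fn)$r), 0.15)
})

test_that("phenotype descriptives: moments, KS normality, gender t-test", {
  s <- describe_phenotype(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
                          rep(0:1, each = 5))
  expect_equal(s$by_gender$skewness, c(0, 0), tolerance = 1e-12)
  expect_equal(s$t_test$p.value, 1)

  set.seed(36)
  z <- rnorm(10000)
  d0 <- describe_phenotype(z, rep(0:1, 5000), corrected = FALSE)
  expect_lt(max(abs(d0$by_gender$kurtosis)), 0.15)
  expect_lt(max(abs(d0$by_gender$skewness)), 0.1)
  expect_true(all(d0$by_gender$ks_p > 0.01))
  expect_warning(describe_phenotype(rnorm(30), rep(1, 30)), "t-test")
})

test_that("model methods: coef, predict, residuals, simulate, plot run coherently", {
  d <- synthetic_s1_cohort(seed = 4)
  fit <- path_model(sps_total ~ gene_score + gender, mediator = "reho_pcc",
                    data = d)
  cf <- coef(fit)
  expect_named(cf, c("a", "b", "c_prime", "c", "ab"))
  expect_equal(unname(cf["ab"]), unname(cf["a"] * cf["b"]))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(length(residuals(fit)), nrow(d))
  expect_lt(abs(mean(residuals(fit))), 1e-10)
  nd <- data.frame(gene_score = 0, reho_pcc = 0, gender = 0)
  expect_equal(unname(predict(fit, nd)), unname(coef(fit$lm_y)[1]), tolerance = 1e-8)
  sim <- simulate(fit, nsim = 1, seed = 1)
  expect_equal(dim(sim), dim(fit$frame))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_output(print(summary(fit)), "Standardized paths")
})
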