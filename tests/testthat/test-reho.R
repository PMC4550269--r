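test_that("Kendall's W matches hand-ranked cases and stays in [0, 1]", {
  expect_equal(kendalls_w(matrix(rep(1:7, 3), 3, byrow = TRUE)), 1)
  expect_equal(kendalls_w(rbind(c(1, 2, 3), c(3, 2, 1))), 0)
  # ranks (1,2,3) and (2,1,3): R = (3,3,6), S = 6, W = 72/96
  expect_equal(kendalls_w(rbind(c(1, 2, 3), c(2, 1, 3))), 0.75)
  set.seed(1)
  for (i in 1:20) {
    w <- kendalls_w(matrix(rnorm(5 * 30), 5, 30))
    expect_gte(w, 0); expect_lte(w, 1)
  }
  expect_error(kendalls_w(matrix(1:5, 1)), "2 series")
})

test_that("W is invariant to strictly monotone transforms of each series", {
  set.seed(2)
  x <- matrix(rnorm(4 * 25), 4, 25)
  y <- rbind(exp(x[1, ]), x[2, ]^3, 5 * x[3, ] - 2, atan(x[4, ]))
  expect_equal(kendalls_w(y), kendalls_w(x))
})

test_that("zero-variance series contribute constant (all-tied) ranks", {
  x <- rbind(c(1, 2, 3, 4), rep(5, 4))
  expect_equal(kendalls_w(x), kendalls_w(rbind(c(1, 2, 3, 4), c(1, 1, 1, 1))))
  expect_lt(kendalls_w(x), 1)
})

test_that("reho_map equals kendalls_w applied voxel-by-voxel (exhaustive toy grid)", {
  vol <- toy_bold(c(5, 5, 5), T = 12, seed = 4)
  mask <- array(TRUE, c(5, 5, 5))
  mask[2, 3, 1] <- FALSE  # irregular mask exercises clipping
  rm1 <- reho_map(vol, mask)
  for (x in 1:5) for (y in 1:5) for (z in 1:5) {
    if (!mask[x, y, z]) { expect_equal(rm1[x, y, z], 0); next }
    nb <- expand.grid(x + (-1:1), y + (-1:1), z + (-1:1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 5 & nb[, 2] >= 1 & nb[, 2] <= 5 &
               nb[, 3] >= 1 & nb[, 3] <= 5, ]
    nb <- nb[mask[as.matrix(nb)], ]
    series <- t(apply(nb, 1, function(ijk) vol$data[ijk[1], ijk[2], ijk[3], ]))
    expect_equal(rm1[x, y, z], kendalls_w(series), tolerance = 1e-12)
  }
})

test_that("a volume with one shared series gives W = 1 in the mask interior", {
  T <- 30
  s <- sin(seq_len(T))
  vol <- bold4d(array(rep(s, each = 4^3), c(4, 4, 4, T)))
  rm1 <- reho_map(vol, array(TRUE, c(4, 4, 4)))
  expect_true(all(abs(rm1 - 1) < 1e-12))
})

test_that("null ReHo matches a direct Monte-Carlo oracle of 27 white series", {
  # oracle: E[W] for 27 independent series of length T, direct simulation
  T <- 100
  set.seed(6)
  oracle <- mean(vapply(1:300, function(i)
    kendalls_w(matrix(rnorm(27 * T), 27, T)), numeric(1)))
  vol <- toy_bold(c(10, 10, 10), T = T, seed = 7)
  rm1 <- reho_map(vol, array(TRUE, c(10, 10, 10)))
  interior <- rm1[2:9, 2:9, 2:9]  # full 27-voxel neighbourhoods only
  expect_equal(mean(interior), oracle, tolerance = 0.01 / oracle)
  expect_lt(abs(mean(interior) - oracle), 0.01)
})

test_that("cluster W increases with the shared-signal proportion", {
  cfg <- synth_config(grid_dims = c(9, 9, 9), n_timepoints = 60)
  cl <- cfg$cluster_ijk
  centre <- cl[14, ]
  mean_w <- vapply(c(0.2, 0.5, 0.8), function(lam) {
    mean(vapply(1:25, function(i) {
      b <- gen_bold(cfg, lambda = lam, seed = 100 * lam + i)
      rm1 <- reho_map(b)
      rm1[centre[1], centre[2], centre[3]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_w) > 0))
})

test_that("lambda extremes give perfect and null concordance", {
  cfg <- synth_config(grid_dims = c(9, 9, 9), n_timepoints = 40)
  cl <- cfg$cluster_ijk
  b1 <- gen_bold(cfg, lambda = 1, seed = 31)
  w1 <- reho_map(b1)
  expect_equal(w1[cl[14, 1], cl[14, 2], cl[14, 3]], 1, tolerance = 1e-12)
  b0 <- gen_bold(cfg, lambda = 0, seed = 32)
  w0 <- reho_map(b0)
  incl <- w0[cl]
  outcl <- w0[-(cl[, 1] + 9 * (cl[, 2] - 1) + 81 * (cl[, 3] - 1))]
  expect_lt(abs(mean(incl) - mean(outcl[outcl > 0])), 0.05)
})

test_that("demeaning subtract/divide behave as documented", {
  vol <- toy_bold(c(4, 4, 4), T = 20, seed = 8)
  mask <- array(TRUE, c(4, 4, 4))
  rm1 <- reho_map(vol, mask)
  sub <- normalize_reho(rm1, "subtract")
  expect_lt(abs(mean(sub[mask])), 1e-12)
  div <- normalize_reho(rm1, "divide")
  expect_equal(mean(div[mask]), 1, tolerance = 1e-12)
  # constant map: zeros under subtract, ones under divide
  cst <- rm1; cst[] <- 3.5
  expect_true(all(abs(normalize_reho(cst, "subtract")) < 1e-12))
  expect_true(all(abs(normalize_reho(cst, "divide") - 1) < 1e-12))
  expect_error(normalize_reho(sub), "raw")
})

test_that("gaussian smoothing preserves constants, identity at fwhm 0, 4 mm kernel width", {
  arr <- array(rnorm(12^3), c(12, 12, 12))
  expect_equal(gaussian_smooth(arr, 0, voxel_mm = c(3, 3, 3)), arr)
  cst <- array(2, c(8, 8, 8))
  expect_equal(gaussian_smooth(cst, 4, voxel_mm = c(3, 3, 3)), cst,
               tolerance = 1e-12)
  # delta image: measure the kernel's FWHM along x in mm
  delta <- array(0, c(15, 15, 15)); delta[8, 8, 8] <- 1
  sm <- gaussian_smooth(delta, 4, voxel_mm = c(1, 1, 1))
  prof <- sm[, 8, 8]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  i1 <- above[1]; i2 <- above[2]
  x_left <- (i1 - 1) + (half - prof[i1 - 1]) / (prof[i1] - prof[i1 - 1])
  x_right <- i2 + (prof[i2] - half) / (prof[i2] - prof[i2 + 1])
  expect_equal(x_right - x_left, 4, tolerance = 0.5 / 4)
})

test_that("smoothness estimation recovers applied FWHM and its anisotropy", {
  set.seed(9)
  dims <- c(30, 30, 30)
  mask <- array(TRUE, dims)
  maps <- lapply(1:4, function(i)
    gaussian_smooth(array(rnorm(prod(dims)), dims), 8, voxel_mm = c(3, 3, 3)))
  est <- estimate_fwhm(maps, mask, c(3, 3, 3))
  expect_true(all(abs(est - 8) / 8 < 0.15))

  aniso <- lapply(1:4, function(i)
    gaussian_smooth(array(rnorm(prod(dims)), dims), c(8, 8, 4),
                    voxel_mm = c(3, 3, 3)))
  est2 <- estimate_fwhm(aniso, mask, c(3, 3, 3))
  expect_gt(est2[1], est2[3])
  expect_gt(est2[2], est2[3])

  # white noise: the difference-ratio sits at the estimator's boundary, so
  # individual-axis estimates can only be bounded well below a voxel
  white <- lapply(1:8, function(i) array(rnorm(prod(dims)), dims))
  est3 <- estimate_fwhm(white, mask, c(3, 3, 3))
  expect_true(all(est3 < 2))
})
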