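# Regional homogeneity: Kendall's coefficient of concordance over the
# 27-voxel neighbourhood, plus map normalization and smoothing.

#' Kendall's coefficient of concordance
#'
#' Agreement statistic W in \[0, 1\] for K series ranked over n time points.
#' Each series is ranked over time with average ranks for ties; with
#' `R_i` the rank sum at time i,
#' `W = 12 * sum_i (R_i - mean(R))^2 / (K^2 (n^3 - n))`.
#' The default denominator carries no tie-correction term (the convention of
#' the classic resting-state toolkits); `tie_correction = TRUE` subtracts
#' `K * sum_j T_j` with `T_j = sum(t^3 - t)` over tie groups of series j.
#' A zero-variance series is all-tied and contributes constant ranks.
#'
#' @param x numeric matrix, K rows (series) x n columns (time points).
#' @param tie_correction use the tie-corrected denominator.
#' @return W, a scalar in \[0, 1\].
#' @export
kendalls_w <- function(x, tie_correction = FALSE) {
  x <- as.matrix(x)
  K <- nrow(x); n <- ncol(x)
  if (K < 2) stop("Kendall's W needs at least 2 series")
  if (n < 2) stop("Kendall's W needs at least 2 time points")
  ranks <- t(apply(x, 1, rank))
  Ri <- colSums(ranks)
  S <- sum((Ri - mean(Ri))^2)
  denom <- K^2 * (n^3 - n)
  if (tie_correction) {
    Tj <- apply(x, 1, function(s) {
      tt <- table(s)
      sum(tt^3 - tt)
    })
    denom <- denom - K * sum(Tj)
  }
  if (denom <= 0) return(0)
  12 * S / denom
}

#' Regional homogeneity map
#'
#' For each in-mask voxel, Kendall's W over the 3x3x3 cube centred there
#' (centre included), restricted to in-mask cube members; K is the per-voxel
#' count of member series (neighbourhoods are clipped to the mask rather than
#' requiring full 27-voxel cubes). Voxels whose in-mask neighbourhood has
#' fewer than 2 members get value 0.
#'
#' @param vol a [bold4d].
#' @param mask logical 3D array; `NULL` means all voxels.
#' @param tie_correction passed to the W denominator (see [kendalls_w]).
#' @return a `reho_map`: 3D array of W values (0 outside the mask) with
#'   attributes `mask`, `state = "raw"`, `voxel_mm`, `affine`.
#' @export
reho_map <- function(vol, mask = NULL, tie_correction = FALSE) {
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (any(dim(mask) != d[1:3])) stop("mask dims do not match volume")
  if (!any(mask)) stop("empty mask")
  w <- .reho_core(as.numeric(vol$data), as.integer(d), as.logical(mask),
                  isTRUE(tie_correction))
  new_reho_map(array(w, d[1:3]), mask, "raw", vol$voxel_mm, vol$affine)
}

new_reho_map <- function(data, mask, state, voxel_mm, affine) {
  structure(data, mask = mask, state = state, voxel_mm = voxel_mm,
            affine = affine, class = "reho_map")
}

#' @export
print.reho_map <- function(x, ...) {
  d <- dim(x)
  v <- x[attr(x, "mask")]
  cat(sprintf("<reho_map> %d x %d x %d (%s), %d in-mask voxels, mean W %.4f\n",
              d[1], d[2], d[3], attr(x, "state"), length(v), mean(v)))
  invisible(x)
}

#' Normalize a ReHo map across the mask
#'
#' Default mode subtracts the in-mask mean (literal demeaning); `"divide"`
#' divides by the in-mask mean instead (the "mReHo" convention). Either is an
#' affine per-subject transform; in subtract mode it leaves across-subject
#' voxel correlations unchanged.
#'
#' @param map a raw `reho_map`.
#' @param mode `"subtract"` or `"divide"`.
#' @return the normalized `reho_map` (state `"demeaned"`).
#' @export
normalize_reho <- function(map, mode = c("subtract", "divide")) {
  mode <- match.arg(mode)
  if (attr(map, "state") != "raw")
    stop("normalize_reho expects a raw map, got state '", attr(map, "state"), "'")
  mask <- attr(map, "mask")
  if (!any(mask)) stop("empty mask")
  mu <- mean(map[mask])
  out <- unclass(map)
  if (mode == "subtract") out[mask] <- out[mask] - mu
  else {
    if (mu == 0) stop("in-mask mean is zero; cannot divide")
    out[mask] <- out[mask] / mu
  }
  out[!mask] <- 0
  new_reho_map(out, mask, "demeaned", attr(map, "voxel_mm"), attr(map, "affine"))
}

# 1D Gaussian kernel in voxels for a FWHM in mm; truncated at 4 sigma
gauss_kernel <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  if (sigma < 1e-8) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution along one axis with edge renormalization, so a
# constant image is exactly preserved near the boundary
conv_axis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  half <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- M %*% matrix(a, n)
  dim(a) <- da
  aperm(a, order(perm))
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis
#' in mm (converted by the voxel size); applied over the whole grid, with the
#' kernel renormalized at grid edges so constants are preserved. For a
#' `reho_map` the state advances to `"smoothed"`.
#'
#' @param map a `reho_map` or plain 3D array.
#' @param fwhm smoothing FWHM in mm (scalar or length 3; default 4).
#' @param voxel_mm voxel size for plain arrays.
#' @return smoothed object of the same kind.
#' @export
gaussian_smooth <- function(map, fwhm = 4, voxel_mm = NULL) {
  if (any(fwhm < 0)) stop("fwhm must be >= 0")
  fwhm <- rep_len(fwhm, 3)
  is_map <- inherits(map, "reho_map")
  vox <- if (is_map) attr(map, "voxel_mm") else (voxel_mm %||% c(3, 3, 3))
  arr <- unclass(map)
  attributes(arr) <- list(dim = dim(arr))
  for (ax in 1:3) arr <- conv_axis(arr, gauss_kernel(fwhm[ax], vox[ax]), ax)
  if (!is_map) return(arr)
  new_reho_map(arr, attr(map, "mask"), "smoothed", vox, attr(map, "affine"))
}

#' Estimate spatial smoothness (FWHM) from residual maps
#'
#' Classic per-axis Gaussian-autocorrelation estimator: with `s2_diff` the
#' variance of first differences between in-mask neighbours along an axis and
#' `s2` the in-mask variance,
#' `FWHM = dx * sqrt(-2 ln 2 / ln(1 - s2_diff / (2 s2)))`.
#' Estimates are averaged over maps. An axis rougher than white noise
#' (`s2_diff >= 2 s2`) reports 0.
#'
#' @param maps a 3D array, `reho_map`, or list of them.
#' @param mask logical 3D array; default from the first map or all voxels.
#' @param voxel_mm voxel size in mm.
#' @return numeric length 3: per-axis FWHM in mm.
#' @export
estimate_fwhm <- function(maps, mask = NULL, voxel_mm = c(3, 3, 3)) {
  if (!is.list(maps)) maps <- list(maps)
  if (!length(maps)) stop("need at least one map")
  if (inherits(maps[[1]], "reho_map")) {
    mask <- mask %||% attr(maps[[1]], "mask")
    voxel_mm <- attr(maps[[1]], "voxel_mm")
  }
  d <- dim(maps[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  est <- vapply(maps, function(m) {
    m <- unclass(m)
    v <- m[mask]
    s2 <- stats::var(v)
    out <- numeric(3)
    for (ax in 1:3) {
      lead <- slice_shift(d, ax)
      pair <- mask & lead$ok & shift_arr(mask, ax)
      dif <- (shift_arr(m, ax) - m)[pair]
      if (length(dif) < 2 || s2 <= 0) { out[ax] <- NA_real_; next }
      s2d <- mean(dif^2)  # mean square difference (differences have mean ~0)
      ratio <- s2d / (2 * s2)
      out[ax] <- if (ratio >= 1) 0 else
        voxel_mm[ax] * sqrt(-2 * log(2) / log(1 - ratio))
    }
    out
  }, numeric(3))
  rowMeans(est, na.rm = TRUE)
}

# value of the next voxel along an axis (content shifted towards lower index);
# the trailing slice is padded with the edge value and flagged invalid
shift_arr <- function(a, axis) {
  d <- dim(a)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- c(seq_len(d[axis])[-1], d[axis])
  do.call(`[`, c(list(a), idx))
}
slice_shift <- function(d, axis) {
  ok <- array(TRUE, d)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- d[axis]
  ok <- do.call(`[<-`, c(list(ok), idx, list(value = FALSE)))
  list(ok = ok)
}
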