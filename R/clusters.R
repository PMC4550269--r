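# Cluster labeling and the two cluster-extent correction schemes.

#' Label suprathreshold clusters
#'
#' Connected components of a binary 3D mask under 6, 18 or 26 connectivity
#' (default 26, i.e. corners touch). Peaks are located by maximal `|value|`
#' within each cluster when a value map is supplied.
#'
#' @param sig_mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @param values optional 3D array (e.g. mediation effects) for peak finding.
#' @param affine optional 4x4 voxel-to-world matrix for peak mm coordinates.
#' @param voxel_mm voxel size, used for cluster volumes in mm^3.
#' @return a `cluster_table` data frame: `cluster`, `size_vox`, `size_mm3`,
#'   `peak_i/j/k` (0-based), `peak_x/y/z` (mm, if affine given), `peak_value`
#'   (if values given); plus a `members` attribute (list of linear indices).
#'   An empty mask gives an empty table.
#' @export
label_clusters <- function(sig_mask, connectivity = 26, values = NULL,
                           affine = NULL, voxel_mm = c(3, 3, 3)) {
  d <- dim(sig_mask)
  lab <- .label_components(as.logical(sig_mask), as.integer(d),
                           as.integer(connectivity))
  ncl <- max(lab)
  empty <- data.frame(cluster = integer(0), size_vox = integer(0),
                      size_mm3 = numeric(0))
  if (ncl == 0) {
    attr(empty, "members") <- list()
    class(empty) <- c("cluster_table", "data.frame")
    return(empty)
  }
  members <- split(which(lab > 0), lab[lab > 0])
  sizes <- lengths(members)
  ord <- order(sizes, decreasing = TRUE)
  members <- members[ord]
  tab <- data.frame(cluster = seq_len(ncl), size_vox = as.integer(sizes[ord]),
                    size_mm3 = sizes[ord] * prod(voxel_mm))
  peak <- vapply(members, function(ix) {
    if (is.null(values)) ix[1]
    else ix[which.max(abs(values[ix]))]
  }, numeric(1))
  ijk <- arrayInd(as.integer(peak), d) - 1L
  tab$peak_i <- ijk[, 1]; tab$peak_j <- ijk[, 2]; tab$peak_k <- ijk[, 3]
  if (!is.null(affine)) {
    xyz <- voxel_to_world(ijk, affine)
    tab$peak_x <- xyz[, 1]; tab$peak_y <- xyz[, 2]; tab$peak_z <- xyz[, 3]
  }
  if (!is.null(values)) tab$peak_value <- values[peak]
  rownames(tab) <- NULL
  attr(tab, "members") <- members
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

# compact quasi-spherical mask of exactly mask_size voxels centred in a grid
# that leaves room for the smoothing kernel
ball_mask <- function(mask_size, sigma_vox) {
  r <- (3 * mask_size / (4 * pi))^(1 / 3)
  side <- ceiling(2 * r + 8 * max(sigma_vox) + 2)
  side <- side + side %% 2
  dims <- rep(side, 3)
  ctr <- (dims + 1) / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  idx <- order(d2)[seq_len(mask_size)]
  list(dims = dims, idx = idx)
}

# periodic Gaussian transfer function for one axis (sigma in voxels)
gauss_transfer <- function(n, sigma) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  exp(-2 * pi^2 * sigma^2 * k^2)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the minimum cluster size controlling family-wise error at
#' `alpha` for a voxel-level threshold `voxel_p`, by simulating smooth
#' Gaussian null fields: white noise on a 3D grid is smoothed to the target
#' FWHM (periodic FFT convolution), restricted to a compact quasi-spherical
#' mask of `mask_size` voxels (the true anatomy being unavailable, this
#' stand-in minimises boundary truncation and is documented to bias the
#' threshold upward by about one voxel relative to a folded grey-matter
#' ribbon), standardized within the mask, thresholded two-sided at
#' `voxel_p`, and clustered; the maximum cluster size per field is recorded.
#' Positive and negative suprathreshold sets are clustered separately, as
#' mediation effects can take either sign.
#'
#' @param mask_size number of in-mask voxels.
#' @param fwhm smoothness in mm (length 3 or scalar).
#' @param voxel_mm voxel size in mm (default 3 mm isotropic).
#' @param voxel_p per-voxel two-sided threshold probability.
#' @param alpha target family-wise error (default 0.05).
#' @param n_iter number of simulated fields (>= 1000 recommended).
#' @param connectivity cluster connectivity (default 26).
#' @param sided 2 (default) or 1.
#' @param seed RNG seed.
#' @return list with `threshold` (smallest k with P(max >= k) <= alpha),
#'   `max_sizes`, and the exceedance probabilities `p_exceed` for sizes up to
#'   the observed maximum.
#' @export
cluster_threshold_mc <- function(mask_size, fwhm, voxel_mm = c(3, 3, 3),
                                 voxel_p = 0.000125, alpha = 0.05,
                                 n_iter = 1000, connectivity = 26,
                                 sided = 2, seed = NULL) {
  if (voxel_p <= 0 || voxel_p > 1) stop("voxel_p must be in (0, 1]")
  if (any(fwhm < 0)) stop("fwhm must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  fwhm <- rep_len(fwhm, 3)
  voxel_mm <- rep_len(voxel_mm, 3)
  sigma_vox <- fwhm / voxel_mm / (2 * sqrt(2 * log(2)))
  bm <- ball_mask(mask_size, sigma_vox)
  dims <- bm$dims
  H <- outer(outer(gauss_transfer(dims[1], sigma_vox[1]),
                   gauss_transfer(dims[2], sigma_vox[2])),
             gauss_transfer(dims[3], sigma_vox[3]))
  zthr <- if (sided == 2) stats::qnorm(1 - voxel_p / 2) else stats::qnorm(1 - voxel_p)
  nvox <- prod(dims)
  mask_arr <- array(FALSE, dims)
  mask_arr[bm$idx] <- TRUE
  mx <- integer(n_iter)
  supra <- array(FALSE, dims)
  for (it in seq_len(n_iter)) {
    x <- array(stats::rnorm(nvox), dims)
    xs <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / nvox
    v <- xs[bm$idx]
    v <- (v - mean(v)) / stats::sd(v)
    best <- 0L
    signs <- if (sided == 2) c(1, -1) else 1
    for (s in signs) {
      hit <- bm$idx[s * v > zthr]
      if (!length(hit)) next
      supra[] <- FALSE
      supra[hit] <- TRUE
      lab <- .label_components(supra, as.integer(dims), as.integer(connectivity))
      best <- max(best, max(tabulate(lab[hit])))
    }
    mx[it] <- best
  }
  kmax <- max(mx, 1L)
  p_exceed <- vapply(seq_len(kmax), function(k) mean(mx >= k), numeric(1))
  thr <- which(p_exceed <= alpha)
  threshold <- if (length(thr)) min(thr) else min(kmax + 1L, mask_size)
  list(threshold = as.integer(threshold), max_sizes = mx, p_exceed = p_exceed)
}

#' Random-gene-score permutation cluster threshold
#'
#' Empirical cluster-extent threshold by rebuilding the gene score from
#' random draws of `n_select` loci out of a larger genotyped pool, re-running
#' the full three-step mediation scan, and recording the maximum significant
#' cluster size per draw. The threshold is the
#' `ceil((1 - alpha) * (n_perm + 1))`-th order statistic of the max-size
#' distribution (0 when that index is below 1).
#'
#' Weights for each random 10-locus score are re-estimated by multiple
#' regression of the trait on the 10 codes, mirroring how the real score's
#' weights were obtained (`weight_policy = "refit"`); `"unit"` uses equal
#' weights instead.
#'
#' @param snp_pool [genotype_matrix] of the full locus pool.
#' @param Y,gender trait and covariate vectors.
#' @param reho_stack n x V matrix of voxel values.
#' @param mask logical 3D array mapping stack columns to grid voxels
#'   (`sum(mask) == ncol(reho_stack)`).
#' @param n_select loci per random score (default 10).
#' @param n_perm number of permutations (default 1000; fewer than 100 gives
#'   an unstable tail and warns).
#' @param alpha family-wise level (default 0.05).
#' @param step_alpha per-step level inside the scan (default 0.05).
#' @param connectivity cluster connectivity.
#' @param weight_policy `"refit"` or `"unit"`.
#' @param seed RNG seed.
#' @return list with `threshold` (voxels) and `max_sizes`.
#' @export
cluster_threshold_perm <- function(snp_pool, Y, gender, reho_stack, mask,
                                   n_select = 10, n_perm = 1000, alpha = 0.05,
                                   step_alpha = 0.05, connectivity = 26,
                                   weight_policy = c("refit", "unit"),
                                   seed = NULL) {
  weight_policy <- match.arg(weight_policy)
  if (ncol(snp_pool) < n_select)
    stop("locus pool smaller than n_select")
  if (n_perm < 100) warning("n_perm < 100: the 95% tail is unstable")
  if (sum(mask) != ncol(reho_stack))
    stop("mask size must equal the number of stack columns")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(mask)
  codes <- unclass(snp_pool)
  storage.mode(codes) <- "double"
  sig_arr <- array(FALSE, d)
  mx <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    pick <- sample.int(ncol(codes), n_select)
    sub <- codes[, pick, drop = FALSE]
    keep <- apply(sub, 2, stats::sd) > 0
    sub <- sub[, keep, drop = FALSE]
    score <- if (weight_policy == "refit" && ncol(sub) > 0) {
      w <- stats::lm.fit(cbind(1, sub), Y)$coefficients[-1]
      w[is.na(w)] <- 0
      drop(sub %*% w)
    } else rowSums(sub)
    if (stats::sd(score) == 0) { mx[p] <- 0L; next }
    scan <- mediation_scan(score, Y, gender, reho_stack, alpha = step_alpha)
    if (!any(scan$sig)) { mx[p] <- 0L; next }
    sig_arr[] <- FALSE
    sig_arr[which(mask)[scan$sig]] <- TRUE
    lab <- .label_components(sig_arr, as.integer(d), as.integer(connectivity))
    mx[p] <- max(tabulate(lab[lab > 0]))
  }
  k <- ceiling((1 - alpha) * (n_perm + 1))
  threshold <- if (k < 1) 0L else if (k > n_perm) max(mx) + 1L else
    as.integer(sort(mx)[k])
  list(threshold = threshold, max_sizes = mx)
}
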