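# Temporal preprocessing of 4D runs. Stage order is fixed and mirrors the
# acquisition pipeline: discard -> detrend -> band-pass -> nuisance.

#' Discard initial volumes
#'
#' Removes the first `n_discard` frames from the data (and, if supplied, the
#' matching rows of the motion trace) so that the retained series starts
#' after signal equilibration.
#'
#' @param vol a [bold4d].
#' @param n_discard number of leading frames to drop (default 10).
#' @param motion optional [motion_trace] trimmed in lockstep.
#' @return the trimmed [bold4d], or `list(vol, motion)` when motion is given.
#' @export
discard_initial <- function(vol, n_discard = 10, motion = NULL) {
  T <- dim(vol$data)[4]
  if (n_discard < 0 || n_discard >= T)
    stop(sprintf("cannot discard %d of %d frames", n_discard, T))
  keep <- seq.int(n_discard + 1L, T)
  out <- vol
  out$data <- vol$data[, , , keep, drop = FALSE]
  if (is.null(motion)) return(out)
  list(vol = out, motion = motion_trace(unclass(motion)[keep, , drop = FALSE]))
}

# flatten to T x V matrix and back
as_tmat <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, prod(d[1:3]), d[4]))
}
from_tmat <- function(vol, m) {
  vol$data <- array(t(m), dim = dim(vol$data))
  vol
}

#' Linear detrending
#'
#' Per voxel, subtracts the least-squares line in frame index (intercept and
#' slope), leaving residuals with zero mean and zero linear trend.
#'
#' @param vol a [bold4d] with at least 3 frames.
#' @return detrended [bold4d].
#' @export
detrend_linear <- function(vol) {
  T <- dim(vol$data)[4]
  if (T < 3) stop("detrending needs at least 3 frames")
  X <- cbind(1, seq_len(T))
  m <- as_tmat(vol)
  beta <- qr.coef(qr(X), m)
  from_tmat(vol, m - X %*% beta)
}

#' Ideal band-pass filter
#'
#' Rectangular frequency-domain filter: discrete-Fourier components with
#' frequency in `[low, high]` (band edges inclusive) are retained, all others
#' -- including DC -- are zeroed. This is the ideal-filter behaviour of the
#' classic resting-state toolkits rather than a Butterworth design.
#'
#' @param vol a [bold4d].
#' @param low,high band edges in Hz (defaults 0.01 and 0.08).
#' @return filtered [bold4d].
#' @export
bandpass_filter <- function(vol, low = 0.01, high = 0.08) {
  T <- dim(vol$data)[4]
  nyq <- 1 / (2 * vol$tr)
  if (low <= 0 || high <= low || high >= nyq)
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                 low, high, nyq))
  freqs <- seq.int(0, T - 1) / (T * vol$tr)
  freqs <- pmin(freqs, 1 / vol$tr - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  m <- stats::mvfft(as_tmat(vol))
  m[!keep, ] <- 0
  from_tmat(vol, Re(stats::mvfft(m, inverse = TRUE)) / T)
}

#' Nuisance regression
#'
#' Per voxel, returns the residual of an OLS regression on an intercept, the
#' six motion parameters, and the mean series of the global, white-matter and
#' CSF masks. Residuals are orthogonal to every regressor.
#'
#' @param vol a [bold4d].
#' @param motion a [motion_trace] with T rows.
#' @param masks named list of logical 3D arrays: `global`, `wm`, `csf`
#'   (any subset; missing entries are skipped).
#' @return residual [bold4d].
#' @export
regress_nuisance <- function(vol, motion, masks = list()) {
  T <- dim(vol$data)[4]
  if (nrow(motion) != T)
    stop(sprintf("motion has %d rows but volume has %d frames", nrow(motion), T))
  m <- as_tmat(vol)
  X <- cbind(intercept = 1, unclass(motion))
  for (nm in intersect(c("global", "wm", "csf"), names(masks))) {
    msk <- masks[[nm]]
    if (any(dim(msk) != dim(vol$data)[1:3])) stop("mask dims do not match volume")
    X <- cbind(X, rowMeans(m[, as.vector(msk), drop = FALSE]))
    colnames(X)[ncol(X)] <- nm
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  from_tmat(vol, m - X %*% qr.coef(qx, m))
}

#' Head-motion summary indices
#'
#' Per frame, the Euclidean norm of the three translations
#' (`sqrt(dx^2 + dy^2 + dz^2)`, mm) and of the three rotations (radians).
#' Both the mean and the maximum over frames are reported, since the
#' conventional index leaves the aggregation unstated.
#'
#' @param motion a [motion_trace].
#' @return list with `trans_index`, `rot_index` (means), `trans_max`,
#'   `rot_max`, and per-frame vectors `trans`, `rot`.
#' @export
motion_summary <- function(motion) {
  m <- unclass(motion)
  e <- sqrt(rowSums(m[, 1:3, drop = FALSE]^2))
  r <- sqrt(rowSums(m[, 4:6, drop = FALSE]^2))
  list(trans_index = mean(e), rot_index = mean(r),
       trans_max = max(e), rot_max = max(r), trans = e, rot = r)
}

#' Framewise displacement
#'
#' Power-style FD: sum of absolute frame-to-frame changes in the three
#' translations plus the rotation changes converted to arc length on a
#' sphere of the given radius. `FD[1] = 0` by convention.
#'
#' @param motion a [motion_trace] (rotations in radians).
#' @param radius sphere radius in mm (default 50).
#' @return list with per-frame `fd` and `mean_fd`.
#' @export
framewise_displacement <- function(motion, radius = 50) {
  m <- unclass(motion)
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd))
}

#' Maximum-motion exclusion check
#'
#' A run fails if any translation exceeds `max_trans` mm or any rotation
#' exceeds `max_rot_deg` degrees at any frame (displacement relative to the
#' reference frame, per axis).
#'
#' @param motion a [motion_trace].
#' @param max_trans translation limit in mm (default 2).
#' @param max_rot_deg rotation limit in degrees (default 2).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
max_motion_check <- function(motion, max_trans = 2, max_rot_deg = 2) {
  m <- unclass(motion)
  max(abs(m[, 1:3])) <= max_trans &&
    max(abs(m[, 4:6])) <= max_rot_deg * pi / 180
}
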