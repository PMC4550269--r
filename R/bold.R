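#' 4D BOLD time-series container
#'
#' A minimal in-memory representation of a resting-state run: a 4D numeric
#' array (x, y, z, time), the voxel size in mm, a 4x4 voxel-to-world affine
#' (0-based voxel indices, MNI mm on output), and the repetition time in
#' seconds.
#'
#' @param data 4D numeric array.
#' @param voxel_mm numeric length-3 voxel size in mm.
#' @param affine 4x4 voxel-to-world matrix; default a diagonal scaling
#'   centred on the grid.
#' @param tr repetition time in seconds.
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, voxel_mm = c(3, 3, 3), affine = NULL, tr = 2) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("'data' must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("a bold4d needs at least 2 time points")
  if (!all(is.finite(data))) stop("non-finite values in volume")
  stopifnot_scalar(tr, "tr", lower = 1e-6)
  if (is.null(affine)) affine <- default_affine(dim(data)[1:3], voxel_mm)
  if (!is.matrix(affine) || any(dim(affine) != 4) ||
      abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("'affine' must be an invertible 4x4 matrix")
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm),
                 affine = affine, tr = tr),
            class = "bold4d")
}

# RAS affine with the world origin at the grid centre (0-based voxel indices)
default_affine <- function(dims, voxel_mm) {
  a <- diag(c(voxel_mm, 1))
  a[1:3, 4] <- -voxel_mm * (dims - 1) / 2
  a
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d time points, voxel %s mm, TR %g s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_mm, 3), collapse = "x"), x$tr))
  invisible(x)
}

#' @export
dim.bold4d <- function(x) dim(x$data)

# 0-based voxel ijk (rows) -> world mm coordinates
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  xyz <- cbind(ijk, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' Read and write NIfTI-1 volumes
#'
#' `read_bold()` reads a 4D NIfTI file into a [bold4d]; `read_mask()` reads a
#' 3D file and returns a logical array (nonzero = in mask). `write_map()`
#' writes a 3D or 4D array with the supplied affine; round trips preserve
#' data and affine.
#'
#' @param path NIfTI-1 file (optionally gzipped).
#' @param tr_override repetition time in seconds; when supplied it takes
#'   precedence over the header (headers written by some tools carry no
#'   usable TR). An error is raised if neither source gives a TR.
#' @return `read_bold()` a [bold4d]; `read_mask()` a logical 3D array with
#'   attributes `voxel_mm` and `affine`.
#' @export
read_bold <- function(path, tr_override = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("'%s' is %dD; a 4D volume is required", path, length(d)))
  pix <- RNifti::pixdim(img)
  tr <- tr_override %||% if (length(pix) >= 4) pix[4] else 0
  if (!is.finite(tr) || tr <= 0)
    stop(sprintf("no TR in header of '%s' and no tr_override given", path))
  bold4d(array(as.numeric(img), dim = d), voxel_mm = pix[1:3],
         affine = nifti_affine(img), tr = tr)
}

#' @rdname read_bold
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s' is %dD; a 3D mask is required", path, length(d)))
  m <- array(as.numeric(img) != 0, dim = d)
  attr(m, "voxel_mm") <- RNifti::pixdim(img)[1:3]
  attr(m, "affine") <- nifti_affine(img)
  m
}

nifti_affine <- function(img) {
  a <- tryCatch(structure(RNifti::xform(img), class = NULL),
                error = function(e) NULL)
  if (is.null(a)) a <- default_affine(dim(img)[1:3], RNifti::pixdim(img)[1:3])
  matrix(as.numeric(a), 4, 4)
}

#' @rdname read_bold
#' @param x a [bold4d], 3D/4D array, or `reho_map` data.
#' @param affine 4x4 voxel-to-world matrix for plain arrays.
#' @param voxel_mm voxel size in mm for plain arrays.
#' @param tr repetition time in seconds stored in pixdim\[4\] for 4D data.
#' @export
write_map <- function(x, path, affine = NULL, voxel_mm = c(3, 3, 3), tr = NULL) {
  if (inherits(x, "bold4d")) {
    affine <- x$affine; voxel_mm <- x$voxel_mm; tr <- x$tr; x <- x$data
  } else if (inherits(x, "reho_map")) {
    affine <- attr(x, "affine") %||% affine
    voxel_mm <- attr(x, "voxel_mm") %||% voxel_mm
    x <- unclass(x)
    attributes(x)[c("voxel_mm", "affine", "state", "mask")] <- NULL
  }
  if (is.null(affine)) affine <- default_affine(dim(x)[1:3], voxel_mm)
  img <- RNifti::asNifti(x)
  pd <- c(voxel_mm, if (length(dim(x)) == 4L) tr %||% 1 else numeric(0))
  RNifti::pixdim(img) <- pd
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write motion-parameter files
#'
#' Whitespace-delimited T x 6 text files in the SPM `rp_*.txt` convention:
#' three translations (mm) then three rotations (radians by default).
#'
#' @param path text file path.
#' @param degrees if `TRUE` the three rotation columns are converted from
#'   degrees to radians on read.
#' @return a `motion_trace`: T x 6 numeric matrix with columns
#'   `tx, ty, tz, rx, ry, rz`.
#' @export
read_motion <- function(path, degrees = FALSE) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop(sprintf("'%s' must have 6 columns, found %d", path, ncol(m)))
  if (degrees) m[, 4:6] <- m[, 4:6] * pi / 180
  motion_trace(m)
}

#' @rdname read_motion
#' @param m T x 6 numeric matrix.
#' @export
write_motion <- function(m, path) {
  utils::write.table(format(unclass(m), digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_motion
#' @export
motion_trace <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 6L || nrow(m) < 2L)
    stop("a motion trace is a T x 6 matrix with T >= 2")
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  class(m) <- c("motion_trace", "matrix", "array")
  m
}
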