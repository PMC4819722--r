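#' Construct a volume
#'
#' A `volume` is the basic image container used throughout the package: a 3D
#' numeric array together with a 4x4 voxel-to-world affine in millimetres.
#' Voxel indices are 0-based when mapped through the affine, matching the
#' NIfTI-1 convention.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @return An object of class `volume` with elements `data` and `affine`.
#' @export
as_volume <- function(data, affine = diag(4)) {
  if (inherits(data, "volume")) return(data)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("expected 3D volume")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps * 64) {
    stop("non-invertible affine")
  }
  attributes(data) <- list(dim = dim(data))
  structure(list(data = data, affine = unname(affine)), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d, voxel sizes %s mm\n",
              d[1], d[2], d[3],
              paste(signif(voxel_sizes(x), 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Voxel sizes of a volume
#'
#' Lengths of the three voxel edges in mm, read off the affine columns.
#'
#' @param v A `volume` or `deformation_field`.
#' @return Numeric length-3 vector (mm).
#' @export
voxel_sizes <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Voxel volume in cubic millimetres
#'
#' @param v A `volume`.
#' @return Scalar, `|det|` of the 3x3 affine block.
#' @export
voxel_volume <- function(v) {
  abs(det(v$affine[1:3, 1:3]))
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what)
  invisible(TRUE)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads `.nii` or `.nii.gz`. The payload must be 3-dimensional and the
#' stored affine invertible.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A `volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D")
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  as_volume(array(as.numeric(img), dim = d), aff)
}

#' Write a volume as NIfTI-1
#'
#' The affine is stored in both the sform and qform; `float` payloads
#' round-trip exactly through [read_volume()] once quantised to float32.
#'
#' @param v A `volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype, `"float"` (default) or `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float") {
  v <- as_volume(v)
  img <- RNifti::asNifti(v$data)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Coerce a volume to a binary label mask
#'
#' @param v A `volume` or array whose values are (numerically) 0/1.
#' @param affine Affine, used when `v` is a bare array.
#' @return A `volume` flagged as a binary mask.
#' @export
as_label_mask <- function(v, affine = diag(4)) {
  v <- if (inherits(v, "volume")) v else as_volume(v, affine)
  u <- unique(as.vector(v$data))
  if (!all(u %in% c(0, 1))) stop("mask is not binary")
  v
}

is_binary <- function(v) all(v$data == 0 | v$data == 1)

check_probability <- function(v, what = "volume", tol = 1e-9) {
  r <- range(v$data)
  if (r[1] < -tol || r[2] > 1 + tol) {
    stop(what, " has values outside [0,1]: range ",
         paste(signif(r, 6), collapse = " .. "))
  }
  invisible(TRUE)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
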