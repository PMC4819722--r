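#' Construct a tissue-probability-map set
#'
#' An ordered collection of per-class probability volumes on a common grid.
#' After [normalize_tpm()] the classes sum to one at every voxel, the
#' constraint a prior-driven classifier requires.
#'
#' @param volumes Named list of `volume`s, one per tissue class, in class
#'   order (e.g. GM, WM, CSF, BG).
#' @return An object of class `tpm_set`.
#' @export
tpm_set <- function(volumes) {
  if (length(volumes) < 2L) stop("need at least 2 tissue classes")
  if (is.null(names(volumes)) || any(names(volumes) == "")) {
    stop("volumes must be a named list (class names)")
  }
  volumes <- lapply(volumes, as_volume)
  for (i in seq_along(volumes)[-1]) {
    stop_if_grid_mismatch(volumes[[1]], volumes[[i]], "tissue classes")
  }
  structure(list(class_names = names(volumes), volumes = volumes),
            class = "tpm_set")
}

#' @export
print.tpm_set <- function(x, ...) {
  cat(sprintf("<tpm_set> %s; grid %s\n",
              paste(x$class_names, collapse = ", "),
              paste(dim(x$volumes[[1]]$data), collapse = " x ")))
  invisible(x)
}

tpm_class_matrix <- function(tpm) {
  vapply(tpm$volumes, function(v) as.vector(v$data),
         numeric(length(tpm$volumes[[1]]$data)))
}

tpm_sums <- function(tpm) {
  s <- 0
  for (v in tpm$volumes) s <- s + v$data
  s
}

is_normalized_tpm <- function(tpm, tol = 1e-6) {
  max(abs(tpm_sums(tpm) - 1)) <= tol
}

#' Normalize a TPM set to sum to one voxel-wise
#'
#' Divides each class by the voxel-wise class sum. Zero-sum voxels cannot be
#' normalized; they are assigned entirely to `background` (with a reported
#' count). An optional probability `floor` is added to every class and
#' re-normalized in, guaranteeing strictly positive priors so that image
#' likelihoods can override the prior anywhere.
#'
#' @param tpm A `tpm_set`.
#' @param floor Non-negative probability floor (default 0).
#' @param background Class name receiving zero-sum voxels; required if any
#'   exist.
#' @return Normalized `tpm_set`.
#' @export
normalize_tpm <- function(tpm, floor = 0, background = NULL) {
  if (!inherits(tpm, "tpm_set")) stop("tpm must be a tpm_set")
  if (floor < 0) stop("floor must be >= 0")
  s <- tpm_sums(tpm)
  zero <- s <= 0
  nzero <- sum(zero)
  if (nzero > 0L) {
    if (is.null(background) || !background %in% tpm$class_names) {
      stop(nzero, " zero-sum voxel(s); supply a background class name")
    }
    message(nzero, " zero-sum voxel(s) assigned to class '", background, "'")
  }
  s[zero] <- 1
  K <- length(tpm$volumes)
  out <- lapply(tpm$volumes, function(v) {
    p <- v$data / s
    if (floor > 0) p <- (p + floor) / (1 + K * floor)
    as_volume(p, v$affine)
  })
  names(out) <- tpm$class_names
  if (nzero > 0L) {
    for (nm in tpm$class_names) {
      base <- if (floor > 0) floor / (1 + K * floor) else 0
      out[[nm]]$data[zero] <- if (nm == background) {
        1 - (K - 1) * base
      } else {
        base
      }
    }
  }
  tpm_set(out)
}

#' Warp a binary mask and re-binarize
#'
#' Trilinear warp of a 0/1 mask followed by thresholding: warp first, then
#' binarize, which limits the non-linear effects of resampling on small
#' structures. The comparison is `>=`, so an interpolated value exactly at
#' the threshold is kept.
#'
#' @param mask Binary `volume` in native space.
#' @param d `deformation_field` to the template grid.
#' @param threshold In (0,1); default 0.5.
#' @return Binary `volume` on the template grid.
#' @export
warp_and_binarize <- function(mask, d, threshold = 0.5) {
  mask <- as_label_mask(mask)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  w <- apply_deformation(mask, d, interp = "trilinear")
  as_volume((w$data >= threshold) * 1, w$affine)
}

#' Average binary masks across raters
#'
#' Voxel-wise arithmetic mean of R binary masks; values lie on the grid
#' {0, 1/R, ..., 1} and estimate the per-voxel labelling probability.
#'
#' @param masks Non-empty list of binary `volume`s on one grid.
#' @return A probability `volume`.
#' @export
average_raters <- function(masks) {
  if (length(masks) == 0L) stop("empty mask list")
  masks <- lapply(masks, as_label_mask)
  for (i in seq_along(masks)[-1]) {
    stop_if_grid_mismatch(masks[[1]], masks[[i]], "rater masks")
  }
  acc <- 0
  for (m in masks) acc <- acc + m$data
  as_volume(acc / length(masks), masks[[1]]$affine)
}

#' Combine per-structure probability maps into one
#'
#' Voxel-wise maximum, so overlapping blurred borders of neighbouring
#' structures cannot push the combined probability above 1.
#'
#' @param avgs List of probability `volume`s (one per structure).
#' @return A probability `volume`.
#' @export
combine_structures <- function(avgs) {
  if (length(avgs) == 0L) stop("empty list")
  avgs <- lapply(avgs, as_volume)
  acc <- avgs[[1]]$data
  for (m in avgs[-1]) acc <- pmax(acc, m$data)
  as_volume(acc, avgs[[1]]$affine)
}

#' Build the nucleus probability (MBP) map
#'
#' Smooths the rater-averaged label probability with an isotropic Gaussian
#' (default 4 mm FWHM, chosen to preserve borders between neighbouring
#' structures while absorbing residual registration error), then clips
#' numerically negligible excursions back into [0,1].
#'
#' @param avg Probability `volume` (rater average, template space).
#' @param fwhm_mm Smoothing FWHM in mm; default 4.
#' @return A probability `volume` (the MBP map).
#' @export
build_mbp <- function(avg, fwhm_mm = 4) {
  avg <- as_volume(avg)
  check_probability(avg, "rater average")
  s <- gaussian_smooth_fwhm(avg, fwhm_mm)
  over <- max(0, max(s$data) - 1, -min(s$data))
  if (over > 1e-9) {
    stop("smoothed map exceeds [0,1] by ", signif(over, 3),
         "; refusing to clip")
  }
  as_volume(pmin(pmax(s$data, 0), 1), s$affine)
}

#' Merge a nucleus probability map into a TPM set
#'
#' At each voxel every class, including gray matter, is first scaled by
#' `(1 - MBP)`; the nucleus probability is then added to the gray-matter
#' class. This conserves the voxel-wise sum at one, never decreases GM and
#' never increases any other class.
#'
#' @param tpm Normalized `tpm_set`.
#' @param mbp Probability `volume` on the same grid.
#' @param gm_class Name of the gray-matter class (default `"GM"`).
#' @return A `tpm_set` with updated priors.
#' @export
merge_into_tpm <- function(tpm, mbp, gm_class = "GM") {
  if (!inherits(tpm, "tpm_set")) stop("tpm must be a tpm_set")
  if (!gm_class %in% tpm$class_names) {
    stop("unknown gm_class '", gm_class, "'")
  }
  mbp <- as_volume(mbp)
  check_probability(mbp, "MBP map")
  stop_if_grid_mismatch(tpm$volumes[[1]], mbp, "TPM and MBP")
  if (!is_normalized_tpm(tpm)) {
    stop("input TPM does not sum to one; call normalize_tpm() first")
  }
  keep <- 1 - mbp$data
  out <- lapply(tpm$volumes, function(v) as_volume(v$data * keep, v$affine))
  names(out) <- tpm$class_names
  out[[gm_class]]$data <- out[[gm_class]]$data + mbp$data
  tpm_set(out)
}

#' Write a TPM set as NIfTI files
#'
#' One 3D file per class, named `<prefix>_<class>.nii.gz`.
#'
#' @param tpm A `tpm_set`.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_tpm <- function(tpm, prefix) {
  paths <- character(0)
  for (nm in tpm$class_names) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    write_volume(tpm$volumes[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
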