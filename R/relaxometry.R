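#' Bundle a multi-echo magnitude series
#'
#' @param volumes List of `volume`s, one per echo, sharing grid and affine.
#' @param echo_times Echo times in ms, strictly increasing, length >= 2.
#' @return An object of class `multi_echo_series`.
#' @export
multi_echo_series <- function(volumes, echo_times) {
  if (length(volumes) < 2L) stop("need at least 2 echoes")
  if (length(volumes) != length(echo_times)) {
    stop("one echo time per volume required")
  }
  if (any(diff(echo_times) <= 0)) stop("echo_times must be strictly increasing")
  volumes <- lapply(volumes, as_volume)
  for (i in seq_along(volumes)[-1]) {
    stop_if_grid_mismatch(volumes[[1]], volumes[[i]], "echo volumes")
  }
  structure(list(volumes = volumes, echo_times = as.numeric(echo_times)),
            class = "multi_echo_series")
}

#' The standard eight-echo time grid (ms)
#'
#' Eight equidistant echoes between 2.34 and 19.7 ms, the default TE grid
#' for PD-weighted multi-echo FLASH.
#'
#' @return Numeric vector of length 8.
#' @export
default_echo_times <- function() {
  seq(2.34, 19.7, length.out = 8)
}

#' Estimate an R2* map by log-linear regression
#'
#' Per-voxel ordinary least squares of `log(S)` against echo time: the
#' negated slope is R2* and `exp(intercept)` is the extrapolated signal at
#' TE = 0. Voxels inside the mask with any non-positive echo cannot be
#' log-transformed; they are excluded from the fit and flagged.
#'
#' @param series A `multi_echo_series`.
#' @param mask A binary `volume`; only masked voxels are fitted.
#' @return List with `r2star` (`volume`, 1/s; NA outside the fitted set),
#'   `s0` (`volume`, signal units), `excluded` (binary `volume` of masked
#'   voxels dropped for non-positive signal), `n_excluded`.
#' @export
fit_r2star <- function(series, mask) {
  if (!inherits(series, "multi_echo_series")) {
    stop("series must be a multi_echo_series")
  }
  mask <- as_label_mask(mask)
  stop_if_grid_mismatch(series$volumes[[1]], mask, "series and mask")
  te <- series$echo_times
  idx <- which(mask$data == 1)
  if (length(idx) == 0L) stop("mask is empty")
  S <- vapply(series$volumes, function(v) v$data[idx],
              numeric(length(idx)))
  bad <- rowSums(S <= 0) > 0
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with non-positive signal excluded from fit")
  }
  dm <- dim(mask$data)
  r2s <- array(NA_real_, dim = dm)
  s0 <- array(NA_real_, dim = dm)
  keep <- idx[!bad]
  if (length(keep) > 0L) {
    L <- log(S[!bad, , drop = FALSE])
    tc <- te - mean(te)
    sxx <- sum(tc^2)
    slope <- as.vector(L %*% tc) / sxx        # per ms
    inter <- rowMeans(L) - slope * mean(te)
    r2s[keep] <- -slope * 1000                # export in 1/s
    s0[keep] <- exp(inter)
  }
  excl <- array(0, dim = dm)
  excl[idx[bad]] <- 1
  list(r2star = as_volume(r2s, mask$affine),
       s0 = as_volume(s0, mask$affine),
       excluded = as_volume(excl, mask$affine),
       n_excluded = sum(bad))
}
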