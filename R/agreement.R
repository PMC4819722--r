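#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)` for two binary masks on one grid. Symmetric and
#' independent of any surrounding voxel population.
#'
#' @param a,b Binary `volume`s.
#' @return Scalar in [0,1].
#' @export
dice <- function(a, b) {
  a <- as_label_mask(a); b <- as_label_mask(b)
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) stop("undefined Dice: both masks empty")
  2 * sum(a$data * b$data) / (na + nb)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with marginals
#' estimated over an explicit voxel population (`domain`). Unlike Dice,
#' kappa depends on that population: enlarging the domain with voxels both
#' raters leave unlabeled inflates observed agreement, so the domain is a
#' recorded analysis parameter.
#'
#' @param a,b Binary `volume`s.
#' @param domain Binary `volume`; the voxel population for the chance term.
#' @return Scalar in [-1, 1].
#' @export
cohen_kappa <- function(a, b, domain) {
  a <- as_label_mask(a); b <- as_label_mask(b); domain <- as_label_mask(domain)
  stop_if_grid_mismatch(a, b, "masks")
  stop_if_grid_mismatch(a, domain, "mask and domain")
  idx <- domain$data == 1
  n <- sum(idx)
  if (n == 0) stop("empty domain")
  av <- a$data[idx]; bv <- b$data[idx]
  po <- mean(av == bv)
  pa <- mean(av); pb <- mean(bv)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (1 - pe < .Machine$double.eps * 8) {
    stop("kappa undefined: both raters constant over domain")
  }
  (po - pe) / (1 - pe)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater, from the mean
#' squares of a two-way ANOVA (targets x raters):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings Numeric matrix, rows = targets, columns = raters; binary
#'   or continuous scores.
#' @return Scalar.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need >= 2 targets and >= 2 raters")
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (ssr <= .Machine$double.eps * sst || abs(denom) < .Machine$double.eps) {
    stop("ICC undefined: no between-target variance")
  }
  (msr - mse) / denom
}

#' Percentage of rater disagreement
#'
#' `100 (|union| - |intersection|) / |union|`: the share of voxels labeled
#' by at least one rater that are not labeled by all raters.
#'
#' @param masks List (length >= 2) of binary `volume`s.
#' @return Scalar percentage in [0, 100].
#' @export
disagreement_pct <- function(masks) {
  if (length(masks) < 2L) stop("need >= 2 masks")
  masks <- lapply(masks, as_label_mask)
  for (i in seq_along(masks)[-1]) {
    stop_if_grid_mismatch(masks[[1]], masks[[i]], "masks")
  }
  uni <- masks[[1]]$data
  int <- masks[[1]]$data
  for (m in masks[-1]) {
    uni <- pmax(uni, m$data)
    int <- int * m$data
  }
  nu <- sum(uni)
  if (nu == 0) stop("empty union")
  100 * (nu - sum(int)) / nu
}

# bounding box of a binary array dilated by `pad` voxels, as a 0/1 array
bbox_domain <- function(mask_data, pad = 5L) {
  out <- array(0, dim = dim(mask_data))
  w <- which(mask_data == 1, arr.ind = TRUE)
  if (nrow(w) == 0L) return(out)
  lo <- pmax(apply(w, 2, min) - pad, 1L)
  hi <- pmin(apply(w, 2, max) + pad, dim(mask_data))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  out
}

#' Multi-rater agreement summary for one structure
#'
#' Mean and SD of Dice and Cohen's kappa over all unordered rater pairs,
#' ICC(2,1) on the voxel x rater binary table restricted to the union of
#' all masks, the disagreement percentage, and labeled volume (mm^3,
#' mean/SD across raters). The kappa domain defaults to the union's
#' bounding box dilated by 5 voxels, keeping the chance term local to the
#' structure rather than diluted over the whole volume.
#'
#' @param masks List (length >= 2) of binary `volume`s, one per rater.
#' @param domain Optional binary `volume` for the kappa chance term.
#' @param structure,side Optional labels carried into the report.
#' @return A one-row `data.frame` (class `agreement_report`).
#' @export
pairwise_summary <- function(masks, domain = NULL, structure = NA_character_,
                             side = NA_character_) {
  if (length(masks) < 2L) stop("need >= 2 raters")
  masks <- lapply(masks, as_label_mask)
  aff <- masks[[1]]$affine
  uni <- masks[[1]]$data
  for (m in masks[-1]) uni <- pmax(uni, m$data)
  if (is.null(domain)) {
    domain <- as_volume(bbox_domain(uni, 5L), aff)
  }
  pairs <- utils::combn(length(masks), 2L)
  dv <- numeric(ncol(pairs)); kv <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    dv[p] <- dice(masks[[i]], masks[[j]])
    kv[p] <- cohen_kappa(masks[[i]], masks[[j]], domain)
  }
  uidx <- which(uni == 1)
  tab <- vapply(masks, function(m) m$data[uidx], numeric(length(uidx)))
  icc_val <- tryCatch(icc(tab), error = function(e) NA_real_)
  vv <- voxel_volume(masks[[1]])
  vols <- vapply(masks, function(m) sum(m$data) * vv, numeric(1))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  out <- data.frame(
    structure = structure, side = side,
    n_raters = length(masks),
    volume_mean = mean(vols), volume_sd = sd0(vols),
    disagreement_pct = disagreement_pct(masks),
    dice_mean = mean(dv), dice_sd = sd0(dv),
    kappa_mean = mean(kv), kappa_sd = sd0(kv),
    icc = icc_val,
    stringsAsFactors = FALSE
  )
  class(out) <- c("agreement_report", class(out))
  out
}
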