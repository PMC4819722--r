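#' Jacobian modulation of a warped probability map
#'
#' Warps the map through the deformation (trilinear) and multiplies
#' voxel-wise by the deformation's Jacobian determinant, so that regional
#' integrals represent volume despite local compression or expansion.
#' Non-positive determinants are clamped to 0 with a warning.
#'
#' @param gm_post Probability `volume` (e.g. a GM posterior).
#' @param d A `deformation_field` on the target grid.
#' @return A `volume` of local tissue volume (mm^3 per voxel, up to the
#'   voxel-volume factor).
#' @export
modulate <- function(gm_post, d) {
  gm_post <- as_volume(gm_post)
  w <- apply_deformation(gm_post, d, interp = "trilinear")
  jd <- jacobian_determinant(d)
  if (any(jd$data <= 0)) {
    warning(sum(jd$data <= 0), " non-positive Jacobian value(s) clamped to 0")
    jd$data[jd$data <= 0] <- 0
  }
  as_volume(w$data * jd$data, w$affine)
}

#' Probability-weighted Gaussian smoothing
#'
#' Computes `smooth(w * x) / smooth(w)`: smoothing restricted to where the
#' weight lives, which prevents values from low-weight tissue bleeding into
#' the region of interest. Voxels where the smoothed weight falls below
#' 0.05 are masked out (NA).
#'
#' @param x A `volume` of values (e.g. R2*).
#' @param w A non-negative weight `volume` (e.g. a GM probability map).
#' @param fwhm_mm Smoothing FWHM in mm.
#' @param min_weight Smoothed-weight cut-off below which the output is
#'   masked; default 0.05.
#' @return A `volume`, NA where the smoothed weight is below `min_weight`.
#' @export
weighted_smooth <- function(x, w, fwhm_mm, min_weight = 0.05) {
  x <- as_volume(x); w <- as_volume(w)
  stop_if_grid_mismatch(x, w, "values and weights")
  if (min(w$data) < 0) stop("weights must be non-negative")
  if (max(w$data) == 0) stop("all-zero weight volume")
  xw <- x$data * w$data
  xw[w$data == 0] <- 0   # value where weight is 0 must not contribute (NA-safe)
  sw <- gaussian_smooth_fwhm(as_volume(w$data, w$affine), fwhm_mm)
  sxw <- gaussian_smooth_fwhm(as_volume(xw, x$affine), fwhm_mm)
  out <- sxw$data / sw$data
  out[sw$data < min_weight] <- NA_real_
  as_volume(out, x$affine)
}

#' Ordinary least squares fit of stacked scan data
#'
#' Fits `y = X b + e` by OLS, column-wise when `y` is a matrix (scans x
#' voxels), returning everything needed for contrast t-tests.
#'
#' @param y Numeric vector (one value per scan) or matrix (scans x voxels).
#' @param X Design matrix (scans x regressors) with column names.
#' @return A `glm_fit` object: `coefficients` (p x V), `sigma2`, `df`,
#'   `residuals`, `XtX_inv`, `X`.
#' @export
glm_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Y <- as.matrix(y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("y and X disagree on the number of scans")
  if (n <= p) stop("need more scans than regressors")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  XtX_inv <- chol2inv(chol(crossprod(X)))
  B <- XtX_inv %*% crossprod(X, Y)
  R <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(R^2) / df
  structure(list(coefficients = B, sigma2 = sigma2, df = df,
                 residuals = R, XtX_inv = XtX_inv, X = X),
            class = "glm_fit")
}

#' Contrast t-statistics from a GLM fit
#'
#' `t = c'b / sqrt(sigma2 * c' (X'X)^-1 c)` per voxel.
#'
#' @param fit A `glm_fit`.
#' @param contrast Numeric contrast vector (length = regressors) or the
#'   name of a single regressor.
#' @return List with `t` (per voxel), `estimate`, `se`, `df`.
#' @export
glm_contrast <- function(fit, contrast) {
  if (is.character(contrast)) {
    cn <- colnames(fit$X)
    if (!contrast %in% cn) stop("unknown regressor '", contrast, "'")
    cvec <- as.numeric(cn == contrast)
  } else {
    cvec <- as.numeric(contrast)
  }
  est <- as.vector(crossprod(cvec, fit$coefficients))
  vc <- as.numeric(t(cvec) %*% fit$XtX_inv %*% cvec)
  se <- sqrt(fit$sigma2 * vc)
  tv <- ifelse(se > 0, est / se, 0)
  list(t = tv, estimate = est, se = se, df = fit$df)
}

#' Voxel-wise paired t-map
#'
#' One-sample t on the per-subject differences `a - b` at every voxel.
#' Voxels with zero-variance differences are reported as t = 0 and flagged
#' in the `degenerate` mask.
#'
#' @param maps_a,maps_b Lists of `volume`s, matched by subject.
#' @return A `stat_map` object: `t` (`volume`), `df`, `n`, `degenerate`
#'   (binary `volume`).
#' @export
paired_t_map <- function(maps_a, maps_b) {
  if (length(maps_a) != length(maps_b)) stop("unmatched map lists")
  n <- length(maps_a)
  if (n < 2L) stop("need >= 2 subject pairs")
  dm <- dim(maps_a[[1]]$data)
  D <- vapply(seq_len(n), function(i) {
    stop_if_grid_mismatch(maps_a[[i]], maps_b[[i]], "paired maps")
    as.vector(maps_a[[i]]$data - maps_b[[i]]$data)
  }, numeric(prod(dm)))
  m <- rowMeans(D)
  sdd <- sqrt(pmax(rowSums((D - m)^2) / (n - 1), 0))
  degen <- sdd == 0
  tv <- numeric(length(m))
  tv[!degen] <- m[!degen] / (sdd[!degen] / sqrt(n))
  structure(list(
    t = as_volume(array(tv, dim = dm), maps_a[[1]]$affine),
    df = n - 1L, n = n,
    degenerate = as_volume(array(degen * 1, dim = dm), maps_a[[1]]$affine)
  ), class = "stat_map")
}

#' Voxel-wise difference of two volume maps
#'
#' @param gm_new,gm_old `volume`s on one grid.
#' @return `volume` of `gm_new - gm_old`.
#' @export
delta_gm <- function(gm_new, gm_old) {
  gm_new <- as_volume(gm_new); gm_old <- as_volume(gm_old)
  stop_if_grid_mismatch(gm_new, gm_old, "GM maps")
  as_volume(gm_new$data - gm_old$data, gm_new$affine)
}

#' Regress volume differences on R2*
#'
#' Per-voxel OLS of the volume difference on R2*, testing whether iron
#' content (expressed by R2*) explains where the two prior sets disagree.
#' By default an intercept is included so the residuals are zero-mean;
#' `intercept = FALSE` fits the bare proportional model.
#'
#' @param delta Subjects x voxels matrix (or vector, one value per subject).
#' @param r2s Matched R2* values: subjects x voxels matrix or a length-n
#'   vector reused at every voxel.
#' @param intercept Include an intercept? Default TRUE.
#' @return A `regression_result`: `beta`, `t_beta`, `se`, `df`,
#'   `residuals`, `intercept_used`.
#' @export
regress_delta_r2s <- function(delta, r2s, intercept = TRUE) {
  D <- as.matrix(delta)
  n <- nrow(D)
  if (n < 3L) stop("need >= 3 subjects")
  if (is.matrix(r2s) || (is.array(r2s) && length(dim(r2s)) == 2L)) {
    R <- as.matrix(r2s)
    if (!all(dim(R) == dim(D))) stop("delta and r2s dimensions disagree")
  } else {
    R <- matrix(as.numeric(r2s), n, ncol(D))
  }
  if (any(!is.finite(R))) stop("r2s must be finite")
  if (intercept) {
    Rc <- sweep(R, 2, colMeans(R))
    Dc <- sweep(D, 2, colMeans(D))
    df <- n - 2L
  } else {
    Rc <- R; Dc <- D
    df <- n - 1L
  }
  sxx <- colSums(Rc^2)
  if (any(sxx <= 0)) stop("zero variance in r2s at ", sum(sxx <= 0), " voxel(s)")
  beta <- colSums(Rc * Dc) / sxx
  fitted <- sweep(Rc, 2, beta, "*")
  res <- Dc - fitted
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 / sxx)
  tb <- ifelse(se > 0, beta / se, 0)
  structure(list(beta = beta, t_beta = tb, se = se, df = df,
                 residuals = res, intercept_used = intercept),
            class = "regression_result")
}

#' Permutation / sign-flip maxT family-wise error control
#'
#' Builds the null distribution of the maximum absolute statistic across
#' voxels over `n_perm` random relabelings and thresholds the observed map
#' at its `1 - alpha` quantile, controlling the probability of any false
#' positive without distributional assumptions about spatial smoothness.
#'
#' Two exchangeability schemes are supported: `"sign_flip"` for paired /
#' one-sample designs (`data` = subjects x voxels matrix of differences;
#' the statistic is the one-sample t) and `"permute"` for a simple
#' regression (`data` = list with `y`, subjects x voxels, and `x`, the
#' covariate vector whose rows are permuted; the statistic is the slope t).
#' `exhaustive = TRUE` enumerates all 2^n sign patterns instead of
#' sampling, giving the exact test for small n.
#'
#' @param data See above.
#' @param n_perm Number of random draws (>= 100 recommended).
#' @param alpha Family-wise error level, default 0.05.
#' @param seed RNG seed for the draws.
#' @param type `"sign_flip"` or `"permute"`.
#' @param exhaustive Enumerate all sign patterns (sign_flip only).
#' @return List: `t_obs`, `threshold`, `significant` (logical per voxel),
#'   `p_fwe` (maxT-adjusted p-values), `max_t_null`, `alpha`, `type`.
#' @export
permutation_fwe <- function(data, n_perm = 1000L, alpha = 0.05, seed = 1L,
                            type = c("sign_flip", "permute"),
                            exhaustive = FALSE) {
  type <- match.arg(type)
  if (!exhaustive && n_perm < 100L) {
    warning("n_perm < 100 gives a coarse null distribution")
  }
  if (type == "sign_flip") {
    D <- as.matrix(data)
    n <- nrow(D); V <- ncol(D)
    if (n < 2L) stop("need >= 2 subjects")
    ss <- colSums(D^2)
    t_of_signs <- function(S) {
      # S: draws x n matrix of +-1
      M <- (S %*% D) / n
      varr <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
      varr[varr < 0] <- 0
      se <- sqrt(varr / n)
      Tm <- M / se
      Tm[se == 0] <- 0
      Tm
    }
    t_obs <- as.vector(t_of_signs(matrix(1, 1, n)))
    if (exhaustive) {
      if (n > 20L) stop("exhaustive enumeration limited to n <= 20")
      S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      S <- with_seed(seed,
                     matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                            n_perm, n))
    }
    Tn <- t_of_signs(S)
    max_t_null <- apply(abs(Tn), 1, max)
  } else {
    y <- as.matrix(data$y)
    x <- as.numeric(data$x)
    n <- nrow(y)
    if (length(x) != n) stop("covariate length must match rows of y")
    if (stats::sd(x) == 0) stop("non-exchangeable design: constant covariate")
    slope_t <- function(xv) {
      r <- regress_delta_r2s(y, xv, intercept = TRUE)
      r$t_beta
    }
    t_obs <- slope_t(x)
    perms <- with_seed(seed,
                       replicate(n_perm, sample.int(n), simplify = FALSE))
    max_t_null <- vapply(perms, function(p) max(abs(slope_t(x[p]))),
                         numeric(1))
  }
  thr <- stats::quantile(max_t_null, probs = 1 - alpha, type = 1, names = FALSE)
  p_fwe <- vapply(abs(t_obs), function(tv) mean(max_t_null >= tv), numeric(1))
  list(t_obs = t_obs, threshold = thr,
       significant = abs(t_obs) >= thr,
       p_fwe = p_fwe, max_t_null = max_t_null,
       alpha = alpha, type = type)
}

#' Label supra-threshold clusters (26-connectivity)
#'
#' Connected components of `|t| >= threshold` under 26-neighbour
#' connectivity, with peak statistics and peak world coordinates.
#'
#' @param stat A `volume` of statistics.
#' @param threshold Cluster-forming threshold on `|stat|`.
#' @return `data.frame` with one row per cluster: peak coordinates (mm),
#'   peak t, cluster size (voxels), sorted by size.
#' @export
cluster_table <- function(stat, threshold) {
  stat <- as_volume(stat)
  dm <- dim(stat$data)
  supra <- which(abs(stat$data) >= threshold)
  if (length(supra) == 0L) {
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      peak_t = numeric(0), size_vox = integer(0)))
  }
  lab <- integer(prod(dm))
  lab[supra] <- -1L   # unvisited supra-threshold
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  coord <- arrayInd(supra, dm)
  rownames(coord) <- NULL
  idx_of <- function(co) co[, 1] + dm[1] * (co[, 2] - 1) + dm[1] * dm[2] * (co[, 3] - 1)
  next_lab <- 0L
  rows <- list()
  for (s in seq_along(supra)) {
    v <- supra[s]
    if (lab[v] != -1L) next
    next_lab <- next_lab + 1L
    queue <- v
    lab[v] <- next_lab
    members <- v
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0)
      co <- arrayInd(cur, dm)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(co, 2, offs[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
          nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
        if (!any(ok)) next
        ni <- idx_of(nb[ok, , drop = FALSE])
        new <- ni[lab[ni] == -1L]
        if (length(new) > 0L) {
          lab[new] <- next_lab
          queue <- c(queue, new)
          members <- c(members, new)
        }
      }
    }
    peak <- members[which.max(abs(stat$data[members]))]
    pc <- arrayInd(peak, dm) - 1L   # 0-based voxel index
    world <- stat$affine %*% c(pc, 1)
    rows[[next_lab]] <- data.frame(
      x_mm = world[1], y_mm = world[2], z_mm = world[3],
      peak_t = stat$data[peak], size_vox = length(members)
    )
  }
  out <- do.call(rbind, rows)
  out[order(-out$size_vox), , drop = FALSE]
}
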