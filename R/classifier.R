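# 1D clustering for component initialisation: deterministic farthest-point
# seeding (median first, then the point farthest from all chosen centers)
# followed by Lloyd iterations. Farthest-point seeding cannot miss a
# separated minority mode, unlike random restarts.
lloyd_1d <- function(vals, G, n_iter = 25L) {
  centers <- stats::median(vals)
  while (length(centers) < G) {
    d <- Reduce(pmin, lapply(centers, function(ct) abs(vals - ct)))
    centers <- c(centers, vals[which.max(d)])
  }
  centers <- sort(centers)
  assign_g <- NULL
  for (it in seq_len(n_iter)) {
    dmat <- vapply(centers, function(ct) abs(vals - ct),
                   numeric(length(vals)))
    assign_g <- max.col(-dmat, ties.method = "first")
    new_c <- vapply(seq_len(G), function(g) {
      s <- vals[assign_g == g]
      if (length(s) > 0L) mean(s) else centers[g]
    }, numeric(1))
    if (max(abs(new_c - centers)) < 1e-10) { centers <- new_c; break }
    centers <- new_c
  }
  vars <- vapply(seq_len(G), function(g) {
    s <- vals[assign_g == g]
    if (length(s) > 1L) stats::var(s) else NA_real_
  }, numeric(1))
  ord <- order(centers)
  list(centers = centers[ord], vars = vars[ord])
}

#' Prior-weighted Gaussian-mixture tissue classification
#'
#' Fits, by expectation-maximisation, a per-voxel mixture whose mixing
#' weights are the spatial tissue priors (optionally rescaled by fixed
#' global class weights). Each tissue class is modelled by one or more
#' Gaussians over image intensity; the posterior responsibilities are the
#' soft segmentation. There is no bias-field model and no embedded
#' registration: the image must already live on the priors' grid.
#'
#' Multiple Gaussians per class let a class with heterogeneous intensity
#' (e.g. gray matter spanning cortex and iron-rich nuclei) cover several
#' modes. Component means are initialised from a prior-weighted intensity
#' sample by deterministic farthest-point seeding followed by Lloyd
#' iterations, so minority intensity modes are found even when they hold a
#' small share of a class's mass; the sample is controlled by `seed`.
#' Within-class component weights are fixed at equal shares by default
#' (`update_weights = FALSE`): a globally estimated weight would starve
#' the intensity mode of a small structure whose presence is asserted by
#' the spatial prior, precisely the case these priors exist for. With all
#' mixing weights held fixed the EM objective is non-decreasing at every
#' iteration; the maximum-likelihood weight update remains available.
#'
#' @param image A `volume` of intensities.
#' @param priors A normalized `tpm_set` on the image grid.
#' @param n_gauss_per_class Integer vector (recycled) of Gaussians per class.
#' @param tol Relative log-likelihood change for convergence.
#' @param max_iter Maximum EM iterations.
#' @param seed Seed for the initialisation sample.
#' @param class_weights Fixed global class weights (recycled, default 1).
#' @param update_weights Re-estimate within-class component weights by
#'   maximum likelihood (default FALSE: equal fixed shares).
#' @param init_means Optional named list (class name -> numeric vector of
#'   length `n_gauss` for that class) of explicit component mean
#'   initialisations, e.g. prior-weighted intensity anchors; overrides the
#'   sampling-based seeding for those classes.
#' @return A `segmentation` object: `posteriors` (a `tpm_set` of
#'   responsibilities), `params` (data.frame of per-component mean,
#'   variance, within-class weight), `log_likelihood_trace`, `converged`.
#' @export
segment <- function(image, priors, n_gauss_per_class = 1L, tol = 1e-6,
                    max_iter = 100L, seed = 1L, class_weights = 1,
                    update_weights = FALSE, init_means = NULL) {
  image <- as_volume(image)
  if (!inherits(priors, "tpm_set")) stop("priors must be a tpm_set")
  stop_if_grid_mismatch(image, priors$volumes[[1]], "image and priors")
  if (!is_normalized_tpm(priors)) {
    stop("priors are not normalized; call normalize_tpm() first")
  }
  y <- as.vector(image$data)
  if (any(!is.finite(y))) stop("image must be finite")
  K <- length(priors$class_names)
  G <- rep_len(as.integer(n_gauss_per_class), K)
  gamma <- rep_len(as.numeric(class_weights), K)
  P <- tpm_class_matrix(priors)           # V x K
  if (any(gamma != 1)) {
    Pw <- sweep(P, 2, gamma, "*")
    P <- Pw / rowSums(Pw)
  }
  V <- length(y)
  var_floor <- 1e-6 * stats::var(y)

  # initialisation: prior-weighted moments; k-means on a weighted sample
  # for classes with several Gaussians
  mu <- numeric(0); va <- numeric(0); w <- numeric(0)
  comp_class <- integer(0)
  with_seed(seed, {
    for (c in seq_len(K)) {
      pc <- P[, c]
      tw <- sum(pc)
      m1 <- if (tw > 0) sum(pc * y) / tw else mean(y)
      v1 <- if (tw > 0) sum(pc * (y - m1)^2) / tw else stats::var(y)
      v1 <- max(v1, var_floor)
      cname <- priors$class_names[c]
      if (!is.null(init_means) && cname %in% names(init_means)) {
        anchors <- sort(as.numeric(init_means[[cname]]))
        if (length(anchors) != G[c]) {
          stop("init_means for class '", cname, "' must have length ", G[c])
        }
        mu <- c(mu, anchors)
        # limit each anchored component's initial spread to half the gap
        # to its nearest neighbour, so a dominant intensity mode cannot
        # capture components anchored elsewhere during early iterations
        if (G[c] > 1L) {
          gaps <- diff(anchors)
          near <- pmin(c(gaps[1], gaps), c(gaps, gaps[length(gaps)]))
          va <- c(va, pmin(v1, (near / 2)^2))
        } else {
          va <- c(va, v1)
        }
        w <- c(w, rep(1 / G[c], G[c]))
      } else if (G[c] == 1L) {
        mu <- c(mu, m1); va <- c(va, v1); w <- c(w, 1)
      } else {
        ns <- min(5000L, V)
        # restrict the seeding sample to voxels where the class prior is
        # non-negligible: floor-level prior mass spread over the whole
        # volume would otherwise dominate farthest-point seeding
        pos <- pc > 0.01
        if (sum(pos) < G[c]) pos <- pc > 0
        if (sum(pos) < G[c]) {
          idx <- sample.int(V, ns, replace = TRUE)
        } else {
          idx <- sample(which(pos), ns, replace = TRUE,
                        prob = pc[pos])
        }
        cl <- lloyd_1d(y[idx], G[c])
        mu <- c(mu, cl$centers)
        va <- c(va, pmax(ifelse(is.na(cl$vars), v1, cl$vars), var_floor))
        w <- c(w, rep(1 / G[c], G[c]))
      }
      comp_class <- c(comp_class, rep.int(c, G[c]))
    }
  })
  # components with identical means AND identical spatial priors start at
  # a symmetric EM fixed point (e.g. flat priors give every class the same
  # moment init); spread such duplicates over intensity quantiles so they
  # can separate. Equal means under different priors are left alone: the
  # priors themselves break the symmetry.
  ncomp <- length(mu)
  dup <- rep(FALSE, ncomp)
  if (ncomp > 1L) {
    for (j in 2:ncomp) {
      for (k in 1:(j - 1L)) {
        if (!dup[j] && !dup[k] &&
            signif(mu[j], 8) == signif(mu[k], 8) &&
            (comp_class[j] == comp_class[k] ||
             identical(P[, comp_class[j]], P[, comp_class[k]]))) {
          dup[j] <- TRUE
        }
      }
    }
  }
  if (any(dup)) {
    nd <- sum(dup)
    mu[dup] <- stats::quantile(y, probs = (seq_len(nd) - 0.5) / nd,
                               names = FALSE)
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  ncomp <- length(mu)
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    # E step
    like <- matrix(0, V, ncomp)
    for (j in seq_len(ncomp)) {
      like[, j] <- P[, comp_class[j]] * w[j] *
        stats::dnorm(y, mu[j], sqrt(va[j]))
    }
    s <- rowSums(like)
    zero <- s <= 0
    if (any(zero)) {
      # numerically impossible voxels: fall back to the prior
      like[zero, ] <- P[zero, comp_class, drop = FALSE] *
        rep(w, each = sum(zero))
      s[zero] <- rowSums(like[zero, , drop = FALSE])
      s[s <= 0] <- 1
    }
    ll <- sum(log(s[!zero]))
    ll_trace <- c(ll_trace, ll)
    resp <- like / s
    if (is.finite(ll_prev) &&
        (ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M step
    nk <- colSums(resp)
    degen <- nk <= V * 1e-12
    for (j in seq_len(ncomp)) {
      if (degen[j]) {
        va[j] <- max(va[j], var_floor)
        next
      }
      mu[j] <- sum(resp[, j] * y) / nk[j]
      va[j] <- max(sum(resp[, j] * (y - mu[j])^2) / nk[j], var_floor)
    }
    if (any(degen)) {
      warning("degenerate component(s): variance floored")
    }
    if (update_weights) {
      for (c in seq_len(K)) {
        jj <- which(comp_class == c)
        if (length(jj) > 1L) {
          tot <- sum(nk[jj])
          if (tot > 0) w[jj] <- nk[jj] / tot
        }
      }
    }
  }

  dm <- dim(image$data)
  post <- lapply(seq_len(K), function(c) {
    jj <- which(comp_class == c)
    as_volume(array(rowSums(resp[, jj, drop = FALSE]), dim = dm),
              image$affine)
  })
  names(post) <- priors$class_names
  structure(list(
    posteriors = tpm_set(post),
    params = data.frame(class = priors$class_names[comp_class],
                        mean = mu, variance = va, weight = w),
    log_likelihood_trace = ll_trace,
    converged = converged
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d classes, %d EM iterations (%s)\n",
              length(x$posteriors$class_names),
              length(x$log_likelihood_trace),
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Gray-matter volume inside a consensus region
#'
#' Volume (mm^3) of consensus voxels whose gray-matter probability reaches
#' the threshold; the comparison is `>=`.
#'
#' @param gm_post Gray-matter probability `volume`.
#' @param consensus Binary `volume` (voxels labeled by all raters).
#' @param threshold GM probability cut-off, default 0.2.
#' @return Scalar volume in mm^3.
#' @export
gm_volume_in_consensus <- function(gm_post, consensus, threshold = 0.2) {
  gm_post <- as_volume(gm_post)
  consensus <- as_label_mask(consensus)
  stop_if_grid_mismatch(gm_post, consensus, "GM map and consensus")
  if (sum(consensus$data) == 0) stop("empty consensus mask")
  voxel_volume(gm_post) * sum(consensus$data * (gm_post$data >= threshold))
}

#' Dice overlap between a thresholded probability map and a mask
#'
#' @param gm_post Probability `volume`.
#' @param consensus Binary `volume`.
#' @param threshold Probability cut-off (`>=`).
#' @return Scalar Dice coefficient.
#' @export
overlap_dice <- function(gm_post, consensus, threshold) {
  gm_post <- as_volume(gm_post)
  consensus <- as_label_mask(consensus)
  stop_if_grid_mismatch(gm_post, consensus, "GM map and consensus")
  dice(as_volume((gm_post$data >= threshold) * 1, gm_post$affine), consensus)
}

#' Paired t-test that tolerates zero variance
#'
#' One-sample t on the paired differences. When the differences have zero
#' variance the statistic is reported as 0 with `degenerate = TRUE` rather
#' than failing, so batch harnesses survive identical inputs.
#'
#' @param x,y Numeric vectors of paired measurements.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must match in length")
  d <- x - y
  n <- length(d)
  if (n < 2L) stop("need >= 2 pairs")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(t = 0, df = n - 1L, p = 1, mean_diff = mean(d),
                degenerate = TRUE))
  }
  tv <- mean(d) / (sdd / sqrt(n))
  list(t = tv, df = n - 1L, p = 2 * stats::pt(-abs(tv), n - 1L),
       mean_diff = mean(d), degenerate = FALSE)
}
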