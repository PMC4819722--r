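#' Default phantom specification
#'
#' A desk-scale digital brain phantom: a 64^3 grid at 1 mm isotropic
#' resolution holding a CSF rim, a cortical gray-matter shell, a
#' white-matter core, and four ellipsoidal "nuclei" (caudate-, putamen-,
#' pallidum-, and thalamus-like) embedded in the white matter. All nuclei
#' are gray matter by tissue class, but the pallidum-like nucleus carries
#' WM-like intensity on both channels — the hardest case for an
#' intensity-driven classifier, mimicking the effect of high iron content.
#'
#' Two intensity channels are generated: `mt` (an MT-saturation-like map
#' with good subcortical contrast except in the iron-rich nucleus) and
#' `t1w` (a T1-weighted-like map). The iron model makes the pallidum-like
#' nucleus's R2* rise linearly with age and its T1w intensity drift toward
#' the white-matter mean in proportion to that R2* elevation, so that
#' gray–white contrast is lost with age while true nucleus volume stays
#' constant.
#'
#' @param grid_shape Integer length-3 grid size; default `c(64, 64, 64)`.
#' @param voxel_size_mm Isotropic voxel edge (mm); default 1.
#' @param noise_sd Gaussian intensity noise SD (intensity units); default 3.
#' @return A `phantom_spec` list; see fields in the source.
#' @export
default_phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                                 voxel_size_mm = 1,
                                 noise_sd = 3) {
  ctr <- (grid_shape - 1) / 2
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    affine = rbind(cbind(diag(3) * voxel_size_mm,
                         -ctr * voxel_size_mm), c(0, 0, 0, 1)),
    # tissue envelope radii (mm, from grid centre)
    radius_csf = 28, radius_gm = 26, radius_wm = 20,
    structures = list(
      caudate  = list(center = c(10, 6, 4),   axes = c(5, 6, 5)),
      putamen  = list(center = c(-10, 4, 2),  axes = c(6, 7, 5)),
      pallidum = list(center = c(-5, -10, 0), axes = c(6.5, 6.5, 6.5)),
      thalamus = list(center = c(7, -6, -2),  axes = c(6, 5, 5))
    ),
    # class-conditional intensity means; nuclei override the GM mean
    intensity = list(
      mt  = c(BG = 2, CSF = 8, GM = 35, WM = 70,
              caudate = 35, putamen = 35, pallidum = 62, thalamus = 38),
      t1w = c(BG = 2, CSF = 15, GM = 60, WM = 90,
              caudate = 60, putamen = 62, pallidum = 75, thalamus = 65)
    ),
    noise_sd = noise_sd,
    # baseline R2* (1/s) per tissue; the iron model overrides the pallidum
    r2s = c(BG = 0.5, CSF = 1, GM = 20, WM = 25,
            caudate = 30, putamen = 35, pallidum = 40, thalamus = 25),
    iron = list(
      structure = "pallidum",
      r2s_base = 40,            # 1/s at the reference age
      r2s_age_slope = 0.4,      # 1/s per year
      age_ref = 40,             # years
      contrast_loss_coeff = 0.8 # T1w intensity units per (1/s) of R2*
    )
  ), class = "phantom_spec")
}

ellipsoid_mask <- function(spec, center_mm, axes_mm) {
  gs <- spec$grid_shape
  ctr <- (gs - 1) / 2 * spec$voxel_size_mm
  x <- (seq_len(gs[1]) - 1) * spec$voxel_size_mm - ctr[1] - center_mm[1]
  y <- (seq_len(gs[2]) - 1) * spec$voxel_size_mm - ctr[2] - center_mm[2]
  z <- (seq_len(gs[3]) - 1) * spec$voxel_size_mm - ctr[3] - center_mm[3]
  q <- outer(outer((x / axes_mm[1])^2, (y / axes_mm[2])^2, "+"),
             (z / axes_mm[3])^2, "+")
  (q <= 1) * 1
}

# deterministic label volume: 0 BG, 1 CSF, 2 GM, 3 WM, 4.. nuclei
phantom_labels <- function(spec) {
  csf <- ellipsoid_mask(spec, c(0, 0, 0), rep(spec$radius_csf, 3))
  gm <- ellipsoid_mask(spec, c(0, 0, 0), rep(spec$radius_gm, 3))
  wm <- ellipsoid_mask(spec, c(0, 0, 0), rep(spec$radius_wm, 3))
  lab <- csf * 1
  lab[gm == 1] <- 2
  lab[wm == 1] <- 3
  for (i in seq_along(spec$structures)) {
    s <- spec$structures[[i]]
    m <- ellipsoid_mask(spec, s$center, s$axes)
    if (any(m == 1 & lab != 3)) {
      stop("structure '", names(spec$structures)[i],
           "' exceeds the white-matter core")
    }
    lab[m == 1] <- 3 + i
  }
  lab
}

label_name <- function(spec, code) {
  c("BG", "CSF", "GM", "WM", names(spec$structures))[code + 1]
}

#' Generate one phantom subject
#'
#' Builds the deterministic label geometry, assigns class-conditional mean
#' intensities on both channels, applies the iron model for the configured
#' age (nucleus R2* = base + slope x (age - reference age); the nucleus's
#' T1w mean shifts toward the WM mean by `contrast_loss_coeff` per unit of
#' R2* elevation, capped at the WM mean), and adds Gaussian voxel noise.
#' Fully deterministic given `(spec, age, seed)`.
#'
#' @param spec A `phantom_spec`.
#' @param age Subject age in years.
#' @param seed RNG seed for the noise.
#' @return A `phantom_subject`: `labels`, `mt`, `t1w` (`volume`s),
#'   `r2s_true` (`volume`, 1/s), `nuclei_masks` (list of binary
#'   `volume`s), `age`, `nucleus_r2s` (scalar truth for the iron-model
#'   structure).
#' @export
make_phantom <- function(spec, age, seed = 1L) {
  lab <- phantom_labels(spec)
  aff <- spec$affine
  iron <- spec$iron
  r2s_nuc <- iron$r2s_base + iron$r2s_age_slope * (age - iron$age_ref)

  mean_map <- function(channel) {
    mu <- spec$intensity[[channel]]
    m <- array(0, dim = spec$grid_shape)
    for (code in 0:(3 + length(spec$structures))) {
      nm <- label_name(spec, code)
      m[lab == code] <- mu[[nm]]
    }
    if (channel == "t1w") {
      shift <- iron$contrast_loss_coeff * (r2s_nuc - iron$r2s_base)
      icode <- 3 + match(iron$structure, names(spec$structures))
      m[lab == icode] <- min(mu[[iron$structure]] + shift, mu[["WM"]])
    }
    m
  }
  r2s <- array(0, dim = spec$grid_shape)
  for (code in 0:(3 + length(spec$structures))) {
    r2s[lab == code] <- spec$r2s[[label_name(spec, code)]]
  }
  icode <- 3 + match(iron$structure, names(spec$structures))
  r2s[lab == icode] <- r2s_nuc

  nvox <- prod(spec$grid_shape)
  noise <- with_seed(seed, list(
    mt = array(stats::rnorm(nvox, 0, spec$noise_sd), dim = spec$grid_shape),
    t1w = array(stats::rnorm(nvox, 0, spec$noise_sd), dim = spec$grid_shape)
  ))
  nuclei <- lapply(seq_along(spec$structures), function(i) {
    as_volume((lab == 3 + i) * 1, aff)
  })
  names(nuclei) <- names(spec$structures)
  structure(list(
    labels = as_volume(lab, aff),
    mt = as_volume(mean_map("mt") + noise$mt, aff),
    t1w = as_volume(mean_map("t1w") + noise$t1w, aff),
    r2s_true = as_volume(r2s, aff),
    nuclei_masks = nuclei,
    age = age,
    nucleus_r2s = r2s_nuc
  ), class = "phantom_subject")
}

# binary array of voxels on either side of the label surface
# (voxels with at least one 6-neighbour of the opposite value)
boundary_layer <- function(mask_data) {
  d <- dim(mask_data)
  differs <- array(FALSE, dim = d)
  for (axis in 1:3) {
    n <- d[axis]
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(mask_data, perm), nrow = n)
    df <- matrix(FALSE, n, ncol(m))
    df[-1, ] <- df[-1, ] | (m[-1, ] != m[-n, ])
    df[-n, ] <- df[-n, ] | (m[-1, ] != m[-n, ])
    differs <- differs | aperm(array(df, dim = d[perm]), order(perm))
  }
  differs
}

#' Simulate rater masks by boundary-layer flips
#'
#' Each simulated rater copies the true mask and independently flips each
#' voxel in the boundary layer (surface voxels and their immediate
#' neighbours across the surface) with probability `flip_prob`, so
#' disagreement concentrates at structure borders as in real manual
#' labels. Interior voxels are never touched.
#'
#' @param truth Binary `volume` (true structure mask), non-empty.
#' @param n_raters Number of raters.
#' @param flip_prob Per-voxel flip probability in [0, 0.5).
#' @param seed RNG seed.
#' @return List of `n_raters` binary `volume`s.
#' @export
simulate_raters <- function(truth, n_raters, flip_prob, seed = 1L) {
  truth <- as_label_mask(truth)
  if (sum(truth$data) == 0) stop("empty truth mask")
  if (flip_prob < 0 || flip_prob >= 0.5) stop("flip_prob must be in [0, 0.5)")
  bl <- which(boundary_layer(truth$data))
  with_seed(seed, {
    lapply(seq_len(n_raters), function(r) {
      m <- truth$data
      if (flip_prob > 0 && length(bl) > 0) {
        flip <- bl[stats::runif(length(bl)) < flip_prob]
        m[flip] <- 1 - m[flip]
      }
      as_volume(m, truth$affine)
    })
  })
}

#' Closed-form expected pairwise Dice under the boundary-flip model
#'
#' For the rater model of [simulate_raters()]: with I interior labeled
#' voxels, B1 boundary-layer voxels labeled in truth and B0 unlabeled
#' boundary-layer voxels, each flipped independently with probability p by
#' each of two raters,
#' `E|A n B| = I + B1 (1-p)^2 + B0 p^2` and
#' `E|A| = I + B1 (1-p) + B0 p`; the expected Dice is approximated by the
#' ratio of expectations.
#'
#' @param truth Binary `volume`.
#' @param flip_prob Flip probability.
#' @return Scalar expected Dice.
#' @export
expected_pairwise_dice <- function(truth, flip_prob) {
  truth <- as_label_mask(truth)
  bl <- boundary_layer(truth$data)
  b1 <- sum(truth$data == 1 & bl)
  b0 <- sum(truth$data == 0 & bl)
  interior <- sum(truth$data == 1 & !bl)
  p <- flip_prob
  num <- interior + b1 * (1 - p)^2 + b0 * p^2
  den <- interior + b1 * (1 - p) + b0 * p
  num / den
}

#' Simulate a smooth invertible deformation field
#'
#' Gaussian-filtered white-noise displacement components, rescaled so the
#' largest displacement magnitude equals `amplitude_mm`. If any Jacobian
#' determinant is non-positive the amplitude is halved (with a warning)
#' until the field is invertible.
#'
#' @param grid_shape Integer length-3.
#' @param amplitude_mm Maximum displacement magnitude (mm); 0 gives the
#'   identity field.
#' @param smoothness_mm FWHM (mm) of the smoothing applied to the noise.
#' @param seed RNG seed.
#' @param affine Target-grid affine (voxel sizes are read from it).
#' @return A `deformation_field` with everywhere-positive Jacobian.
#' @export
simulate_deformation <- function(grid_shape, amplitude_mm, smoothness_mm = 8,
                                 seed = 1L, affine = diag(4)) {
  grid_shape <- as.integer(grid_shape)
  disp <- array(0, dim = c(grid_shape, 3L))
  if (amplitude_mm > 0) {
    vox <- sqrt(colSums(as.matrix(affine)[1:3, 1:3]^2))
    sigma <- fwhm_to_sigma(smoothness_mm, vox)
    raw <- with_seed(seed, array(stats::rnorm(prod(grid_shape) * 3),
                                 dim = c(grid_shape, 3L)))
    for (k in 1:3) raw[, , , k] <- smooth_array(raw[, , , k], sigma)
    mag <- sqrt(raw[, , , 1]^2 + raw[, , , 2]^2 + raw[, , , 3]^2)
    mmax <- max(mag)
    if (mmax > 0) {
      amp <- amplitude_mm
      for (try in 1:10) {
        for (k in 1:3) {
          disp[, , , k] <- raw[, , , k] / mmax * (amp / vox[k])
        }
        jd <- jacobian_determinant(as_deformation(disp, affine))
        if (min(jd$data) > 0) break
        amp <- amp / 2
        warning("non-positive Jacobian; amplitude reduced to ", amp, " mm")
      }
    }
  }
  as_deformation(disp, affine)
}

#' Simulate a multi-echo magnitude series
#'
#' `S(TE) = S0 exp(-R2* TE) + noise`, with R2* supplied in 1/s and echo
#' times in ms.
#'
#' @param r2s_true R2* `volume` (1/s).
#' @param s0 Signal-at-zero-TE `volume`.
#' @param tes Echo times (ms), strictly increasing; default
#'   [default_echo_times()].
#' @param noise_sd Gaussian noise SD (signal units); >= 0.
#' @param seed RNG seed.
#' @return A `multi_echo_series`.
#' @export
simulate_multiecho <- function(r2s_true, s0, tes = default_echo_times(),
                               noise_sd = 0, seed = 1L) {
  r2s_true <- as_volume(r2s_true); s0 <- as_volume(s0)
  stop_if_grid_mismatch(r2s_true, s0, "R2* and S0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  nvox <- length(s0$data)
  vols <- with_seed(seed, lapply(tes, function(te) {
    sig <- s0$data * exp(-(r2s_true$data / 1000) * te)
    if (noise_sd > 0) {
      sig <- sig + array(stats::rnorm(nvox, 0, noise_sd),
                         dim = dim(sig))
    }
    as_volume(sig, s0$affine)
  }))
  multi_echo_series(vols, tes)
}

#' Conventional (nucleus-blind) tissue priors for a phantom
#'
#' Emulates T1w-derived priors that miss iron-rich nuclei: the pallidum-like
#' structure is assigned to the white-matter prior (its T1w appearance),
#' while the remaining nuclei go to gray matter. One-hot class maps are
#' smoothed and normalized with a small probability floor so every class
#' keeps non-zero prior mass everywhere.
#'
#' @param spec A `phantom_spec`.
#' @param fwhm_mm Prior smoothness (mm); default 6.
#' @param floor Probability floor; default 1e-3.
#' @return A normalized `tpm_set` with classes GM, WM, CSF, BG.
#' @export
make_base_tpm <- function(spec, fwhm_mm = 6, floor = 1e-3) {
  lab <- phantom_labels(spec)
  aff <- spec$affine
  wm_like <- spec$iron$structure
  gm <- (lab == 2) * 1
  wm <- (lab == 3) * 1
  for (i in seq_along(spec$structures)) {
    tgt <- if (names(spec$structures)[i] == wm_like) quote(wm) else quote(gm)
    m <- (lab == 3 + i) * 1
    if (identical(tgt, quote(wm))) wm <- wm + m else gm <- gm + m
  }
  vols <- list(
    GM = as_volume(gm, aff),
    WM = as_volume(wm, aff),
    CSF = as_volume((lab == 1) * 1, aff),
    BG = as_volume((lab == 0) * 1, aff)
  )
  sm <- lapply(vols, gaussian_smooth_fwhm, fwhm_mm = fwhm_mm)
  normalize_tpm(tpm_set(sm), floor = floor, background = "BG")
}

#' Generate an age cohort of phantom subjects
#'
#' Ages are spread evenly over `age_range` (a regular sample of the design
#' range, maximising contrast for age regressions at small n). Every
#' subject gets a phantom (geometry identical across subjects; noise and
#' the iron model differ), per-structure rater masks, and a small smooth
#' deformation standing in for estimated registration. Per-subject seeds
#' are drawn once from `seed`, so the cohort is fully reproducible. With
#' `out_dir` set, NIfTI volumes plus `manifest.csv` and `covars.csv` are
#' written.
#'
#' @param spec A `phantom_spec`.
#' @param n_subjects Number of subjects (>= 3).
#' @param age_range Length-2 numeric (years); default `c(21, 88)`.
#' @param seed Master RNG seed.
#' @param n_raters Raters per structure; default 4.
#' @param flip_prob Rater boundary flip probability; default 0.1.
#' @param deform_amplitude_mm Max displacement of the per-subject
#'   deformation; default 0.7.
#' @param deform_smoothness_mm Deformation smoothness FWHM; default 8.
#' @param out_dir Optional output directory for NIfTI + CSV artifacts.
#' @return A `phantom_cohort`: `spec`, `subjects` (list with `phantom`,
#'   `raters` (structure -> list of masks), `deformation`, `age`,
#'   `gender`, `tiv`, `id`), `covariates` (data.frame), `manifest`
#'   (data.frame; paths filled when `out_dir` is used).
#' @export
make_age_cohort <- function(spec = default_phantom_spec(), n_subjects,
                            age_range = c(21, 88), seed = 1L,
                            n_raters = 4L, flip_prob = 0.1,
                            deform_amplitude_mm = 0.7,
                            deform_smoothness_mm = 8,
                            out_dir = NULL) {
  if (n_subjects < 3L) stop("need >= 3 subjects")
  if (n_subjects > 1L && age_range[1] >= age_range[2]) {
    stop("degenerate age range")
  }
  ages <- seq(age_range[1], age_range[2], length.out = n_subjects)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          n_subjects * 3L))
  subjects <- vector("list", n_subjects)
  vv <- abs(det(spec$affine[1:3, 1:3]))
  for (i in seq_len(n_subjects)) {
    ph <- make_phantom(spec, ages[i], seed = sub_seeds[i])
    raters <- lapply(names(spec$structures), function(nm) {
      simulate_raters(ph$nuclei_masks[[nm]], n_raters, flip_prob,
                      seed = sub_seeds[n_subjects + i] +
                        match(nm, names(spec$structures)))
    })
    names(raters) <- names(spec$structures)
    def <- simulate_deformation(spec$grid_shape, deform_amplitude_mm,
                                deform_smoothness_mm,
                                seed = sub_seeds[2L * n_subjects + i],
                                affine = spec$affine)
    brain_vox <- sum(ph$labels$data > 0)
    # recorded TIV carries a few percent of measurement spread so it can
    # act as a covariate even though the geometry is shared
    tiv_jitter <- with_seed(sub_seeds[i] + 7L, stats::runif(1, 0.97, 1.03))
    subjects[[i]] <- list(
      id = sprintf("sub%02d", i),
      phantom = ph,
      raters = raters,
      deformation = def,
      age = ages[i],
      gender = if (i %% 2L == 0L) "F" else "M",
      tiv = brain_vox * vv * tiv_jitter
    )
  }
  cov <- data.frame(
    subject = vapply(subjects, `[[`, character(1), "id"),
    age = ages,
    gender = vapply(subjects, `[[`, character(1), "gender"),
    tiv = vapply(subjects, `[[`, numeric(1), "tiv"),
    stringsAsFactors = FALSE
  )
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rows <- list()
    for (s in subjects) {
      base <- file.path(out_dir, s$id)
      write_volume(s$phantom$mt, paste0(base, "_mt.nii.gz"))
      write_volume(s$phantom$t1w, paste0(base, "_t1w.nii.gz"))
      for (nm in names(s$raters)) {
        for (r in seq_along(s$raters[[nm]])) {
          mp <- sprintf("%s_%s_rater%d.nii.gz", base, nm, r)
          write_volume(s$raters[[nm]][[r]], mp)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s$id, rater = r, structure = nm,
            mask_path = mp,
            mt_path = paste0(base, "_mt.nii.gz"),
            t1w_path = paste0(base, "_t1w.nii.gz"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(cov, file.path(out_dir, "covars.csv"),
                     row.names = FALSE)
  }
  structure(list(spec = spec, subjects = subjects, covariates = cov,
                 manifest = manifest, seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, ages %s-%s, grid %s\n",
              length(x$subjects),
              min(x$covariates$age), max(x$covariates$age),
              paste(x$spec$grid_shape, collapse = "x")))
  invisible(x)
}
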