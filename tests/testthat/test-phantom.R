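test_that("phantom generation is deterministic and respects the iron model", {
  spec <- default_phantom_spec()
  p1 <- make_phantom(spec, age = 40, seed = 7)
  p2 <- make_phantom(spec, age = 40, seed = 7)
  expect_identical(p1$mt$data, p2$mt$data)
  expect_identical(p1$t1w$data, p2$t1w$data)
  p3 <- make_phantom(spec, age = 40, seed = 8)
  expect_false(identical(p1$mt$data, p3$mt$data))
  expect_identical(p1$labels$data, p3$labels$data)

  # at the reference age the nucleus R2* equals its baseline
  expect_equal(p1$nucleus_r2s, spec$iron$r2s_base)
  older <- make_phantom(spec, age = 60, seed = 7)
  expect_equal(older$nucleus_r2s,
               spec$iron$r2s_base + 20 * spec$iron$r2s_age_slope)

  # noiseless intensities sit exactly at the class means
  spec0 <- default_phantom_spec(noise_sd = 1e-12)
  p0 <- make_phantom(spec0, age = spec0$iron$age_ref, seed = 1)
  wm <- p0$labels$data == 3
  expect_equal(max(abs(p0$mt$data[wm] - spec0$intensity$mt[["WM"]])), 0,
               tolerance = 1e-9)
  pal <- p0$nuclei_masks$pallidum$data == 1
  expect_equal(mean(p0$t1w$data[pal]), spec0$intensity$t1w[["pallidum"]],
               tolerance = 1e-9)

  # the T1w nucleus mean drifts toward (and never past) the WM mean
  pold <- make_phantom(spec0, age = 150, seed = 1)
  expect_equal(mean(pold$t1w$data[pal]), spec0$intensity$t1w[["WM"]],
               tolerance = 1e-9)
})

test_that("structures outside the white-matter core are rejected", {
  spec <- default_phantom_spec()
  spec$structures$pallidum$center <- c(30, 0, 0)
  expect_error(make_phantom(spec, 40, 1), "exceeds")
})

test_that("simulated raters flip only boundary voxels at the set rate", {
  truth <- ball_mask(c(18L, 18L, 18L), radius = 5)
  r0 <- simulate_raters(truth, 4, 0, seed = 1)
  for (m in r0) expect_identical(m$data, truth$data)

  raters <- simulate_raters(truth, 4, 0.2, seed = 2)
  bl <- subprior:::boundary_layer(truth$data)
  for (m in raters) {
    expect_true(all((m$data == truth$data) | bl))
  }
  flips <- vapply(raters, function(m) sum(m$data != truth$data), numeric(1))
  expect_lt(abs(mean(flips) / sum(bl) - 0.2), 0.05)

  one <- simulate_raters(truth, 1, 0.2, seed = 3)
  expect_length(one, 1L)
  expect_error(pairwise_summary(one), ">= 2")
  expect_error(simulate_raters(truth, 2, 0.6, seed = 1), "flip_prob")
  empty <- as_volume(array(0, dim = c(4L, 4L, 4L)))
  expect_error(simulate_raters(empty, 2, 0.1, 1), "empty")
})

test_that("simulated deformations are smooth, bounded and invertible", {
  d0 <- simulate_deformation(c(10L, 10L, 10L), amplitude_mm = 0, seed = 1)
  expect_true(all(d0$disp == 0))

  for (s in 1:20) {
    d <- simulate_deformation(c(12L, 12L, 12L), amplitude_mm = 1.5,
                              smoothness_mm = 6, seed = s)
    mag <- sqrt(d$disp[, , , 1]^2 + d$disp[, , , 2]^2 + d$disp[, , , 3]^2)
    expect_equal(max(mag), 1.5, tolerance = 1e-9)
    expect_gt(min(jacobian_determinant(d)$data), 0)
  }
})

test_that("warping there-and-back through the inverted field preserves labels", {
  truth <- ball_mask(c(16L, 16L, 16L), radius = 5)
  d <- simulate_deformation(c(16L, 16L, 16L), amplitude_mm = 1,
                            smoothness_mm = 8, seed = 11)
  # numerical inverse by fixed-point iteration on the displacement
  inv <- d
  for (it in 1:30) {
    w <- array(0, dim = dim(d$disp))
    for (k in 1:3) {
      w[, , , k] <- apply_deformation(
        as_volume(d$disp[, , , k], d$affine), inv)$data
    }
    inv$disp <- -w
  }
  fwd <- apply_deformation(truth, d)
  back <- apply_deformation(fwd, inv)
  back_bin <- as_volume((back$data >= 0.5) * 1, back$affine)
  expect_gte(dice(back_bin, truth), 0.95)
})

test_that("multi-echo simulation closes the loop with the R2* fit", {
  spec <- default_phantom_spec()
  ph <- make_phantom(spec, 55, seed = 3)
  s0 <- as_volume(array(100, dim = spec$grid_shape), spec$affine)
  series <- simulate_multiecho(ph$r2s_true, s0, noise_sd = 0, seed = 1)
  expect_equal(series$echo_times, default_echo_times())
  mask <- ph$nuclei_masks$pallidum
  fit <- fit_r2star(series, mask)
  est <- fit$r2star$data[mask$data == 1]
  expect_lt(max(abs(est - ph$nucleus_r2s)), 1e-8)

  s1 <- simulate_multiecho(ph$r2s_true, s0, noise_sd = 2, seed = 9)
  s2 <- simulate_multiecho(ph$r2s_true, s0, noise_sd = 2, seed = 9)
  expect_identical(s1$volumes[[3]]$data, s2$volumes[[3]]$data)
  expect_error(simulate_multiecho(ph$r2s_true, s0, noise_sd = -1), "noise_sd")
})

test_that("age cohorts are reproducible with shared geometry", {
  co <- make_age_cohort(n_subjects = 4, seed = 5)
  expect_length(co$subjects, 4L)
  expect_equal(range(co$covariates$age), c(21, 88))
  co2 <- make_age_cohort(n_subjects = 4, seed = 5)
  expect_identical(co$subjects[[2]]$phantom$t1w$data,
                   co2$subjects[[2]]$phantom$t1w$data)
  co3 <- make_age_cohort(n_subjects = 4, seed = 6)
  expect_false(identical(co$subjects[[2]]$phantom$t1w$data,
                         co3$subjects[[2]]$phantom$t1w$data))
  expect_identical(co$subjects[[2]]$phantom$labels$data,
                   co3$subjects[[2]]$phantom$labels$data)
  expect_error(make_age_cohort(n_subjects = 2, seed = 1), ">= 3")
  expect_error(make_age_cohort(n_subjects = 4, age_range = c(50, 50)),
               "degenerate")
})

test_that("cohort manifests reference loadable files", {
  dir <- withr::local_tempdir()
  co <- make_age_cohort(n_subjects = 3, seed = 2, out_dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3 * 4 * 4)  # subjects x structures x raters
  expect_true(all(file.exists(man$mask_path)))
  m <- read_volume(man$mask_path[1])
  expect_true(all(m$data %in% c(0, 1)))
  cov <- read.csv(file.path(dir, "covars.csv"))
  expect_equal(nrow(cov), 3L)
  expect_true(all(c("subject", "age", "gender", "tiv") %in% names(cov)))
})

test_that("cohort nucleus R2* regression recovers the generating slope", {
  spec <- default_phantom_spec()
  co <- make_age_cohort(spec, n_subjects = 10, seed = 3)
  s0 <- as_volume(array(100, dim = spec$grid_shape), spec$affine)
  r2s <- vapply(co$subjects, function(s) {
    nuc <- s$phantom$nuclei_masks[[spec$iron$structure]]
    series <- simulate_multiecho(s$phantom$r2s_true, s0, noise_sd = 2,
                                 seed = round(s$age))
    fit <- fit_r2star(series, nuc)
    mean(fit$r2star$data[nuc$data == 1], na.rm = TRUE)
  }, numeric(1))
  fit <- glm_fit(r2s, cbind(intercept = 1, age = co$covariates$age))
  ct <- glm_contrast(fit, "age")
  expect_lt(abs(ct$estimate - spec$iron$r2s_age_slope), 3 * ct$se + 1e-6)
})
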