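test_that("modulate: identity, constant expansion, mass conservation", {
  gm <- ball_mask(c(24L, 24L, 24L), radius = 6)
  id <- identity_deformation(dim(gm))
  expect_equal(modulate(gm, id)$data, gm$data, tolerance = 1e-12)

  # disp = x (doubling coordinates): jacobian 2^3 = 8 where defined
  n <- 24L
  ix <- array(rep(0:(n - 1), n * n), dim = c(n, n, n))
  d <- identity_deformation(c(n, n, n))
  d$disp[, , , 1] <- ix
  d$disp[, , , 2] <- aperm(ix, c(2, 1, 3))
  d$disp[, , , 3] <- aperm(ix, c(3, 2, 1))
  flat <- as_volume(array(1, dim = c(n, n, n)))
  m <- modulate(flat, d)
  # interior samples stay inside the grid up to index (n-1)/2
  expect_equal(m$data[5, 5, 5], 8, tolerance = 1e-9)

  # smooth random warp conserves the total integral within 1 percent
  dsm <- simulate_deformation(c(24L, 24L, 24L), amplitude_mm = 1.5,
                              smoothness_mm = 8, seed = 6)
  mm <- modulate(gm, dsm)
  expect_lt(abs(sum(mm$data) - sum(gm$data)), 0.01 * sum(gm$data))
})

test_that("weighted smoothing: unit weights, constants, no bleed", {
  dims <- c(20L, 20L, 20L)
  set.seed(4)
  x <- as_volume(array(runif(prod(dims)), dim = dims))
  w1 <- as_volume(array(1, dim = dims))
  ws <- weighted_smooth(x, w1, 4)
  ps <- gaussian_smooth_fwhm(x, 4)
  # identical where the kernel support stays inside the grid; at the
  # zero-padded faces the weighted form renormalizes by construction
  r <- ceiling(4 * fwhm_to_sigma(4, 1))
  core <- (r + 1):(20 - r)
  expect_lt(max(abs(ws$data[core, core, core] - ps$data[core, core, core])),
            1e-10)

  # constant value under a compact weight: ratio cancels exactly
  w <- as_volume(array(0, dim = dims))
  w$data[6:15, 6:15, 6:15] <- 1
  xc <- as_volume(array(0.42, dim = dims))
  wc <- weighted_smooth(xc, w, 6)
  expect_equal(wc$data[10, 10, 10], 0.42, tolerance = 1e-10)

  # two-compartment phantom: values from the w = 0 region must not bleed
  x2 <- as_volume(array(1000, dim = dims))
  x2$data[w$data == 1] <- 1
  b <- weighted_smooth(x2, w, 6)
  inner <- b$data[8:13, 8:13, 8:13]
  expect_lt(max(abs(inner - 1)), 1e-6)

  expect_error(weighted_smooth(x, as_volume(array(0, dim = dims)), 6),
               "all-zero")
})

test_that("glm_fit is exact on noiseless data and flags collinearity", {
  age <- c(20, 30, 40, 50, 60, 70)
  X <- cbind(age = age, intercept = 1)
  y <- 2 * age + 1
  fit <- glm_fit(y, X)
  expect_equal(as.vector(fit$coefficients), c(2, 1), tolerance = 1e-10)

  # permutation of scans leaves the estimate unchanged
  p <- c(3, 1, 6, 2, 5, 4)
  fit2 <- glm_fit(y[p], X[p, ])
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)

  Xbad <- cbind(age = age, twice_age = 2 * age, intercept = 1)
  expect_error(glm_fit(y, Xbad), "collinear")

  # residuals orthogonal to the design
  set.seed(8)
  Y <- matrix(rnorm(6 * 50), 6, 50)
  f3 <- glm_fit(Y, X)
  expect_lt(max(abs(crossprod(X, f3$residuals))), 1e-8)
})

test_that("glm contrasts recover simulated effects within 3 SE", {
  set.seed(123)
  n <- 50
  X <- cbind(intercept = 1, x = rnorm(n))
  beta <- c(0.5, 1.7)
  y <- X %*% beta + rnorm(n, 0, 1)
  fit <- glm_fit(as.vector(y), X)
  ct <- glm_contrast(fit, "x")
  expect_lt(abs(ct$estimate - 1.7), 3 * ct$se)
  # closed-form SE check
  se_ref <- sqrt(fit$sigma2 * solve(crossprod(X))[2, 2])
  expect_equal(ct$se, as.vector(se_ref), tolerance = 1e-10)
  expect_error(glm_contrast(fit, "nope"), "unknown regressor")
})

test_that("paired_t_map: zeros, hand value, antisymmetry", {
  dims <- c(4L, 4L, 4L)
  mk <- function(v) as_volume(array(v, dim = dims))
  a <- list(mk(1), mk(2), mk(3))
  t0 <- paired_t_map(a, a)
  expect_true(all(t0$t$data == 0))
  expect_true(all(t0$degenerate$data == 1))

  b <- list(mk(1 - 2), mk(2 - 4), mk(3 - 6))
  tm <- paired_t_map(a, b)
  expect_equal(tm$t$data[2, 2, 2], 3.4641, tolerance = 1e-4)
  expect_equal(tm$df, 2L)
  swapped <- paired_t_map(b, a)
  expect_equal(swapped$t$data, -tm$t$data, tolerance = 1e-12)
})

test_that("delta_gm is an element-wise difference with grid checks", {
  a <- rand_volume(c(5L, 5L, 5L), seed = 1)
  b <- rand_volume(c(5L, 5L, 5L), seed = 2)
  expect_true(all(delta_gm(a, a)$data == 0))
  expect_equal(delta_gm(a, b)$data, a$data - b$data)
  plus5 <- as_volume(a$data + 5)
  expect_true(all(abs(delta_gm(plus5, a)$data - 5) < 1e-12))
  c8 <- rand_volume(c(8L, 8L, 8L), seed = 3)
  expect_error(delta_gm(a, c8), "grid mismatch")
})

test_that("delta-GM on R2* regression: exact fit, recovery, residuals", {
  r2s <- seq(30, 60, length.out = 10)
  delta <- 0.5 * r2s
  fit <- regress_delta_r2s(matrix(delta, ncol = 1), r2s, intercept = FALSE)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  fit_i <- regress_delta_r2s(matrix(delta + 3, ncol = 1), r2s,
                             intercept = TRUE)
  expect_equal(fit_i$beta, 0.5, tolerance = 1e-12)

  set.seed(55)
  n <- 30
  x <- rnorm(n, 45, 5)
  d <- 0.5 * x + rnorm(n, 0, 0.1)
  f <- regress_delta_r2s(matrix(d, ncol = 1), x)
  expect_lt(abs(f$beta - 0.5), 3 * f$se)
  expect_lt(max(abs(crossprod(cbind(1, x), cbind(f$residuals)))), 1e-8)

  expect_error(regress_delta_r2s(matrix(d, ncol = 1), rep(1, n)),
               "zero variance")
  expect_error(regress_delta_r2s(matrix(1:2, ncol = 1), 1:2), ">= 3")
})

test_that("null slope t-values follow the t reference distribution", {
  # Eq-style per-voxel null: independent outcomes, shared covariate
  set.seed(77)
  n <- 100; V <- 1000
  D <- matrix(rnorm(n * V), n, V)
  x <- rnorm(n, 45, 5)
  f <- regress_delta_r2s(D, x, intercept = TRUE)
  crit <- qt(0.975, df = f$df)
  frac <- mean(abs(f$t_beta) < crit)
  # 95 percent nominal; 3-sigma binomial band around 0.95
  expect_gt(frac, 0.95 - 3 * sqrt(0.05 * 0.95 / V))
})

test_that("sign-flip maxT matches exact enumeration on one voxel (n=8)", {
  set.seed(9)
  d <- rnorm(8, 1, 1)
  res <- permutation_fwe(matrix(d, ncol = 1), alpha = 0.05,
                         type = "sign_flip", exhaustive = TRUE)
  tstat <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  null_t <- apply(signs, 1, function(s) abs(tstat(s * d)))
  expect_equal(sort(res$max_t_null), sort(null_t), tolerance = 1e-10)
  expect_equal(res$p_fwe, mean(null_t >= abs(tstat(d))), tolerance = 1e-12)
})

test_that("maxT threshold honours the quantile contract at alpha = 1", {
  set.seed(10)
  D <- matrix(rnorm(6 * 5), 6, 5)
  res <- permutation_fwe(D, n_perm = 200, alpha = 1, seed = 3)
  expect_equal(res$threshold, min(res$max_t_null))
  res05 <- permutation_fwe(D, n_perm = 200, alpha = 0.05, seed = 3)
  expect_gte(res05$threshold, res$threshold)
  expect_warning(permutation_fwe(D, n_perm = 50, seed = 1), "n_perm")
})

test_that("permute-type FWE handles covariate designs", {
  set.seed(12)
  y <- matrix(rnorm(20 * 10), 20, 10)
  x <- rnorm(20)
  res <- permutation_fwe(list(y = y, x = x), n_perm = 200, seed = 4,
                         type = "permute")
  expect_length(res$t_obs, 10)
  expect_true(all(res$p_fwe >= 0 & res$p_fwe <= 1))
  expect_error(permutation_fwe(list(y = y, x = rep(1, 20)), type = "permute"),
               "non-exchangeable")
})

test_that("sign-flip FWE is calibrated near the nominal level", {
  # modest repetition count keeps this quick; the acceptance suite runs
  # the full calibration
  nrep <- 60; n <- 10; V <- 40
  hits <- 0
  for (r in seq_len(nrep)) {
    set.seed(1000 + r)
    D <- matrix(rnorm(n * V), n, V)
    res <- permutation_fwe(D, n_perm = 300, alpha = 0.05, seed = r)
    hits <- hits + any(res$significant)
  }
  rate <- hits / nrep
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("cluster_table labels 26-connected components with peaks", {
  dims <- c(10L, 10L, 10L)
  t_ <- array(0, dim = dims)
  t_[2:3, 2:3, 2:3] <- 4      # cluster of 8
  t_[3, 3, 3] <- 6            # corner-connected continuation
  t_[8, 8, 8] <- -5           # separate negative peak
  tab <- cluster_table(as_volume(t_), threshold = 3.5)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$size_vox[1], 8L)
  expect_equal(tab$peak_t[1], 6)
  expect_equal(tab$size_vox[2], 1L)
  expect_equal(tab$peak_t[2], -5)
  none <- cluster_table(as_volume(t_), threshold = 100)
  expect_equal(nrow(none), 0L)
})
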