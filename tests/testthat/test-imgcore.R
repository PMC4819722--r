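test_that("volumes round-trip through NIfTI in both encodings", {
  aff <- diag(4)
  aff[1:3, 4] <- c(-16, -20, -24)
  aff[2, 2] <- 1.5
  v <- rand_volume(c(8L, 8L, 8L), affine = aff, seed = 42)
  # quantize to float32 once so the written payload is exactly representable
  p1 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, p1)
  v32 <- read_volume(p1)
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  p3 <- withr::local_tempfile(fileext = ".nii")
  write_volume(v32, p2)
  write_volume(v32, p3)
  r2 <- read_volume(p2)
  r3 <- read_volume(p3)
  expect_identical(as.vector(r2$data), as.vector(v32$data))
  expect_identical(as.vector(r3$data), as.vector(r2$data))
  expect_equal(r2$affine, v$affine, tolerance = 1e-6)
  expect_equal(r3$affine, r2$affine)
})

test_that("read_volume rejects 4D payloads and missing files", {
  p <- withr::local_tempfile(fileext = ".nii.gz")
  arr4 <- array(0, dim = c(4, 4, 4, 3))
  RNifti::writeNifti(RNifti::asNifti(arr4), p)
  expect_error(read_volume(p), "expected 3D")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
})

test_that("volume constructor enforces its invariants", {
  expect_error(as_volume(matrix(0, 2, 2)), "3D")
  bad_aff <- diag(4); bad_aff[1, 1] <- 0
  expect_error(as_volume(array(0, dim = c(2, 2, 2)), bad_aff),
               "non-invertible")
  aff <- diag(c(2, 3, 4, 1))
  v <- as_volume(array(0, dim = c(2, 2, 2)), aff)
  expect_equal(voxel_sizes(v), c(2, 3, 4))
  expect_equal(voxel_volume(v), 24)
})

test_that("fwhm_to_sigma matches the closed form", {
  expect_equal(fwhm_to_sigma(2.3548, 1), 1, tolerance = 1e-3)
  expect_equal(fwhm_to_sigma(4, 1), 4 / (2 * sqrt(2 * log(2))),
               tolerance = 1e-12)
  expect_equal(fwhm_to_sigma(4, 1), 1.6986, tolerance = 1e-3)
  expect_equal(fwhm_to_sigma(6, 2), 1.2739, tolerance = 1e-3)
  expect_error(fwhm_to_sigma(0, 1), "positive")
  expect_error(fwhm_to_sigma(4, -1), "positive")
})

test_that("gaussian smoothing: identity at 0, flat fields, impulse peak", {
  v <- rand_volume(c(10L, 10L, 10L), seed = 3)
  expect_identical(gaussian_smooth_fwhm(v, 0)$data, v$data)
  expect_error(gaussian_smooth_fwhm(v, -1), ">= 0")

  const <- as_volume(array(0.7, dim = c(17L, 17L, 17L)))
  sm <- gaussian_smooth_fwhm(const, 4)
  expect_equal(sm$data[9, 9, 9], 0.7, tolerance = 1e-6)

  # unit impulse: center value equals the peak of the normalized discrete
  # 3D Gaussian, built independently here
  imp <- array(0, dim = c(21L, 21L, 21L))
  imp[11, 11, 11] <- 1
  sm <- gaussian_smooth_fwhm(as_volume(imp), 4)
  sigma <- 4 / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma)
  k1 <- dnorm(seq(-r, r), sd = sigma); k1 <- k1 / sum(k1)
  peak3d <- max(k1)^3
  expect_equal(sm$data[11, 11, 11], peak3d, tolerance = 1e-12)
})

test_that("smoothing conserves interior sums", {
  set.seed(7)
  a <- array(0, dim = c(24L, 24L, 24L))
  a[9:16, 9:16, 9:16] <- runif(512)
  total <- sum(a)
  sm <- gaussian_smooth_fwhm(as_volume(a), 4)
  expect_equal(sum(sm$data), total, tolerance = 1e-6 * total)
})

test_that("apply_deformation: identity, translation, fill, range bound", {
  v <- rand_volume(c(8L, 8L, 8L), seed = 5)
  id <- identity_deformation(dim(v))
  expect_equal(apply_deformation(v, id)$data, v$data, tolerance = 1e-12)

  hot <- array(0, dim = c(8L, 8L, 8L)); hot[5, 4, 4] <- 1
  d <- identity_deformation(c(8L, 8L, 8L))
  d$disp[, , , 1] <- 2   # sample from x+2: value moves to lower x
  w <- apply_deformation(as_volume(hot), d)
  expect_equal(w$data[3, 4, 4], 1)
  expect_equal(sum(w$data), 1)

  far <- identity_deformation(c(8L, 8L, 8L))
  far$disp[, , , 1] <- 100
  expect_true(all(apply_deformation(v, far)$data == 0))

  # trilinear output bounded by input range for random smooth fields
  for (s in 1:5) {
    d2 <- simulate_deformation(c(8L, 8L, 8L), amplitude_mm = 1.5,
                               smoothness_mm = 4, seed = s)
    w2 <- apply_deformation(v, d2)
    expect_gte(min(w2$data), min(min(v$data), 0))
    expect_lte(max(w2$data), max(v$data))
  }
})

test_that("apply_deformation agrees with a pointwise reference sampler", {
  v <- rand_volume(c(6L, 6L, 6L), seed = 11)
  d <- simulate_deformation(c(6L, 6L, 6L), amplitude_mm = 1.2,
                            smoothness_mm = 3, seed = 2)
  w <- apply_deformation(v, d)
  for (idx in list(c(1, 1, 1), c(3, 4, 2), c(6, 6, 6), c(2, 5, 3))) {
    i <- idx[1]; j <- idx[2]; k <- idx[3]
    ref <- trilinear_ref(v$data,
                         (i - 1) + d$disp[i, j, k, 1],
                         (j - 1) + d$disp[i, j, k, 2],
                         (k - 1) + d$disp[i, j, k, 3])
    expect_equal(w$data[i, j, k], ref, tolerance = 1e-12)
  }
})

test_that("nearest-neighbour interpolation keeps values from the input set", {
  v <- as_volume(array(sample(c(0, 3, 7), 8^3, TRUE), dim = c(8L, 8L, 8L)))
  d <- simulate_deformation(c(8L, 8L, 8L), amplitude_mm = 1,
                            smoothness_mm = 4, seed = 3)
  w <- apply_deformation(v, d, interp = "nearest")
  expect_true(all(w$data %in% c(0, 3, 7)))
})

test_that("jacobian determinant: identity, anisotropic scaling, oracle", {
  id <- identity_deformation(c(8L, 8L, 8L))
  expect_equal(jacobian_determinant(id)$data,
               array(1, dim = c(8L, 8L, 8L)))

  # disp(x) = (a-1)x etc gives output(x) = input(diag(a,b,c) x):
  # analytic determinant a*b*c everywhere (field is exactly linear)
  n <- 8L
  ix <- array(rep(0:(n - 1), n * n), dim = c(n, n, n))
  d <- identity_deformation(c(n, n, n))
  abc <- c(1.2, 0.9, 1.05)
  d$disp[, , , 1] <- (abc[1] - 1) * ix
  d$disp[, , , 2] <- (abc[2] - 1) * aperm(ix, c(2, 1, 3))
  d$disp[, , , 3] <- (abc[3] - 1) * aperm(ix, c(3, 2, 1))
  jd <- jacobian_determinant(d)
  expect_equal(jd$data, array(prod(abc), dim = c(n, n, n)),
               tolerance = 1e-12)

  # independent second implementation with a different stencil ordering
  d2 <- simulate_deformation(c(8L, 8L, 8L), amplitude_mm = 1,
                             smoothness_mm = 4, seed = 9)
  jd2 <- jacobian_determinant(d2)
  grad_ref <- function(a, axis) {
    d_ <- dim(a); out <- array(NA_real_, d_)
    for (i in seq_len(d_[1])) for (j in seq_len(d_[2])) for (k in seq_len(d_[3])) {
      p <- c(i, j, k); lo <- p; hi <- p
      lo[axis] <- max(1, p[axis] - 1); hi[axis] <- min(d_[axis], p[axis] + 1)
      out[i, j, k] <- (a[hi[1], hi[2], hi[3]] - a[lo[1], lo[2], lo[3]]) /
        (hi[axis] - lo[axis])
    }
    out
  }
  J <- array(0, dim = c(8, 8, 8))
  g <- list()
  for (i in 1:3) for (j in 1:3) g[[paste(i, j)]] <- grad_ref(d2$disp[, , , i], j)
  for (i in seq_len(8)) for (j in seq_len(8)) for (k in seq_len(8)) {
    M <- diag(3)
    for (a in 1:3) for (b in 1:3) M[a, b] <- M[a, b] + g[[paste(a, b)]][i, j, k]
    J[i, j, k] <- det(M)
  }
  expect_equal(jd2$data, J, tolerance = 1e-10)
})

test_that("small-amplitude jacobian is 1 + divergence to first order", {
  d <- simulate_deformation(c(10L, 10L, 10L), amplitude_mm = 1,
                            smoothness_mm = 5, seed = 4)
  eps <- 1e-4 / max(sqrt(d$disp[, , , 1]^2 + d$disp[, , , 2]^2 +
                           d$disp[, , , 3]^2))
  d$disp <- d$disp * eps
  jd <- jacobian_determinant(d)
  div <- subprior:::diff_axis(d$disp[, , , 1], 1) +
    subprior:::diff_axis(d$disp[, , , 2], 2) +
    subprior:::diff_axis(d$disp[, , , 3], 3)
  expect_lt(max(abs(jd$data - (1 + div))), 1e-6)
})
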