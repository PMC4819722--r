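# Shared fixture builders; everything is generated in code at test time.

rand_volume <- function(dim = c(8L, 8L, 8L), affine = diag(4), seed = 1L) {
  set.seed(seed)
  as_volume(array(runif(prod(dim)), dim = dim), affine)
}

ball_mask <- function(dim = c(16L, 16L, 16L), center = (dim - 1) / 2,
                      radius = 4, affine = diag(4)) {
  x <- (seq_len(dim[1]) - 1) - center[1]
  y <- (seq_len(dim[2]) - 1) - center[2]
  z <- (seq_len(dim[3]) - 1) - center[3]
  q <- outer(outer(x^2, y^2, "+"), z^2, "+")
  as_volume((q <= radius^2) * 1, affine)
}

# tiny 3-class intensity phantom with known labels and flat geometry:
# equal thirds along x
three_class_phantom <- function(dim = c(12L, 12L, 12L),
                                means = c(10, 50, 90), sd = 2, seed = 1L) {
  set.seed(seed)
  lab <- array(rep(rep(1:3, each = dim[1] / 3), dim[2] * dim[3]), dim = dim)
  img <- array(rnorm(prod(dim), means[lab], sd), dim = dim)
  list(image = as_volume(img), labels = lab)
}

flat_priors <- function(dim, K = 3L, names_ = paste0("c", seq_len(K))) {
  vols <- lapply(seq_len(K), function(i) {
    as_volume(array(1 / K, dim = dim))
  })
  names(vols) <- names_
  tpm_set(vols)
}

# independent trilinear sample of one point (0-based coords), zero fill
trilinear_ref <- function(arr, x, y, z) {
  d <- dim(arr)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    wgt <- (1 - abs(x - xi)) * (1 - abs(y - yi)) * (1 - abs(z - zi))
    val <- if (xi >= 0 && xi < d[1] && yi >= 0 && yi < d[2] &&
               zi >= 0 && zi < d[3]) arr[xi + 1, yi + 1, zi + 1] else 0
    acc <- acc + wgt * val
  }
  acc
}
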