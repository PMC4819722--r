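#' Construct a deformation field
#'
#' Displacements are stored in voxel units on the target grid in pull-back
#' convention: the warped image at voxel `x` samples the input at
#' `x + disp(x)`. This makes applying a warp a single gather pass and
#' matches how estimated warps are typically exported.
#'
#' @param disp 4D array `(nx, ny, nz, 3)` of voxel-unit displacements.
#' @param affine 4x4 voxel-to-world matrix of the target grid.
#' @return An object of class `deformation_field`.
#' @export
as_deformation <- function(disp, affine = diag(4)) {
  if (inherits(disp, "deformation_field")) return(disp)
  disp <- as.array(disp)
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L) {
    stop("disp must be a (nx, ny, nz, 3) array")
  }
  if (!all(is.finite(disp))) stop("displacements must be finite")
  structure(list(disp = disp, affine = unname(as.matrix(affine))),
            class = "deformation_field")
}

#' @export
dim.deformation_field <- function(x) dim(x$disp)[1:3]

#' Identity deformation on a grid
#'
#' @param grid_shape Integer length-3.
#' @param affine Target-grid affine.
#' @return A `deformation_field` with zero displacement.
#' @export
identity_deformation <- function(grid_shape, affine = diag(4)) {
  as_deformation(array(0, dim = c(grid_shape, 3L)), affine)
}

#' Resample a volume through a deformation field
#'
#' Computes `out(x) = v(x + disp(x))` on the deformation's grid. Samples
#' falling outside the input domain are filled with 0 (probabilities and
#' masks vanish outside the head).
#'
#' @param v Input `volume`.
#' @param d A `deformation_field` defined on the output grid.
#' @param interp `"trilinear"` (default) or `"nearest"`.
#' @return A `volume` on the deformation's grid.
#' @export
apply_deformation <- function(v, d, interp = c("trilinear", "nearest")) {
  v <- as_volume(v)
  d <- as_deformation(d$disp, d$affine)
  interp <- match.arg(interp)
  dm <- dim(v$data)
  gd <- dim(d)
  if (!all(dm == gd)) stop("shape mismatch between volume and deformation grid")

  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  nvox <- prod(dm)
  # 0-based sampling coordinates
  ix <- rep.int(seq_len(nx) - 1, ny * nz)
  iy <- rep.int(rep(seq_len(ny) - 1, each = nx), nz)
  iz <- rep(seq_len(nz) - 1, each = nx * ny)
  xs <- ix + as.vector(d$disp[, , , 1])
  ys <- iy + as.vector(d$disp[, , , 2])
  zs <- iz + as.vector(d$disp[, , , 3])

  out <- numeric(nvox)
  if (interp == "nearest") {
    rx <- round(xs); ry <- round(ys); rz <- round(zs)
    ok <- rx >= 0 & rx <= nx - 1 & ry >= 0 & ry <= ny - 1 & rz >= 0 & rz <= nz - 1
    lin <- rx[ok] + nx * (ry[ok] + ny * rz[ok]) + 1
    out[ok] <- v$data[lin]
  } else {
    # gather from a zero-padded copy: out-of-domain neighbours contribute 0
    P <- array(0, dim = dm + 2L)
    P[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- v$data
    px <- xs + 2; py <- ys + 2; pz <- zs + 2  # 1-based index into P
    x0 <- floor(px); y0 <- floor(py); z0 <- floor(pz)
    fx <- px - x0; fy <- py - y0; fz <- pz - z0
    ok <- x0 >= 1 & x0 + 1 <= nx + 2 & y0 >= 1 & y0 + 1 <= ny + 2 &
      z0 >= 1 & z0 + 1 <= nz + 2
    x0[!ok] <- 1; y0[!ok] <- 1; z0[!ok] <- 1
    sx <- dim(P)[1]; sxy <- sx * dim(P)[2]
    base <- x0 + sx * (y0 - 1) + sxy * (z0 - 1)
    acc <-
      P[base]                  * (1 - fx) * (1 - fy) * (1 - fz) +
      P[base + 1]              * fx       * (1 - fy) * (1 - fz) +
      P[base + sx]             * (1 - fx) * fy       * (1 - fz) +
      P[base + sx + 1]         * fx       * fy       * (1 - fz) +
      P[base + sxy]            * (1 - fx) * (1 - fy) * fz +
      P[base + sxy + 1]        * fx       * (1 - fy) * fz +
      P[base + sxy + sx]       * (1 - fx) * fy       * fz +
      P[base + sxy + sx + 1]   * fx       * fy       * fz
    acc[!ok] <- 0
    out <- acc
  }
  as_volume(array(out, dim = dm), d$affine)
}

# finite difference of a 3D array along an axis: central on the interior,
# one-sided at the faces (unit voxel spacing)
diff_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  if (n < 2L) return(array(0, dim = d))
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  g <- matrix(0, nrow = n, ncol = ncol(m))
  if (n > 2L) g[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
  g[1, ] <- m[2, ] - m[1, ]
  g[n, ] <- m[n, ] - m[n - 1, ]
  aperm(array(g, dim = d[perm]), order(perm))
}

#' Jacobian determinant of a deformation field
#'
#' Determinant of `I + d(disp)/dx` computed with central differences on the
#' interior and one-sided differences at the faces. Values near 1 indicate
#' volume preservation; the determinant map is the modulation factor in
#' morphometry.
#'
#' @param d A `deformation_field`.
#' @return A `volume` of determinants on the deformation grid.
#' @export
jacobian_determinant <- function(d) {
  d <- as_deformation(d$disp, d$affine)
  g <- vector("list", 9L)
  for (i in 1:3) {
    for (j in 1:3) {
      g[[(i - 1) * 3 + j]] <- diff_axis(d$disp[, , , i], j)
    }
  }
  a11 <- 1 + g[[1]]; a12 <- g[[2]];     a13 <- g[[3]]
  a21 <- g[[4]];     a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]];     a32 <- g[[8]];     a33 <- 1 + g[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  as_volume(det, d$affine)
}
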