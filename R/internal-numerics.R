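# Internal numerical primitives shared by the phantom generator, the
# registration engine and the morphometry operators. Everything works in
# 0-based continuous voxel coordinates internally; physical quantities
# (displacements, sigmas) are converted at the call site using the grid
# spacing, so anisotropic voxels are handled uniformly.

#' Evaluate code with a temporarily seeded RNG
#'
#' Saves and restores \code{.Random.seed} so that seeded generators do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# n x 3 matrix of 0-based voxel indices for a full grid, x fastest
grid_index_points <- function(dm) {
  cbind(
    rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3]),
    rep.int(rep(seq_len(dm[2]) - 1, each = dm[1]), dm[3]),
    rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2])
  )
}

# Trilinear interpolation of a 3D array at 0-based continuous voxel coords.
# mode "fill": samples with any support outside the grid take `fill`;
# mode "clamp": coordinates are clamped to the grid (used when extending
# displacement/velocity fields beyond their support).
interp3 <- function(arr, pts, mode = c("fill", "clamp"), fill = 0) {
  mode <- match.arg(mode)
  dm <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (mode == "clamp") {
    x <- pmin(pmax(x, 0), dm[1] - 1)
    y <- pmin(pmax(y, 0), dm[2] - 1)
    z <- pmin(pmax(z, 0), dm[3] - 1)
    outside <- FALSE
  } else {
    outside <- x < 0 | x > dm[1] - 1 | y < 0 | y > dm[2] - 1 | z < 0 | z > dm[3] - 1
    x <- pmin(pmax(x, 0), dm[1] - 1)
    y <- pmin(pmax(y, 0), dm[2] - 1)
    z <- pmin(pmax(z, 0), dm[3] - 1)
  }
  x0 <- pmin(floor(x), dm[1] - 2); y0 <- pmin(floor(y), dm[2] - 2); z0 <- pmin(floor(z), dm[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  i000 <- x0 + 1 + y0 * nx + z0 * nxy
  v <- arr[i000]          * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[i000 + 1]      * fx       * (1 - fy) * (1 - fz) +
       arr[i000 + nx]     * (1 - fx) * fy       * (1 - fz) +
       arr[i000 + nx + 1] * fx       * fy       * (1 - fz) +
       arr[i000 + nxy]          * (1 - fx) * (1 - fy) * fz +
       arr[i000 + nxy + 1]      * fx       * (1 - fy) * fz +
       arr[i000 + nxy + nx]     * (1 - fx) * fy       * fz +
       arr[i000 + nxy + nx + 1] * fx       * fy       * fz
  if (mode == "fill" && any(outside)) v[outside] <- fill
  v
}

# Nearest-neighbour interpolation (label propagation).
interp3_nearest <- function(arr, pts, fill = 0) {
  dm <- dim(arr)
  x <- round(pts[, 1]); y <- round(pts[, 2]); z <- round(pts[, 3])
  outside <- x < 0 | x > dm[1] - 1 | y < 0 | y > dm[2] - 1 | z < 0 | z > dm[3] - 1
  x <- pmin(pmax(x, 0), dm[1] - 1)
  y <- pmin(pmax(y, 0), dm[2] - 1)
  z <- pmin(pmax(z, 0), dm[3] - 1)
  v <- arr[x + 1 + y * dm[1] + z * dm[1] * dm[2]]
  if (any(outside)) v[outside] <- fill
  v
}

# Dense 1D Gaussian convolution matrix with renormalized (constant-preserving)
# boundaries; n x n, truncated at 3 sigma.
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  offs <- (-r):r
  w <- exp(-0.5 * (offs / sigma)^2)
  K <- matrix(0, n, n)
  for (j in seq_along(offs)) {
    idx <- seq_len(n) + offs[j]
    ok <- idx >= 1 & idx <= n
    K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + w[j]
  }
  K / rowSums(K)
}

# Separable Gaussian smoothing of a 3D array; sigma_vox is per-axis, in voxels.
gauss_smooth3 <- function(arr, sigma_vox) {
  dm <- dim(arr)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0 || dm[ax] < 2) next
    K <- gauss_kernel_matrix(dm[ax], sigma_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dmp <- dim(m)
    m <- K %*% matrix(m, nrow = dmp[1])
    dim(m) <- dmp
    arr <- aperm(m, order(perm))
  }
  arr
}

# Smooth each component of an [nx,ny,nz,3] vector array.
gauss_smooth_vec <- function(vec, sigma_vox) {
  for (k in 1:3) vec[, , , k] <- gauss_smooth3(vec[, , , k], sigma_vox)
  vec
}

# Central finite differences along one axis in physical mm (one-sided at the
# boundary). arr is 3D; h is the spacing along `ax`.
fd_axis <- function(arr, ax, h) {
  dm <- dim(arr)
  n <- dm[ax]
  if (n < 3) stop("grid has fewer than 3 voxels along axis ", ax, call. = FALSE)
  perm <- c(ax, setdiff(1:3, ax))
  m <- aperm(arr, perm)
  dmp <- dim(m)
  dim(m) <- c(dmp[1], dmp[2] * dmp[3])
  d <- m
  d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
  d[1, ] <- (m[2, ] - m[1, ]) / h
  d[n, ] <- (m[n, ] - m[n - 1, ]) / h
  dim(d) <- dmp
  aperm(d, order(perm))
}

# Compose two displacement fields given as [nx,ny,nz,3] mm arrays on the same
# grid: result(x) = u2(x) + u1(x + u2(x)). Fields are clamped outside support.
compose_disp <- function(u1, u2, spacing, base = NULL) {
  dm <- dim(u1)[1:3]
  if (is.null(base)) base <- grid_index_points(dm)
  n <- nrow(base)
  pts <- base
  pts[, 1] <- pts[, 1] + u2[seq_len(n)] / spacing[1]
  pts[, 2] <- pts[, 2] + u2[n + seq_len(n)] / spacing[2]
  pts[, 3] <- pts[, 3] + u2[2 * n + seq_len(n)] / spacing[3]
  out <- u2
  for (k in 1:3) {
    out[, , , k] <- out[, , , k] + interp3(u1[, , , k], pts, mode = "clamp")
  }
  out
}

# Exponential of a stationary velocity field (mm, [nx,ny,nz,3]) by scaling and
# squaring. Guarantees at least `min_squarings` squarings; more are used when
# the field is large so the scaled step stays below ~0.5 voxel.
exp_velocity_arr <- function(v, spacing, min_squarings = 6L, base = NULL) {
  maxstep <- max(abs(sweep(matrix(v, ncol = 3), 2, spacing, "/")))
  n_sq <- max(as.integer(min_squarings), ceiling(log2(max(1, maxstep / 0.5))))
  u <- v / 2^n_sq
  dm <- dim(v)[1:3]
  if (is.null(base)) base <- grid_index_points(dm)
  for (i in seq_len(n_sq)) u <- compose_disp(u, u, spacing, base = base)
  u
}
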