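# Internal numerics shared across modules: axis-wise filtering, Gaussian
# smoothing, trilinear sampling, seed handling.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a master seed; stays within
# 32-bit integer range.
deriveSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, preprocess = 23L, extract = 37L, label = 41L,
               split = 53L, select = 67L, balance = 71L, train = 83L,
               evaluate = 89L, bootstrap = 97L)
  k <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage))
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

# Correlation (sliding inner product) of `x` with `filt` along `axis`,
# same-length output, half-sample symmetric boundary extension.
# y[i] = sum_k filt[k] * xpad[i + k - 1], with pad (floor((L-1)/2),
# ceil((L-1)/2)).
convAxisSym <- function(x, filt, axis) {
  d <- dim(x)
  L <- length(filt)
  padL <- (L - 1L) %/% 2L
  padR <- L - 1L - padL
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  n <- d[axis]
  m <- prod(d[-axis])
  dim(xp) <- c(n, m)
  if (n < L) stop("volume smaller than filter support along axis ", axis)
  # symmetric (half-sample) extension: edge value repeated then mirrored
  idxL <- if (padL > 0) padL:1 else integer()
  idxR <- if (padR > 0) n:(n - padR + 1L) else integer()
  xpad <- rbind(xp[idxL, , drop = FALSE], xp, xp[idxR, , drop = FALSE])
  y <- matrix(0, n, m)
  for (k in seq_len(L))
    y <- y + filt[k] * xpad[(k):(k + n - 1L), , drop = FALSE]
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

# Separable Gaussian smoothing (sigma in voxels), truncated at 3 sigma.
gaussianSmooth3D <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  for (ax in 1:3) {
    if (dim(x)[ax] >= length(g)) x <- convAxisSym(x, g, ax)
  }
  x
}

# Trilinear sampling of a 3D array at fractional 1-based voxel coordinates
# given as an n x 3 matrix; coordinates are clamped to the grid (edge
# extension). Returns a numeric vector of length n.
trilinearSample <- function(data, coords) {
  d <- dim(data)
  cx <- pmin(pmax(coords[, 1], 1), d[1])
  cy <- pmin(pmax(coords[, 2], 1), d[2])
  cz <- pmin(pmax(coords[, 3], 1), d[3])
  i0 <- pmin(floor(cx), d[1] - 1L); i0[d[1] == 1L] <- 1
  j0 <- pmin(floor(cy), d[2] - 1L)
  k0 <- pmin(floor(cz), d[3] - 1L)
  if (d[1] == 1L) i0 <- rep(1, length(cx))
  if (d[2] == 1L) j0 <- rep(1, length(cy))
  if (d[3] == 1L) k0 <- rep(1, length(cz))
  fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  at <- function(i, j, k) data[cbind(i, j, k)]
  v000 <- at(i0, j0, k0); v100 <- at(i1, j0, k0)
  v010 <- at(i0, j1, k0); v110 <- at(i1, j1, k0)
  v001 <- at(i0, j0, k1); v101 <- at(i1, j0, k1)
  v011 <- at(i0, j1, k1); v111 <- at(i1, j1, k1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

# Nearest-neighbour sampling, same interface as trilinearSample.
nearestSample <- function(data, coords) {
  d <- dim(data)
  i <- pmin(pmax(round(coords[, 1]), 1), d[1])
  j <- pmin(pmax(round(coords[, 2]), 1), d[2])
  k <- pmin(pmax(round(coords[, 3]), 1), d[3])
  data[cbind(i, j, k)]
}

# Voxel-centre world coordinates of a grid as an n x 3 matrix (column-major
# voxel order, matching as.vector on the array).
gridWorldCoords <- function(dims, spacing, origin = c(0, 0, 0)) {
  i <- seq_len(dims[1]); j <- seq_len(dims[2]); k <- seq_len(dims[3])
  cbind(rep(origin[1] + (i - 1) * spacing[1], times = dims[2] * dims[3]),
        rep(rep(origin[2] + (j - 1) * spacing[2], each = dims[1]),
            times = dims[3]),
        rep(origin[3] + (k - 1) * spacing[3], each = dims[1] * dims[2]))
}

# Rotation matrix for ZYX Euler angles (applied as Rz %*% Ry %*% Rx).
rotationMatrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Apply a RigidTransform to world points (n x 3): R (x - c) + c + t.
transformPoints <- function(transform, pts) {
  R <- rotationMatrix(transform@rotation)
  ctr <- transform@centre
  sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + transform@translation, "+")
}
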