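# Preprocessing: isotropic resampling, rigid mutual-information
# co-registration to the T1c grid, and whole-image Z-score normalization.

#' Resample a volume to a target (isotropic) spacing
#'
#' Resamples onto a grid with the requested voxel size whose physical extent
#' covers the input. Image volumes use trilinear interpolation; binary masks
#' (\code{contrast == "mask"} or \code{method = "nearest"}) use
#' nearest-neighbour so mask fractions are never interpolated.
#'
#' @param vol an [ImageVolume-class].
#' @param targetSpacing numeric target voxel size in mm (scalar or length 3);
#'   the conventional choice is 1 mm isotropic.
#' @param method \code{"linear"} or \code{"nearest"}; defaults to
#'   nearest-neighbour for masks and trilinear otherwise.
#' @return An [ImageVolume-class] with \code{voxelSpacing(x) ==
#'   targetSpacing}.
#' @examples
#' v <- imageVolume(array(rnorm(4^3), c(4, 4, 4)), spacing = 2)
#' dim(voxelData(resampleIsotropic(v, 1)))
#' @export
resampleIsotropic <- function(vol, targetSpacing = 1, method = NULL) {
  stopifnot(is(vol, "ImageVolume"))
  if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3L)
  if (any(!is.finite(targetSpacing)) || any(targetSpacing <= 0))
    stop("targetSpacing must be strictly positive")
  if (is.null(method))
    method <- if (vol@contrast == "mask") "nearest" else "linear"
  d <- dim(vol@data)
  if (all(abs(vol@spacing - targetSpacing) < 1e-12)) return(vol)
  nOut <- pmax(1L, as.integer(ceiling(d * vol@spacing / targetSpacing)))
  # world coords of output voxel centres, then fractional input indices
  w <- gridWorldCoords(nOut, targetSpacing, vol@origin)
  idx <- sweep(sweep(w, 2, vol@origin), 2, vol@spacing, "/") + 1
  vals <- if (method == "nearest") nearestSample(vol@data, idx)
          else trilinearSample(vol@data, idx)
  imageVolume(array(vals, nOut), spacing = targetSpacing,
              contrast = vol@contrast, origin = vol@origin)
}

#' Z-score intensity normalization
#'
#' Standardizes intensities using the whole-image mean and standard
#' deviation (all voxels, background included), giving a volume with mean 0
#' and SD 1. The transform is monotone, so intensity order is preserved. A
#' constant volume yields all zeros with a warning.
#'
#' @param vol an [ImageVolume-class].
#' @return A standardized [ImageVolume-class].
#' @export
zscoreNormalize <- function(vol) {
  stopifnot(is(vol, "ImageVolume"))
  mu <- mean(vol@data)
  sdv <- stats::sd(as.vector(vol@data))
  if (!is.finite(sdv) || sdv == 0) {
    warning("volume has zero intensity variance; returning all zeros")
    out <- array(0, dim(vol@data))
  } else {
    out <- (vol@data - mu) / sdv
  }
  imageVolume(out, spacing = vol@spacing, contrast = vol@contrast,
              origin = vol@origin)
}

# Joint-histogram mutual information (nats) between two intensity vectors
# over `bins` equal-width bins each.
.miValue <- function(a, b, bins = 32L) {
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(0)
  ia <- pmin(floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, bins)
  ib <- pmin(floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1L, bins)
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins)
  n <- length(a)
  pj <- joint[joint > 0] / n
  hj <- -sum(pj * log(pj))
  pa <- tabulate(ia, nbins = bins) / n
  pb <- tabulate(ib, nbins = bins) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  ha + hb - hj
}

# Resample `moving` into the grid of `fixed` under `transform` (fixed-world
# -> moving-world mapping). Returns the resampled array.
.resampleInto <- function(moving, fixed, transform, method = "linear") {
  w <- gridWorldCoords(dim(fixed@data), fixed@spacing, fixed@origin)
  wm <- transformPoints(transform, w)
  idx <- sweep(sweep(wm, 2, moving@origin), 2, moving@spacing, "/") + 1
  vals <- if (method == "nearest") nearestSample(moving@data, idx)
          else trilinearSample(moving@data, idx)
  array(vals, dim(fixed@data))
}

# Block-mean downsampling by a factor of 2 (for the coarse pyramid level).
.downsample2 <- function(vol) {
  d <- dim(vol@data)
  d2 <- pmax(1L, d %/% 2L)
  x <- vol@data[seq_len(d2[1] * 2), seq_len(d2[2] * 2), seq_len(d2[3] * 2),
                drop = FALSE]
  x <- (x[seq(1, 2 * d2[1], 2), , , drop = FALSE] +
        x[seq(2, 2 * d2[1], 2), , , drop = FALSE]) / 2
  x <- (x[, seq(1, 2 * d2[2], 2), , drop = FALSE] +
        x[, seq(2, 2 * d2[2], 2), , drop = FALSE]) / 2
  x <- (x[, , seq(1, 2 * d2[3], 2), drop = FALSE] +
        x[, , seq(2, 2 * d2[3], 2), drop = FALSE]) / 2
  imageVolume(x, spacing = vol@spacing * d / pmax(1L, d2),
              contrast = vol@contrast, origin = vol@origin +
                (vol@spacing * d / pmax(1L, d2) - vol@spacing) / 2)
}

#' Rigid co-registration by mutual information
#'
#' Estimates the six-parameter rigid body transform (three rotations, three
#' translations) aligning \code{moving} to \code{fixed} by maximizing the
#' 32-bin joint-histogram mutual information, using a two-level
#' multi-resolution Nelder-Mead search (gradient-free, convergence tolerance
#' 1e-4). The returned transform maps fixed-image world coordinates into the
#' moving image; the moving image resampled onto the fixed grid is returned
#' alongside the final metric value for quality logging.
#'
#' @param moving,fixed [ImageVolume-class]s on a common spacing (resample
#'   first; see [resampleIsotropic()]).
#' @param bins histogram bins for the MI metric.
#' @param qualityThreshold final MI (nats) below which the registration is
#'   flagged as poor (\code{quality_ok = FALSE}); structured aligned images
#'   score well above this, unrelated noise near zero.
#' @param maxit Nelder-Mead iteration cap per pyramid level.
#' @return A list with elements \code{transform} ([RigidTransform-class]),
#'   \code{registered} (moving resampled into the fixed grid),
#'   \code{metric} (final MI, nats), \code{quality_ok}, and
#'   \code{trace} (optimizer metric trace, one value per level).
#' @examples
#' v <- imageVolume(gaussianSmooth3D(array(rnorm(16^3), c(16, 16, 16)), 2))
#' fit <- rigidRegister(v, v)
#' fit$transform
#' @export
rigidRegister <- function(moving, fixed, bins = 32L, qualityThreshold = 0.1,
                          maxit = 300L) {
  stopifnot(is(moving, "ImageVolume"), is(fixed, "ImageVolume"))
  if (any(abs(moving@spacing - fixed@spacing) > 1e-9))
    stop("resample both volumes to a common spacing before registration")
  centre <- fixed@origin + (dim(fixed@data) - 1) * fixed@spacing / 2
  # parameter scaling: radians ~ mm for Nelder-Mead conditioning
  objective <- function(par, mv, fx) {
    tr <- rigidTransform(par[1:3], par[4:6], centre)
    reg <- .resampleInto(mv, fx, tr)
    -.miValue(as.vector(reg), as.vector(fx@data), bins)
  }
  levels <- list()
  if (all(dim(fixed@data) >= 12L))
    levels[[1]] <- list(mv = .downsample2(moving), fx = .downsample2(fixed))
  levels[[length(levels) + 1L]] <- list(mv = moving, fx = fixed)
  par <- rep(0, 6)
  trace <- numeric()
  for (lv in levels) {
    opt <- stats::optim(par, objective, mv = lv$mv, fx = lv$fx,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-4,
                                       parscale = c(rep(0.05, 3), rep(2, 3))))
    par <- opt$par
    trace <- c(trace, -opt$value)
  }
  # restart at the finest level with a fresh simplex: Nelder-Mead converges
  # prematurely on occasion, and a restart from the incumbent recovers it
  fine <- levels[[length(levels)]]
  opt <- stats::optim(par, objective, mv = fine$mv, fx = fine$fx,
                      method = "Nelder-Mead",
                      control = list(maxit = min(maxit, 150L), reltol = 1e-6,
                                     parscale = c(rep(0.01, 3), rep(0.5, 3))))
  if (opt$value <= -trace[length(trace)]) {
    par <- opt$par
    trace <- c(trace, -opt$value)
  }
  transform <- rigidTransform(par[1:3], par[4:6], centre)
  registered <- imageVolume(.resampleInto(moving, fixed, transform),
                            spacing = fixed@spacing,
                            contrast = moving@contrast, origin = fixed@origin)
  metric <- -objective(par, moving, fixed)
  list(transform = transform, registered = registered, metric = metric,
       quality_ok = metric >= qualityThreshold, trace = trace)
}

#' Apply a rigid transform to resample a volume onto a reference grid
#'
#' @param vol volume to resample (image or mask; masks use
#'   nearest-neighbour).
#' @param transform a [RigidTransform-class] mapping reference-world
#'   coordinates into \code{vol}'s world space.
#' @param reference [ImageVolume-class] supplying the output grid.
#' @return An [ImageVolume-class] on the reference grid.
#' @export
applyRigidTransform <- function(vol, transform, reference) {
  method <- if (vol@contrast == "mask") "nearest" else "linear"
  imageVolume(.resampleInto(vol, reference, transform, method),
              spacing = reference@spacing, contrast = vol@contrast,
              origin = reference@origin)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class] (same rotation centre).
#' @export
invertRigidTransform <- function(transform) {
  R <- rotationMatrix(transform@rotation)
  # inverse mapping: x -> R^T (x - c - t) + c; recover ZYX angles from R^T
  Ri <- t(R)
  ry <- asin(-Ri[3, 1])
  rx <- atan2(Ri[3, 2], Ri[3, 3])
  rz <- atan2(Ri[2, 1], Ri[1, 1])
  rigidTransform(c(rx, ry, rz), as.vector(-Ri %*% transform@translation),
                 transform@centre)
}
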