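# Radiomic feature families: discretization, histogram, GLCM, GLRLM, LBP,
# geometry, and the full per-lesion extractor.

# The 13 unique 3D displacement directions at Chebyshev distance 1 (unique
# up to sign; first nonzero component positive). Closed under axis
# permutation and 90-degree rotation, which gives the direction-averaged
# texture features their rotational invariance.
GLCM_DIRECTIONS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

#' DiscretizedROI: integer gray levels of the in-mask voxels
#'
#' Equal-width discretization of the in-mask intensities, the prerequisite
#' of the GLCM and GLRLM families. Voxels outside the mask are \code{NA}.
#'
#' @slot levels 3D integer array (cropped to the mask bounding box), levels
#'   in \code{1..nLevels} inside the mask, \code{NA} outside.
#' @slot nLevels gray-level count.
#' @export
setClass("DiscretizedROI",
  representation(levels = "array", nLevels = "integer"))

setValidity("DiscretizedROI", function(object) {
  lv <- object@levels[!is.na(object@levels)]
  if (length(lv) == 0) return("ROI must contain at least one voxel")
  if (any(lv < 1L | lv > object@nLevels))
    return("levels out of range 1..nLevels")
  TRUE
})

.asMaskArray <- function(mask) {
  m <- if (is(mask, "ImageVolume")) mask@data else mask
  array(m != 0, dim(m))
}

.maskBBox <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  list(x = range(idx[, 1]), y = range(idx[, 2]), z = range(idx[, 3]))
}

#' Discretize the in-mask intensities of a volume
#'
#' Equal-width binning of in-mask intensities into \code{nLevels} bins over
#' the in-mask \code{[min, max]} range; the top bin is right-closed. A
#' constant ROI maps to level 1 everywhere.
#'
#' @param vol [ImageVolume-class] or 3D array.
#' @param mask binary mask (array or \code{ImageVolume}), nonempty.
#' @param nLevels number of gray levels (default 32, the package-wide
#'   texture discretization).
#' @return A [DiscretizedROI-class] cropped to the mask bounding box.
#' @examples
#' v <- array(c(0, 0.5, 1, 0), c(4, 1, 1))
#' m <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
#' discretizeROI(v, m, 2)@levels[1:3]   # 1 2 2
#' @export
discretizeROI <- function(vol, mask, nLevels = 32L) {
  x <- if (is(vol, "ImageVolume")) vol@data else vol
  m <- .asMaskArray(mask)
  if (!any(m)) stop("empty mask")
  if (nLevels < 1L) stop("nLevels must be >= 1")
  bb <- .maskBBox(m)
  xs <- x[bb$x[1]:bb$x[2], bb$y[1]:bb$y[2], bb$z[1]:bb$z[2], drop = FALSE]
  ms <- m[bb$x[1]:bb$x[2], bb$y[1]:bb$y[2], bb$z[1]:bb$z[2], drop = FALSE]
  vals <- xs[ms]
  lo <- min(vals); hi <- max(vals)
  lev <- array(NA_integer_, dim(xs))
  if (hi == lo || nLevels == 1L) {
    lev[ms] <- 1L
  } else {
    lev[ms] <- pmin(as.integer(floor((xs[ms] - lo) / (hi - lo) * nLevels)) +
                      1L, as.integer(nLevels))
  }
  new("DiscretizedROI", levels = lev, nLevels = as.integer(nLevels))
}

#' Histogram (first-order) features of the in-mask intensities
#'
#' The 16 registry-fixed global statistics of the ROI intensity
#' distribution. \code{entropy} and \code{uniformity} are computed on the
#' \code{nLevels}-bin equal-width discretized distribution (entropy in
#' bits); \code{energy} is the sum of squared intensities. Skewness and
#' kurtosis (non-excess) are 0 by convention for a constant ROI.
#'
#' @inheritParams discretizeROI
#' @return Named numeric of length 16.
#' @examples
#' m <- array(TRUE, c(2, 2, 1))
#' histogramFeatures(array(1:4, c(2, 2, 1)), m)[c("minimum", "maximum", "mean")]
#' @export
histogramFeatures <- function(vol, mask, nLevels = 32L) {
  x <- if (is(vol, "ImageVolume")) vol@data else vol
  m <- .asMaskArray(mask)
  if (!any(m)) stop("empty mask")
  v <- x[m]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  roi <- discretizeROI(vol, mask, nLevels)
  p <- tabulate(roi@levels[!is.na(roi@levels)], nbins = roi@nLevels) / n
  p <- p[p > 0]
  q <- stats::quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  c(energy = sum(v^2),
    entropy = -sum(p * log2(p)),
    minimum = min(v), maximum = max(v), mean = mu,
    median = stats::median(v), range = max(v) - min(v),
    variance = m2, std = sqrt(m2), skewness = skew, kurtosis = kurt,
    uniformity = sum(p^2), p10 = q[1], p90 = q[4], iqr = q[3] - q[2],
    mad = mean(abs(v - mu)))
}

# Symmetric co-occurrence counts for one direction; NULL if no valid pair.
.glcmCounts <- function(lev, d, ng) {
  dm <- dim(lev)
  lo <- pmax(1, 1 - d); hi <- pmin(dm, dm - d)
  if (any(hi < lo)) return(NULL)
  xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
  a <- lev[xr, yr, zr, drop = FALSE]
  b <- lev[xr + d[1], yr + d[2], zr + d[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cnt <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  C <- matrix(cnt, ng, ng, byrow = TRUE)
  C + t(C)
}

# Per-gray-level-count index cache for the co-occurrence feature formulas:
# element-wise weight vectors over the flattened ng x ng matrix plus one-hot
# aggregation matrices for the difference/sum distributions.
.glcmCache <- new.env(parent = emptyenv())
.glcmIdx <- function(ng) {
  key <- as.character(ng)
  if (!is.null(.glcmCache[[key]])) return(.glcmCache[[key]])
  iv <- rep(seq_len(ng), times = ng)   # row index of as.vector(P)
  jv <- rep(seq_len(ng), each = ng)
  ad <- abs(iv - jv)
  idx <- list(
    iv = iv, jv = jv,
    wContrast = (iv - jv)^2, wAbsDiff = ad, wIJ = iv * jv,
    wHom1 = 1 / (1 + ad), wIdn = 1 / (1 + ad / ng),
    wHom2 = 1 / (1 + (iv - jv)^2), wIdmn = 1 / (1 + (iv - jv)^2 / ng^2),
    wInvVar = ifelse(ad > 0, 1 / (iv - jv)^2, 0),
    D = outer(ad, 0:(ng - 1), "==") * 1,       # ng^2 x ng
    S = outer(iv + jv, 2:(2 * ng), "==") * 1)  # ng^2 x (2ng-1)
  .glcmCache[[key]] <- idx
  idx
}

# The 26 co-occurrence features of one normalized symmetric GLCM.
.glcmFeaturesFromP <- function(P) {
  ng <- nrow(P)
  ix <- .glcmIdx(ng)
  Pv <- as.vector(P)
  px <- rowSums(P); py <- colSums(P)
  lv <- seq_len(ng)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx2 <- sum((lv - mux)^2 * px)
  sy2 <- sum((lv - muy)^2 * py)
  nz <- Pv > 0
  hxy <- -sum(Pv[nz] * log2(Pv[nz]))
  pxpy <- as.vector(outer(px, py))
  okm <- pxpy > 0
  hxy1 <- -sum(Pv[okm] * log2(pxpy[okm]))
  hxy2 <- -sum(pxpy[okm] * log2(pxpy[okm]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sx2 > 0 && sy2 > 0)
    (sum(ix$wIJ * Pv) - mux * muy) / sqrt(sx2 * sy2) else 0
  pd <- as.vector(crossprod(ix$D, Pv))
  ps <- as.vector(crossprod(ix$S, Pv))
  da <- sum((0:(ng - 1)) * pd)
  sa <- sum((2:(2 * ng)) * ps)
  pdn <- pd[pd > 0]; psn <- ps[ps > 0]
  # maximal correlation coefficient (Haralick f14) on present levels
  keep <- px > 0
  mcc <- 0
  if (sum(keep) >= 2) {
    Pk <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    Q <- (Pk / pxk) %*% t(sweep(Pk, 2, pyk, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, min(1, ev[2])))
  }
  sums <- ix$iv + ix$jv - mux - muy
  c(joint_maximum = max(Pv),
    joint_average = mux,
    joint_variance = sum((ix$iv - mux)^2 * Pv),
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum(((0:(ng - 1)) - da)^2 * pd),
    difference_entropy = -sum(pdn * log2(pdn)),
    sum_average = sa,
    sum_variance = sum(((2:(2 * ng)) - sa)^2 * ps),
    sum_entropy = -sum(psn * log2(psn)),
    energy = sum(Pv^2),
    contrast = sum(ix$wContrast * Pv),
    dissimilarity = sum(ix$wAbsDiff * Pv),
    homogeneity1 = sum(ix$wHom1 * Pv),
    idn = sum(ix$wIdn * Pv),
    homogeneity2 = sum(ix$wHom2 * Pv),
    idmn = sum(ix$wIdmn * Pv),
    inverse_variance = sum(ix$wInvVar * Pv),
    correlation = corr,
    autocorrelation = sum(ix$wIJ * Pv),
    cluster_tendency = sum(sums^2 * Pv),
    cluster_shade = sum(sums^3 * Pv),
    cluster_prominence = sum(sums^4 * Pv),
    imc1 = imc1, imc2 = imc2, mcc = mcc)
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence matrices at displacement 1 are built for each of
#' the 13 unique 3D directions, normalized, and the 26 registry features are
#' computed per direction and averaged (directions without a valid voxel
#' pair are skipped). Degenerate conventions: IMC1, correlation and the
#' maximal correlation coefficient are 0 when the relevant marginal entropy
#' or variance is zero.
#'
#' @param roi a [DiscretizedROI-class].
#' @return Named numeric of length 26.
#' @examples
#' roi <- discretizeROI(array(1, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
#' glcmFeatures(roi)[c("contrast", "homogeneity1", "imc1", "energy")]
#' @export
glcmFeatures <- function(roi) {
  stopifnot(is(roi, "DiscretizedROI"))
  ng <- roi@nLevels
  acc <- NULL; nd <- 0L
  for (r in seq_len(nrow(GLCM_DIRECTIONS))) {
    C <- .glcmCounts(roi@levels, GLCM_DIRECTIONS[r, ], ng)
    if (is.null(C)) next
    f <- .glcmFeaturesFromP(C / sum(C))
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) {
    # single-voxel-scale ROI: features of the single-entry matrix
    P <- matrix(1, 1, 1)
    return(.glcmFeaturesFromP(P))
  }
  acc / nd
}

# Run-length counts r(level, length) for one direction using an ordered
# line-id scan; returns list(counts, nVox).
.glrlmCounts <- function(lev, d, ng) {
  dm <- dim(lev)
  idx <- seq_along(lev)  # all bbox voxels
  co <- arrayInd(idx, dm)
  # position along the direction: coordinate of the first nonzero component
  ax <- which(d != 0)[1]
  t <- co[, ax] * d[ax]
  lid <- co - cbind(t * d[1], t * d[2], t * d[3])
  l1 <- lid[, 1] - min(lid[, 1]); l2 <- lid[, 2] - min(lid[, 2])
  l3 <- lid[, 3] - min(lid[, 3])
  m1 <- max(l1) + 1L; m2 <- max(l2) + 1L
  key <- l1 + l2 * m1 + l3 * m1 * m2
  ord <- order(key, t)
  lv <- lev[idx[ord]]
  # encode line membership so runs never cross lines; NAs break runs
  comb <- key[ord] * (ng + 2) + as.numeric(lv)
  r <- rle(comb)
  keepRuns <- !is.na(r$values)
  lens <- r$lengths[keepRuns]
  gl <- as.integer(round(r$values[keepRuns] %% (ng + 2)))
  list(levels = gl, lengths = lens, nVox = sum(!is.na(lev)))
}

.glrlmFeaturesFromRuns <- function(gl, len, nVox) {
  nr <- length(gl)
  p <- rep(1 / nr, nr)
  mg <- sum(p * gl); ml <- sum(p * len)
  glnNum <- sum(tabulate(gl)^2)
  rlnNum <- sum(tabulate(len)^2)
  c(sre = mean(1 / len^2), lre = mean(len^2),
    gln = glnNum / nr, rln = rlnNum / nr, rp = nr / nVox,
    lgre = mean(1 / gl^2), hgre = mean(gl^2),
    srlge = mean(1 / (gl^2 * len^2)), srhge = mean(gl^2 / len^2),
    lrlge = mean(len^2 / gl^2), lrhge = mean(gl^2 * len^2),
    glv = sum(p * (gl - mg)^2), rlv = sum(p * (len - ml)^2))
}

#' Gray-level run-length (GLRLM) features
#'
#' Maximal runs of equal gray level along each of the 13 unique 3D
#' directions (mask gaps break runs); the 13 classical run-length features
#' are computed per direction and averaged.
#'
#' @param roi a [DiscretizedROI-class].
#' @return Named numeric of length 13: SRE, LRE, GLN, RLN, RP, LGRE, HGRE,
#'   SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV (lower-case names).
#' @export
glrlmFeatures <- function(roi) {
  stopifnot(is(roi, "DiscretizedROI"))
  acc <- NULL; nd <- 0L
  for (r in seq_len(nrow(GLCM_DIRECTIONS))) {
    rc <- .glrlmCounts(roi@levels, GLCM_DIRECTIONS[r, ], roi@nLevels)
    if (length(rc$levels) == 0) next
    f <- .glrlmFeaturesFromRuns(rc$levels, rc$lengths, rc$nVox)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("ROI has no voxels for run-length analysis")
  acc / nd
}

#' Rotation-invariant uniform LBP code histogram
#'
#' 8-neighbour, radius-1 local binary patterns computed slice-by-slice along
#' the third axis at in-mask voxels (voxels on the volume edge are skipped),
#' mapped to the 10 rotation-invariant uniform (riu2) codes, pooled across
#' slices, and returned as a normalized 10-bin histogram. Neighbours are
#' compared to the centre with \code{>=}.
#'
#' @param vol [ImageVolume-class] or 3D array.
#' @param mask binary mask, nonempty.
#' @return Named numeric of length 10 summing to 1.
#' @export
lbpFeatures <- function(vol, mask) {
  x <- if (is(vol, "ImageVolume")) vol@data else vol
  m <- .asMaskArray(mask)
  if (!any(m)) stop("empty mask")
  dm <- dim(x)
  if (dm[1] < 3 || dm[2] < 3)
    stop("slices must be at least 3x3 for 8-neighbour LBP")
  # crop to the mask bounding box plus the 1-voxel neighbourhood margin;
  # voxels on the original volume edge keep being skipped
  bb <- .maskBBox(m)
  xr <- max(1, bb$x[1] - 1):min(dm[1], bb$x[2] + 1)
  yr <- max(1, bb$y[1] - 1):min(dm[2], bb$y[2] + 1)
  zr <- bb$z[1]:bb$z[2]
  x <- x[xr, yr, zr, drop = FALSE]
  m <- m[xr, yr, zr, drop = FALSE]
  dm <- dim(x)
  if (dm[1] < 3 || dm[2] < 3)
    stop("mask has no voxel with a full in-plane neighbourhood")
  # circular neighbour order (row, col offsets)
  offs <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  counts <- numeric(10)
  rs <- 2:(dm[1] - 1); cs <- 2:(dm[2] - 1)
  for (z in seq_len(dm[3])) {
    msl <- m[rs, cs, z]
    if (!any(msl)) next
    ctr <- x[rs, cs, z]
    s <- array(0L, c(length(rs), length(cs), 8))
    for (k in 1:8)
      s[, , k] <- (x[rs + offs[k, 1], cs + offs[k, 2], z] >= ctr) * 1L
    ones <- rowSums(s, dims = 2)
    trans <- abs(s[, , 1] - s[, , 8])
    for (k in 1:7) trans <- trans + abs(s[, , k + 1] - s[, , k])
    code <- ifelse(trans <= 2, ones, 9L)
    counts <- counts + tabulate(code[msl] + 1L, nbins = 10)
  }
  if (sum(counts) == 0)
    stop("mask has no voxel with a full in-plane neighbourhood")
  h <- counts / sum(counts)
  names(h) <- LBP_NAMES
  h
}

#' Geometry (shape and size) features of a lesion mask
#'
#' Volume by voxel counting, surface area by exposed-face counting (a known
#' overestimate for smooth shapes, but deterministic and oracle-checkable),
#' their ratio, three compactness-type shape descriptors, spherical
#' disproportion, and the maximum 3D diameter (largest pairwise distance
#' between surface-voxel centres).
#'
#' @param mask binary mask (array or \code{ImageVolume}), nonempty.
#' @param spacing numeric(3) voxel size in mm (taken from the mask when it is
#'   an \code{ImageVolume}).
#' @return Named numeric of length 8.
#' @examples
#' geometryFeatures(array(TRUE, c(1, 1, 1)), c(1, 1, 1))[1:2]  # V=1, A=6
#' @export
geometryFeatures <- function(mask, spacing = NULL) {
  if (is(mask, "ImageVolume") && is.null(spacing)) spacing <- mask@spacing
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  m <- .asMaskArray(mask)
  if (!any(m)) stop("empty mask")
  dm <- dim(m)
  vol <- sum(m) * prod(spacing)
  # exposed faces per axis: neighbour absent or outside the grid
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
  faceAreas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  exposed <- array(0L, dm)
  A <- 0
  for (ax in 1:3) {
    sel <- function(off) {
      idx <- lapply(1:3, function(a) {
        r <- 2:(dm[a] + 1)
        if (a == ax) r + off else r
      })
      pad[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    ex <- (!sel(-1L)) + (!sel(1L))
    ex[!m] <- 0L
    exposed <- exposed + ex
    A <- A + sum(ex) * faceAreas[ax]
  }
  surf <- which(m & exposed > 0)
  co <- arrayInd(surf, dm)
  pts <- sweep(co - 1, 2, spacing, "*")
  maxd <- 0
  if (nrow(pts) > 1) {
    g2 <- rowSums(pts^2)
    maxd <- sqrt(max(0, max(outer(g2, g2, "+") - 2 * pts %*% t(pts))))
  }
  R <- (3 * vol / (4 * pi))^(1 / 3)
  c(volume_mm3 = vol, surface_area_mm2 = A,
    surface_to_volume_ratio = A / vol,
    sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / A,
    compactness1 = vol / (sqrt(pi) * A^1.5),
    compactness2 = 36 * pi * vol^2 / A^3,
    spherical_disproportion = A / (4 * pi * R^2),
    max_diameter_3d_mm = maxd)
}

# The 65 intensity features of one image set (histogram + GLCM + GLRLM +
# LBP) under the package-wide discretization.
.imageSetFeatures <- function(arr, mask, nLevels) {
  roi <- discretizeROI(arr, mask, nLevels)
  c(histogramFeatures(arr, mask, nLevels), glcmFeatures(roi),
    glrlmFeatures(roi), lbpFeatures(arr, mask))
}

#' Extract the full 1763-entry radiomic profile of one lesion
#'
#' For each contrast, computes the 16 histogram and 49 texture features on
#' the original volume and on each of the 8 undecimated coif1 wavelet
#' subbands (585 features per contrast), plus the 8 geometry features of the
#' mask: 1763 features in the fixed [featureRegistry()] order.
#'
#' @param t1w,t1c,t2w co-registered, normalized [ImageVolume-class]s sharing
#'   the mask grid.
#' @param mask binary lesion mask on the same grid.
#' @param nLevels texture gray-level count (default 32).
#' @param subbands optional precomputed list (per contrast) of
#'   [waveletDecompose3D()] outputs, so multi-lesion patients pay the
#'   wavelet cost once.
#' @return Named numeric of length 1763, all finite.
#' @export
extractAllFeatures <- function(t1w, t1c, t2w, mask, nLevels = 32L,
                               subbands = NULL) {
  vols <- list(T1w = t1w, T1c = t1c, T2w = t2w)
  m <- .asMaskArray(mask)
  dms <- vapply(vols, function(v) dim(v@data), integer(3))
  if (any(dms != dim(m)))
    stop("contrast volumes and mask must share one grid")
  if (!any(m)) stop("empty mask")
  out <- numeric(0)
  for (ct in VALID_CONTRASTS) {
    v <- vols[[ct]]
    sets <- c(list(none = v@data),
              lapply(if (is.null(subbands)) waveletDecompose3D(v)
                     else subbands[[ct]], function(s) s@data))
    for (tag in IMAGE_SET_TAGS) {
      f <- .imageSetFeatures(sets[[tag]], m, nLevels)
      names(f) <- paste(ct, tag,
                        rep(c("histogram", "glcm", "glrlm", "lbp"),
                            c(16, 26, 13, 10)),
                        names(f), sep = ".")
      out <- c(out, f)
    }
  }
  g <- geometryFeatures(m, spacing = if (is(mask, "ImageVolume"))
    mask@spacing else voxelSpacing(t1w))
  names(g) <- paste("mask", "none", "geometry", names(g), sep = ".")
  out <- c(out, g)
  stopifnot(length(out) == 1763L, all(is.finite(out)))
  out
}

#' Extract features for every lesion of a cohort
#'
#' Applies Z-score normalization per volume ([zscoreNormalize()]), computes
#' the wavelet subbands once per patient, and extracts the 1763-entry
#' profile for every lesion mask.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param nLevels texture gray-level count.
#' @param normalize apply [zscoreNormalize()] to each volume first (the
#'   standard preprocessing).
#' @return Numeric matrix, lesions x 1763, rownames = lesion ids.
#' @export
extractCohortFeatures <- function(cohort, nLevels = 32L, normalize = TRUE) {
  stopifnot(is(cohort, "SyntheticCohort"))
  reg <- featureRegistry()
  lesions <- cohort@clinical$lesion_id
  out <- matrix(NA_real_, length(lesions), nrow(reg),
                dimnames = list(lesions, reg$name))
  for (p in names(cohort@volumes)) {
    vols <- cohort@volumes[[p]]
    if (normalize) vols <- lapply(vols, zscoreNormalize)
    subbands <- lapply(vols, waveletDecompose3D)
    for (lid in lesions[cohort@clinical$patient_id == p]) {
      out[lid, ] <- extractAllFeatures(vols$T1w, vols$T1c, vols$T2w,
                                       cohort@masks[[lid]], nLevels,
                                       subbands = subbands)
    }
  }
  out
}
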