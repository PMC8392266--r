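# Undecimated separable 3D Coiflet-1 decomposition.

# Coiflet-1 analysis filter bank (6 taps, double precision).
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578,    0.8525720202116004,
               0.3378976624574818,   -0.07273261951252645)
COIF1_HI <- c( 0.07273261951252645,   0.3378976624574818,
              -0.8525720202116004,    0.3848648468648578,
               0.07273261951252645,  -0.015655728135791993)

#' Single-level undecimated 3D wavelet decomposition (coif1)
#'
#' Applies the Coiflet-1 low (L) and high (H) pass analysis filters along
#' each of the three image axes in turn, producing the eight filtered image
#' sets LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH. The transform is
#' undecimated (stationary), so every subband shares the input grid and an
#' ROI mask applies to the subbands directly. Boundaries use half-sample
#' symmetric extension. The letter order follows the image axes: the first
#' letter is the filter applied along axis 1.
#'
#' @param vol an [ImageVolume-class]; each axis must be at least as long as
#'   the 6-tap coif1 filter.
#' @return Named list of eight \code{ImageVolume}s, tagged
#'   \code{LLL ... HHH}, on the input grid.
#' @examples
#' v <- imageVolume(array(rnorm(8^3), c(8, 8, 8)))
#' sub <- waveletDecompose3D(v)
#' names(sub)
#' @export
waveletDecompose3D <- function(vol) {
  stopifnot(is(vol, "ImageVolume"))
  d <- dim(vol@data)
  if (any(d < length(COIF1_LO)))
    stop("volume smaller than the coif1 filter support (6 voxels per axis)")
  lev1 <- list(L = convAxisSym(vol@data, COIF1_LO, 1L),
               H = convAxisSym(vol@data, COIF1_HI, 1L))
  out <- vector("list", 8L)
  names(out) <- WAVELET_TAGS
  for (tag in WAVELET_TAGS) {
    f <- strsplit(tag, "")[[1]]
    a <- lev1[[f[1]]]
    a <- convAxisSym(a, if (f[2] == "L") COIF1_LO else COIF1_HI, 2L)
    a <- convAxisSym(a, if (f[3] == "L") COIF1_LO else COIF1_HI, 3L)
    out[[tag]] <- imageVolume(a, spacing = vol@spacing,
                              contrast = vol@contrast, origin = vol@origin)
  }
  out
}
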