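# The fixed 1763-entry feature registry: 585 intensity features per contrast
# (9 image sets x (16 histogram + 49 texture)) plus 8 geometry features.

HIST_NAMES <- c("energy", "entropy", "minimum", "maximum", "mean", "median",
                "range", "variance", "std", "skewness", "kurtosis",
                "uniformity", "p10", "p90", "iqr", "mad")

GLCM_NAMES <- c("joint_maximum", "joint_average", "joint_variance",
                "joint_entropy", "difference_average", "difference_variance",
                "difference_entropy", "sum_average", "sum_variance",
                "sum_entropy", "energy", "contrast", "dissimilarity",
                "homogeneity1", "idn", "homogeneity2", "idmn",
                "inverse_variance", "correlation", "autocorrelation",
                "cluster_tendency", "cluster_shade", "cluster_prominence",
                "imc1", "imc2", "mcc")

GLRLM_NAMES <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge",
                 "srhge", "lrlge", "lrhge", "glv", "rlv")

LBP_NAMES <- c(paste0("riu2_", 0:8), "riu2_nonuniform")

GEOM_NAMES <- c("volume_mm3", "surface_area_mm2", "surface_to_volume_ratio",
                "sphericity", "compactness1", "compactness2",
                "spherical_disproportion", "max_diameter_3d_mm")

#' The radiomic feature registry
#'
#' Fixed, ordered inventory of the 1763 features extracted per lesion: for
#' each contrast (T1w, T1c, T2w) and each of 9 image sets (the original
#' image plus 8 coif1 wavelet subbands), 16 histogram features and 49
#' texture features (26 GLCM + 13 GLRLM + 10 rotation-invariant uniform LBP
#' codes), i.e. 585 per contrast, plus 8 mask geometry features. Entry names
#' are \code{contrast.filter.family.feature}.
#'
#' @return A data.frame with columns \code{contrast}, \code{filter},
#'   \code{family}, \code{feature}, \code{name} and exactly 1763 rows.
#' @examples
#' reg <- featureRegistry()
#' nrow(reg)                      # 1763
#' table(reg$contrast)            # 585 per imaging contrast + 8 geometry
#' @export
featureRegistry <- function() {
  rows <- vector("list", 3L * 9L * 4L + 1L)
  i <- 1L
  for (ct in VALID_CONTRASTS) {
    for (tag in IMAGE_SET_TAGS) {
      for (fam in c("histogram", "glcm", "glrlm", "lbp")) {
        feats <- switch(fam, histogram = HIST_NAMES, glcm = GLCM_NAMES,
                        glrlm = GLRLM_NAMES, lbp = LBP_NAMES)
        rows[[i]] <- data.frame(contrast = ct, filter = tag, family = fam,
                                feature = feats, stringsAsFactors = FALSE)
        i <- i + 1L
      }
    }
  }
  rows[[i]] <- data.frame(contrast = "mask", filter = "none",
                          family = "geometry", feature = GEOM_NAMES,
                          stringsAsFactors = FALSE)
  reg <- do.call(rbind, rows)
  reg$name <- paste(reg$contrast, reg$filter, reg$family, reg$feature,
                    sep = ".")
  stopifnot(nrow(reg) == 1763L, !anyDuplicated(reg$name))
  rownames(reg) <- NULL
  reg
}
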