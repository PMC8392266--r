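#' Accessors for ImageVolume
#'
#' @param x an [ImageVolume-class].
#' @return \code{voxelData} the 3D array; \code{voxelSpacing} the mm spacing;
#'   \code{contrastTag} the contrast label; \code{volumeOrigin} the world
#'   origin.
#' @name ImageVolume-accessors
#' @examples
#' v <- imageVolume(array(0, c(4, 4, 4)))
#' dim(voxelData(v)); voxelSpacing(v)
NULL

#' @rdname ImageVolume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@data)

#' @rdname ImageVolume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname ImageVolume-accessors
#' @export
setGeneric("contrastTag", function(x) standardGeneric("contrastTag"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("contrastTag", "ImageVolume", function(x) x@contrast)

#' @rdname ImageVolume-accessors
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @rdname ImageVolume-accessors
#' @export
setMethod("volumeOrigin", "ImageVolume", function(x) x@origin)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s] %d x %d x %d voxels, spacing %s mm\n",
              object@contrast, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n")
  cat("  rotation (deg):", paste(signif(object@rotation * 180 / pi, 4),
                                 collapse = ", "), "\n")
  cat("  translation (mm):", paste(signif(object@translation, 4),
                                   collapse = ", "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d patients, %d-%d lesions each, grid %s @ %s mm\n",
              object@nPatients, object@lesionsPerPatient[1],
              object@lesionsPerPatient[2],
              paste(object@gridShape, collapse = "x"),
              paste(signif(object@spacing, 3), collapse = "x")))
  cat(sprintf("  heterogeneity good/poor: %.3g / %.3g, flip rate %.3g, seed %d\n",
              object@heterogeneityByClass["good"],
              object@heterogeneityByClass["poor"],
              object@flipRate, object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d patients, %d lesions, contrasts %s\n",
              length(object@volumes), length(object@masks),
              paste(VALID_CONTRASTS, collapse = "/")))
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable [%s, %s-wise]: %d rows, %d clinical + %d radiomic columns\n",
              object@task, object@unit, nrow(object@data),
              length(object@clinicalCols), length(object@featureCols)))
  print(table(object@data$outcome))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d models, %d bootstrap resamples\n",
              nrow(object@metrics), dim(object@boot)[1]))
  print(round(object@metrics, 3))
  sig <- object@comparisons[object@comparisons$significant, , drop = FALSE]
  cat(sprintf("  %d of %d pairwise comparisons significant at alpha = %.3g (Bonferroni)\n",
              nrow(sig), nrow(object@comparisons),
              object@alpha))
})

#' Accessors for CohortTable and EvalReport
#'
#' @param x a [CohortTable-class] or [EvalReport-class].
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))
#' @rdname result-accessors
#' @export
setMethod("cohortData", "CohortTable", function(x) x@data)

#' @rdname result-accessors
#' @export
setGeneric("clinicalColumns", function(x) standardGeneric("clinicalColumns"))
#' @rdname result-accessors
#' @export
setMethod("clinicalColumns", "CohortTable", function(x) x@clinicalCols)

#' @rdname result-accessors
#' @export
setGeneric("featureColumns", function(x) standardGeneric("featureColumns"))
#' @rdname result-accessors
#' @export
setMethod("featureColumns", "CohortTable", function(x) x@featureCols)

#' @rdname result-accessors
#' @export
setGeneric("evalMetrics", function(x) standardGeneric("evalMetrics"))
#' @rdname result-accessors
#' @export
setMethod("evalMetrics", "EvalReport", function(x) x@metrics)

#' @rdname result-accessors
#' @export
setGeneric("evalComparisons", function(x) standardGeneric("evalComparisons"))
#' @rdname result-accessors
#' @export
setMethod("evalComparisons", "EvalReport", function(x) x@comparisons)

#' @rdname result-accessors
#' @export
setGeneric("bootDistributions", function(x) standardGeneric("bootDistributions"))
#' @rdname result-accessors
#' @export
setMethod("bootDistributions", "EvalReport", function(x) x@boot)

#' @rdname result-accessors
#' @export
setGeneric("cohortClinical", function(x) standardGeneric("cohortClinical"))
#' @rdname result-accessors
#' @export
setMethod("cohortClinical", "SyntheticCohort", function(x) x@clinical)
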