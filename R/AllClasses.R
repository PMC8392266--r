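#' @import methods
NULL

VALID_CONTRASTS <- c("T1w", "T1c", "T2w")
WAVELET_TAGS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
IMAGE_SET_TAGS <- c("none", WAVELET_TAGS)

#' ImageVolume: a 3D scalar grid with voxel spacing and contrast tag
#'
#' The basic image container of the package: a dense 3D array of intensities
#' together with its per-axis voxel size in millimetres, an MRI contrast tag
#' and a world-space origin. Voxel centre \code{(i, j, k)} (1-based) maps to
#' world coordinate \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @slot data 3D numeric array of voxel intensities (all finite).
#' @slot spacing numeric(3), strictly positive voxel size in mm per axis.
#' @slot contrast one of \code{"T1w"}, \code{"T1c"}, \code{"T2w"}, or
#'   \code{"mask"} for binary lesion masks.
#' @slot origin numeric(3), world coordinate (mm) of the first voxel centre.
#'
#' @seealso [imageVolume()], [resampleIsotropic()], [zscoreNormalize()]
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric",
                 contrast = "character", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), contrast = "T1w", origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values")
  if (!(object@contrast %in% c(VALID_CONTRASTS, "mask")))
    msgs <- c(msgs, "contrast must be one of T1w, T1c, T2w, mask")
  if (any(!is.finite(object@data)))
    msgs <- c(msgs, "data must be finite everywhere")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3) voxel size in mm (recycled from length 1).
#' @param contrast contrast tag (\code{"T1w"}, \code{"T1c"}, \code{"T2w"} or
#'   \code{"mask"}).
#' @param origin numeric(3) world position of the first voxel centre, mm.
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- imageVolume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = 1)
#' voxelSpacing(vol)
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), contrast = "T1w",
                        origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      contrast = contrast, origin = as.numeric(origin))
}

#' RigidTransform: a six-parameter rigid body transform
#'
#' Rotation angles (radians, applied as Rz Ry Rx about the volume centre)
#' plus a translation in mm. Used by [rigidRegister()] to map fixed-image
#' world coordinates into the moving image.
#'
#' @slot rotation numeric(3) rotation angles in radians (about x, y, z).
#' @slot translation numeric(3) offsets in mm.
#' @slot centre numeric(3) rotation centre in world coordinates (mm).
#' @export
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric",
                 centre = "numeric"),
  prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0),
            centre = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  if (length(object@rotation) != 3L || length(object@translation) != 3L ||
      length(object@centre) != 3L ||
      any(!is.finite(c(object@rotation, object@translation, object@centre))))
    "rotation, translation and centre must each be 3 finite values"
  else TRUE
})

#' @rdname RigidTransform-class
#' @param rotation numeric(3) angles in radians.
#' @param translation numeric(3) offsets in mm.
#' @param centre numeric(3) rotation centre (mm).
#' @return A \code{RigidTransform}.
#' @export
rigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           centre = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation), centre = as.numeric(centre))
}

#' PhantomSpec: parameters of the synthetic phantom cohort generator
#'
#' Describes the study conditions a generated cohort emulates: the imaging
#' grid, cohort size, lesion geometry, the per-class texture heterogeneity
#' amplitudes that plant the radiomic signal, per-contrast intensity levels,
#' standardized clinical effect sizes, outcome-label noise and the survival
#' distributions. See the package vignette for the rationale behind the
#' defaults.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot nPatients number of patients.
#' @slot lesionsPerPatient integer(2) inclusive range of lesions per patient.
#' @slot lesionRadius numeric(2) range of mean lesion radius in mm; per-axis
#'   radii are jittered +/- 30\% to give ellipsoids.
#' @slot heterogeneityByClass named numeric, texture noise amplitude inside
#'   lesions for the \code{good} and \code{poor} latent class (dimensionless,
#'   relative to the lesion/background intensity contrast).
#' @slot contrastMeans named list per contrast with \code{background} and
#'   \code{lesion} mean intensities (arbitrary units).
#' @slot noiseSD background white-noise standard deviation (intensity units).
#' @slot effectSizes named numeric standardized mean differences between
#'   outcome classes for the clinical covariates \code{kps_ge90},
#'   \code{extracranial_mets}, \code{primary_controlled}, \code{n_lesions}.
#' @slot flipRate probability a lesion's follow-up volume (and a patient's
#'   survival time) is drawn from the other class's distribution.
#' @slot osMedians named numeric, median overall survival in months for the
#'   \code{good} and \code{poor} class (log-normal, sdlog 0.5, truncated at
#'   the geometric midpoint so the median split is exact at flip rate 0).
#' @slot seed integer RNG seed; fixed seed gives bit-identical cohorts.
#' @seealso [phantomSpec()], [makePhantomCohort()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 nPatients = "integer", lesionsPerPatient = "integer",
                 lesionRadius = "numeric", heterogeneityByClass = "numeric",
                 contrastMeans = "list", noiseSD = "numeric",
                 effectSizes = "numeric", flipRate = "numeric",
                 osMedians = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    msgs <- c(msgs, "gridShape must be 3 values >= 4")
  if (any(object@spacing <= 0)) msgs <- c(msgs, "spacing must be positive")
  if (object@nPatients < 1L) msgs <- c(msgs, "nPatients must be >= 1")
  if (length(object@lesionsPerPatient) != 2L ||
      object@lesionsPerPatient[1] < 1L ||
      diff(object@lesionsPerPatient) < 0)
    msgs <- c(msgs, "lesionsPerPatient must be an increasing range >= 1")
  if (length(object@lesionRadius) != 2L || any(object@lesionRadius <= 0) ||
      diff(object@lesionRadius) < 0)
    msgs <- c(msgs, "lesionRadius must be a positive increasing range")
  # jittered ellipsoid semi-axes (up to 1.3 r) must fit inside the grid
  ext <- object@gridShape * object@spacing
  if (2 * 1.3 * object@lesionRadius[2] >= min(ext) - 2 * max(object@spacing))
    msgs <- c(msgs, "largest lesion does not fit inside the grid")
  if (!all(c("good", "poor") %in% names(object@heterogeneityByClass)))
    msgs <- c(msgs, "heterogeneityByClass needs entries 'good' and 'poor'")
  if (any(object@heterogeneityByClass < 0))
    msgs <- c(msgs, "heterogeneity amplitudes must be >= 0")
  if (!all(VALID_CONTRASTS %in% names(object@contrastMeans)))
    msgs <- c(msgs, "contrastMeans needs entries T1w, T1c, T2w")
  if (object@flipRate < 0 || object@flipRate > 1)
    msgs <- c(msgs, "flipRate must be in [0, 1]")
  if (!all(c("good", "poor") %in% names(object@osMedians)) ||
      any(object@osMedians <= 0))
    msgs <- c(msgs, "osMedians needs positive entries 'good' and 'poor'")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCohort: phantom volumes, masks and clinical table
#'
#' The in-memory product of [makePhantomCohort()]: per patient one aligned
#' [ImageVolume-class] per contrast, per lesion a binary mask volume, and a
#' per-lesion clinical/outcome table that includes the latent classes the
#' generator planted (for validation only; the modeling stages never see
#' them).
#'
#' @slot volumes named list (by patient id) of named lists (by contrast) of
#'   \code{ImageVolume}s.
#' @slot masks named list (by lesion id) of \code{ImageVolume}s with binary
#'   data.
#' @slot clinical data.frame, one row per lesion, with columns
#'   \code{patient_id, lesion_id, kps_ge90, extracranial_mets,
#'   primary_controlled, n_lesions, os_months, vol_baseline_mm3,
#'   vol_followup_mm3} plus latent classes \code{latent_control},
#'   \code{latent_survival}.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("SyntheticCohort",
  representation(volumes = "list", masks = "list", clinical = "data.frame",
                 spec = "PhantomSpec"))

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  if (nrow(object@clinical) > 0 &&
      !all(object@clinical$lesion_id %in% names(object@masks)))
    msgs <- c(msgs, "every clinical row must have a mask")
  for (m in object@masks)
    if (sum(m@data) == 0) msgs <- c(msgs, "masks must be nonempty")
  if (length(msgs)) unique(msgs) else TRUE
})

#' CohortTable: a labeled modeling table
#'
#' One row per modeling unit (lesion for local control, patient for
#' survival) holding clinical covariates, radiomic features and the binary
#' outcome. Use [cohortView()] to obtain the clinical-only, radiomics-only or
#' combined column subset.
#'
#' @slot data data.frame with an \code{outcome} factor (levels
#'   \code{good}, \code{poor}), unit identifiers, clinical covariate columns
#'   and radiomic feature columns.
#' @slot task \code{"local_control"} (lesion-wise) or \code{"survival"}
#'   (patient-wise, largest lesion per patient).
#' @slot unit \code{"lesion"} or \code{"patient"}.
#' @slot clinicalCols character, names of the clinical covariate columns.
#' @slot featureCols character, names of the radiomic feature columns.
#' @export
setClass("CohortTable",
  representation(data = "data.frame", task = "character", unit = "character",
                 clinicalCols = "character", featureCols = "character"))

setValidity("CohortTable", function(object) {
  msgs <- character()
  if (!object@task %in% c("local_control", "survival"))
    msgs <- c(msgs, "task must be 'local_control' or 'survival'")
  if (!object@unit %in% c("lesion", "patient"))
    msgs <- c(msgs, "unit must be 'lesion' or 'patient'")
  if (!"outcome" %in% names(object@data))
    msgs <- c(msgs, "data must contain an 'outcome' column")
  modCols <- c(object@clinicalCols, object@featureCols)
  missing <- setdiff(modCols, names(object@data))
  if (length(missing))
    msgs <- c(msgs, paste("missing modeling columns:",
                          paste(utils::head(missing, 3), collapse = ", ")))
  else if (nrow(object@data) &&
           anyNA(object@data[, modCols, drop = FALSE]))
    msgs <- c(msgs, "modeling columns must have no missing values")
  if (length(msgs)) msgs else TRUE
})

#' EvalReport: test-set metrics with bootstrap comparison of models
#'
#' Produced by [bootstrapCompare()]: point metrics (AUC, accuracy,
#' sensitivity, specificity) per model on the common test set, the per-metric
#' bootstrap distributions over shared resamples, and Bonferroni-corrected
#' paired t-test comparisons for every model pair.
#'
#' @slot metrics numeric matrix, models x metrics, on the full test set.
#' @slot boot 3D array, resamples x metrics x models.
#' @slot comparisons data.frame with columns \code{metric, model1, model2,
#'   p_value, significant} (significance at \code{alpha /} number of pairs).
#' @slot alpha nominal significance level before correction.
#' @slot indices integer matrix of bootstrap resample indices (resamples x
#'   test size), shared across models (pairing).
#' @export
setClass("EvalReport",
  representation(metrics = "matrix", boot = "array",
                 comparisons = "data.frame", alpha = "numeric",
                 indices = "matrix"))

setValidity("EvalReport", function(object) {
  msgs <- character()
  if (any(object@metrics < -1e-9 | object@metrics > 1 + 1e-9, na.rm = TRUE))
    msgs <- c(msgs, "metrics must lie in [0, 1]")
  if (dim(object@boot)[1] != nrow(object@indices))
    msgs <- c(msgs, "bootstrap distributions must have one entry per resample")
  if (length(msgs)) msgs else TRUE
})
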