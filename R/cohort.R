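# Outcome labeling and modeling-table assembly.

CLINICAL_COLS <- c("kps_ge90", "extracranial_mets", "primary_controlled",
                   "n_lesions", "log_volume_mm3")

#' Local tumor control label from baseline and follow-up volumes
#'
#' A lesion shows poor local control (progression) when its volume increased
#' by more than 10\% between the pre-treatment MRI and the last follow-up;
#' stable volume or regression (including exactly +10\%) is good control.
#'
#' @param baseline,followup lesion volumes in mm^3 (vectors allowed), > 0.
#' @return factor with levels \code{good}, \code{poor}.
#' @examples
#' labelTumorControl(c(100, 100, 100), c(111, 110, 85))  # poor good good
#' @export
labelTumorControl <- function(baseline, followup) {
  if (any(baseline <= 0) || any(followup <= 0))
    stop("volumes must be positive")
  delta <- (followup - baseline) / baseline
  factor(ifelse(delta > 0.10, "poor", "good"), levels = c("good", "poor"))
}

#' Survival label from the cohort median split
#'
#' Patients at or above the cohort median overall survival are labeled
#' \code{good}, below it \code{poor}. The boundary (OS exactly equal to the
#' median) counts as good. The median is a descriptor of the full analyzed
#' cohort (computed before any train/test split; see the vignette for the
#' leakage note).
#'
#' @param os overall survival in months, >= 0.
#' @param cohortMedian the cohort median OS; defaults to \code{median(os)}.
#' @return factor with levels \code{good}, \code{poor}.
#' @examples
#' labelSurvival(c(5, 10, 20, 40))  # poor poor good good (median 15)
#' @export
labelSurvival <- function(os, cohortMedian = stats::median(os)) {
  if (any(os < 0)) stop("overall survival must be non-negative")
  factor(ifelse(os >= cohortMedian, "good", "poor"),
         levels = c("good", "poor"))
}

#' Select the largest lesion per patient
#'
#' For patient-wise (survival) modeling only the radiomic features of the
#' largest brain metastasis are used. Ties on baseline volume are broken by
#' the lexicographically smallest lesion id and reported via a message.
#'
#' @param records data.frame with columns \code{patient_id},
#'   \code{lesion_id}, \code{vol_baseline_mm3} (one row per lesion).
#' @return The input rows of the per-patient largest lesions, ordered by
#'   patient id.
#' @export
largestBMPerPatient <- function(records) {
  stopifnot(all(c("patient_id", "lesion_id", "vol_baseline_mm3") %in%
                names(records)))
  if (nrow(records) == 0) stop("no lesion records")
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$patient_id),
    function(ix) {
      v <- records$vol_baseline_mm3[ix]
      best <- ix[v == max(v)]
      if (length(best) > 1) {
        best <- best[order(records$lesion_id[best])]
        message("volume tie for patient ",
                records$patient_id[best[1]], "; keeping lesion ",
                records$lesion_id[best[1]])
      }
      best[1]
    }))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a labeled modeling table
#'
#' Joins per-lesion radiomic features with the clinical covariates and the
#' task's outcome label into a [CohortTable-class]. Local tumor control is
#' modeled lesion-wise (one row per lesion, label from the +/-10\% volume
#' rule); survival is modeled patient-wise (one row per patient, largest
#' lesion's features, label from the cohort-median OS split). Clinical
#' covariates are the dichotomized KPS (>= 90), extracranial-metastasis and
#' primary-tumor-control flags, the lesion count and the log-transformed
#' baseline volume of the (largest) lesion.
#'
#' @param features numeric matrix of radiomic features, rownames = lesion
#'   ids (e.g. from [extractCohortFeatures()]).
#' @param clinical data.frame with one row per lesion: \code{patient_id},
#'   \code{lesion_id}, the clinical covariates, \code{os_months},
#'   \code{vol_baseline_mm3}, \code{vol_followup_mm3} (the
#'   [SyntheticCohort-class] clinical slot has this shape).
#' @param task \code{"local_control"} or \code{"survival"}.
#' @return A [CohortTable-class].
#' @export
assembleTable <- function(features, clinical, task = c("local_control",
                                                       "survival")) {
  task <- match.arg(task)
  need <- c("patient_id", "lesion_id", "kps_ge90", "extracranial_mets",
            "primary_controlled", "n_lesions", "os_months",
            "vol_baseline_mm3", "vol_followup_mm3")
  missing <- setdiff(need, names(clinical))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  noFeat <- setdiff(clinical$lesion_id, rownames(features))
  if (length(noFeat))
    stop("no features for lesions: ",
         paste(utils::head(noFeat, 5), collapse = ", "))
  rows <- clinical
  if (task == "survival") rows <- largestBMPerPatient(rows)
  outcome <- if (task == "local_control")
    labelTumorControl(rows$vol_baseline_mm3, rows$vol_followup_mm3)
  else labelSurvival(rows$os_months)
  dat <- data.frame(
    patient_id = rows$patient_id, lesion_id = rows$lesion_id,
    kps_ge90 = rows$kps_ge90, extracranial_mets = rows$extracranial_mets,
    primary_controlled = rows$primary_controlled, n_lesions = rows$n_lesions,
    log_volume_mm3 = log(rows$vol_baseline_mm3),
    outcome = outcome, stringsAsFactors = FALSE)
  feat <- features[rows$lesion_id, , drop = FALSE]
  if (anyNA(feat)) stop("missing feature values")
  dat <- cbind(dat, as.data.frame(feat))
  rownames(dat) <- NULL
  new("CohortTable", data = dat, task = task,
      unit = if (task == "survival") "patient" else "lesion",
      clinicalCols = CLINICAL_COLS, featureCols = colnames(features))
}

#' Column-subset views of a CohortTable
#'
#' The three model families share one table; this returns the feature
#' columns visible to each: \code{"clinical"} (covariates only),
#' \code{"radiomics"} (radiomic features only) or \code{"combined"}.
#'
#' @param table a [CohortTable-class].
#' @param view \code{"clinical"}, \code{"radiomics"} or \code{"combined"}.
#' @return Character vector of predictor column names.
#' @export
cohortView <- function(table, view = c("clinical", "radiomics", "combined")) {
  view <- match.arg(view)
  switch(view,
         clinical = table@clinicalCols,
         radiomics = table@featureCols,
         combined = c(table@clinicalCols, table@featureCols))
}
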