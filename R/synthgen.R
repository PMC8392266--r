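# Synthetic multi-contrast phantom cohorts with planted outcome structure.

#' Construct a PhantomSpec
#'
#' Returns the generator parameters with defaults describing the emulated
#' study conditions: a 1 mm isotropic grid, ellipsoidal lesions, class-
#' dependent intra-lesion texture heterogeneity (the "poor" outcome class is
#' more heterogeneous), clinical covariates with moderate standardized
#' effect sizes, a small outcome-label flip rate, and class-separated
#' log-normal survival distributions. See the vignette for the rationale
#' behind each default.
#'
#' @param gridShape integer(3) voxels per axis.
#' @param spacing numeric voxel size in mm (scalar or length 3).
#' @param nPatients number of patients.
#' @param lesionsPerPatient integer(2) range of lesions per patient.
#' @param lesionRadius numeric(2) range of mean lesion radius, mm.
#' @param heterogeneityByClass named numeric \code{c(good=, poor=)}: texture
#'   noise amplitude inside lesions, expressed relative to the
#'   lesion-background intensity difference of each contrast.
#' @param contrastMeans per-contrast list of \code{background} and
#'   \code{lesion} mean intensities.
#' @param noiseSD background white-noise SD (intensity units).
#' @param effectSizes named standardized mean differences (good vs poor) of
#'   the clinical covariates; set all to 0 for a clinically null cohort.
#' @param flipRate probability that a lesion's follow-up volume (or a
#'   patient's survival time) is drawn from the other class.
#' @param osMedians named numeric \code{c(good=, poor=)} median survival in
#'   months.
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(nPatients = 4, seed = 1)
#' spec
#' @export
phantomSpec <- function(gridShape = c(32L, 32L, 32L),
                        spacing = 1,
                        nPatients = 20L,
                        lesionsPerPatient = c(1L, 3L),
                        lesionRadius = c(3, 6),
                        heterogeneityByClass = c(good = 0.15, poor = 0.45),
                        contrastMeans = list(
                          T1w = list(background = 100, lesion = 80),
                          T1c = list(background = 100, lesion = 160),
                          T2w = list(background = 100, lesion = 140)),
                        noiseSD = 5,
                        effectSizes = c(kps_ge90 = 0.8,
                                        extracranial_mets = 0.8,
                                        primary_controlled = 0.5,
                                        n_lesions = 0.5),
                        flipRate = 0.05,
                        osMedians = c(good = 24, poor = 8),
                        seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), nPatients = as.integer(nPatients),
      lesionsPerPatient = as.integer(lesionsPerPatient),
      lesionRadius = as.numeric(lesionRadius),
      heterogeneityByClass = heterogeneityByClass,
      contrastMeans = contrastMeans, noiseSD = as.numeric(noiseSD),
      effectSizes = effectSizes, flipRate = as.numeric(flipRate),
      osMedians = osMedians, seed = as.integer(seed))
}

# Bernoulli probability pair giving approximately the requested standardized
# mean difference d between classes at pooled prevalence 0.5.
.effectProbs <- function(d) {
  shift <- d / 4
  c(good = min(max(0.5 + shift, 0.02), 0.98),
    poor = min(max(0.5 - shift, 0.02), 0.98))
}

# Place one ellipsoidal lesion that fits the grid and avoids `occupied`.
# Returns a logical 3D array, or NULL after `retries` failed draws.
.placeLesion <- function(gridShape, spacing, radius, occupied, retries = 500L) {
  ext <- gridShape * spacing
  coords <- gridWorldCoords(gridShape, spacing)
  for (i in seq_len(retries)) {
    semi <- radius * stats::runif(3, 0.7, 1.3)
    lo <- semi + spacing
    hi <- ext - spacing - semi
    if (any(hi <= lo)) next
    ctr <- stats::runif(3, lo, hi)
    inside <- ((coords[, 1] - ctr[1]) / semi[1])^2 +
              ((coords[, 2] - ctr[2]) / semi[2])^2 +
              ((coords[, 3] - ctr[3]) / semi[3])^2 <= 1
    if (!any(inside)) next
    mask <- array(inside, gridShape)
    if (!any(mask & occupied)) return(mask)
  }
  NULL
}

#' Generate a synthetic phantom cohort
#'
#' Builds aligned T1w/T1c/T2w phantom volumes, per-lesion ellipsoidal masks
#' and a clinical/outcome table with planted statistical structure:
#' \itemize{
#'   \item each patient carries a balanced latent outcome class
#'     (\code{good}/\code{poor}); lesions inherit it;
#'   \item lesions of the \code{poor} class receive a higher-amplitude
#'     spatially correlated intensity noise field (correlation length about
#'     2 voxels), making them texturally more heterogeneous;
#'   \item follow-up lesion volumes are drawn so the +/-10\% volume rule
#'     recovers the latent class, flipped with probability \code{flipRate};
#'   \item survival times are class-conditional log-normals truncated at the
#'     geometric midpoint of the class medians, so the cohort-median split
#'     recovers the latent class exactly at flip rate 0;
#'   \item binary/ordinal clinical covariates differ between classes by the
#'     configured standardized effect sizes.
#' }
#' Output is bit-identical for a fixed \code{spec} (including its seed).
#'
#' @param spec a [PhantomSpec-class].
#' @return A [SyntheticCohort-class].
#' @examples
#' cohort <- makePhantomCohort(phantomSpec(nPatients = 2, seed = 7))
#' head(cohortClinical(cohort))
#' @export
makePhantomCohort <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    n <- spec@nPatients
    pid <- sprintf("p%03d", seq_len(n))
    cls <- sample(rep(c("good", "poor"), length.out = n))
    probsK <- .effectProbs(spec@effectSizes[["kps_ge90"]])
    probsE <- .effectProbs(spec@effectSizes[["extracranial_mets"]])
    probsP <- .effectProbs(spec@effectSizes[["primary_controlled"]])
    kps <- stats::rbinom(n, 1, probsK[cls])
    # extracranial metastases are adverse: more frequent in the poor class
    ecm <- stats::rbinom(n, 1, 1 - probsE[cls])
    prim <- stats::rbinom(n, 1, probsP[cls])

    # lesion counts: monotone class bias over the configured range
    rng <- spec@lesionsPerPatient
    counts <- rng[1]:rng[2]
    dN <- spec@effectSizes[["n_lesions"]]
    nLes <- vapply(cls, function(cl) {
      if (length(counts) == 1L) return(counts)
      z <- scale(counts)[, 1]
      w <- exp(if (cl == "good") -dN * z else dN * z)
      sample(counts, 1L, prob = w / sum(w))
    }, integer(1))

    # survival: truncated log-normals, flip by drawing from the other class
    tcut <- sqrt(prod(spec@osMedians))
    sdlog <- 0.5
    drawOS <- function(cl) {
      m <- spec@osMedians[[cl]]
      F <- stats::plnorm(tcut, log(m), sdlog)
      u <- if (cl == "good") stats::runif(1, F, 1) else stats::runif(1, 0, F)
      stats::qlnorm(u, log(m), sdlog)
    }
    osCls <- ifelse(stats::runif(n) < spec@flipRate,
                    ifelse(cls == "good", "poor", "good"), cls)
    os <- vapply(osCls, drawOS, numeric(1))

    voxVol <- prod(spec@spacing)
    volumes <- list(); masks <- list(); rows <- list()
    for (p in seq_len(n)) {
      occupied <- array(FALSE, spec@gridShape)
      pmasks <- list()
      for (l in seq_len(nLes[p])) {
        r <- stats::runif(1, spec@lesionRadius[1], spec@lesionRadius[2])
        m <- .placeLesion(spec@gridShape, spec@spacing, r, occupied)
        if (is.null(m))
          stop("lesion placement failed for patient ", pid[p],
               " after bounded retries")
        occupied <- occupied | m
        lid <- sprintf("%s_l%02d", pid[p], l)
        pmasks[[lid]] <- m
      }
      # volumes: one heterogeneity field and noise field per contrast
      amp <- spec@heterogeneityByClass[[cls[p]]]
      vols <- list()
      for (ct in VALID_CONTRASTS) {
        cm <- spec@contrastMeans[[ct]]
        noise <- array(stats::rnorm(prod(spec@gridShape), 0, spec@noiseSD),
                       spec@gridShape)
        field <- gaussianSmooth3D(
          array(stats::rnorm(prod(spec@gridShape)), spec@gridShape), 2)
        field <- field / stats::sd(field)
        img <- cm$background + noise
        ampAbs <- amp * abs(cm$lesion - cm$background)
        img[occupied] <- cm$lesion + ampAbs * field[occupied] +
          noise[occupied]
        vols[[ct]] <- imageVolume(img, spacing = spec@spacing, contrast = ct)
      }
      volumes[[pid[p]]] <- vols
      for (lid in names(pmasks)) {
        masks[[lid]] <- imageVolume(array(as.numeric(pmasks[[lid]]),
                                          spec@gridShape),
                                    spacing = spec@spacing, contrast = "mask")
        vb <- sum(pmasks[[lid]]) * voxVol
        lcls <- if (stats::runif(1) < spec@flipRate)
          setdiff(c("good", "poor"), cls[p]) else cls[p]
        delta <- if (lcls == "good") stats::runif(1, -0.5, 0.05)
                 else stats::runif(1, 0.15, 0.9)
        rows[[lid]] <- data.frame(
          patient_id = pid[p], lesion_id = lid,
          kps_ge90 = kps[p], extracranial_mets = ecm[p],
          primary_controlled = prim[p], n_lesions = nLes[p],
          os_months = os[p], vol_baseline_mm3 = vb,
          vol_followup_mm3 = vb * (1 + delta),
          latent_control = cls[p], latent_survival = cls[p],
          stringsAsFactors = FALSE)
      }
    }
    clinical <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    new("SyntheticCohort", volumes = volumes, masks = masks,
        clinical = clinical, spec = spec)
  })
}

#' Write a cohort to disk as NIfTI volumes plus CSV and JSON manifest
#'
#' Writes one \code{.nii.gz} per patient and contrast, one \code{.nii.gz}
#' per lesion mask, a clinical CSV (columns \code{patient_id, lesion_id,
#' kps_ge90, extracranial_mets, primary_controlled, n_lesions, os_months,
#' vol_baseline_mm3, vol_followup_mm3}) and a JSON manifest listing every
#' file with patient/lesion ids plus the generator metadata. Volumes are
#' stored as float32; [readCohort()] round-trips the cohort within float32
#' precision.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return Path to the manifest JSON, invisibly.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create directory ", dir)
  writeVol <- function(vol, path) {
    im <- RNifti::asNifti(vol@data)
    RNifti::pixdim(im) <- vol@spacing
    RNifti::writeNifti(im, path, datatype = "float")
  }
  volFiles <- list()
  for (p in names(cohort@volumes)) {
    volFiles[[p]] <- list()
    for (ct in names(cohort@volumes[[p]])) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", p, ct))
      writeVol(cohort@volumes[[p]][[ct]], f)
      volFiles[[p]][[ct]] <- basename(f)
    }
  }
  maskFiles <- list()
  for (l in names(cohort@masks)) {
    f <- file.path(dir, sprintf("%s_mask.nii.gz", l))
    writeVol(cohort@masks[[l]], f)
    maskFiles[[l]] <- basename(f)
  }
  csvCols <- c("patient_id", "lesion_id", "kps_ge90", "extracranial_mets",
               "primary_controlled", "n_lesions", "os_months",
               "vol_baseline_mm3", "vol_followup_mm3")
  clin <- cohort@clinical
  if (nrow(clin) == 0) clin <- clin[, intersect(csvCols, names(clin)),
                                    drop = FALSE]
  else clin <- clin[, csvCols, drop = FALSE]
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  sp <- cohort@spec
  manifest <- list(
    n_patients = length(cohort@volumes),
    n_lesions = length(cohort@masks),
    grid_shape = sp@gridShape, spacing_mm = sp@spacing,
    clinical_csv = "clinical.csv",
    volumes = volFiles, masks = maskFiles,
    latent = if (nrow(cohort@clinical))
      cohort@clinical[, c("lesion_id", "patient_id", "latent_control",
                          "latent_survival")] else list(),
    spec = list(gridShape = sp@gridShape, spacing = sp@spacing,
                nPatients = sp@nPatients,
                lesionsPerPatient = sp@lesionsPerPatient,
                lesionRadius = sp@lesionRadius,
                heterogeneityByClass = as.list(sp@heterogeneityByClass),
                contrastMeans = sp@contrastMeans, noiseSD = sp@noiseSD,
                effectSizes = as.list(sp@effectSizes),
                flipRate = sp@flipRate, osMedians = as.list(sp@osMedians),
                seed = sp@seed))
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifestPath)
}

#' Read a cohort written by writeCohort
#'
#' @param manifestPath path to a \code{manifest.json} written by
#'   [writeCohort()].
#' @return A [SyntheticCohort-class].
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath)) stop("no manifest at ", manifestPath)
  dir <- dirname(manifestPath)
  mf <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  sp <- mf$spec
  spec <- phantomSpec(gridShape = sp$gridShape, spacing = sp$spacing,
                      nPatients = sp$nPatients,
                      lesionsPerPatient = sp$lesionsPerPatient,
                      lesionRadius = sp$lesionRadius,
                      heterogeneityByClass = unlist(sp$heterogeneityByClass),
                      contrastMeans = sp$contrastMeans,
                      noiseSD = sp$noiseSD,
                      effectSizes = unlist(sp$effectSizes),
                      flipRate = sp$flipRate,
                      osMedians = unlist(sp$osMedians), seed = sp$seed)
  readVol <- function(file, contrast) {
    im <- RNifti::readNifti(file.path(dir, file))
    imageVolume(array(as.numeric(im), dim(im)),
                spacing = RNifti::pixdim(im)[1:3], contrast = contrast)
  }
  volumes <- list()
  for (p in names(mf$volumes))
    volumes[[p]] <- mapply(readVol, mf$volumes[[p]], names(mf$volumes[[p]]),
                           SIMPLIFY = FALSE)
  masks <- list()
  for (l in names(mf$masks)) masks[[l]] <- readVol(mf$masks[[l]], "mask")
  clin <- utils::read.csv(file.path(dir, mf$clinical_csv),
                          stringsAsFactors = FALSE)
  if (nrow(clin) && length(mf$latent))
    clin <- merge(clin, mf$latent[, c("lesion_id", "latent_control",
                                      "latent_survival")],
                  by = "lesion_id", sort = FALSE)
  # restore generator column order
  if (nrow(clin)) {
    ord <- c("patient_id", "lesion_id", "kps_ge90", "extracranial_mets",
             "primary_controlled", "n_lesions", "os_months",
             "vol_baseline_mm3", "vol_followup_mm3", "latent_control",
             "latent_survival")
    clin <- clin[order(clin$lesion_id), intersect(ord, names(clin))]
    rownames(clin) <- NULL
  }
  new("SyntheticCohort", volumes = volumes, masks = masks, clinical = clin,
      spec = spec)
}
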