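# End-to-end orchestration: simulate -> preprocess -> extract -> label ->
# select/balance/train -> evaluate -> compare, under one master seed.

#' Default pipeline configuration
#'
#' One list holding every stage parameter plus the master seed, from which
#' all stage seeds are derived deterministically. Any entry can be
#' overridden via \code{...}.
#'
#' @param ... named overrides of the defaults.
#' @return A named list (see the vignette for the meaning and units of each
#'   entry).
#' @examples
#' cfg <- defaultRunConfig(nPatients = 8, seed = 42)
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    nPatients = 20L,
    gridShape = c(32L, 32L, 32L),
    spacing = 1,
    lesionsPerPatient = c(1L, 3L),
    lesionRadius = c(3, 6),
    heterogeneityByClass = c(good = 0.15, poor = 0.45),
    effectSizes = c(kps_ge90 = 0.8, extracranial_mets = 0.8,
                    primary_controlled = 0.5, n_lesions = 0.5),
    flipRate = 0.05,
    osMedians = c(good = 24, poor = 8),
    nLevels = 32L,
    trainFraction = 0.7,
    nCandidates = 25L,
    alphaSelect = 0.05,
    searchIterations = 15L,
    bootstrapB = 100L,
    alpha = 0.05,
    tasks = c("local_control", "survival"),
    views = c("clinical", "radiomics", "combined"),
    register = FALSE,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# Train and evaluate one view on one labeled table; returns scores, model,
# and the selection record.
.runView <- function(table, view, split, cfg, seedBase) {
  dat <- table@data
  y <- dat$outcome
  train <- split$train; test <- split$test
  candidates <- NULL; selected <- NULL
  if (view == "clinical") {
    predictors <- table@clinicalCols
  } else {
    xTrain <- as.matrix(dat[train, table@featureCols, drop = FALSE])
    candidates <- ttestRank(xTrain, y[train], k = cfg$nCandidates,
                            alpha = cfg$alphaSelect)
    candNames <- candidates$feature
    if (length(candNames) == 0) {
      # no feature is nominally significant; keep the single best-ranked one
      pAll <- ttestRank(xTrain, y[train], k = 1L, alpha = 1)
      candNames <- pAll$feature
    }
    predictors <- if (view == "radiomics") candNames
                  else c(table@clinicalCols, candNames)
  }
  balIdx <- train[nearMiss2(dat[train, predictors, drop = FALSE], y[train])]
  if (view != "clinical") {
    xb <- dat[balIdx, , drop = FALSE]
    ctrS <- colMeans(as.matrix(xb[, candNames, drop = FALSE]))
    sclS <- apply(as.matrix(xb[, candNames, drop = FALSE]), 2, stats::sd)
    sclS[sclS == 0] <- 1
    xs <- scale(as.matrix(xb[, candNames, drop = FALSE]), ctrS, sclS)
    sfs <- sfsSelect(xs, y[balIdx], candNames,
                     seed = deriveSeed(seedBase, "select"))
    selected <- sfs$selected
    if (length(selected) == 0) selected <- candNames[1]
    predictors <- if (view == "radiomics") selected
                  else c(table@clinicalCols, selected)
  }
  model <- trainSVM(as.matrix(dat[balIdx, predictors, drop = FALSE]),
                    y[balIdx], searchIterations = cfg$searchIterations,
                    seed = deriveSeed(seedBase, "train"))
  scores <- predictScores(model, dat[test, predictors, drop = FALSE])
  list(view = view, model = model, predictors = predictors,
       candidates = candidates, selected = selected, scores = scores)
}

# Table-2-style report of the selected features: registry columns plus
# per-class mean +/- SD of the standardized training values.
.selectedFeatureReport <- function(table, split, selected) {
  if (is.null(selected) || length(selected) == 0) return(NULL)
  reg <- featureRegistry()
  dat <- table@data[split$train, , drop = FALSE]
  do.call(rbind, lapply(selected, function(f) {
    v <- dat[[f]]
    z <- (v - mean(v)) / ifelse(stats::sd(v) > 0, stats::sd(v), 1)
    r <- reg[reg$name == f, , drop = FALSE]
    data.frame(contrast = r$contrast, filter = r$filter, family = r$family,
               feature = r$feature,
               good_mean = mean(z[dat$outcome == "good"]),
               good_sd = stats::sd(z[dat$outcome == "good"]),
               poor_mean = mean(z[dat$outcome == "poor"]),
               poor_sd = stats::sd(z[dat$outcome == "poor"]),
               stringsAsFactors = FALSE)
  }))
}

#' Run the full pipeline
#'
#' Generates a phantom cohort, preprocesses it (Z-score normalization;
#' rigid registration of T1w/T2w to T1c when \code{config$register} is
#' TRUE), extracts the 1763-entry feature table, labels both outcomes,
#' splits 70/30, applies two-step feature selection and NearMiss-2
#' balancing, trains the Bayesian-optimized RBF SVM for each view
#' (clinical / radiomics / combined), evaluates on the held-out test set and
#' compares the views by paired bootstrap. All artifacts (cohort, feature
#' table, selected-feature reports, summary JSON with MD5 content hashes)
#' are written under \code{outDir}; deterministic stages reproduce their
#' hashes on rerun with the same config.
#'
#' @param config list from [defaultRunConfig()].
#' @param outDir output directory for the run artifacts.
#' @return Invisibly, a list with the per-task [EvalReport-class]s
#'   (\code{reports}), per-task per-view results, the feature matrix and the
#'   summary list.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile()) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- config$seed
  spec <- phantomSpec(gridShape = config$gridShape, spacing = config$spacing,
                      nPatients = config$nPatients,
                      lesionsPerPatient = config$lesionsPerPatient,
                      lesionRadius = config$lesionRadius,
                      heterogeneityByClass = config$heterogeneityByClass,
                      effectSizes = config$effectSizes,
                      flipRate = config$flipRate,
                      osMedians = config$osMedians,
                      seed = deriveSeed(seed, "simulate"))
  message("stage simulate: ", config$nPatients, " patients")
  cohort <- makePhantomCohort(spec)
  writeCohort(cohort, file.path(outDir, "cohort"))
  if (isTRUE(config$register)) {
    message("stage preprocess: rigid registration to T1c")
    for (p in names(cohort@volumes)) {
      fx <- cohort@volumes[[p]]$T1c
      for (ct in c("T1w", "T2w")) {
        fit <- rigidRegister(cohort@volumes[[p]][[ct]], fx)
        cohort@volumes[[p]][[ct]] <- fit$registered
      }
    }
  }
  message("stage extract: ", length(cohort@masks), " lesions x 1763 features")
  features <- extractCohortFeatures(cohort, nLevels = config$nLevels)
  featPath <- file.path(outDir, "features.csv")
  utils::write.csv(data.frame(lesion_id = rownames(features), features,
                              check.names = FALSE),
                   featPath, row.names = FALSE)
  results <- list(); reports <- list(); summary <- list()
  for (task in config$tasks) {
    message("stage model: task ", task)
    table <- assembleTable(features, cohort@clinical, task)
    split <- holdoutSplit(table, config$trainFraction,
                          seed = deriveSeed(seed, paste0("split_", task)))
    yTest <- table@data$outcome[split$test]
    viewRes <- lapply(config$views, function(v)
      .runView(table, v, split, config,
               seedBase = deriveSeed(seed, paste0(task, "_", v))))
    names(viewRes) <- config$views
    scores <- lapply(viewRes, `[[`, "scores")
    report <- bootstrapCompare(scores, yTest, B = config$bootstrapB,
                               alpha = config$alpha,
                               seed = deriveSeed(seed, "bootstrap"))
    for (v in config$views) {
      rep2 <- .selectedFeatureReport(table, split, viewRes[[v]]$selected)
      if (!is.null(rep2))
        utils::write.csv(rep2, file.path(outDir,
          sprintf("selected_features_%s_%s.csv", task, v)), row.names = FALSE)
    }
    results[[task]] <- viewRes
    reports[[task]] <- report
    summary[[task]] <- list(
      n_rows = nrow(table@data),
      metrics = as.data.frame(evalMetrics(report)),
      selected = lapply(viewRes, `[[`, "selected"),
      comparisons = evalComparisons(report))
  }
  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  hashes <- tools::md5sum(files)
  names(hashes) <- substring(names(hashes), nchar(outDir) + 2)
  out <- list(config = config, summary = summary, hashes = as.list(hashes))
  jsonlite::write_json(out, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(list(reports = reports, results = results, features = features,
                 cohort = cohort, summary = summary, dir = outDir))
}
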