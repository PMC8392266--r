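# Hold-out split, t-test ranking, NearMiss-2, SFS, SVM training, metrics
# and paired bootstrap comparison.

makeToyTable <- function(n = 100, pFeat = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * pFeat), n,
              dimnames = list(NULL, sprintf("T1w.none.histogram.f%02d",
                                            seq_len(pFeat))))
  dat <- data.frame(patient_id = sprintf("p%03d", seq_len(n)),
                    lesion_id = sprintf("p%03d_l01", seq_len(n)),
                    kps_ge90 = rbinom(n, 1, 0.5),
                    extracranial_mets = rbinom(n, 1, 0.5),
                    primary_controlled = rbinom(n, 1, 0.5),
                    n_lesions = sample(1:3, n, TRUE),
                    log_volume_mm3 = rnorm(n, 5),
                    outcome = factor(rep(c("good", "poor"), length.out = n),
                                     levels = c("good", "poor")))
  dat <- cbind(dat, as.data.frame(x))
  new("CohortTable", data = dat, task = "survival", unit = "patient",
      clinicalCols = GKRadiomics:::CLINICAL_COLS, featureCols = colnames(x))
}

test_that("rank AUC matches the closed cases and pROC on random scores", {
  expect_equal(aucRank(c(0.9, 0.8, 0.2, 0.1), c("poor", "poor", "good", "good")), 1)
  expect_equal(aucRank(c(0.1, 0.2, 0.8, 0.9), c("poor", "poor", "good", "good")), 0)
  expect_equal(aucRank(rep(0.5, 6), rep(c("good", "poor"), 3)), 0.5)
  expect_error(aucRank(1:3, rep("poor", 3)), "single class")
  set.seed(2)
  s <- rnorm(40); y <- sample(c("good", "poor"), 40, TRUE)
  expect_equal(aucRank(s, y),
               as.numeric(suppressMessages(pROC::auc(pROC::roc(
                 response = y, predictor = s, levels = c("good", "poor"),
                 direction = "<")))))
})

test_that("patient-wise hold-out gives stratified 70/30 and is seed-stable", {
  tab <- makeToyTable(100)
  sp <- holdoutSplit(tab, 0.7, seed = 5)
  expect_length(sp$train, 70L)
  expect_length(sp$test, 30L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  y <- cohortData(tab)$outcome
  expect_equal(as.vector(table(y[sp$train])), c(35, 35))
  sp2 <- holdoutSplit(tab, 0.7, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, holdoutSplit(tab, 0.7, seed = 6)))
})

test_that("lesion-wise splits keep all lesions of a patient on one side", {
  tab <- makeToyTable(60)
  dat <- cohortData(tab)
  dat$patient_id <- rep(sprintf("q%02d", 1:6), each = 10)  # 10 lesions each
  dat$lesion_id <- sprintf("%s_l%02d", dat$patient_id, rep(1:10, 6))
  tabL <- new("CohortTable", data = dat, task = "local_control",
              unit = "lesion", clinicalCols = tab@clinicalCols,
              featureCols = tab@featureCols)
  sp <- holdoutSplit(tabL, 0.7, seed = 3)
  sides <- tapply(seq_len(60) %in% sp$train, dat$patient_id,
                  function(v) length(unique(v)))
  expect_true(all(sides == 1))
})

test_that("t-test ranking recovers planted shifts and caps at k", {
  set.seed(11)
  n <- 300; pFeat <- 200
  x <- matrix(rnorm(n * pFeat), n,
              dimnames = list(NULL, sprintf("f%03d", 1:pFeat)))
  y <- factor(rep(c("good", "poor"), each = n / 2),
              levels = c("good", "poor"))
  planted <- sample(pFeat, 60)
  x[y == "poor", planted] <- x[y == "poor", planted] + 1.0
  out <- ttestRank(x, y, k = 25, alpha = 0.05)
  expect_equal(nrow(out), 25L)
  expect_true(all(out$p < 0.05))
  expect_true(all(diff(out$p) >= 0))
  expect_true(all(out$feature %in% colnames(x)[planted]))
})

test_that("under the null the candidate count is binomial-sized, never above k", {
  set.seed(21)
  x <- matrix(rnorm(40 * 200), 40,
              dimnames = list(NULL, sprintf("f%03d", 1:200)))
  y <- factor(rep(c("good", "poor"), each = 20), levels = c("good", "poor"))
  out <- ttestRank(x, y, k = 25, alpha = 0.05)
  expect_true(all(out$p < 0.05))
  # expected 200 * 0.05 = 10 passes; stay within a generous binomial band
  expect_gte(nrow(out), 2L)
  expect_lte(nrow(out), 22L)
})

test_that("constant features are never selected", {
  set.seed(31)
  x <- cbind(const = rep(1, 40), sig = c(rnorm(20), rnorm(20, 3)),
             noise = rnorm(40))
  y <- factor(rep(c("good", "poor"), each = 20), levels = c("good", "poor"))
  out <- ttestRank(x, y, k = 3)
  expect_false("const" %in% out$feature)
  expect_true("sig" %in% out$feature)
})

test_that("NearMiss-2 matches the brute-force 1-D toy and equalizes counts", {
  x <- matrix(c(0, 1, 0.4, 0.5, 5, 9), ncol = 1)
  y <- factor(c("poor", "poor", "good", "good", "good", "good"),
              levels = c("good", "poor"))
  keep <- nearMiss2(x, y, k = 2)
  expect_setequal(keep, c(1, 2, 3, 4))   # minority + the two close majority
  # brute force: average distance to the 2 farthest minority points
  xs <- scale(x)
  avg <- sapply(3:6, function(i)
    mean(sort(abs(xs[1:2] - xs[i]), decreasing = TRUE)[1:2]))
  expect_equal(sort(avg[1:2]), sort(avg[order(avg)][1:2]))
  # balanced input returned unchanged
  xb <- matrix(rnorm(8), ncol = 2)
  yb <- factor(rep(c("good", "poor"), 2), levels = c("good", "poor"))
  expect_identical(nearMiss2(xb, yb), 1:4)
})

test_that("NearMiss-2 output is a balanced subset of the input", {
  set.seed(41)
  x <- matrix(rnorm(60 * 4), 60)
  y <- factor(rep(c("good", "poor"), c(45, 15)), levels = c("good", "poor"))
  keep <- nearMiss2(x, y, k = 3)
  expect_true(all(keep %in% 1:60))
  expect_equal(as.vector(table(y[keep])), c(15, 15))
  expect_true(all(which(y == "poor") %in% keep))  # minority untouched
})

test_that("SFS picks planted features before noise and accepts a lone winner", {
  set.seed(51)
  n <- 120
  y <- factor(rep(c("good", "poor"), each = n / 2), levels = c("good", "poor"))
  x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  x[y == "poor", "f1"] <- x[y == "poor", "f1"] + 2
  x[y == "poor", "f2"] <- x[y == "poor", "f2"] + 2
  xs <- scale(x)
  sel <- sfsSelect(xs, y, paste0("f", 1:8), seed = 7)
  expect_true(all(c("f1", "f2") %in% sel$selected[1:2]))
  expect_true(all(diff(sel$trace) > 0))
  solo <- sfsSelect(xs, y, "f1", seed = 7)
  expect_identical(solo$selected, "f1")
})

test_that("SFS under the null stays bounded and near chance criterion", {
  res <- lapply(1:8, function(s) {
    set.seed(100 + s)
    n <- 150
    y <- factor(rep(c("good", "poor"), each = n / 2),
                levels = c("good", "poor"))
    x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
    sfsSelect(scale(x), y, paste0("f", 1:10), seed = s)
  })
  counts <- lengths(lapply(res, `[[`, "selected"))
  finals <- vapply(res, function(r) if (length(r$trace)) max(r$trace) else 0.5,
                   numeric(1))
  # greedy CV maximization accrues some optimism under the null, but the
  # selection never absorbs most candidates and the criterion stays well
  # below genuinely informative levels
  expect_true(all(counts <= 5))
  expect_true(all(finals < 0.75))
  expect_gt(mean(counts <= 2), 0.4)
})

test_that("the Bayesian-optimized SVM separates planted blobs and is deterministic", {
  set.seed(61)
  n <- 200
  y <- factor(rep(c("good", "poor"), each = n / 2), levels = c("good", "poor"))
  x <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b")))
  x[y == "poor", ] <- x[y == "poor", ] + 6
  m1 <- trainSVM(x, y, searchIterations = 10, seed = 3)
  expect_gte(aucRank(predictScores(m1, x), y), 0.99)
  expect_gte(m1$cvAUC, 0.99)
  m2 <- trainSVM(x, y, searchIterations = 10, seed = 3)
  expect_identical(c(m1$cost, m1$gamma), c(m2$cost, m2$gamma))
  expect_true(m1$cost >= 1e-3 && m1$cost <= 1e3)
  expect_true(m1$gamma >= 1e-4 && m1$gamma <= 10)
})

test_that("permuted labels give chance-level CV AUC across seeds", {
  aucs <- sapply(1:12, function(s) {
    set.seed(200 + s)
    n <- 160
    x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(sample(rep(c("good", "poor"), each = n / 2)),
                levels = c("good", "poor"))
    trainSVM(x, y, searchIterations = 6, seed = s)$cvAUC
  })
  expect_true(all(aucs > 0.35 & aucs < 0.65))
})

test_that("test-set metrics follow the score threshold and positive class", {
  scores <- c(2, 1, -1, -2)
  y <- factor(c("poor", "poor", "good", "good"), levels = c("good", "poor"))
  m <- metricsFromScores(scores, y)
  expect_equal(unname(m), c(1, 1, 1, 1))
  # one false negative at threshold 0
  m2 <- metricsFromScores(c(2, -1, -1, -2), y)
  expect_equal(m2[["sensitivity"]], 0.5)
  expect_equal(m2[["specificity"]], 1)
  expect_equal(m2[["accuracy"]], 0.75)
})

test_that("paired bootstrap of identical models is never significant", {
  set.seed(71)
  y <- factor(rep(c("good", "poor"), 15), levels = c("good", "poor"))
  s <- rnorm(30) + (y == "poor")
  rep <- bootstrapCompare(list(a = s, b = s, c = s), y, B = 100, seed = 9)
  expect_s4_class(rep, "EvalReport")
  expect_equal(dim(bootDistributions(rep)), c(100L, 4L, 3L))
  comp <- evalComparisons(rep)
  expect_equal(nrow(comp), 12L)  # 3 pairs x 4 metrics
  expect_true(all(comp$p_value == 1))
  expect_false(any(comp$significant))
  # pairing: identical scores give identical bootstrap distributions
  expect_identical(bootDistributions(rep)[, , "a"],
                   bootDistributions(rep)[, , "b"])
  # every resample keeps both classes
  expect_true(all(apply(rep@indices, 1,
                        function(ix) length(unique(y[ix])) == 2)))
})

test_that("bootstrap comparison detects a genuinely dominant model", {
  set.seed(81)
  n <- 60
  y <- factor(rep(c("good", "poor"), n / 2), levels = c("good", "poor"))
  strong <- rnorm(n, 0, 0.3) + ifelse(y == "poor", 2, -2)
  weak <- rnorm(n)
  rep <- bootstrapCompare(list(strong = strong, weak = weak), y,
                          B = 100, seed = 10)
  comp <- evalComparisons(rep)
  aucRow <- comp[comp$metric == "auc", ]
  expect_true(aucRow$significant)
  expect_gt(aucRow$mean_diff, 0)
})
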