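# Modeling: hold-out split, two-step feature selection, NearMiss-2
# balancing, RBF-SVM with Bayesian hyperparameter search, evaluation and
# paired bootstrap model comparison. The positive class throughout is
# "poor" (poor tumor control / poor survival).

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic of
#' the decision scores; tied scores contribute 1/2, so an all-tied score
#' vector gives 0.5.
#'
#' @param scores numeric decision scores (higher = more likely positive).
#' @param labels factor or character with levels \code{good}, \code{poor}.
#' @param positive the positive class (default \code{"poor"}).
#' @return AUC in \code{[0, 1]}.
#' @examples
#' aucRank(c(0.9, 0.8, 0.2, 0.1), c("poor", "poor", "good", "good"))  # 1
#' @export
aucRank <- function(scores, labels, positive = "poor") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: test set has a single class")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified (and patient-grouped) 70/30 hold-out split
#'
#' Splits a [CohortTable-class] into disjoint, exhaustive train and test
#' row sets, stratified by outcome class. For lesion-wise tables the split
#' is grouped at the patient level, so all lesions of a patient fall on one
#' side (no within-patient leakage); grouping takes precedence over the
#' exact train fraction when they conflict.
#'
#' @param table a [CohortTable-class] with at least 2 rows per class.
#' @param trainFraction fraction of samples assigned to training (0.7).
#' @param seed integer seed; identical seeds give identical partitions.
#' @return list with integer row indices \code{train} and \code{test}.
#' @export
holdoutSplit <- function(table, trainFraction = 0.7, seed = 1L) {
  stopifnot(is(table, "CohortTable"), trainFraction > 0, trainFraction < 1)
  y <- table@data$outcome
  if (any(table(y) < 2)) stop("need at least 2 rows per class to split")
  withSeed(seed, {
    if (table@unit == "lesion") {
      pid <- table@data$patient_id
      # patient stratum = majority label of the patient's lesions
      pstr <- vapply(split(as.character(y), pid), function(v)
        names(sort(table(v), decreasing = TRUE))[1], character(1))
      trainPat <- unlist(lapply(split(names(pstr), pstr), function(ps) {
        k <- round(trainFraction * length(ps))
        k <- min(max(k, 1L), length(ps) - 1L)
        sample(ps, k)
      }))
      trainIdx <- which(pid %in% trainPat)
    } else {
      trainIdx <- unlist(lapply(split(seq_along(y), y), function(ix) {
        k <- round(trainFraction * length(ix))
        k <- min(max(k, 1L), length(ix) - 1L)
        sample(ix, k)
      }))
    }
    trainIdx <- sort(trainIdx)
    list(train = trainIdx, test = setdiff(seq_along(y), trainIdx))
  })
}

#' Welch t-test feature ranking (selection step 1)
#'
#' Per radiomic feature, a Welch two-sample t-test between outcome classes;
#' features with p below \code{alpha} are kept and the \code{k} smallest-p
#' features returned (fewer if fewer pass). Features with zero variance in
#' both groups get p = 1 and are never selected. Fully deterministic.
#'
#' @param x numeric matrix (rows = training samples, columns = features).
#' @param y outcome factor (\code{good}/\code{poor}), both classes present.
#' @param k maximum number of candidates (default 25).
#' @param alpha significance cut-off (default 0.05).
#' @return data.frame with columns \code{feature}, \code{p}, sorted by
#'   ascending p, at most \code{k} rows.
#' @export
ttestRank <- function(x, y, k = 25L, alpha = 0.05) {
  x <- as.matrix(x)
  g <- y == "good"
  if (!any(g) || all(g)) stop("both classes must be present")
  n1 <- sum(g); n2 <- sum(!g)
  m1 <- colMeans(x[g, , drop = FALSE]); m2 <- colMeans(x[!g, , drop = FALSE])
  v1 <- apply(x[g, , drop = FALSE], 2, stats::var)
  v2 <- apply(x[!g, , drop = FALSE], 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(p)] <- 1          # zero variance in both groups etc.
  p[v1 + v2 == 0] <- 1
  keep <- which(p < alpha)
  keep <- keep[order(p[keep], colnames(x)[keep])]
  keep <- utils::head(keep, k)
  data.frame(feature = colnames(x)[keep], p = p[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' NearMiss-2 undersampling
#'
#' Balances a binary training set by keeping only those majority-class
#' samples whose average Euclidean distance (on per-feature standardized
#' values) to their \code{k} farthest minority-class samples is smallest,
#' until class counts are equal. Minority samples are never touched. If the
#' nominal minority class is not smaller, the input is returned unchanged
#' with a warning.
#'
#' @param x numeric matrix or data.frame of predictors.
#' @param y outcome factor (\code{good}/\code{poor}).
#' @param k number of farthest minority neighbours to average (default 3).
#' @return Integer vector of retained row indices (sorted).
#' @export
nearMiss2 <- function(x, y, k = 3L) {
  x <- as.matrix(x)
  tab <- table(y)
  if (length(tab) < 2 || any(tab == 0)) stop("both classes must be present")
  minCl <- names(tab)[which.min(tab)]
  majCl <- names(tab)[which.max(tab)]
  if (tab[minCl] == tab[majCl]) return(seq_along(y))
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  minIdx <- which(y == minCl); majIdx <- which(y == majCl)
  kk <- min(k, length(minIdx))
  avgFar <- vapply(majIdx, function(i) {
    d2 <- colSums((t(xs[minIdx, , drop = FALSE]) - xs[i, ])^2)
    mean(sqrt(sort(d2, decreasing = TRUE)[seq_len(kk)]))
  }, numeric(1))
  keepMaj <- majIdx[order(avgFar, majIdx)][seq_len(tab[minCl])]
  sort(c(minIdx, keepMaj))
}

# Stratified k-fold assignment; error if any fold would lack a class.
stratifiedFolds <- function(y, k = 5L, seed = 1L) {
  if (min(table(y)) < k)
    k <- max(2L, min(table(y)))
  folds <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(factor(y))) {
      ix <- which(y == cl)
      folds[ix] <- sample(rep(seq_len(k), length.out = length(ix)))
    }
  })
  folds
}

# Decision score oriented toward the positive ("poor") class.
.svmScores <- function(fit, x) {
  pr <- stats::predict(fit, as.matrix(x), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1]
  if (grepl("^poor", colnames(dv)[1])) s else -s
}

# Pooled k-fold CV AUC of an RBF SVM at fixed hyperparameters on
# standardized predictors.
.cvAUC <- function(x, y, cost, gamma, folds) {
  scores <- numeric(length(y))
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1)
      stop("criterion undefined: single-class fold")
    fit <- e1071::svm(as.matrix(x[tr, , drop = FALSE]), y[tr],
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    scores[!tr] <- .svmScores(fit, x[!tr, , drop = FALSE])
  }
  aucRank(scores, y)
}

#' Sequential forward selection (selection step 2)
#'
#' Greedy wrapper selection over the t-test candidates: at each step the
#' feature whose addition maximizes the stratified 5-fold cross-validated
#' AUC of the RBF SVM on the training set is added; selection stops when no
#' addition improves the criterion by more than \code{tol}. The empty model
#' has criterion 0.5. Folds are fixed once per call, so criterion values are
#' comparable across steps.
#'
#' @param x numeric matrix of standardized training predictors (columns must
#'   include the candidates).
#' @param y outcome factor.
#' @param candidates character vector of candidate feature names (step-1
#'   output), in rank order.
#' @param tol minimum criterion improvement to continue (default 1e-4).
#' @param cost,gamma SVM hyperparameters used inside the wrapper (defaults:
#'   cost 1, gamma 1/number of active features).
#' @param seed fold seed.
#' @return list with \code{selected} (ordered names) and \code{trace}
#'   (criterion after each accepted addition).
#' @export
sfsSelect <- function(x, y, candidates, tol = 1e-4, cost = 1, gamma = NULL,
                      seed = 1L) {
  if (length(candidates) < 1) stop("need at least one candidate")
  x <- as.matrix(x)
  folds <- stratifiedFolds(y, 5L, seed)
  selected <- character(0)
  trace <- numeric(0)
  best <- 0.5
  remaining <- candidates
  while (length(remaining)) {
    crit <- vapply(remaining, function(f) {
      cols <- c(selected, f)
      g <- if (is.null(gamma)) 1 / length(cols) else gamma
      .cvAUC(x[, cols, drop = FALSE], y, cost, g, folds)
    }, numeric(1))
    i <- which.max(crit)
    if (crit[i] - best <= tol) break
    best <- crit[i]
    selected <- c(selected, remaining[i])
    trace <- c(trace, best)
    remaining <- remaining[-i]
  }
  list(selected = selected, trace = trace)
}

# Gaussian-process expected improvement over a [0,1]^d design.
# X: evaluated points (rows), yv: objective values (maximized).
.eiPropose <- function(X, yv, candidates, lengthscale = 0.25,
                       nugget = 1e-5) {
  ys <- stats::sd(yv)
  if (!is.finite(ys) || ys == 0) return(candidates[1, , drop = FALSE])
  yn <- (yv - mean(yv)) / ys
  sqd <- function(A, B)
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  K <- exp(-sqd(X, X) / (2 * lengthscale^2)) + diag(nugget, nrow(X))
  Ks <- exp(-sqd(candidates, X) / (2 * lengthscale^2))
  Kinv <- solve(K)
  mu <- as.vector(Ks %*% Kinv %*% yn)
  s2 <- pmax(1e-12, 1 - rowSums((Ks %*% Kinv) * Ks))
  s <- sqrt(s2)
  fbest <- max(yn)
  z <- (mu - fbest) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  candidates[which.max(ei), , drop = FALSE]
}

#' Train an RBF SVM with Bayesian hyperparameter optimization
#'
#' Standardizes the predictors with training statistics, then searches
#' log-uniform ranges of the SVM cost C and kernel width gamma by expected-
#' improvement Bayesian optimization (Latin-hypercube initial design,
#' Gaussian-process surrogate), maximizing the stratified 5-fold
#' cross-validated AUC. The final model is refit on the full training set at
#' the best point. Deterministic under a fixed seed.
#'
#' @param x training predictor matrix (raw scale).
#' @param y outcome factor with both classes.
#' @param searchIterations total number of hyperparameter evaluations
#'   (default 30; the first third forms the initial design).
#' @param costRange,gammaRange log10 search bounds (defaults C in
#'   [1e-3, 1e3], gamma in [1e-4, 1e1]).
#' @param seed RNG seed for the design and CV folds.
#' @return Object of class \code{gkSVM}: the fitted e1071 model plus
#'   scaling, feature names, chosen \code{cost}/\code{gamma} and the search
#'   \code{cvAUC}.
#' @seealso [predictScores()], [evaluateModel()]
#' @export
trainSVM <- function(x, y, searchIterations = 30L,
                     costRange = c(-3, 3), gammaRange = c(-4, 1),
                     seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("good", "poor"))
  if (length(unique(y)) < 2) stop("training data has a single class")
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  folds <- stratifiedFolds(y, 5L, seed)
  evalPoint <- function(u) {
    cost <- 10^(costRange[1] + u[1] * diff(costRange))
    gamma <- 10^(gammaRange[1] + u[2] * diff(gammaRange))
    .cvAUC(xs, y, cost, gamma, folds)
  }
  nInit <- max(4L, min(searchIterations, ceiling(searchIterations / 3)))
  withSeed(seed + 1L, {
    X <- lhs::randomLHS(nInit, 2)
    yv <- apply(X, 1, evalPoint)
    while (nrow(X) < searchIterations) {
      cand <- lhs::randomLHS(256, 2)
      u <- .eiPropose(X, yv, cand)
      X <- rbind(X, u)
      yv <- c(yv, evalPoint(u[1, ]))
    }
    ibest <- which.max(yv)
    cost <- 10^(costRange[1] + X[ibest, 1] * diff(costRange))
    gamma <- 10^(gammaRange[1] + X[ibest, 2] * diff(gammaRange))
    fit <- e1071::svm(xs, y, kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    structure(list(fit = fit, center = ctr, scale = scl,
                   features = colnames(x), cost = cost, gamma = gamma,
                   cvAUC = yv[ibest], searchTrace = yv, seed = seed),
              class = "gkSVM")
  })
}

#' @export
print.gkSVM <- function(x, ...) {
  cat(sprintf("RBF SVM: %d features, cost %.4g, gamma %.4g, CV AUC %.3f\n",
              length(x$features), x$cost, x$gamma, x$cvAUC))
  invisible(x)
}

#' Decision scores of a trained model
#'
#' @param model a \code{gkSVM} from [trainSVM()].
#' @param newdata matrix or data.frame containing the model's feature
#'   columns (raw scale; the training standardization is applied).
#' @return Numeric scores, positive = leaning \code{poor}.
#' @export
predictScores <- function(model, newdata) {
  stopifnot(inherits(model, "gkSVM"))
  x <- as.matrix(as.data.frame(newdata)[, model$features, drop = FALSE])
  xs <- scale(x, model$center, model$scale)
  .svmScores(model$fit, xs)
}

#' Test-set metrics of a trained model
#'
#' AUC by the rank statistic over decision scores; accuracy, sensitivity and
#' specificity at the default score threshold 0. Sensitivity is the recall
#' of the positive (\code{poor}) class.
#'
#' @param model a \code{gkSVM}.
#' @param newdata test predictors (raw scale).
#' @param y test outcome factor with both classes present.
#' @return Named numeric: \code{auc}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}.
#' @export
evaluateModel <- function(model, newdata, y) {
  s <- predictScores(model, newdata)
  metricsFromScores(s, y)
}

#' Metrics from raw decision scores
#'
#' @param scores decision scores (positive = \code{poor}).
#' @param y outcome factor/character.
#' @return Named numeric: \code{auc}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}.
#' @export
metricsFromScores <- function(scores, y) {
  pos <- y == "poor"
  pred <- scores > 0
  c(auc = aucRank(scores, y),
    accuracy = mean(pred == pos),
    sensitivity = if (any(pos)) mean(pred[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(!pred[!pos]) else NA_real_)
}

#' Paired bootstrap comparison of models on a shared test set
#'
#' Resamples the test set with replacement \code{B} times (resample size =
#' test size, indices shared across models so the comparison is paired),
#' recomputes AUC, accuracy, sensitivity and specificity per model and
#' resample, and compares every model pair per metric with a paired t-test
#' at the Bonferroni-corrected level \code{alpha /} number of pairs.
#' Resamples containing a single class are redrawn (bounded retries).
#'
#' @param scores named list of per-model decision-score vectors, all on the
#'   identical test rows.
#' @param y test outcome factor.
#' @param B number of bootstrap resamples (default 100).
#' @param alpha nominal significance level (default 0.05).
#' @param seed resampling seed.
#' @return An [EvalReport-class].
#' @export
bootstrapCompare <- function(scores, y, B = 100L, alpha = 0.05, seed = 1L) {
  stopifnot(is.list(scores), length(scores) >= 1, B >= 2)
  n <- length(y)
  lens <- vapply(scores, length, integer(1))
  if (any(lens != n)) stop("all models must be scored on the same test rows")
  models <- names(scores)
  metricNames <- c("auc", "accuracy", "sensitivity", "specificity")
  idx <- matrix(0L, B, n)
  withSeed(seed, {
    for (b in seq_len(B)) {
      for (try in seq_len(1000L)) {
        ix <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[ix])) == 2) break
        if (try == 1000L) stop("could not draw a two-class resample")
      }
      idx[b, ] <- ix
    }
  })
  boot <- array(NA_real_, c(B, length(metricNames), length(models)),
                dimnames = list(NULL, metricNames, models))
  for (m in models)
    for (b in seq_len(B))
      boot[b, , m] <- metricsFromScores(scores[[m]][idx[b, ]], y[idx[b, ]])
  metrics <- t(vapply(models, function(m) metricsFromScores(scores[[m]], y),
                      numeric(4)))
  colnames(metrics) <- metricNames
  pairs <- if (length(models) >= 2) utils::combn(models, 2) else
    matrix(character(0), 2, 0)
  nPairs <- max(1L, ncol(pairs))
  comp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(ip) {
    do.call(rbind, lapply(metricNames, function(met) {
      d <- boot[, met, pairs[1, ip]] - boot[, met, pairs[2, ip]]
      d <- d[is.finite(d)]
      p <- if (length(d) < 2 || stats::sd(d) == 0) 1
           else stats::t.test(d)$p.value
      data.frame(metric = met, model1 = pairs[1, ip], model2 = pairs[2, ip],
                 mean_diff = mean(d), p_value = p,
                 significant = p < alpha / nPairs,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(comp))
    comp <- data.frame(metric = character(), model1 = character(),
                       model2 = character(), mean_diff = numeric(),
                       p_value = numeric(), significant = logical())
  new("EvalReport", metrics = metrics, boot = boot, comparisons = comp,
      alpha = alpha, indices = idx)
}
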