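#' Stratified shuffle-split trials
#'
#' Draws independent stratified random train/test partitions (shuffle
#' split, not K-fold: test sets of different trials may overlap). Each
#' test set holds \code{testFraction} of the instances with class
#' proportions preserved.
#'
#' @param labels factor or character class labels.
#' @param nTrials number of independent trials.
#' @param testFraction fraction of instances held out per trial.
#' @param seed integer seed.
#' @return list of trial splits, each a list with integer \code{train}
#'   and \code{test} index vectors and a \code{trial} index (0-based).
#' @examples
#' sp <- splitTrials(rep(c("active", "inactive"), each = 100), seed = 3)
#' lengths(sp[[1]])
#' @export
splitTrials <- function(labels, nTrials = 10L, testFraction = 0.1, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 instances")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)")
  withSeed(seed, {
    lapply(seq_len(nTrials), function(t) {
      test <- integer(0)
      for (cl in names(counts)) {
        idx <- which(labels == cl)
        nTest <- max(1L, round(testFraction * length(idx)))
        if (nTest >= length(idx)) stop("testFraction leaves no training data for class ", cl)
        test <- c(test, sample(idx, nTest))
      }
      test <- sort(test)
      structure(list(train = setdiff(seq_along(labels), test), test = test,
                     trial = t - 1L), class = "TrialSplit")
    })
  })
}

#' Tanimoto kernel between binary fingerprint matrices
#'
#' K[i, j] = c / (a + b - c) with a, b the on-bit counts of the two rows
#' and c their shared on-bits. The similarity of two all-zero rows is
#' defined as 1 (self-similarity limit, keeps the matrix positive
#' semi-definite on degenerate inputs).
#'
#' @param X,Y 0/1 matrices with the same number of columns (Y defaults to X).
#' @return nrow(X) x nrow(Y) similarity matrix.
#' @examples
#' tanimotoKernel(rbind(c(1, 1, 0)), rbind(c(1, 0, 1)))  # 1/3
#' @export
tanimotoKernel <- function(X, Y = X) {
  assertBinaryMatrix(X, "X"); assertBinaryMatrix(Y, "Y")
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same feature count")
  shared <- tcrossprod(X, Y)
  denom <- outer(rowSums(X), rowSums(Y), "+") - shared
  K <- shared / denom
  K[denom == 0] <- 1
  K
}

## RBF kernel on binary rows: squared Euclidean distance is a + b - 2c.
rbfKernelBinary <- function(X, Y = X, gamma) {
  shared <- tcrossprod(X, Y)
  d2 <- outer(rowSums(X), rowSums(Y), "+") - 2 * shared
  exp(-gamma * d2)
}

#' Model specification with hyperparameter grid
#'
#' Default grids are the full production grids: random forests over
#' minimum leaf sizes 1/2/5/10, minimum split sizes 2/3/5/10 and
#' 25/50/100/200/400 trees; SVMs over C in 0.001, 0.005, 0.01, 0.05, 0.1,
#' 0.5, 1, 10, 100, 10000 (the RBF kernel additionally over gamma in
#' 0.0001 ... 100); the neural network over initial learning rates 0.01,
#' 0.001, 0.0001. Smaller grids can be supplied for quick runs.
#'
#' The default explanation target (\code{outputMode}) is the probability
#' of the active class for RFC and FFNN and the signed decision value for
#' the SVMs.
#'
#' @param method one of "RFC", "FFNN", "SVM_RBF", "SVM_TAN".
#' @param grid named list of hyperparameter value vectors; NULL for the
#'   full default grid.
#' @param outputMode "probability" or "decision"; NULL for the
#'   method-specific default.
#' @return a list of class \code{ModelSpec}.
#' @export
modelSpec <- function(method = c("RFC", "FFNN", "SVM_RBF", "SVM_TAN"),
                      grid = NULL, outputMode = NULL) {
  method <- match.arg(method)
  svmC <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 10, 100, 10000)
  defaults <- switch(method,
    RFC = list(minLeaf = c(1, 2, 5, 10), minSplit = c(2, 3, 5, 10),
               numTrees = c(25, 50, 100, 200, 400)),
    SVM_RBF = list(C = svmC, gamma = c(0.0001, 0.001, 0.01, 0.1, 1, 10, 100)),
    SVM_TAN = list(C = svmC),
    FFNN = list(learningRate = c(0.01, 0.001, 0.0001)))
  if (is.null(grid)) grid <- defaults
  if (!all(names(grid) %in% names(defaults)))
    stop("unknown grid entries for ", method, ": ",
         paste(setdiff(names(grid), names(defaults)), collapse = ", "))
  for (nm in setdiff(names(defaults), names(grid)))
    grid[[nm]] <- defaults[[nm]][1L]
  grid <- grid[names(defaults)]
  if (any(vapply(grid, function(g) any(!is.finite(g) | g <= 0), TRUE)))
    stop("grid values must be positive and finite")
  if (is.null(outputMode))
    outputMode <- if (method %in% c("SVM_RBF", "SVM_TAN")) "decision" else "probability"
  structure(list(method = method, grid = grid, outputMode = outputMode),
            class = "ModelSpec")
}

#' Train one classifier with fixed hyperparameters
#'
#' @param X 0/1 training matrix (compounds x features).
#' @param y labels ("active"/"inactive").
#' @param method model family.
#' @param hyper named list of hyperparameters (one value each); missing
#'   entries take the first default grid value.
#' @param seed integer seed for model randomness.
#' @param outputMode explanation target; NULL for the family default.
#' @param featureIds integer 0-based ids of the columns of X.
#' @return an \linkS4class{ActivityModel}.
#' @export
trainModel <- function(X, y, method, hyper = list(), seed = 1L,
                       outputMode = NULL, featureIds = seq_len(ncol(X)) - 1L) {
  assertBinaryMatrix(X, "X")
  colnames(X) <- sprintf("f%d", featureIds)
  y <- factor(as.character(y), levels = c("active", "inactive"))
  if (any(table(y) == 0L)) stop("training data must contain both classes")
  spec <- modelSpec(method, grid = lapply(hyper, function(v) v[1L]),
                    outputMode = outputMode)
  hyper <- lapply(spec$grid, function(v) v[1L])
  fitObj <- NULL; trainX <- matrix(0, 0, 0); signFlip <- 1

  if (method == "RFC") {
    fitObj <- ranger::ranger(x = X, y = y, probability = TRUE,
                             num.trees = hyper$numTrees,
                             min.bucket = hyper$minLeaf,
                             min.node.size = hyper$minSplit,
                             seed = as.integer(seed), num.threads = 1L)
  } else if (method == "FFNN") {
    fitObj <- mlpFit(X, as.integer(y == "active"),
                     learningRate = hyper$learningRate, seed = seed)
  } else {
    K <- if (method == "SVM_TAN") tanimotoKernel(X)
         else rbfKernelBinary(X, gamma = hyper$gamma)
    fitObj <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y,
                            type = "C-svc", C = hyper$C, kernel = "matrix")
    trainX <- X
  }
  model <- new("ActivityModel", method = method, fit = fitObj,
               hyper = hyper, trainX = trainX, signFlip = 1,
               outputMode = spec$outputMode, nFeatures = ncol(X),
               featureIds = as.integer(featureIds),
               info = list(seed = as.integer(seed)))
  if (method %in% c("SVM_RBF", "SVM_TAN")) {
    dec <- rawSvmDecision(model, X)
    if (mean(dec[y == "active"]) < mean(dec[y == "inactive"]))
      model@signFlip <- -1
  }
  model
}

rawSvmDecision <- function(model, X) {
  ## kernlab's kernel-matrix predict expects columns ordered like the
  ## support vectors, so the cross-kernel is computed against SVs only
  sv <- model@trainX[kernlab::SVindex(model@fit), , drop = FALSE]
  K <- if (model@method == "SVM_TAN") tanimotoKernel(X, sv)
       else rbfKernelBinary(X, sv, gamma = model@hyper$gamma)
  as.numeric(kernlab::predict(model@fit, kernlab::as.kernelMatrix(K),
                              type = "decision"))
}

#' @rdname predictScore
#' @aliases predictScore,ActivityModel-method
setMethod("predictScore", "ActivityModel", function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model@nFeatures)
    stop("feature width mismatch: model expects ", model@nFeatures,
         " features, got ", ncol(X))
  switch(model@method,
    RFC = {
      colnames(X) <- model@fit$forest$independent.variable.names
      as.numeric(predict(model@fit, data = X,
                         num.threads = 1L)$predictions[, "active"])
    },
    FFNN = as.numeric(mlpPredict(model@fit, X)),
    model@signFlip * rawSvmDecision(model, X))
})

#' @rdname predictLabel
#' @aliases predictLabel,ActivityModel-method
setMethod("predictLabel", "ActivityModel", function(model, X) {
  s <- predictScore(model, X)
  cut <- if (model@outputMode == "probability" ||
             model@method %in% c("RFC", "FFNN")) 0.5 else 0
  factor(ifelse(s > cut, "active", "inactive"),
         levels = c("active", "inactive"))
})

## F1 from truth/prediction factors (active = positive)
f1Score <- function(truth, pred) {
  tp <- sum(truth == "active" & pred == "active")
  fp <- sum(truth == "inactive" & pred == "active")
  fn <- sum(truth == "active" & pred == "inactive")
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Grid-search training for one trial
#'
#' Performs grid search over the model specification's hyperparameter grid with
#' an inner stratified shuffle split (default 10 x 90/10) on the training
#' portion of the trial, selecting by mean F1 (ties broken by first
#' position in the grid), then refits the winning configuration on the
#' full training split.
#'
#' @param dataset a \linkS4class{FingerprintSet}.
#' @param split one element of \code{\link{splitTrials}}.
#' @param spec a \code{\link{modelSpec}}.
#' @param seed integer seed.
#' @param innerFolds number of inner shuffle-split folds.
#' @param innerTestFraction validation fraction of each inner fold.
#' @return an \linkS4class{ActivityModel}; the grid-search table is kept
#'   in \code{model@info$selection}.
#' @export
tuneAndTrain <- function(dataset, split, spec, seed = 1L, innerFolds = 10L,
                         innerTestFraction = 0.1) {
  X <- bitMatrix(dataset)[split$train, , drop = FALSE]
  y <- compoundLabels(dataset)[split$train]
  if (any(table(y) < 2L)) stop("degenerate training class in split")
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  meanF1 <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L) {
    inner <- splitTrials(y, nTrials = innerFolds,
                         testFraction = innerTestFraction,
                         seed = deriveSeed(seed, "inner"))
    for (g in seq_len(nrow(grid))) {
      f1s <- vapply(inner, function(sp) {
        m <- trainModel(X[sp$train, , drop = FALSE], y[sp$train],
                        spec$method, hyper = as.list(grid[g, , drop = FALSE]),
                        seed = deriveSeed(seed, paste0("fit", g)),
                        outputMode = spec$outputMode)
        f1Score(y[sp$test], predictLabel(m, X[sp$test, , drop = FALSE]))
      }, numeric(1))
      meanF1[g] <- mean(f1s)
    }
    best <- which.max(meanF1)  # first maximum: first-in-grid tie break
  } else best <- 1L
  model <- trainModel(X, y, spec$method,
                      hyper = as.list(grid[best, , drop = FALSE]),
                      seed = deriveSeed(seed, "final"),
                      outputMode = spec$outputMode,
                      featureIds = featureIds(dataset))
  model@info$selection <- cbind(grid, mean_f1 = meanF1)
  model@info$trial <- split$trial
  model
}

#' Confusion counts and the five performance metrics
#'
#' Builds a \linkS4class{PerformanceReport} from truth and predictions
#' (active = positive): precision TP/(TP+FP); recall TP/(TP+FN); balanced
#' accuracy (TPR+TNR)/2; F1 = 2TP/(2TP+FP+FN); MCC =
#' (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), taken as 0 when a
#' marginal is empty.
#'
#' @param truth,pred factors/characters with values active/inactive.
#' @return a \linkS4class{PerformanceReport}.
#' @examples
#' performanceReport(rep(c("active", "inactive"), c(50, 50)),
#'                   rep(c("active", "inactive"), c(60, 40)))
#' @export
performanceReport <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (!length(truth)) stop("empty test set")
  tp <- sum(truth == "active" & pred == "active")
  fp <- sum(truth == "inactive" & pred == "active")
  tn <- sum(truth == "inactive" & pred == "inactive")
  fn <- sum(truth == "active" & pred == "inactive")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  ba <- (recall + tnr) / 2
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  new("PerformanceReport", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      metrics = c(precision = precision, recall = recall,
                  balanced_accuracy = ba, f1 = f1, mcc = mcc))
}

#' Evaluate a trained model on a test split
#'
#' @param model an \linkS4class{ActivityModel}.
#' @param dataset a \linkS4class{FingerprintSet}.
#' @param testIdx integer indices of the test instances.
#' @return a \linkS4class{PerformanceReport}.
#' @export
evaluateModel <- function(model, dataset, testIdx) {
  if (!length(testIdx)) stop("empty test set")
  X <- bitMatrix(dataset)[testIdx, , drop = FALSE]
  if (length(model@featureIds) && model@nFeatures < ncol(X))
    X <- X[, model@featureIds + 1L, drop = FALSE]
  performanceReport(compoundLabels(dataset)[testIdx], predictLabel(model, X))
}
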