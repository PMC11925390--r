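test_that("shuffle-split trials are stratified, seeded and not a partition", {
  y <- rep(c("active", "inactive"), each = 100)
  sp <- splitTrials(y, nTrials = 10, testFraction = 0.1, seed = 3)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(s$test, 20)
    expect_equal(as.integer(table(y[s$test])), c(10, 10))
    expect_length(intersect(s$train, s$test), 0)
  }
  sp2 <- splitTrials(y, nTrials = 10, testFraction = 0.1, seed = 3)
  expect_identical(sp, sp2)
  ## shuffle split, not K-fold: pooled test sets revisit instances
  pooled <- unlist(lapply(sp, `[[`, "test"))
  expect_gt(max(table(pooled)), 1)
  expect_error(splitTrials(c("active", "inactive")), "at least 2")
})

test_that("Tanimoto kernel matches hand counts and guards its input", {
  expect_equal(tanimotoKernel(rbind(c(1, 0, 1)))[1, 1], 1)
  expect_equal(tanimotoKernel(rbind(c(1, 1, 0)), rbind(c(1, 0, 1)))[1, 1], 1 / 3)
  expect_equal(tanimotoKernel(rbind(c(1, 1, 0)), rbind(c(0, 0, 1)))[1, 1], 0)
  expect_equal(tanimotoKernel(rbind(c(0, 0, 0)), rbind(c(0, 0, 0)))[1, 1], 1)
  expect_error(tanimotoKernel(rbind(c(0.5, 1, 0))), "0/1")
  K <- tanimotoKernel(matrix(rbinom(50 * 16, 1, 0.3), 50))
  expect_true(all(K >= 0 & K <= 1))
  expect_equal(K, t(K))
})

test_that("performance metrics follow the printed formulas", {
  r <- performanceReport(rep(c("active", "inactive"), c(50, 50)),
                         c(rep("active", 50),
                           rep(c("active", "inactive"), c(10, 40))))
  expect_equal(r@tp, 50L); expect_equal(r@fp, 10L)
  expect_equal(r@tn, 40L); expect_equal(r@fn, 0L)
  expect_equal(unname(r@metrics["precision"]), 0.8333, tolerance = 1e-4)
  expect_equal(unname(r@metrics["recall"]), 1)
  expect_equal(unname(r@metrics["balanced_accuracy"]), 0.9)
  expect_equal(unname(r@metrics["f1"]), 0.9091, tolerance = 1e-4)
  expect_equal(unname(r@metrics["mcc"]), 0.8165, tolerance = 1e-4)

  y <- rep(c("active", "inactive"), c(30, 20))
  perfect <- performanceReport(y, y)
  expect_true(all(perfect@metrics == 1))
  inverted <- performanceReport(y, ifelse(y == "active", "inactive", "active"))
  expect_equal(unname(inverted@metrics["mcc"]), -1)
  expect_error(performanceReport(character(0), character(0)), "empty")
})

test_that("metric identities hold on random confusion outcomes", {
  for (seed in 1:20) {
    y <- withr::with_seed(seed, sample(c("active", "inactive"), 60, TRUE))
    p <- withr::with_seed(seed + 100, sample(c("active", "inactive"), 60, TRUE))
    r <- performanceReport(y, p)
    m <- r@metrics
    ## F1 is the harmonic mean of precision and recall
    if (m["precision"] + m["recall"] > 0)
      expect_equal(unname(m["f1"]),
                   unname(2 * m["precision"] * m["recall"] /
                            (m["precision"] + m["recall"])))
    ## MCC is invariant to swapping classes in truth and prediction together
    sw <- function(v) ifelse(v == "active", "inactive", "active")
    expect_equal(unname(performanceReport(sw(y), sw(p))@metrics["mcc"]),
                 unname(m["mcc"]))
  }
  ## BA equals plain accuracy on balanced test sets
  y <- rep(c("active", "inactive"), each = 25)
  p <- withr::with_seed(1, sample(c("active", "inactive"), 50, TRUE))
  r <- performanceReport(y, p)
  expect_equal(unname(r@metrics["balanced_accuracy"]), mean(y == p))
})

test_that("a perfectly separable bit pattern gives a perfect Tanimoto SVM", {
  ## two bits equal the class label; remaining bits are sparse noise
  withr::with_seed(1, {
    n <- 60
    X <- cbind(rep(c(1L, 0L), each = n / 2), rep(c(1L, 0L), each = n / 2),
               matrix(rbinom(n * 6, 1, 0.15), n, 6))
    y <- rep(c("active", "inactive"), each = n / 2)
  })
  fps <- ShapCompare:::newFingerprintSet(X, y, sprintf("S%02d", 1:60))
  sp <- splitTrials(y, nTrials = 3, seed = 9)
  for (s in sp) {
    m <- trainModel(X[s$train, ], y[s$train], "SVM_TAN", list(C = 10), seed = 2)
    expect_equal(unname(evaluateModel(m, fps, s$test)@metrics["f1"]), 1)
  }
})

test_that("grid search is deterministic and stores its selection table", {
  fps <- tinyDataset()
  sp <- splitTrials(compoundLabels(fps), nTrials = 1, seed = 3)[[1]]
  spec <- modelSpec("SVM_TAN", grid = list(C = c(0.01, 1, 100)))
  m1 <- tuneAndTrain(fps, sp, spec, seed = 5, innerFolds = 4)
  m2 <- tuneAndTrain(fps, sp, spec, seed = 5, innerFolds = 4)
  expect_identical(m1@hyper, m2@hyper)
  expect_identical(m1@info$selection, m2@info$selection)
  expect_equal(nrow(m1@info$selection), 3)
  expect_true(m1@hyper$C %in% c(0.01, 1, 100))

  expect_error(modelSpec("SVM_TAN", grid = list(C = -1)), "positive")
  expect_error(modelSpec("XGB"), "arg")
})

test_that("the neural network learns, is seeded and outputs probabilities", {
  withr::with_seed(8, {
    X <- matrix(rbinom(120 * 10, 1, 0.4), 120, 10)
    y <- as.integer(X[, 1] == 1 | X[, 2] == 1)
  })
  f1 <- mlpFit(X, y, hidden = 32, learningRate = 0.01, seed = 3)
  f2 <- mlpFit(X, y, hidden = 32, learningRate = 0.01, seed = 3)
  expect_identical(f1$pars, f2$pars)
  p <- mlpPredict(f1, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p > 0.5) == y), 0.9)
  expect_lte(f1$epochs, 400)
})

test_that("every model family fits the default synthetic signal", {
  fps <- tinyDataset()
  sp <- splitTrials(compoundLabels(fps), nTrials = 1, seed = 3)[[1]]
  X <- bitMatrix(fps); y <- compoundLabels(fps)
  for (meth in c("RFC", "FFNN", "SVM_RBF", "SVM_TAN")) {
    m <- trainModel(X[sp$train, ], y[sp$train], meth, tinyHyper(meth), seed = 11)
    rep <- evaluateModel(m, fps, sp$test)
    expect_gte(rep@metrics[["mcc"]], 0.7)
    ## scalar output respects the declared mode
    s <- predictScore(m, X[sp$test, , drop = FALSE])
    if (m@outputMode == "probability") expect_true(all(s >= 0 & s <= 1))
  }
  expect_error(evaluateModel(trainModel(X, y, "RFC", seed = 1), fps,
                             integer(0)), "empty")
})
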