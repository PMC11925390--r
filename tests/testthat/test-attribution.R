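test_that("subset-weight enumeration agrees with the permutation oracle", {
  for (seed in 1:8) {
    n <- 3 + seed %% 3
    g <- randomGame(n, seed)
    expect_equal(exactShapley(g)@phi, permutationShapley(g),
                 tolerance = 1e-12)
  }
})

test_that("exact Shapley satisfies efficiency, symmetry and dummy axioms", {
  ## symmetric pair: payoff depends only on coalition size and membership
  ## of players 1/2 interchangeably
  for (seed in 1:5) {
    n <- 4
    base <- randomGame(n, seed)
    vals <- base@values
    ## symmetrise players 1 and 2 by averaging over the swap
    swapMask <- function(m) {
      b1 <- bitwAnd(m, 1L) != 0L; b2 <- bitwAnd(m, 2L) != 0L
      m - 1L * b1 - 2L * b2 + 1L * b2 + 2L * b1
    }
    masks <- 0:(2^n - 1)
    symVals <- (vals + vals[vapply(masks, swapMask, 1L) + 1L]) / 2
    g <- new("ToyGame", nPlayers = as.integer(n), values = symVals)
    phi <- exactShapley(g)@phi
    expect_equal(phi[1], phi[2], tolerance = 1e-12)
    expect_equal(sum(phi), symVals[2^n] - symVals[1], tolerance = 1e-12)
  }
  ## dummy player: duplicate every coalition value across player n
  n <- 4
  inner <- randomGame(n - 1, 42)
  masks <- 0:(2^n - 1)
  vals <- inner@values[bitwAnd(masks, 2^(n - 1) - 1L) + 1L]
  g <- new("ToyGame", nPlayers = as.integer(n), values = vals)
  expect_identical(exactShapley(g)@phi[n], 0)
})

test_that("marginal value function obeys its boundary identities", {
  fps <- tinyDataset()
  sp <- splitTrials(compoundLabels(fps), nTrials = 1, seed = 3)[[1]]
  X <- bitMatrix(fps); y <- compoundLabels(fps)
  m <- trainModel(X[sp$train, ], y[sp$train], "RFC", tinyHyper("RFC"), seed = 1)
  bg <- sampleBackground(X[sp$train, ], 15, 4)
  inst <- X[sp$test[1], ]
  vf <- marginalValueFunction(m, inst, bg)
  expect_equal(vf$eval(rep(TRUE, 8)), vf$fx)
  expect_equal(vf$eval(rep(FALSE, 8)),
               mean(predictScore(m, bg)))
  expect_equal(vf$v0, vf$eval(rep(FALSE, 8)))
  expect_error(marginalValueFunction(m, inst[1:5], bg), "mismatch")
})

test_that("an additive model's coalition values expand to partial sums", {
  w <- c(0.3, -0.7, 1.1, 0.2)
  f <- additiveModel(w)
  inst <- c(1, 1, 0, 1)
  bg <- matrix(0, 1, 4)   # single all-zeros background row
  vf <- marginalValueFunction(f, inst, bg)
  for (mask in 0:15) {
    S <- bitwAnd(mask, bitwShiftL(1L, 0:3)) != 0L
    expect_equal(vf$eval(S), sum(w[S] * inst[S]))
  }
  phi <- exactShapley(vf)@phi
  expect_equal(phi, w * inst)
})

test_that("KernelSHAP with full enumeration reproduces exact Shapley for all families", {
  fps <- tinyDataset()
  sp <- splitTrials(compoundLabels(fps), nTrials = 1, seed = 3)[[1]]
  X <- bitMatrix(fps); y <- compoundLabels(fps)
  bg <- sampleBackground(X[sp$train, ], 15, 4)
  for (meth in c("RFC", "FFNN", "SVM_RBF", "SVM_TAN")) {
    m <- trainModel(X[sp$train, ], y[sp$train], meth, tinyHyper(meth), seed = 11)
    for (i in sp$test[1:2]) {
      ex <- exactShapley(marginalValueFunction(m, X[i, ], bg))
      ks <- kernelShap(m, X[i, ], bg, enumerate = TRUE)
      expect_lt(max(abs(ex@phi - ks@phi)), 1e-8)
      ## efficiency holds on both routes
      expect_lt(abs(sum(ex@phi) + ex@baseValue - ex@fx), 1e-10)
      expect_lt(abs(sum(ks@phi) + ks@baseValue - ks@fx), 1e-10)
    }
  }
})

test_that("sampled KernelSHAP is seeded, recovers additive models, and errs on tiny budgets", {
  w <- c(2, -1, 0.5, 1.5, -0.25, 0.75)
  f <- additiveModel(w)
  inst <- c(1, 0, 1, 1, 0, 1)
  bg <- matrix(0, 1, 6)
  ks <- kernelShap(f, inst, bg, nSamples = 12, seed = 3)
  expect_equal(ks@phi, w * inst, tolerance = 1e-10)
  ks2 <- kernelShap(f, inst, bg, nSamples = 12, seed = 3)
  expect_identical(ks@phi, ks2@phi)
  expect_error(kernelShap(f, inst, bg, nSamples = 4, seed = 1), "at least")
})

test_that("a constant feature receives zero attribution", {
  withr::with_seed(2, {
    X <- cbind(matrix(rbinom(40 * 5, 1, 0.5), 40, 5), 1L)
    y <- ifelse(X[, 1] == 1, "active", "inactive")
  })
  m <- trainModel(X, y, "SVM_TAN", list(C = 1), seed = 1)
  bg <- X[1:10, ]
  inst <- X[15, ]                # feature 6 constant at 1 everywhere
  ex <- exactShapley(marginalValueFunction(m, inst, bg))
  ks <- kernelShap(m, inst, bg, enumerate = TRUE)
  expect_identical(ex@phi[6], 0)
  expect_lt(abs(ks@phi[6]), 1e-10)
})

test_that("sampled KernelSHAP error shrinks as the budget doubles", {
  M <- 10
  fps <- generateFingerprints(syntheticConfig(nPerClass = 30, nFeatures = M,
                                              nInformative = 4, seed = 21))
  X <- bitMatrix(fps); y <- compoundLabels(fps)
  m <- trainModel(X[1:48, ], y[1:48], "SVM_TAN", list(C = 1), seed = 2)
  bg <- sampleBackground(X[1:48, ], 10, 3)
  inst <- X[55, ]
  exact <- exactShapley(marginalValueFunction(m, inst, bg))@phi
  ## budgets chosen inside the sampling regime (a budget that exactly
  ## covers an enumerated size pair is deterministic, which breaks the
  ## comparison across doublings)
  budgets <- c(24, 48, 96, 192)
  mae <- sapply(budgets, function(b) {
    mean(vapply(1:20, function(s)
      mean(abs(kernelShap(m, inst, bg, nSamples = b, seed = s)@phi - exact)),
      numeric(1)))
  })
  expect_true(all(diff(mae) < 0))
})

test_that("attributeDataset collects rows, keeps efficiency and handles edge cases", {
  fps <- tinyDataset()
  sp <- splitTrials(compoundLabels(fps), nTrials = 1, seed = 3)[[1]]
  X <- bitMatrix(fps); y <- compoundLabels(fps)
  m <- trainModel(X[sp$train, ], y[sp$train], "SVM_TAN", list(C = 1), seed = 1)
  bg <- sampleBackground(X[sp$train, ], 15, 4)

  at <- attributeDataset(m, fps, sp$test[1:4], "exact_enumeration", bg,
                         trial = 0L)
  expect_equal(dim(attrValues(at)), c(4, 8))
  expect_equal(rowSums(attrValues(at)) + baseValues(at), at@fx,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(rownames(attrValues(at)), compoundIds(fps)[sp$test[1:4]])

  empty <- attributeDataset(m, fps, integer(0), "kernel_shap", bg)
  expect_equal(nrow(attrValues(empty)), 0)

  wide <- marginalValueFunction(additiveModel(rep(1, 17)),
                                rep(1, 17), matrix(0, 1, 17))
  expect_error(exactShapley(wide), "capped")
})

test_that("attributions survive a round trip through the long CSV format", {
  fps <- tinyDataset()
  sp <- splitTrials(compoundLabels(fps), nTrials = 1, seed = 3)[[1]]
  X <- bitMatrix(fps); y <- compoundLabels(fps)
  m <- trainModel(X[sp$train, ], y[sp$train], "SVM_TAN", list(C = 1), seed = 1)
  bg <- sampleBackground(X[sp$train, ], 10, 4)
  at <- attributeDataset(m, fps, sp$test[1:3], "kernel_shap", bg,
                         nSamples = 16, seed = 2, trial = 1L)
  path <- file.path(tempdir(), "attr.csv")
  writeAttributions(at, path)
  back <- readAttributions(path)
  expect_equal(attrValues(back), attrValues(at), tolerance = 1e-12)
  expect_equal(baseValues(back), baseValues(at))
  expect_identical(back@method, "kernel_shap")
})
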