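makeAttr <- function(V, method = "kernel_shap", model = "SVM_TAN") {
  rownames(V) <- sprintf("C%02d", seq_len(nrow(V)))
  colnames(V) <- sprintf("f%d", seq_len(ncol(V)) - 1L)
  new("AttributionMatrix", values = V, baseValues = numeric(nrow(V)),
      fx = rowSums(V), method = method, model = model, trial = NA_integer_)
}

test_that("cumulative present/absent sums follow the worked example", {
  V <- rbind(c(0.2, -0.1, 0.3), c(0.1, 0.1, 0.1), c(0, 0, 0))
  bits <- rbind(c(1, 0, 1), c(1, 1, 0), c(0, 1, 0))
  at <- makeAttr(V)
  out <- cumulativePresentAbsent(at, bits,
                                 labels = c("active", "inactive", "active"),
                                 predictions = c("active", "active", "active"))
  ## the misclassified inactive is excluded
  expect_equal(nrow(out), 2)
  expect_equal(out$present_sum[1], 0.5)
  expect_equal(out$absent_sum[1], -0.1)
  ## all-zero attribution row sums to zero in both categories
  expect_equal(out$present_sum[2], 0)
  expect_equal(out$absent_sum[2], 0)
  expect_error(cumulativePresentAbsent(at, bits[1:2, ], c("a", "b"), c("a", "b")),
               "aligned")
})

test_that("Gini matches hand calculations and its invariances", {
  expect_equal(giniCoefficient(c(1, 2, 3, 4)), 0.25)
  expect_equal(giniCoefficient(c(5, 5, 5)), 0)
  expect_equal(giniCoefficient(c(0, 0, 0, 9)), 0)
  expect_error(giniCoefficient(c(0, 0)), "all-zero")
  ## positive rescaling and permutation leave G unchanged; signs ignored
  x <- c(0.1, 0.7, 0.2, 1.4, 0.9)
  expect_equal(giniCoefficient(10 * x), giniCoefficient(x))
  expect_equal(giniCoefficient(withr::with_seed(1, sample(x))),
               giniCoefficient(x))
  expect_equal(giniCoefficient(-x), giniCoefficient(x))
  for (seed in 1:10) {
    g <- giniCoefficient(withr::with_seed(seed, runif(50)))
    expect_true(g >= 0 && g < 1)
  }
})

test_that("compacity counts features up to each mass threshold", {
  out <- compacity(c(0.5, 0.3, 0.1, 0.1), 0.7)
  expect_equal(out$n_features, 2L)
  expect_equal(out$pct, 50)
  ## one dominant value
  expect_equal(compacity(c(10, 0.1, 0.1, 0.1, 0.1), 0.5)$n_features, 1L)
  ## uniform shares
  expect_equal(compacity(rep(1, 10), 0.9)$pct, 90)
  ## monotone, bounded curve over the default grid
  curve <- compacity(withr::with_seed(3, rnorm(40)))
  expect_true(all(diff(curve$pct) >= 0))
  expect_true(all(curve$pct <= 100))
  expect_error(compacity(numeric(0)), "empty")
  expect_error(compacity(c(0, 0)), "all-zero")
})

test_that("consistency reports the per-feature spread of normalised values", {
  ## identical normalised rows: every feature has zero spread
  V <- rbind(c(0.2, 0.8, 0), c(0.1, 0.4, 0))
  cs <- consistencyStd(makeAttr(V))
  expect_equal(unname(cs[1:2]), c(0, 0))
  expect_true(is.na(cs[3]))          # never non-zero
  ## two-point sample standard deviation
  V2 <- rbind(c(0.1, 0.9), c(0.3, 0.7))
  cs2 <- consistencyStd(makeAttr(V2))
  expect_equal(unname(cs2[1]), sd(c(0.1, 0.3)), tolerance = 1e-12)
  expect_equal(unname(cs2[1]), 0.1414, tolerance = 1e-3)
  ## feature non-zero in exactly one instance is undefined
  V3 <- rbind(c(0.5, 0.5), c(0.8, 0))
  expect_true(is.na(consistencyStd(makeAttr(V3))[2]))
  expect_warning(consistencyStd(makeAttr(rbind(c(1, 1), c(0, 0)))), "skipped")
})

test_that("method correlation hits the exact endpoints and the null", {
  A <- makeAttr(withr::with_seed(5, matrix(rnorm(200), 20)))
  expect_equal(methodCorrelation(A, makeAttr(2 * attrValues(A))), 1)
  expect_equal(methodCorrelation(A, makeAttr(-attrValues(A))), -1)
  bits <- withr::with_seed(6, matrix(rbinom(200, 1, 0.4), 20))
  for (ss in c("all", "present", "absent"))
    expect_equal(methodCorrelation(A, A, bits, ss), 1)
  ## independent matrices decorrelate
  B <- makeAttr(withr::with_seed(7, matrix(rnorm(10000), 100)))
  C <- makeAttr(withr::with_seed(8, matrix(rnorm(10000), 100)))
  expect_lt(abs(methodCorrelation(B, C)), 0.05)
  ## zero variance is undefined
  expect_true(is.na(methodCorrelation(A, makeAttr(matrix(1, 20, 10)))))
})

test_that("faithfulness is exact for additive models and guards degeneracies", {
  w <- c(0.4, -0.2, 0.9, 0.1, -0.6)
  f <- additiveModel(w)
  inst <- c(1, 0, 1, 1, 0)
  ## attribution from the Shapley pipeline with an all-zeros background
  phi <- exactShapley(marginalValueFunction(f, inst, matrix(0, 1, 5)))@phi
  expect_equal(faithfulness(f, inst, phi, "present"), 1)
  ## attribution equal to the flip effects themselves
  flips <- vapply(1:5, function(i) {
    x2 <- inst; x2[i] <- 1 - x2[i]
    f(matrix(inst, 1)) - f(matrix(x2, 1))
  }, numeric(1))
  expect_equal(faithfulness(f, inst, flips, "all"), 1)
  ## constant attribution has no defined correlation
  expect_true(is.na(faithfulness(f, inst, rep(0.5, 5), "all")))
  ## single-feature subsets are undefined
  expect_true(is.na(faithfulness(f, c(1, 0, 0, 0, 0), w, "present")))
})

test_that("Wilcoxon family testing adjusts with Holm and tiers the outcome", {
  expect_equal(holmAdjust(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  withr::with_seed(10, {
    x <- rnorm(30)
    pairs <- list(strong = list(x = x, y = x + 2),
                  null = list(x = x, y = x + rnorm(30, 0, 0.001) * 0),
                  weak = list(x = x, y = x + rnorm(30, 0.1)))
  })
  pairs$null$y <- pairs$null$x     # identical vectors: degenerate
  out <- wilcoxonHolm(pairs)
  expect_equal(out$tier[out$label == "strong"], "****")
  expect_true(is.na(out$p[out$label == "null"]))
  ## Holm never reduces a p-value and preserves ordering
  ok <- !is.na(out$p)
  expect_true(all(out$p_adj[ok] >= out$p[ok]))
  expect_equal(order(out$p[ok]), order(out$p_adj[ok]))
  expect_error(wilcoxonHolm(list(a = list(x = 1:3, y = 2:4))), ">= 5")
})
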