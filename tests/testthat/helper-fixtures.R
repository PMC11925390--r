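## Shared fixtures and independent oracles for the test suite.

## Independent Shapley oracle: average marginal contribution over all n!
## player orderings (feasible for n <= 6). Deliberately different from the
## package's subset-weight enumeration.
permutationShapley <- function(game) {
  n <- game@nPlayers
  perms <- permutations(n)
  phi <- numeric(n)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    before <- integer(0)
    for (p in ord) {
      phi[p] <- phi[p] + coalitionValue(game, c(before, p)) -
        coalitionValue(game, before)
      before <- c(before, p)
    }
  }
  phi / nrow(perms)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

## random cooperative game on n players with seeded payoffs
randomGame <- function(n, seed) {
  vals <- withr::with_seed(seed, stats::rnorm(2^n))
  vals[1] <- 0
  masks <- 0:(2^n - 1)
  coalitions <- lapply(masks, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L))
  makeToyGame(coalitions, vals, n)
}

## additive game v(S) = sum of weights over S
additiveGame <- function(weights) {
  n <- length(weights)
  masks <- 0:(2^n - 1)
  coalitions <- lapply(masks, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L))
  makeToyGame(coalitions, vapply(coalitions, function(s) sum(weights[s]), 0), n)
}

## small planted-signal dataset + one trained model, reused across files
tinyDataset <- function(nPerClass = 40, nFeatures = 8, nInformative = 3,
                        seed = 7) {
  generateFingerprints(syntheticConfig(nPerClass = nPerClass,
                                       nFeatures = nFeatures,
                                       nInformative = nInformative,
                                       seed = seed))
}

tinyHyper <- function(method) {
  switch(method,
         RFC = list(numTrees = 50),
         FFNN = list(learningRate = 0.01),
         SVM_RBF = list(C = 10, gamma = 0.1),
         SVM_TAN = list(C = 1))
}

## additive scoring function f(x) = sum w_i x_i (closed-form oracle model)
additiveModel <- function(weights) {
  force(weights)
  function(X) as.numeric(X %*% weights)
}
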