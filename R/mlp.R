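## Minimal seeded feed-forward network: one ReLU hidden layer, sigmoid
## output, binary cross-entropy loss, Adam updates, mini-batches, early
## stopping on a stratified validation carve-out. Written with base matrix
## ops; sized for fingerprint-scale inputs (hundreds of features, a few
## hundred compounds).

sigmoid <- function(z) 1 / (1 + exp(-z))

bceLoss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit the single-hidden-layer neural network
#'
#' Architecture: 256 ReLU units in one hidden layer, sigmoid output,
#' binary cross-entropy loss, Adam optimizer, batch size 16, at most 400
#' epochs. Training stops early when the validation loss (on a stratified
#' 10 percent carve-out of the training data) has not improved by at least
#' \code{tol} for \code{patience} consecutive epochs; the best-validation
#' weights are kept. All randomness (weight initialisation, batch
#' shuffling, validation carve-out) is governed by \code{seed}.
#'
#' @param X 0/1 matrix, compounds x features.
#' @param y integer 0/1 vector (1 = active).
#' @param hidden hidden layer width.
#' @param learningRate initial Adam learning rate.
#' @param batchSize mini-batch size.
#' @param maxEpochs epoch cap.
#' @param patience epochs without improvement before stopping.
#' @param tol minimum validation-loss improvement that counts.
#' @param valFraction validation carve-out fraction.
#' @param seed integer seed.
#' @return an object of class \code{mlpFit} (weight matrices and training
#'   trace).
#' @export
mlpFit <- function(X, y, hidden = 256L, learningRate = 0.001,
                   batchSize = 16L, maxEpochs = 400L, patience = 20L,
                   tol = 1e-4, valFraction = 0.1, seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0L, 1L)))
  M <- ncol(X)
  withSeed(seed, {
    ## stratified validation carve-out (>= 1 per class when possible)
    val <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      if (length(idx) < 2L) return(integer(0))
      sample(idx, max(1L, round(valFraction * length(idx))))
    }))
    tr <- setdiff(seq_len(nrow(X)), val)
    if (!length(val)) { val <- tr }  # degenerate tiny input: validate on train
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xval <- X[val, , drop = FALSE]; yval <- y[val]

    W1 <- matrix(stats::rnorm(M * hidden, sd = sqrt(2 / M)), M, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    mom <- lapply(pars, function(p) p * 0)
    vel <- lapply(pars, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L

    forward <- function(P, Xb) {
      Z1 <- sweep(Xb %*% P$W1, 2, P$b1, "+")
      A1 <- pmax(Z1, 0)
      list(Z1 = Z1, A1 = A1,
           p = as.numeric(sigmoid(A1 %*% P$W2 + P$b2)))
    }

    best <- list(pars = pars, loss = Inf)
    wait <- 0L; trace <- numeric(0)
    for (epoch in seq_len(maxEpochs)) {
      ord <- sample(length(ytr))
      starts <- seq(1L, length(ord), by = batchSize)
      for (s in starts) {
        bidx <- ord[s:min(s + batchSize - 1L, length(ord))]
        Xb <- Xtr[bidx, , drop = FALSE]; yb <- ytr[bidx]
        fw <- forward(pars, Xb)
        d <- matrix((fw$p - yb) / length(yb), ncol = 1)
        grads <- list(
          W1 = crossprod(Xb, (d %*% t(pars$W2)) * (fw$Z1 > 0)),
          b1 = colSums((d %*% t(pars$W2)) * (fw$Z1 > 0)),
          W2 = crossprod(fw$A1, d),
          b2 = sum(d))
        step <- step + 1L
        for (nm in names(pars)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- mom[[nm]] / (1 - beta1^step)
          vhat <- vel[[nm]] / (1 - beta2^step)
          pars[[nm]] <- pars[[nm]] - learningRate * mhat / (sqrt(vhat) + eps)
        }
      }
      vloss <- bceLoss(forward(pars, Xval)$p, yval)
      trace <- c(trace, vloss)
      if (best$loss - vloss >= tol) {
        best <- list(pars = pars, loss = vloss); wait <- 0L
      } else wait <- wait + 1L
      if (wait >= patience) break
    }
    structure(list(pars = best$pars, valLoss = best$loss, trace = trace,
                   epochs = length(trace), hidden = hidden,
                   learningRate = learningRate),
              class = "mlpFit")
  })
}

#' Predict active-class probabilities with a fitted network
#'
#' @param fit an object from \code{\link{mlpFit}}.
#' @param X 0/1 matrix, compounds x features.
#' @return numeric probabilities of the active class.
#' @export
mlpPredict <- function(fit, X) {
  P <- fit$pars
  A1 <- pmax(sweep(X %*% P$W1, 2, P$b1, "+"), 0)
  as.numeric(sigmoid(A1 %*% P$W2 + P$b2))
}
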