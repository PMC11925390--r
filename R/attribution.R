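#' Marginal-expectation value function for one instance
#'
#' Builds the coalition value function v(S) used by both the exact
#' enumerator and KernelSHAP: features inside the coalition S take their
#' values from the explained instance, features outside S are marginalised
#' over a background set of training rows, and v(S) is the mean model
#' score over the resulting composites. By construction v(full set) is the
#' model output for the instance and v(empty set) is the mean background
#' score.
#'
#' @param model an \linkS4class{ActivityModel}, or a plain scoring
#'   function taking a 0/1 matrix and returning numeric outputs.
#' @param instance 0/1 vector of length \code{model@nFeatures}.
#' @param background 0/1 matrix of training rows (non-empty).
#' @param chunkRows maximum composite rows scored per batch.
#' @return a \code{MarginalValueFunction}: list with \code{eval(Z)} (Z a
#'   logical coalition matrix, returns one value per row), \code{v0},
#'   \code{fx} and \code{M}.
#' @export
marginalValueFunction <- function(model, instance, background,
                                  chunkRows = 2e5) {
  instance <- as.numeric(instance)
  if (!all(instance %in% c(0, 1))) stop("instance must be a 0/1 vector")
  if (!is.matrix(background) || nrow(background) == 0L)
    stop("background must be a non-empty matrix")
  if (length(instance) != ncol(background))
    stop("dimension mismatch between instance and background")
  if (is(model, "ActivityModel") && length(instance) != model@nFeatures)
    stop("dimension mismatch between instance and model")
  score <- scoreFun(model)
  M <- length(instance)
  B <- nrow(background)
  v0 <- mean(score(background))
  fx <- score(matrix(instance, nrow = 1))
  onCols <- which(instance == 1)
  evalZ <- function(Z) {
    if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1)
    storage.mode(Z) <- "double"
    nC <- nrow(Z)
    out <- numeric(nC)
    perChunk <- max(1L, floor(chunkRows / B))
    for (start in seq(1L, nC, by = perChunk)) {
      idx <- start:min(start + perChunk - 1L, nC)
      Zc <- Z[idx, , drop = FALSE]
      k <- nrow(Zc)
      ## composite x' = z * x + (1 - z) * b; with binary bits this is
      ## b * (1 - z) plus z restricted to the instance's on columns
      Zbig <- Zc[rep(seq_len(k), each = B), , drop = FALSE]
      comp <- background[rep(seq_len(B), times = k), , drop = FALSE] *
        (1 - Zbig)
      if (length(onCols))
        comp[, onCols] <- comp[, onCols] + Zbig[, onCols]
      preds <- score(comp)
      out[idx] <- colMeans(matrix(preds, nrow = B))
    }
    out
  }
  structure(list(eval = evalZ, v0 = v0, fx = fx, M = M),
            class = "MarginalValueFunction")
}

shapleyWeights <- function(M) {
  s <- 0:(M - 1)
  exp(lfactorial(s) + lfactorial(M - s - 1) - lfactorial(M))
}

#' Exact Shapley values by full coalition enumeration
#'
#' Computes phi_p = sum over S not containing p of
#' |S|! (M - |S| - 1)! / M! * (v(S + p) - v(S)) over all 2^M coalitions.
#' Accepts either a \linkS4class{ToyGame} (the coalition table is the
#' value function) or a \code{\link{marginalValueFunction}}. Capped at 16
#' features; wider problems should use \code{\link{kernelShap}}.
#'
#' @param v a \linkS4class{ToyGame} or \code{MarginalValueFunction}.
#' @return a \linkS4class{ShapleyResult} satisfying the efficiency,
#'   symmetry and dummy axioms.
#' @examples
#' g <- makeToyGame(list(integer(0), 1, 2, c(1, 2)), c(0, 1, 2, 4), 2)
#' exactShapley(g)@phi  # 1.5, 2.5
#' @export
exactShapley <- function(v) {
  if (is(v, "ToyGame")) {
    M <- v@nPlayers
    vals <- v@values
  } else if (inherits(v, "MarginalValueFunction")) {
    M <- v$M
    if (M > 16L)
      stop("exact enumeration is capped at 16 features (2^M coalitions); ",
           "use kernelShap() for wider models")
    masks <- 0:(2^M - 1)
    vals <- v$eval(masksToMatrix(masks, M))
  } else stop("v must be a ToyGame or a MarginalValueFunction")
  if (M > 16L) stop("exact enumeration is capped at 16 players")
  masks <- 0:(2^M - 1)
  sizes <- bitCount(masks, M)
  w <- shapleyWeights(M)
  phi <- numeric(M)
  for (p in seq_len(M)) {
    bit <- bitwShiftL(1L, p - 1L)
    S <- masks[bitwAnd(masks, bit) == 0L]
    phi[p] <- sum(w[sizes[S + 1L] + 1L] * (vals[S + bit + 1L] - vals[S + 1L]))
  }
  new("ShapleyResult", phi = phi, baseValue = vals[1L],
      fx = vals[2^M], method = "exact_enumeration",
      nSamples = NA_integer_, seed = NA_integer_)
}

## Hybrid coalition sampler in the style of the reference KernelSHAP:
## paired sizes (s, M-s) are fully enumerated outward from s = 1 while the
## budget allows (exact kernel weight mass per size), the remaining budget
## is spent on paired random draws from the leftover sizes. Returns a
## logical coalition matrix and regression weights.
sampleCoalitions <- function(M, nSamples) {
  sizes <- 1:(M - 1)
  sizeMass <- (M - 1) / (sizes * (M - sizes))
  sizeMass <- sizeMass / sum(sizeMass)
  Zlist <- list(); wlist <- list()
  remaining <- nSamples
  enumerated <- logical(M - 1)
  for (s in seq_len(ceiling((M - 1) / 2))) {
    comp <- M - s
    paired <- comp != s
    nsub <- choose(M, s)
    need <- if (paired) 2 * nsub else nsub
    if (need > remaining) break
    idx <- utils::combn(M, s)
    block <- matrix(FALSE, ncol(idx), M)
    block[cbind(rep(seq_len(ncol(idx)), each = s), as.vector(idx))] <- TRUE
    mass <- sizeMass[s] + if (paired) sizeMass[comp] else 0
    Zlist[[length(Zlist) + 1L]] <- if (paired) rbind(block, !block) else block
    wlist[[length(wlist) + 1L]] <- rep(mass / need, need)
    enumerated[s] <- TRUE
    if (paired) enumerated[comp] <- TRUE
    remaining <- remaining - need
  }
  leftSizes <- sizes[!enumerated]
  if (length(leftSizes) && remaining >= 2L) {
    ## paired draws: sample a small size s <= M - s, add the coalition and
    ## its complement; pair mass governs the size distribution
    smallLeft <- leftSizes[leftSizes <= M - leftSizes]
    pairMass <- vapply(smallLeft, function(s)
      sizeMass[s] + if (M - s != s) sizeMass[M - s] else 0, numeric(1))
    nDraw <- floor(remaining / 2)
    drawS <- smallLeft[sample.int(length(smallLeft), nDraw, replace = TRUE,
                                  prob = pairMass)]
    Zs <- matrix(FALSE, 2L * nDraw, M)
    for (k in seq_len(nDraw)) {
      Zs[2L * k - 1L, sample.int(M, drawS[k])] <- TRUE
      Zs[2L * k, ] <- !Zs[2L * k - 1L, ]
    }
    Zlist[[length(Zlist) + 1L]] <- Zs
    wlist[[length(wlist) + 1L]] <-
      rep(sum(sizeMass[!enumerated]) / (2L * nDraw), 2L * nDraw)
  }
  Z <- do.call(rbind, Zlist)
  w <- unlist(wlist)
  ## aggregate duplicate coalitions (weights add up)
  key <- apply(Z, 1, function(z) paste(as.integer(z), collapse = ""))
  first <- !duplicated(key)
  agg <- rowsum(w, key)
  list(Z = Z[first, , drop = FALSE], w = as.numeric(agg[key[first], 1L]))
}

#' KernelSHAP: Shapley values by kernel-weighted linear regression
#'
#' Solves the Shapley-kernel weighted least-squares problem over
#' coalitions of features, with weights
#' pi(s) = (M - 1) / (choose(M, s) * s * (M - s)) and the efficiency
#' constraint sum(phi) = f(x) - v(empty) imposed exactly by variable
#' elimination. With \code{enumerate = TRUE} (or a budget covering all
#' 2^M - 2 proper coalitions) the solution coincides with
#' \code{\link{exactShapley}} up to numerical precision. Sampled runs use
#' paired sampling (each drawn coalition enters with its complement) after
#' fully enumerating as many complete coalition sizes as the budget
#' allows. No regularisation is applied.
#'
#' @param model an \linkS4class{ActivityModel}, or a plain scoring
#'   function taking a 0/1 matrix and returning numeric outputs.
#' @param instance 0/1 vector to explain.
#' @param background 0/1 matrix of training rows.
#' @param nSamples coalition budget (at least 2 * M); ignored when
#'   \code{enumerate = TRUE}.
#' @param seed integer seed for coalition sampling.
#' @param enumerate evaluate all proper coalitions instead of sampling.
#' @return a \linkS4class{ShapleyResult} with method "kernel_shap".
#' @export
kernelShap <- function(model, instance, background, nSamples = NULL,
                       seed = 1L, enumerate = FALSE) {
  vf <- marginalValueFunction(model, instance, background)
  M <- vf$M
  full <- 2^M - 2
  if (!enumerate) {
    if (is.null(nSamples)) nSamples <- 2L * M
    if (nSamples >= full) enumerate <- TRUE
    else if (nSamples < 2 * M)
      stop("nSamples must be at least 2 * nFeatures (or use enumerate = TRUE)")
  }
  if (enumerate) {
    if (M > 30L) stop("full enumeration infeasible for M > 30")
    masks <- seq_len(full)
    Z <- masksToMatrix(masks, M)
    s <- bitCount(masks, M)
    w <- (M - 1) / (choose(M, s) * s * (M - s))
    nS <- NA_integer_
  } else {
    sc <- withSeed(seed, sampleCoalitions(M, nSamples))
    Z <- sc$Z; w <- sc$w
    nS <- as.integer(nSamples)
  }
  y <- vf$eval(Z) - vf$v0
  delta <- vf$fx - vf$v0
  ## efficiency by elimination of the last feature
  zM <- Z[, M]
  A <- Z[, -M, drop = FALSE] - zM
  yt <- y - zM * delta
  fit <- stats::lm.wfit(A, yt, w)
  if (fit$rank < M - 1L)
    stop("singular design: too few distinct coalitions sampled")
  phi <- c(fit$coefficients, delta - sum(fit$coefficients))
  new("ShapleyResult", phi = as.numeric(phi), baseValue = vf$v0,
      fx = vf$fx, method = "kernel_shap", nSamples = nS,
      seed = as.integer(seed))
}

#' Seeded background sample of training rows
#'
#' @param X 0/1 training matrix.
#' @param size maximum number of rows to keep (default 100).
#' @param seed integer seed.
#' @return 0/1 matrix of at most \code{size} rows.
#' @export
sampleBackground <- function(X, size = 100L, seed = 1L) {
  if (nrow(X) <= size) return(X)
  X[withSeed(seed, sort(sample.int(nrow(X), size))), , drop = FALSE]
}

#' Attribute a set of instances
#'
#' Runs \code{\link{exactShapley}} or \code{\link{kernelShap}} on each
#' requested row of the dataset and collects the results into an
#' \linkS4class{AttributionMatrix}. Per-instance seeds are derived from
#' \code{seed} so the matrix is reproducible as a whole.
#'
#' @param model an \linkS4class{ActivityModel}, or a plain scoring
#'   function taking a 0/1 matrix and returning numeric outputs.
#' @param dataset a \linkS4class{FingerprintSet} (or a 0/1 matrix).
#' @param rows integer instance indices to attribute (may be empty).
#' @param method "kernel_shap" or "exact_enumeration".
#' @param background 0/1 matrix of training rows.
#' @param nSamples KernelSHAP coalition budget (NULL: 2 * M).
#' @param seed integer seed.
#' @param enumerate force full coalition enumeration in KernelSHAP.
#' @param trial trial index recorded in the result.
#' @param verbose log per-instance progress.
#' @return an \linkS4class{AttributionMatrix}.
#' @export
attributeDataset <- function(model, dataset, rows,
                             method = c("kernel_shap", "exact_enumeration"),
                             background, nSamples = NULL, seed = 1L,
                             enumerate = FALSE, trial = NA_integer_,
                             verbose = FALSE) {
  method <- match.arg(method)
  X <- if (is.matrix(dataset)) dataset else bitMatrix(dataset)
  if (length(model@featureIds) && model@nFeatures < ncol(X))
    X <- X[, model@featureIds + 1L, drop = FALSE]
  M <- ncol(X)
  rows <- as.integer(rows)
  vals <- matrix(numeric(0), 0L, M)
  base <- fx <- numeric(0)
  if (length(rows)) {
    res <- lapply(seq_along(rows), function(k) {
      i <- rows[k]
      if (verbose) message("attributing instance ", i, " (", k, "/",
                           length(rows), ")")
      tryCatch({
        if (method == "exact_enumeration")
          exactShapley(marginalValueFunction(model, X[i, ], background))
        else
          kernelShap(model, X[i, ], background, nSamples = nSamples,
                     seed = deriveSeed(seed, paste0("inst", i)),
                     enumerate = enumerate)
      }, error = function(e)
        stop("attribution failed for instance ", i, ": ",
             conditionMessage(e), call. = FALSE))
    })
    vals <- do.call(rbind, lapply(res, slot, "phi"))
    base <- vapply(res, slot, numeric(1), "baseValue")
    fx <- vapply(res, slot, numeric(1), "fx")
  }
  rn <- if (!is.matrix(dataset)) compoundIds(dataset)[rows] else
    as.character(rows)
  dimnames(vals) <- list(rn, sprintf("f%d", model@featureIds))
  new("AttributionMatrix", values = vals, baseValues = base, fx = fx,
      method = method, model = model@method, trial = as.integer(trial))
}
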