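#' Global feature ranking, least important first
#'
#' Normalises each instance's attribution row by its absolute sum, sums
#' the absolute normalised values per feature across all instances, and
#' returns the feature ids ordered by ascending total importance (ties
#' broken by feature id). All-zero rows are skipped; an all-zero matrix
#' is an error.
#'
#' @param attr an \linkS4class{AttributionMatrix}.
#' @return integer vector of 0-based feature ids, least important first.
#' @export
globalFeatureRanking <- function(attr) {
  V <- attrValues(attr)
  if (!nrow(V)) stop("empty attribution matrix")
  tot <- rowSums(abs(V))
  V <- V[tot > 0, , drop = FALSE]
  if (!nrow(V)) stop("all attribution rows are zero")
  score <- colSums(abs(V / rowSums(abs(V))))
  ids <- as.integer(sub("^f", "", colnames(V)))
  if (anyNA(ids)) ids <- seq_len(ncol(V)) - 1L
  ids[order(score, ids)]
}

#' Desk- and production-scale removal schedules
#'
#' The 2048-feature production schedule removes 100, 1000, 1500, 1700,
#' 1800, 1900, 1950, 2000, 2023, 2038 and 2043 features; the 256-feature
#' desk schedule mirrors its geometry (dense near full removal): 25, 128,
#' 192, 224, 240, 248, 251, 253, 254, 255. Other widths scale the
#' production schedule proportionally.
#'
#' @param nFeatures feature count of the dataset.
#' @return strictly increasing integer vector of removal counts.
#' @export
roarSchedule <- function(nFeatures) {
  prod <- c(100, 1000, 1500, 1700, 1800, 1900, 1950, 2000, 2023, 2038, 2043)
  if (nFeatures == 2048L) return(as.integer(prod))
  if (nFeatures == 256L)
    return(c(25L, 128L, 192L, 224L, 240L, 248L, 251L, 253L, 254L, 255L))
  s <- unique(pmin(as.integer(round(prod / 2048 * nFeatures)),
                   nFeatures - 2L))
  as.integer(sort(s[s >= 1L]))
}

#' Remove-and-retrain (ROAR) evaluation of a feature ranking
#'
#' At each schedule step the first n features of the ranking (the least
#' important) are deleted from the representation, the model is retrained
#' on the reduced feature set with the supplied fixed hyperparameters,
#' and the test split is predicted with the same reduced representation;
#' MCC is recorded. As a control, the procedure is repeated with seeded
#' uniform random removals of equal size. A step of 0 records the
#' unreduced baseline.
#'
#' @param dataset a \linkS4class{FingerprintSet}.
#' @param split one element of \code{\link{splitTrials}}.
#' @param method model family to retrain.
#' @param hyper fixed hyperparameters reused at every step (no re-tuning).
#' @param ranking 0-based feature ids, least important first (see
#'   \code{\link{globalFeatureRanking}}).
#' @param schedule removal counts (strictly increasing, < nFeatures).
#' @param nRandomControls number of random-removal control seeds.
#' @param seed integer master seed.
#' @param methodLabel,modelLabel labels stored in the result.
#' @return a \linkS4class{RoarResult}.
#' @export
roarRun <- function(dataset, split, method, hyper, ranking,
                    schedule = roarSchedule(nrow(dataset)),
                    nRandomControls = 5L, seed = 1L,
                    methodLabel = "kernel_shap", modelLabel = method) {
  X <- bitMatrix(dataset)
  y <- compoundLabels(dataset)
  M <- ncol(X)
  schedule <- as.integer(schedule)
  if (any(schedule >= M)) stop("schedule counts must be below the feature count")
  if (is.unsorted(schedule[schedule > 0L], strictly = TRUE))
    stop("schedule must be strictly increasing")
  if (length(ranking) != M || !setequal(ranking, seq_len(M) - 1L))
    stop("ranking must be a permutation of all 0-based feature ids")

  fitStep <- function(keepIds, fitSeed) {
    keep <- sort(keepIds) + 1L
    if (length(keep) < 1L) stop("schedule step leaves no features")
    m <- trainModel(X[split$train, keep, drop = FALSE], y[split$train],
                    method, hyper = hyper, seed = fitSeed,
                    featureIds = sort(keepIds))
    rep <- performanceReport(y[split$test],
                             predictLabel(m, X[split$test, keep, drop = FALSE]))
    unname(rep@metrics["mcc"])
  }

  rows <- list()
  for (k in seq_along(schedule)) {
    n <- schedule[k]
    keepInformed <- if (n == 0L) seq_len(M) - 1L
                    else ranking[-seq_len(n)]
    rows[[length(rows) + 1L]] <- data.frame(
      step = k, n_removed = n, condition = "informed", control_seed = NA_integer_,
      mcc = fitStep(keepInformed, deriveSeed(seed, paste0("inf", n))))
    if (n > 0L) for (cs in seq_len(nRandomControls)) {
      drop0 <- withSeed(deriveSeed(seed, paste0("rnd", n, "_", cs)),
                        sample.int(M, n) - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        step = k, n_removed = n, condition = "random", control_seed = cs,
        mcc = fitStep(setdiff(seq_len(M) - 1L, drop0),
                      deriveSeed(seed, paste0("rndfit", n, "_", cs))))
    }
  }
  new("RoarResult", schedule = schedule, results = do.call(rbind, rows),
      method = methodLabel, model = modelLabel)
}
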