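#' Configuration for the synthetic fingerprint generator
#'
#' Bundles and validates the parameters of the generator. The generator
#' emulates curated compound classification sets: balanced active and
#' inactive classes of sparse binary vectors in which a known subset of
#' bits carries the class signal. Defaults are desk scale: 256 features
#' (the 2048-bit production width is available via \code{nFeatures}),
#' 20 planted discriminative bits, 100 compounds per class.
#'
#' @param nPerClass compounds per class (actives = inactives).
#' @param nFeatures fingerprint width.
#' @param nInformative number of planted discriminative bits.
#' @param pOnBackground probability a non-informative bit is on.
#' @param pOnActive probability an informative bit is on in an active.
#' @param pOnInactive probability an informative bit is on in an inactive.
#' @param labelNoise probability a label is flipped after bit generation.
#' @param seed integer seed.
#' @return a validated list of class \code{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nPerClass = 50, nFeatures = 64, seed = 1)
#' @export
syntheticConfig <- function(nPerClass = 100L, nFeatures = 256L,
                            nInformative = 20L, pOnBackground = 0.05,
                            pOnActive = 0.8, pOnInactive = 0.1,
                            labelNoise = 0, seed = 1L) {
  if (nPerClass < 1L) stop("nPerClass must be positive")
  if (nFeatures < 1L) stop("nFeatures must be positive")
  if (nInformative < 0L || nInformative > nFeatures)
    stop("nInformative must lie in 0..nFeatures")
  checkProbability(pOnBackground, "pOnBackground")
  checkProbability(pOnActive, "pOnActive")
  checkProbability(pOnInactive, "pOnInactive")
  checkProbability(labelNoise, "labelNoise")
  if (pOnActive < pOnInactive)
    stop("pOnActive must be >= pOnInactive (planted signal)")
  structure(list(nPerClass = as.integer(nPerClass),
                 nFeatures = as.integer(nFeatures),
                 nInformative = as.integer(nInformative),
                 pOnBackground = pOnBackground, pOnActive = pOnActive,
                 pOnInactive = pOnInactive, labelNoise = labelNoise,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic fingerprint dataset
#'
#' Draws a balanced two-class set of binary fingerprints. Informative bits
#' (chosen uniformly without replacement) are on with probability
#' \code{pOnActive} in actives and \code{pOnInactive} in inactives; all
#' other bits are on with \code{pOnBackground} in both classes. Label
#' noise, when requested, flips labels after bit generation, so planted
#' bits stay tied to the pre-noise class. Deterministic for a fixed seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{FingerprintSet} with planted feature ids in its
#'   metadata.
#' @examples
#' fps <- generateFingerprints(syntheticConfig(nPerClass = 20,
#'   nFeatures = 32, nInformative = 5, seed = 7))
#' fps
#' @export
generateFingerprints <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    stop("config must come from syntheticConfig()")
  withSeed(config$seed, {
    n <- 2L * config$nPerClass
    M <- config$nFeatures
    informative <- sort(sample.int(M, config$nInformative)) - 1L
    labels <- rep(c("active", "inactive"), each = config$nPerClass)
    p <- matrix(config$pOnBackground, n, M)
    infCols <- informative + 1L
    p[labels == "active", infCols] <- config$pOnActive
    p[labels == "inactive", infCols] <- config$pOnInactive
    bits <- matrix(as.integer(runif(n * M) < p), n, M)
    if (config$labelNoise > 0) {
      flip <- runif(n) < config$labelNoise
      labels[flip] <- ifelse(labels[flip] == "active", "inactive", "active")
    }
    ids <- sprintf("CPD%05d", seq_len(n))
    newFingerprintSet(bits, labels, ids, informative = informative,
                      config = unclass(config))
  })
}

## Internal constructor shared by the generator and the readers.
newFingerprintSet <- function(bits, labels, ids, informative = integer(0),
                              config = NULL) {
  assertBinaryMatrix(bits, "bits")
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  M <- ncol(bits)
  rn <- sprintf("f%d", seq_len(M) - 1L)
  assays <- list(bits = t(bits))
  dimnames(assays$bits) <- list(rn, ids)
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(feature_id = seq_len(M) - 1L, row.names = rn),
    colData = DataFrame(label = as.character(labels), row.names = ids))
  meta <- list(informative = as.integer(informative))
  if (!is.null(config)) meta$config <- config
  S4Vectors::metadata(se) <- meta
  new("FingerprintSet", se)
}

#' Construct a cooperative game from an explicit coalition table
#'
#' @param coalitions list of integer vectors (1-based player indices); one
#'   entry per coalition, the empty set included.
#' @param values numeric payoffs aligned with \code{coalitions}.
#' @param nPlayers number of players (at most 16).
#' @return a \linkS4class{ToyGame}.
#' @examples
#' g <- makeToyGame(list(integer(0), 1, 2, c(1, 2)), c(0, 1, 2, 4), 2)
#' coalitionValue(g, c(1, 2))
#' @export
makeToyGame <- function(coalitions, values, nPlayers) {
  nPlayers <- as.integer(nPlayers)
  if (nPlayers < 1L || nPlayers > 16L) stop("nPlayers must be in 1..16")
  if (length(coalitions) != length(values))
    stop("coalitions and values must have equal length")
  masks <- vapply(coalitions, function(s) {
    s <- as.integer(s)
    if (length(s) == 0L) return(0L)
    if (anyDuplicated(s) || any(s < 1L | s > nPlayers))
      stop("coalition members must be distinct indices in 1..nPlayers")
    sum(bitwShiftL(1L, s - 1L))
  }, integer(1))
  if (anyDuplicated(masks)) stop("duplicate coalition in table")
  full <- 2L^nPlayers
  if (length(masks) != full || !setequal(masks, seq_len(full) - 1L))
    stop("coalition table must cover all 2^n coalitions exactly once")
  v <- numeric(full)
  v[masks + 1L] <- values
  new("ToyGame", nPlayers = nPlayers, values = v)
}

#' Generate toy activity records for exercising the curation filters
#'
#' Draws records whose fields independently straddle the pass and fail
#' conditions of every curation filter, together with a ground-truth
#' \code{pass} flag computed directly from the drawn field values.
#'
#' @param seed integer seed.
#' @param n number of records (> 0).
#' @param config a \code{\link{curationConfig}} defining the pass
#'   conditions used for the ground-truth flag.
#' @return data.frame of activity records with a logical \code{pass}
#'   column.
#' @export
generateActivityRecords <- function(seed, n, config = curationConfig()) {
  if (n <= 0L) stop("n must be positive")
  withSeed(seed, {
    comments <- c("", "", "active", "inactive", "inconclusive", "not active",
                  "potential author error", "potential transcription error")
    types <- c("Ki", "Kd", "IC50", "other")
    relations <- c("=", "=", ">", "<", ">=")
    relTypes <- c("D", "D", "H", "U")
    rec <- data.frame(
      compound_id = sprintf("CHEM%05d", seq_len(n)),
      molecular_mass = round(runif(n, 150, 1400), 1),
      activity_comment = sample(comments, n, replace = TRUE),
      activity_type = sample(types, n, replace = TRUE),
      relation = sample(relations, n, replace = TRUE),
      standard_value = signif(10^runif(n, -3, 5), 3),
      target_relationship_type = sample(relTypes, n, replace = TRUE),
      confidence_score = sample(c(9L, 9L, 8L, 5L), n, replace = TRUE),
      target_id = sample(sprintf("T%03d", 1:3), n, replace = TRUE),
      stringsAsFactors = FALSE)
    rec$pass <- rec$molecular_mass <= config$maxMass &
      !(rec$activity_comment %in% config$excludedComments) &
      rec$activity_type %in% config$allowedTypes &
      rec$relation == config$requiredRelation &
      rec$standard_value >= config$potencyMin &
      rec$standard_value <= config$potencyMax &
      rec$target_relationship_type == config$requiredRelationshipType &
      rec$confidence_score == config$requiredConfidence
    rec
  })
}
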