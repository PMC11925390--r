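#' Configuration for activity-record curation
#'
#' Defaults mirror standard medicinal-chemistry curation of public
#' bioactivity data: compounds at most 1000 Da, no questionable activity
#' comments, Ki/Kd/IC50 measurements only, exact ("=") measurements inside
#' the 10 pM to 10 uM potency window (0.01 to 10000 nM), direct
#' single-protein assays (relationship type "D") at the highest assay
#' confidence score of 9, and at least 1000 qualifying actives per target
#' class. Potency is handled in nM throughout.
#'
#' @param maxMass maximum molecular mass in Da.
#' @param excludedComments activity comments that disqualify a record.
#' @param allowedTypes allowed activity measurement types.
#' @param requiredRelation required measurement relation symbol.
#' @param potencyMin,potencyMax allowed potency window in nM.
#' @param requiredRelationshipType required target relationship code.
#' @param requiredConfidence required assay confidence score.
#' @param minClassSize minimum qualifying actives per target class.
#' @return a validated list of class \code{CurationConfig}.
#' @export
curationConfig <- function(maxMass = 1000,
                           excludedComments = c("inactive", "inconclusive",
                                                "not active",
                                                "potential author error",
                                                "potential transcription error"),
                           allowedTypes = c("Ki", "Kd", "IC50"),
                           requiredRelation = "=",
                           potencyMin = 0.01, potencyMax = 10000,
                           requiredRelationshipType = "D",
                           requiredConfidence = 9L,
                           minClassSize = 1000L) {
  if (potencyMin >= potencyMax) stop("potencyMin must be < potencyMax")
  structure(list(maxMass = maxMass, excludedComments = excludedComments,
                 allowedTypes = allowedTypes,
                 requiredRelation = requiredRelation,
                 potencyMin = potencyMin, potencyMax = potencyMax,
                 requiredRelationshipType = requiredRelationshipType,
                 requiredConfidence = as.integer(requiredConfidence),
                 minClassSize = as.integer(minClassSize)),
            class = "CurationConfig")
}

curationFields <- c("compound_id", "molecular_mass", "activity_comment",
                    "activity_type", "relation", "standard_value",
                    "target_relationship_type", "confidence_score")

#' Curate activity records
#'
#' Applies the record filters in a fixed order (mass, comment, type,
#' relation, potency range, relationship type, confidence) and keeps a
#' record only if it passes all of them. The audit attributes each
#' rejection to the first failing filter; records missing a required field
#' are counted under \code{malformed}. The surviving SET is independent of
#' filter order; only the audit attribution depends on it. Duplicate
#' compound_id/target_id measurements keep the first occurrence (reported
#' in the audit under \code{duplicate}).
#'
#' @param records data.frame of activity records (see
#'   \code{\link{generateActivityRecords}} for the field layout).
#' @param config a \code{\link{curationConfig}}.
#' @param dropSmallClasses when TRUE and a \code{target_id} column is
#'   present, target classes with fewer than \code{minClassSize} survivors
#'   are dropped with a warning.
#' @return list with \code{survivors} (data.frame) and \code{audit}
#'   (named integer rejection counts, in filter order).
#' @examples
#' rec <- generateActivityRecords(1, 50)
#' cur <- curateRecords(rec, curationConfig(minClassSize = 1))
#' cur$audit
#' @export
curateRecords <- function(records, config = curationConfig(),
                          dropSmallClasses = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  missingCols <- setdiff(curationFields, colnames(records))
  if (length(missingCols))
    stop("records lack required fields: ", paste(missingCols, collapse = ", "))

  malformed <- !stats::complete.cases(records[, curationFields]) |
    (!is.na(records$standard_value) & records$standard_value <= 0)
  tests <- list(
    mass = records$molecular_mass <= config$maxMass,
    comment = !(records$activity_comment %in% config$excludedComments),
    type = records$activity_type %in% config$allowedTypes,
    relation = records$relation == config$requiredRelation,
    potency_range = records$standard_value >= config$potencyMin &
      records$standard_value <= config$potencyMax,
    relationship_type = records$target_relationship_type ==
      config$requiredRelationshipType,
    confidence = records$confidence_score == config$requiredConfidence)

  audit <- c(malformed = sum(malformed))
  rejected <- malformed
  for (nm in names(tests)) {
    fail <- !rejected & (is.na(tests[[nm]]) | !tests[[nm]])
    audit[nm] <- sum(fail)
    rejected <- rejected | fail
  }
  survivors <- records[!rejected, , drop = FALSE]

  if ("target_id" %in% colnames(survivors) && nrow(survivors)) {
    key <- paste(survivors$compound_id, survivors$target_id, sep = "\r")
    dup <- duplicated(key)
    audit["duplicate"] <- sum(dup)
    if (any(dup)) {
      message(sum(dup), " duplicate compound-target measurements; keeping first occurrence")
      survivors <- survivors[!dup, , drop = FALSE]
    }
    if (dropSmallClasses) {
      sizes <- table(survivors$target_id)
      small <- names(sizes)[sizes < config$minClassSize]
      if (length(small)) {
        warning("dropping target classes below minClassSize: ",
                paste(small, collapse = ", "))
        survivors <- survivors[!survivors$target_id %in% small, , drop = FALSE]
      }
    }
  } else audit["duplicate"] <- 0L

  list(survivors = survivors, audit = audit)
}

#' Build a balanced classification dataset from actives and a decoy pool
#'
#' Combines the active compounds with a seeded uniform random sample of
#' decoys of identical cardinality, labelled inactive.
#'
#' @param actives \linkS4class{FingerprintSet} of active compounds.
#' @param decoyPool \linkS4class{FingerprintSet} of candidate decoys,
#'   disjoint from the actives by compound id.
#' @param seed integer seed for the decoy draw.
#' @return a balanced \linkS4class{FingerprintSet}.
#' @export
buildClassificationDataset <- function(actives, decoyPool, seed) {
  nA <- ncol(actives)
  if (ncol(decoyPool) < nA)
    stop("decoy pool smaller than the active set")
  if (length(intersect(compoundIds(actives), compoundIds(decoyPool))))
    stop("decoy pool overlaps the active set by compound id")
  if (nrow(actives) != nrow(decoyPool))
    stop("feature widths differ between actives and decoy pool")
  pick <- withSeed(seed, sort(sample.int(ncol(decoyPool), nA)))
  bits <- rbind(bitMatrix(actives), bitMatrix(decoyPool)[pick, , drop = FALSE])
  labels <- rep(c("active", "inactive"), each = nA)
  ids <- c(compoundIds(actives), compoundIds(decoyPool)[pick])
  newFingerprintSet(bits, labels, ids,
                    informative = informativeFeatures(actives))
}
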