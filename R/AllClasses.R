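#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' FingerprintSet: binary fingerprints with activity labels
#'
#' A \linkS4class{SummarizedExperiment}-backed container for binary
#' molecular fingerprints. Features (bit positions) are rows and compounds
#' are columns of the \code{"bits"} assay; \code{colData} carries the
#' activity label of each compound. When a set is produced by
#' \code{\link{generateFingerprints}}, the identities of the planted
#' class-discriminative bits are stored in \code{metadata(x)$informative}
#' so that feature-recovery analyses have ground truth.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no additional slots.
#' @seealso \code{\link{bitMatrix}}, \code{\link{compoundLabels}},
#'   \code{\link{informativeFeatures}}
#' @export
setClass("FingerprintSet", contains = "SummarizedExperiment")

setValidity("FingerprintSet", function(object) {
  msg <- character()
  if (!"bits" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'bits' is required")
  else {
    b <- SummarizedExperiment::assay(object, "bits")
    if (!all(b %in% c(0, 1))) msg <- c(msg, "bits assay must be 0/1")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "compound ids (colnames) must be unique")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'label' column")
  else if (!all(object$label %in% c("active", "inactive")))
    msg <- c(msg, "labels must be 'active' or 'inactive'")
  if (length(msg)) msg else TRUE
})

#' ToyGame: an explicit cooperative game
#'
#' Stores the payoff of every coalition of a small set of players, indexed
#' by coalition bitmask (player p corresponds to bit 2^(p-1)). Used as the
#' ground-truth fixture for the exact Shapley enumerator.
#'
#' @slot nPlayers integer number of players (at most 16).
#' @slot values numeric of length 2^nPlayers; values[mask + 1] is the
#'   payoff of the coalition encoded by mask (values[1] is the empty set).
#' @export
setClass("ToyGame", representation(nPlayers = "integer", values = "numeric"))

setValidity("ToyGame", function(object) {
  n <- object@nPlayers
  if (length(n) != 1L || is.na(n) || n < 1L || n > 16L)
    return("nPlayers must be a single integer in 1..16")
  if (length(object@values) != 2^n)
    return(sprintf("values must have length 2^%d = %d (one per coalition, empty set included)",
                   n, 2^n))
  if (anyNA(object@values)) return("all coalition values must be defined")
  TRUE
})

#' ShapleyResult: per-feature attribution of one prediction
#'
#' @slot phi numeric per-feature Shapley (or KernelSHAP) values.
#' @slot baseValue numeric, the empty-coalition value v(empty) — the mean
#'   model output over the background set.
#' @slot fx numeric, the model output for the explained instance.
#' @slot method character, "exact_enumeration" or "kernel_shap".
#' @slot nSamples integer, coalition budget for sampled runs (NA for exact).
#' @slot seed integer seed for sampled runs (NA for exact).
#' @export
setClass("ShapleyResult",
         representation(phi = "numeric", baseValue = "numeric", fx = "numeric",
                        method = "character", nSamples = "integer",
                        seed = "integer"))

setValidity("ShapleyResult", function(object) {
  if (!object@method %in% c("exact_enumeration", "kernel_shap"))
    return("method must be 'exact_enumeration' or 'kernel_shap'")
  if (object@method == "exact_enumeration" &&
      abs(sum(object@phi) + object@baseValue - object@fx) > 1e-10)
    return("exact result violates efficiency: sum(phi) + base != f(x)")
  TRUE
})

#' AttributionMatrix: per-instance, per-feature importance values
#'
#' @slot values numeric matrix, instances x features; rownames are compound
#'   ids, colnames feature labels ("f<id>").
#' @slot baseValues numeric per-instance base values.
#' @slot fx numeric per-instance model outputs.
#' @slot method character attribution method label.
#' @slot model character model label.
#' @slot trial integer trial index (NA when pooled).
#' @export
setClass("AttributionMatrix",
         representation(values = "matrix", baseValues = "numeric",
                        fx = "numeric", method = "character",
                        model = "character", trial = "integer"))

setValidity("AttributionMatrix", function(object) {
  n <- nrow(object@values)
  if (length(object@baseValues) != n || length(object@fx) != n)
    return("baseValues and fx must have one entry per instance row")
  TRUE
})

#' PerformanceReport: confusion counts and derived metrics
#'
#' Holds the confusion-matrix counts of a binary activity prediction
#' (active = positive) together with precision, recall, balanced accuracy,
#' F1 and the Matthews correlation coefficient recomputable from them.
#'
#' @slot tp,fp,tn,fn integer confusion counts.
#' @slot metrics named numeric: precision, recall, balanced_accuracy, f1, mcc.
#' @export
setClass("PerformanceReport",
         representation(tp = "integer", fp = "integer", tn = "integer",
                        fn = "integer", metrics = "numeric"))

setValidity("PerformanceReport", function(object) {
  need <- c("precision", "recall", "balanced_accuracy", "f1", "mcc")
  if (!all(need %in% names(object@metrics)))
    return("metrics must contain precision, recall, balanced_accuracy, f1, mcc")
  m <- object@metrics
  if (any(m[c("precision", "recall", "balanced_accuracy", "f1")] < -1e-12, na.rm = TRUE) ||
      any(m[c("precision", "recall", "balanced_accuracy", "f1")] > 1 + 1e-12, na.rm = TRUE))
    return("precision/recall/BA/F1 must lie in [0, 1]")
  if (!is.na(m["mcc"]) && (m["mcc"] < -1 - 1e-12 || m["mcc"] > 1 + 1e-12))
    return("MCC must lie in [-1, 1]")
  TRUE
})

#' ActivityModel: a trained activity classifier
#'
#' Wraps a fitted model of one of the four supported families together
#' with everything needed to score new fingerprints: the method label, the
#' fitted object, selected hyperparameters, and (for kernel SVMs) the
#' training rows required to form cross-kernel matrices.
#'
#' @slot method one of "RFC", "FFNN", "SVM_RBF", "SVM_TAN".
#' @slot fit the underlying fitted object.
#' @slot hyper named list of hyperparameters used for the final fit.
#' @slot trainX binary training matrix (kernel SVMs only; otherwise 0-row).
#' @slot signFlip numeric +1/-1 aligning SVM decision values so that
#'   positive means active.
#' @slot outputMode "probability" or "decision"; the scalar f(x) explained
#'   by the attribution module.
#' @slot nFeatures integer width of the training representation.
#' @slot featureIds integer 0-based ids of the columns the model was
#'   trained on (relative to the originating dataset).
#' @slot info list of fitting metadata (seed, grid-search table, trial).
#' @export
setClass("ActivityModel",
         representation(method = "character", fit = "ANY", hyper = "list",
                        trainX = "matrix", signFlip = "numeric",
                        outputMode = "character", nFeatures = "integer",
                        featureIds = "integer", info = "list"))

setValidity("ActivityModel", function(object) {
  if (!object@method %in% c("RFC", "FFNN", "SVM_RBF", "SVM_TAN"))
    return("unknown method")
  if (!object@outputMode %in% c("probability", "decision"))
    return("outputMode must be 'probability' or 'decision'")
  TRUE
})

#' RoarResult: remove-and-retrain performance trace
#'
#' @slot schedule integer feature counts removed at each step.
#' @slot results data.frame with columns step, n_removed, condition
#'   ("informed"/"random"), control_seed, mcc.
#' @slot method,model character labels for the attribution method and model.
#' @export
setClass("RoarResult",
         representation(schedule = "integer", results = "data.frame",
                        method = "character", model = "character"))

setValidity("RoarResult", function(object) {
  s <- object@schedule[object@schedule > 0L]
  if (is.unsorted(s, strictly = TRUE))
    return("non-zero schedule entries must be strictly increasing")
  need <- c("step", "n_removed", "condition", "control_seed", "mcc")
  if (!all(need %in% colnames(object@results)))
    return("results must contain step, n_removed, condition, control_seed, mcc")
  TRUE
})
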