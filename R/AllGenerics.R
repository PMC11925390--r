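#' Accessors for FingerprintSet and AttributionMatrix
#'
#' \code{bitMatrix} returns the fingerprints as a compounds x features 0/1
#' matrix (the orientation classifiers consume); \code{compoundLabels} the
#' activity labels as a factor with levels \code{active}, \code{inactive};
#' \code{compoundIds} the unique compound identifiers;
#' \code{featureIds} the integer 0-based feature ids;
#' \code{informativeFeatures} the planted discriminative feature ids
#' (integer(0) when unknown); \code{attrValues} and \code{baseValues} the
#' value matrix and per-instance base values of an attribution.
#'
#' @param x a \linkS4class{FingerprintSet} or
#'   \linkS4class{AttributionMatrix}.
#' @return see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bitMatrix", function(x) standardGeneric("bitMatrix"))

#' @rdname accessors
#' @export
setGeneric("compoundLabels", function(x) standardGeneric("compoundLabels"))

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("informativeFeatures", function(x) standardGeneric("informativeFeatures"))

#' @rdname accessors
#' @export
setGeneric("attrValues", function(x) standardGeneric("attrValues"))

#' @rdname accessors
#' @export
setGeneric("baseValues", function(x) standardGeneric("baseValues"))

#' Query a cooperative game
#'
#' @param game a \linkS4class{ToyGame}.
#' @param coalition integer vector of 1-based player indices (may be empty).
#' @return the payoff of the coalition.
#' @export
setGeneric("coalitionValue", function(game, coalition) standardGeneric("coalitionValue"))

#' Model score for new fingerprints
#'
#' Returns the scalar output f(x) that attributions explain: the
#' probability of the active class for RFC and FFNN models, the signed
#' decision value (positive = active) for the SVMs.
#'
#' @param model an \linkS4class{ActivityModel}.
#' @param X 0/1 matrix, compounds x features, with the model's feature width.
#' @return numeric vector, one score per row of \code{X}.
#' @export
setGeneric("predictScore", function(model, X) standardGeneric("predictScore"))

#' Predicted class labels
#'
#' @param model an \linkS4class{ActivityModel}.
#' @param X 0/1 matrix, compounds x features.
#' @return factor with levels active/inactive.
#' @export
setGeneric("predictLabel", function(model, X) standardGeneric("predictLabel"))
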