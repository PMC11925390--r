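#' @importFrom SummarizedExperiment assay assayNames colData SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

#' @rdname accessors
#' @aliases bitMatrix,FingerprintSet-method
setMethod("bitMatrix", "FingerprintSet", function(x) {
  t(assay(x, "bits"))
})

#' @rdname accessors
#' @aliases compoundLabels,FingerprintSet-method
setMethod("compoundLabels", "FingerprintSet", function(x) {
  factor(x$label, levels = c("active", "inactive"))
})

#' @rdname accessors
#' @aliases compoundIds,FingerprintSet-method
setMethod("compoundIds", "FingerprintSet", function(x) colnames(x))

#' @rdname accessors
#' @aliases featureIds,FingerprintSet-method
setMethod("featureIds", "FingerprintSet", function(x) {
  SummarizedExperiment::rowData(x)$feature_id
})

#' @rdname accessors
#' @aliases informativeFeatures,FingerprintSet-method
setMethod("informativeFeatures", "FingerprintSet", function(x) {
  inf <- metadata(x)$informative
  if (is.null(inf)) integer(0) else as.integer(inf)
})

#' @rdname accessors
#' @aliases attrValues,AttributionMatrix-method
setMethod("attrValues", "AttributionMatrix", function(x) x@values)

#' @rdname accessors
#' @aliases baseValues,AttributionMatrix-method
setMethod("baseValues", "AttributionMatrix", function(x) x@baseValues)

#' @rdname coalitionValue
#' @aliases coalitionValue,ToyGame-method
setMethod("coalitionValue", "ToyGame", function(game, coalition) {
  coalition <- as.integer(coalition)
  if (length(coalition)) {
    if (anyDuplicated(coalition) || any(coalition < 1L | coalition > game@nPlayers))
      stop("coalition must be distinct player indices in 1..nPlayers")
    mask <- sum(bitwShiftL(1L, coalition - 1L))
  } else mask <- 0L
  game@values[mask + 1L]
})

setMethod("show", "FingerprintSet", function(object) {
  lab <- table(factor(object$label, levels = c("active", "inactive")))
  cat("FingerprintSet with", ncol(object), "compounds x", nrow(object),
      "features\n")
  cat("  active:", lab[["active"]], " inactive:", lab[["inactive"]], "\n")
  inf <- informativeFeatures(object)
  if (length(inf))
    cat("  planted informative features:", length(inf), "\n")
})

setMethod("show", "ToyGame", function(object) {
  cat("ToyGame with", object@nPlayers, "players (",
      length(object@values), "coalition values )\n")
  cat("  v(empty) =", object@values[1L],
      " v(grand) =", object@values[length(object@values)], "\n")
})

setMethod("show", "ShapleyResult", function(object) {
  cat("ShapleyResult [", object@method, "] over",
      length(object@phi), "features\n")
  cat("  base =", format(object@baseValue, digits = 4),
      " f(x) =", format(object@fx, digits = 4),
      " sum(phi) =", format(sum(object@phi), digits = 4), "\n")
})

setMethod("show", "AttributionMatrix", function(object) {
  cat("AttributionMatrix:", nrow(object@values), "instances x",
      ncol(object@values), "features\n")
  cat("  method:", object@method, " model:", object@model,
      if (!is.na(object@trial)) paste(" trial:", object@trial), "\n")
})

setMethod("show", "PerformanceReport", function(object) {
  cat("PerformanceReport  TP:", object@tp, " FP:", object@fp,
      " TN:", object@tn, " FN:", object@fn, "\n")
  print(round(object@metrics, 4))
})

setMethod("show", "ActivityModel", function(object) {
  cat("ActivityModel [", object@method, "] on", object@nFeatures,
      "features; output:", object@outputMode, "\n")
  if (length(object@hyper))
    cat("  hyper:", paste(names(object@hyper), unlist(object@hyper),
                          sep = "=", collapse = ", "), "\n")
})

setMethod("show", "RoarResult", function(object) {
  cat("RoarResult [", object@method, "/", object@model, "]:",
      length(object@schedule), "schedule steps\n")
})
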