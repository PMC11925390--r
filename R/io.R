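#' Read and write fingerprint datasets
#'
#' Two plain-text formats: \code{"csv"} (one row per compound:
#' compound_id, label, then one 0/1 column per bit, named f0, f1, ...)
#' and the compact sparse \code{"onbits"} format (compound_id, label,
#' semicolon-separated 0-based on-bit indices; the feature width is kept
#' in a \code{#n_features=} header comment).
#'
#' @param x a \linkS4class{FingerprintSet}.
#' @param path file path.
#' @param format "csv" or "onbits".
#' @return \code{readFingerprints} returns a
#'   \linkS4class{FingerprintSet}; \code{writeFingerprints} its path,
#'   invisibly.
#' @export
writeFingerprints <- function(x, path, format = c("csv", "onbits")) {
  format <- match.arg(format)
  bits <- bitMatrix(x)
  if (format == "csv") {
    df <- data.frame(compound_id = compoundIds(x),
                     label = as.character(compoundLabels(x)),
                     bits, check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#n_features=%d", ncol(bits)), con)
    writeLines("compound_id,label,onbits", con)
    on <- apply(bits, 1, function(b) paste(which(b == 1) - 1L, collapse = ";"))
    writeLines(paste(compoundIds(x), as.character(compoundLabels(x)), on,
                     sep = ","), con)
  }
  invisible(path)
}

#' @rdname writeFingerprints
#' @export
readFingerprints <- function(path, format = c("csv", "onbits")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    bits <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(bits) <- "integer"
    newFingerprintSet(bits, df$label, df$compound_id)
  } else {
    lines <- readLines(path)
    header <- grep("^#n_features=", lines, value = TRUE)
    if (!length(header)) stop("onbits file lacks the #n_features header")
    M <- as.integer(sub("^#n_features=", "", header[1L]))
    body <- lines[!grepl("^#", lines)][-1L]
    parts <- strsplit(body, ",", fixed = TRUE)
    bits <- matrix(0L, length(parts), M)
    for (i in seq_along(parts)) {
      onStr <- if (length(parts[[i]]) >= 3L) parts[[i]][3L] else ""
      if (nzchar(onStr))
        bits[i, as.integer(strsplit(onStr, ";", fixed = TRUE)[[1L]]) + 1L] <- 1L
    }
    newFingerprintSet(bits, vapply(parts, `[`, "", 2L),
                      vapply(parts, `[`, "", 1L))
  }
}

#' Read and write activity-record tables
#'
#' @param records data.frame of activity records.
#' @param path CSV file path.
#' @return the records (reader) or the path, invisibly (writer).
#' @export
writeActivityRecords <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeActivityRecords
#' @export
readActivityRecords <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write attribution matrices
#'
#' Long-format CSV (compound_id, feature_id, value) plus a JSON sidecar
#' (\code{<path>.json}) holding the method, model, trial, per-instance
#' base values and model outputs.
#'
#' @param attr an \linkS4class{AttributionMatrix}.
#' @param path CSV file path; the sidecar is written next to it.
#' @return the attribution (reader) or the path, invisibly (writer).
#' @export
writeAttributions <- function(attr, path) {
  V <- attrValues(attr)
  ids <- rownames(V) %||% as.character(seq_len(nrow(V)))
  fids <- as.integer(sub("^f", "", colnames(V)))
  long <- data.frame(compound_id = rep(ids, each = ncol(V)),
                     feature_id = rep(fids, nrow(V)),
                     value = as.vector(t(V)), stringsAsFactors = FALSE)
  write.csv(long, path, row.names = FALSE)
  side <- list(method = attr@method, model = attr@model,
               trial = attr@trial, compound_ids = ids,
               feature_ids = fids, base_values = attr@baseValues,
               fx = attr@fx)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeAttributions
#' @export
readAttributions <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ids <- as.character(side$compound_ids)
  fids <- as.integer(side$feature_ids)
  V <- matrix(NA_real_, length(ids), length(fids),
              dimnames = list(ids, sprintf("f%d", fids)))
  V[cbind(match(long$compound_id, ids), match(long$feature_id, fids))] <-
    long$value
  new("AttributionMatrix", values = V,
      baseValues = as.numeric(side$base_values), fx = as.numeric(side$fx),
      method = side$method, model = side$model,
      trial = as.integer(side$trial %||% NA_integer_))
}

#' Write a ROAR result as CSV
#'
#' @param roar a \linkS4class{RoarResult}.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
writeRoar <- function(roar, path) {
  df <- roar@results
  df$method <- roar@method
  df$model <- roar@model
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
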