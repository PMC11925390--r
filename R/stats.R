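#' Cumulative present/absent attribution sums
#'
#' For every correctly predicted test compound, sums its attribution
#' values separately over the features present (bit = 1) and absent
#' (bit = 0) in its fingerprint, tagged by true class. Both raw sums and
#' sums normalised by the instance's absolute attribution total are
#' reported.
#'
#' @param attr an \linkS4class{AttributionMatrix}.
#' @param bits 0/1 matrix aligned row-by-row with \code{attr} (same
#'   feature columns as the attribution).
#' @param labels true classes aligned with \code{attr} rows.
#' @param predictions predicted classes aligned with \code{attr} rows.
#' @param correctOnly restrict to correctly predicted compounds (default
#'   TRUE, matching the cumulative analysis design).
#' @return data.frame with compound_id, class, present_sum, absent_sum,
#'   present_sum_norm, absent_sum_norm.
#' @export
cumulativePresentAbsent <- function(attr, bits, labels, predictions,
                                    correctOnly = TRUE) {
  V <- attrValues(attr)
  if (!is.matrix(bits) || !identical(dim(bits), dim(V)))
    stop("bits must be a matrix aligned with the attribution values")
  labels <- as.character(labels); predictions <- as.character(predictions)
  if (length(labels) != nrow(V) || length(predictions) != nrow(V))
    stop("labels/predictions misaligned with attribution rows")
  keep <- if (correctOnly) labels == predictions else rep(TRUE, nrow(V))
  present <- rowSums(V * bits)
  absent <- rowSums(V * (1 - bits))
  tot <- rowSums(abs(V))
  tot[tot == 0] <- NA_real_
  out <- data.frame(compound_id = rownames(V) %||% as.character(seq_len(nrow(V))),
                    class = labels,
                    present_sum = present, absent_sum = absent,
                    present_sum_norm = present / tot,
                    absent_sum_norm = absent / tot,
                    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gini coefficient of an importance vector
#'
#' Dispersion of feature importance magnitudes for a single compound:
#' with the non-zero absolute values X sorted ascending and i their rank,
#' G = sum((2i - n - 1) X_i) / (n sum(X_i)). Zero entries are removed
#' before computation (the formula applies to non-zero values only); an
#' all-zero vector is an error. A single surviving value yields 0.
#'
#' @param values numeric attribution values (absolute values are used).
#' @return Gini coefficient in [0, 1).
#' @examples
#' giniCoefficient(c(1, 2, 3, 4))  # 0.25
#' @export
giniCoefficient <- function(values) {
  x <- abs(values)
  x <- x[x != 0]
  if (!length(x)) stop("Gini undefined for an all-zero vector")
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Compacity: features required to reach attribution-mass thresholds
#'
#' With absolute attribution values sorted descending, m(t) is the
#' smallest number of features whose cumulative sum reaches fraction t of
#' the total absolute attribution; compacity reports m(t) as a percentage
#' of the total feature count, per threshold. Non-decreasing in t.
#'
#' @param values numeric attribution values of one instance.
#' @param thresholds fractions in (0, 1); default 0.1 ... 0.9.
#' @return data.frame with threshold, n_features, pct.
#' @examples
#' compacity(c(0.5, 0.3, 0.1, 0.1), 0.7)  # 2 features, 50 percent
#' @export
compacity <- function(values, thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (!length(values)) stop("empty value vector")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must lie in (0, 1)")
  x <- sort(abs(values), decreasing = TRUE)
  tot <- sum(x)
  if (tot == 0) stop("compacity undefined for an all-zero vector")
  cs <- cumsum(x)
  m <- vapply(thresholds, function(t)
    which(cs >= t * tot - 1e-12)[1L], integer(1))
  data.frame(threshold = thresholds, n_features = m,
             pct = 100 * m / length(values))
}

#' Consistency: per-feature spread of normalised attributions
#'
#' Normalises each instance's attribution row by its absolute sum, then
#' reports, for every feature, the sample standard deviation of its
#' normalised values across the instances where that value is non-zero.
#' Features with fewer than two qualifying instances are NA; rows with an
#' all-zero attribution are skipped with a warning.
#'
#' @param attr an \linkS4class{AttributionMatrix}.
#' @return named numeric vector, one entry per feature.
#' @export
consistencyStd <- function(attr) {
  V <- attrValues(attr)
  if (!nrow(V)) stop("empty attribution matrix")
  tot <- rowSums(abs(V))
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero attribution rows skipped")
    V <- V[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  N <- V / tot
  apply(N, 2, function(col) {
    nz <- col[col != 0]
    if (length(nz) < 2L) NA_real_ else sd(nz)
  })
}

subsetMask <- function(bits, subset) {
  switch(subset,
         all = matrix(TRUE, nrow(bits), ncol(bits)),
         present = bits == 1,
         absent = bits == 0,
         stop("subset must be 'all', 'present' or 'absent'"))
}

#' Pearson correlation between two attribution methods
#'
#' Pools all (instance, feature) pairs of the requested feature state and
#' correlates the two methods' values. Zero variance in either pooled
#' vector makes the correlation undefined (NA).
#'
#' @param attrA,attrB aligned \linkS4class{AttributionMatrix} objects.
#' @param bits 0/1 matrix aligned with the attribution rows (required for
#'   the present/absent subsets).
#' @param subset "all", "present" or "absent".
#' @return Pearson r, or NA when undefined.
#' @export
methodCorrelation <- function(attrA, attrB, bits = NULL, subset = "all") {
  A <- attrValues(attrA); B <- attrValues(attrB)
  if (!identical(dim(A), dim(B)))
    stop("attribution matrices misaligned")
  if (subset != "all" && is.null(bits))
    stop("bits required for present/absent subsets")
  mask <- if (subset == "all") matrix(TRUE, nrow(A), ncol(A))
          else subsetMask(bits, subset)
  a <- A[mask]; b <- B[mask]
  if (length(a) < 2L || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Faithfulness of an attribution row
#'
#' Flips each feature bit of the instance in turn (1 to 0 or 0 to 1),
#' records the marginal output change m_i = f(x) - f(x with bit i
#' flipped), and returns the Pearson correlation between the attribution
#' values and m over the requested feature subset. Undefined (NA) for
#' subsets smaller than two features or zero-variance vectors.
#'
#' @param model an \linkS4class{ActivityModel}, or a plain scoring
#'   function taking a 0/1 matrix and returning numeric outputs.
#' @param instance 0/1 vector.
#' @param w numeric attribution values for the instance.
#' @param subset "all", "present" or "absent".
#' @return Pearson r, or NA when undefined.
#' @export
faithfulness <- function(model, instance, w, subset = "all") {
  instance <- as.numeric(instance)
  M <- length(instance)
  if (length(w) != M) stop("attribution length mismatch")
  sel <- switch(subset, all = seq_len(M),
                present = which(instance == 1),
                absent = which(instance == 0),
                stop("subset must be 'all', 'present' or 'absent'"))
  if (length(sel) < 2L) return(NA_real_)
  flipped <- matrix(instance, length(sel), M, byrow = TRUE)
  flipped[cbind(seq_along(sel), sel)] <- 1 - instance[sel]
  score <- scoreFun(model)
  fx <- score(matrix(instance, nrow = 1))
  m <- fx - score(flipped)
  if (sd(w[sel]) == 0 || sd(m) == 0) return(NA_real_)
  cor(w[sel], m)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, monotone and >= the raw values.
#' @examples
#' holmAdjust(c(0.01, 0.03, 0.04))  # 0.03 0.06 0.06
#' @export
holmAdjust <- function(p) p.adjust(p, method = "holm")

significanceTier <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p <= 1e-4, "****",
  ifelse(p <= 1e-3, "***",
  ifelse(p <= 1e-2, "**",
  ifelse(p <= 5e-2, "*", "ns")))))
}

#' Paired Wilcoxon signed-rank tests with Holm-Bonferroni correction
#'
#' Runs a two-sided Wilcoxon signed-rank test for every labelled pair of
#' value vectors, adjusts the p-values across the family with the Holm
#' step-down procedure, and attaches significance tiers: **** for
#' adjusted p <= 1e-4, *** <= 1e-3, ** <= 1e-2, * <= 5e-2, else ns.
#' Pairs with all-zero differences are degenerate and reported NA (they
#' do not enter the Holm family).
#'
#' @param pairs named list; each element a list/data.frame with numeric
#'   \code{x} and \code{y} of equal length >= 5.
#' @return data.frame with label, p, p_adj, tier.
#' @export
wilcoxonHolm <- function(pairs) {
  if (!length(pairs)) stop("empty test family")
  labs <- names(pairs) %||% as.character(seq_along(pairs))
  p <- vapply(seq_along(pairs), function(k) {
    x <- pairs[[k]]$x; y <- pairs[[k]]$y
    if (length(x) != length(y) || length(x) < 5L)
      stop("pair '", labs[k], "': vectors must have equal length >= 5")
    if (all(x - y == 0)) return(NA_real_)
    suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                 alternative = "two.sided")$p.value)
  }, numeric(1))
  adj <- rep(NA_real_, length(p))
  adj[!is.na(p)] <- holmAdjust(p[!is.na(p)])
  data.frame(label = labs, p = p, p_adj = adj,
             tier = significanceTier(adj), stringsAsFactors = FALSE)
}
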