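#' Pipeline configuration
#'
#' Bundles every stage's parameters and validates them up front (an
#' unknown model family fails here, before any compute). All stage seeds
#' are derived deterministically from \code{masterSeed}.
#'
#' @param synthetic a \code{\link{syntheticConfig}}.
#' @param models list of \code{\link{modelSpec}} objects.
#' @param nTrials,testFraction outer trial design.
#' @param innerFolds inner shuffle-split folds for grid search.
#' @param nExplain test instances attributed per trial (correctly
#'   predicted ones preferred, classes interleaved).
#' @param backgroundSize background rows for the value function (at most).
#' @param nSamples KernelSHAP coalition budget (NULL: 2 x features).
#' @param enumTopM feature count for the exact-enumeration protocol: the
#'   model is retrained on the top-M features of the KernelSHAP ranking
#'   and explained exactly at that width.
#' @param thresholds compacity thresholds.
#' @param correctOnly restrict statistics to correctly predicted compounds.
#' @param roarControls random-removal control seeds per ROAR step.
#' @param roarTrial 1-based index of the trial used for ROAR retraining.
#' @param masterSeed integer master seed.
#' @return a validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           models = list(modelSpec("SVM_TAN",
                                                   grid = list(C = c(0.1, 1, 10)))),
                           nTrials = 10L, testFraction = 0.1,
                           innerFolds = 10L, nExplain = 5L,
                           backgroundSize = 100L, nSamples = NULL,
                           enumTopM = 12L, thresholds = seq(0.1, 0.9, 0.1),
                           correctOnly = TRUE, roarControls = 5L,
                           roarTrial = 1L, masterSeed = 1L) {
  if (!inherits(synthetic, "SyntheticConfig"))
    stop("synthetic must come from syntheticConfig()")
  if (!length(models) || !all(vapply(models, inherits, TRUE, "ModelSpec")))
    stop("models must be a non-empty list of modelSpec() objects")
  if (enumTopM > 16L) stop("enumTopM is capped at 16 (exact enumeration)")
  if (roarTrial < 1L || roarTrial > nTrials) stop("roarTrial out of range")
  structure(list(synthetic = synthetic, models = models,
                 nTrials = as.integer(nTrials), testFraction = testFraction,
                 innerFolds = as.integer(innerFolds),
                 nExplain = as.integer(nExplain),
                 backgroundSize = as.integer(backgroundSize),
                 nSamples = nSamples, enumTopM = as.integer(enumTopM),
                 thresholds = thresholds, correctOnly = correctOnly,
                 roarControls = as.integer(roarControls),
                 roarTrial = as.integer(roarTrial),
                 masterSeed = as.integer(masterSeed)),
            class = "PipelineConfig")
}

writeTable <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

## interleave correctly predicted actives and inactives, take n
pickExplainRows <- function(testIdx, truth, pred, n, correctOnly = TRUE) {
  ok <- if (correctOnly) truth == pred else rep(TRUE, length(testIdx))
  act <- testIdx[ok & truth == "active"]
  ina <- testIdx[ok & truth == "inactive"]
  len <- max(length(act), length(ina))
  pool <- as.vector(rbind(c(act, rep(NA, len - length(act))),
                          c(ina, rep(NA, len - length(ina)))))
  head(pool[!is.na(pool)], n)
}

#' Run the full analysis pipeline
#'
#' Executes generate, curate, train, explain (KernelSHAP at full feature
#' width plus exact enumeration on a top-M retrained representation),
#' compare and ROAR, writing all statistic tables as CSV and a JSON run
#' manifest into \code{outDir}. Deterministic: a rerun with an identical
#' configuration reproduces every table byte for byte.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @param verbose log stage progress.
#' @return invisibly, a list with the performance table, pooled
#'   attributions, statistic tables, ROAR results and the manifest path.
#' @export
runPipeline <- function(config, outDir, verbose = FALSE) {
  if (!inherits(config, "PipelineConfig"))
    stop("config must come from pipelineConfig()")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  master <- config$masterSeed
  files <- character(0)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## -- generate -------------------------------------------------------
  fps <- stage("generate", {
    syn <- config$synthetic
    syn$seed <- deriveSeed(master, "generate")
    ds <- generateFingerprints(syn)
    files <- c(files, writeFingerprints(ds, file.path(outDir, "fingerprints.csv")))
    ds
  })
  X <- bitMatrix(fps)
  y <- compoundLabels(fps)
  M <- ncol(X)

  ## -- curate (demonstration on a generated record table) -------------
  stage("curate", {
    rec <- generateActivityRecords(deriveSeed(master, "records"), 60L)
    cur <- curateRecords(rec)
    files <- c(files,
                writeTable(rec, file.path(outDir, "activity_records.csv")),
                writeTable(data.frame(filter = names(cur$audit),
                                      rejected = as.integer(cur$audit)),
                           file.path(outDir, "curation_audit.csv")))
  })

  ## -- train ----------------------------------------------------------
  splits <- splitTrials(y, config$nTrials, config$testFraction,
                        deriveSeed(master, "split"))
  trained <- stage("train", {
    out <- list()
    perf <- list()
    for (spec in config$models) for (sp in splits) {
      m <- tuneAndTrain(fps, sp, spec,
                        seed = deriveSeed(master, paste0("tune_", spec$method,
                                                         "_", sp$trial)),
                        innerFolds = config$innerFolds)
      rep <- evaluateModel(m, fps, sp$test)
      out[[paste(spec$method, sp$trial, sep = "_")]] <-
        list(model = m, split = sp, report = rep)
      perf[[length(perf) + 1L]] <- data.frame(
        model = spec$method, trial = sp$trial,
        seed = m@info$seed, tp = rep@tp, fp = rep@fp, tn = rep@tn,
        fn = rep@fn, t(rep@metrics),
        hyper = paste(names(m@hyper), unlist(m@hyper), sep = "=",
                      collapse = ";"))
    }
    perf <- do.call(rbind, perf)
    files <- c(files, writeTable(perf, file.path(outDir, "performance.csv")))
    list(models = out, performance = perf)
  })

  ## -- explain --------------------------------------------------------
  pool <- stage("explain", {
    perModel <- list()
    for (spec in config$models) {
      meth <- spec$method
      kernelParts <- list(); meta <- list()
      for (sp in splits) {
        ent <- trained$models[[paste(meth, sp$trial, sep = "_")]]
        m <- ent$model
        bg <- sampleBackground(X[sp$train, , drop = FALSE],
                               config$backgroundSize,
                               deriveSeed(master, paste0("bg_", meth, "_",
                                                         sp$trial)))
        pred <- predictLabel(m, X[sp$test, , drop = FALSE])
        rows <- pickExplainRows(sp$test, as.character(y[sp$test]),
                                as.character(pred), config$nExplain,
                                config$correctOnly)
        if (!length(rows)) next
        at <- attributeDataset(m, fps, rows, "kernel_shap", bg,
                               nSamples = config$nSamples,
                               seed = deriveSeed(master, paste0("ks_", meth,
                                                                "_", sp$trial)),
                               trial = sp$trial, verbose = verbose)
        rownames(at@values) <- paste0(compoundIds(fps)[rows], "_t", sp$trial)
        kernelParts[[length(kernelParts) + 1L]] <- at
        meta[[length(meta) + 1L]] <- data.frame(
          row = rownames(at@values), idx = rows, trial = sp$trial,
          label = as.character(y[rows]),
          prediction = as.character(predictLabel(m, X[rows, , drop = FALSE])),
          stringsAsFactors = FALSE)
        files <- c(files, writeAttributions(
          at, file.path(outDir, sprintf("attr_%s_trial%d_kernel_shap.csv",
                                        meth, sp$trial))))
      }
      kAttr <- new("AttributionMatrix",
                   values = do.call(rbind, lapply(kernelParts, attrValues)),
                   baseValues = unlist(lapply(kernelParts, baseValues)),
                   fx = unlist(lapply(kernelParts, slot, "fx")),
                   method = "kernel_shap", model = meth, trial = NA_integer_)
      meta <- do.call(rbind, meta)

      ## exact-enumeration protocol: retrain on the top-M features of the
      ## KernelSHAP ranking and explain at that width
      ranking <- globalFeatureRanking(kAttr)
      topM <- sort(ranking[(M - config$enumTopM + 1L):M])
      exactParts <- list()
      for (sp in splits) {
        rows <- meta$idx[meta$trial == sp$trial]
        if (!length(rows)) next
        ent <- trained$models[[paste(meth, sp$trial, sep = "_")]]
        mr <- trainModel(X[sp$train, topM + 1L, drop = FALSE], y[sp$train],
                         meth, hyper = ent$model@hyper,
                         seed = deriveSeed(master, paste0("ex_", meth, "_",
                                                          sp$trial)),
                         outputMode = spec$outputMode, featureIds = topM)
        bg <- sampleBackground(X[sp$train, topM + 1L, drop = FALSE],
                               config$backgroundSize,
                               deriveSeed(master, paste0("bg_", meth, "_",
                                                         sp$trial)))
        at <- attributeDataset(mr, X[, topM + 1L, drop = FALSE], rows,
                               "exact_enumeration", bg, trial = sp$trial)
        rownames(at@values) <- paste0(compoundIds(fps)[rows], "_t", sp$trial)
        exactParts[[length(exactParts) + 1L]] <- at
        files <- c(files, writeAttributions(
          at, file.path(outDir, sprintf("attr_%s_trial%d_exact.csv",
                                        meth, sp$trial))))
      }
      eAttr <- new("AttributionMatrix",
                   values = do.call(rbind, lapply(exactParts, attrValues)),
                   baseValues = unlist(lapply(exactParts, baseValues)),
                   fx = unlist(lapply(exactParts, slot, "fx")),
                   method = "exact_enumeration", model = meth,
                   trial = NA_integer_)
      perModel[[meth]] <- list(kernel = kAttr, exact = eAttr, meta = meta,
                               ranking = ranking, topM = topM)
    }
    perModel
  })

  ## -- compare --------------------------------------------------------
  statsOut <- stage("compare", {
    cum <- gin <- comp <- cons <- corr <- list()
    wilPairs <- list()
    for (meth in names(pool)) {
      pm <- pool[[meth]]
      for (kind in c("kernel", "exact")) {
        at <- pm[[kind]]
        cols <- if (kind == "kernel") seq_len(M) else pm$topM + 1L
        bits <- X[pm$meta$idx, cols, drop = FALSE]
        cc <- cumulativePresentAbsent(at, bits, pm$meta$label,
                                      pm$meta$prediction,
                                      correctOnly = config$correctOnly)
        cc <- cbind(model = meth, method = at@method, cc)
        cum[[length(cum) + 1L]] <- cc
        for (cl in c("active", "inactive")) {
          px <- cc$present_sum[cc$class == cl]
          ax <- cc$absent_sum[cc$class == cl]
          if (length(px) >= 5L)
            wilPairs[[paste(meth, at@method, cl, sep = "/")]] <-
              list(x = px, y = ax)
        }
        V <- attrValues(at)
        for (i in seq_len(nrow(V))) {
          if (config$correctOnly &&
              pm$meta$label[i] != pm$meta$prediction[i]) next
          for (state in c("present", "absent")) {
            vals <- V[i, subsetMask(bits, state)[i, ]]
            g <- tryCatch(giniCoefficient(vals), error = function(e) NA_real_)
            gin[[length(gin) + 1L]] <- data.frame(
              model = meth, method = at@method, compound = rownames(V)[i],
              class = pm$meta$label[i], state = state, gini = g)
          }
          cp <- compacity(V[i, ], config$thresholds)
          comp[[length(comp) + 1L]] <- cbind(
            model = meth, method = at@method, compound = rownames(V)[i],
            class = pm$meta$label[i], cp)
        }
        cs <- consistencyStd(at)
        cons[[length(cons) + 1L]] <- data.frame(
          model = meth, method = at@method, feature = names(cs),
          std = as.numeric(cs))
      }
      ## kernel vs exact on the shared top-M columns
      kTop <- new("AttributionMatrix",
                  values = attrValues(pm$kernel)[, pm$topM + 1L, drop = FALSE],
                  baseValues = baseValues(pm$kernel), fx = pm$kernel@fx,
                  method = "kernel_shap", model = meth, trial = NA_integer_)
      bitsTop <- X[pm$meta$idx, pm$topM + 1L, drop = FALSE]
      for (ss in c("all", "present", "absent"))
        corr[[length(corr) + 1L]] <- data.frame(
          model = meth, methodA = "kernel_shap", methodB = "exact_enumeration",
          subset = ss, r = methodCorrelation(kTop, pm$exact, bitsTop, ss))
    }
    ## kernel-vs-kernel across models at full width (aligned rows only)
    mm <- names(pool)
    if (length(mm) > 1L) for (i in seq_along(mm)) for (j in seq_along(mm)) {
      if (i >= j) next
      a <- pool[[mm[i]]]; b <- pool[[mm[j]]]
      shared <- intersect(rownames(attrValues(a$kernel)),
                          rownames(attrValues(b$kernel)))
      if (length(shared) < 2L) next
      sub <- function(p) new("AttributionMatrix",
        values = attrValues(p$kernel)[shared, , drop = FALSE],
        baseValues = baseValues(p$kernel)[match(shared, rownames(attrValues(p$kernel)))],
        fx = p$kernel@fx[match(shared, rownames(attrValues(p$kernel)))],
        method = "kernel_shap", model = "x", trial = NA_integer_)
      bitsS <- X[a$meta$idx[match(shared, a$meta$row)], , drop = FALSE]
      for (ss in c("all", "present", "absent"))
        corr[[length(corr) + 1L]] <- data.frame(
          model = paste(mm[i], mm[j], sep = "|"),
          methodA = "kernel_shap", methodB = "kernel_shap", subset = ss,
          r = methodCorrelation(sub(a), sub(b), bitsS, ss))
    }
    wil <- if (length(wilPairs)) wilcoxonHolm(wilPairs) else
      data.frame(label = character(0), p = numeric(0),
                 p_adj = numeric(0), tier = character(0))
    tabs <- list(cumulative = do.call(rbind, cum),
                 gini = do.call(rbind, gin),
                 compacity = do.call(rbind, comp),
                 consistency = do.call(rbind, cons),
                 correlation = do.call(rbind, corr),
                 wilcoxon = wil)
    for (nm in names(tabs))
      files <- c(files, writeTable(tabs[[nm]],
                                    file.path(outDir, paste0(nm, ".csv"))))
    tabs
  })

  ## -- roar -----------------------------------------------------------
  roarOut <- stage("roar", {
    out <- list()
    sp <- splits[[config$roarTrial]]
    for (meth in names(pool)) {
      ent <- trained$models[[paste(meth, sp$trial, sep = "_")]]
      rr <- roarRun(fps, sp, meth, ent$model@hyper, pool[[meth]]$ranking,
                    schedule = c(0L, roarSchedule(M)),
                    nRandomControls = config$roarControls,
                    seed = deriveSeed(master, paste0("roar_", meth)),
                    methodLabel = "kernel_shap", modelLabel = meth)
      files <- c(files, writeRoar(rr, file.path(outDir,
                                                 paste0("roar_", meth, ".csv"))))
      out[[meth]] <- rr
    }
    out
  })

  ## -- manifest -------------------------------------------------------
  manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    list(package = "ShapCompare",
         version = as.character(packageVersion("ShapCompare")),
         master_seed = master,
         config = config[setdiff(names(config), c("models", "synthetic"))],
         synthetic = unclass(config$synthetic),
         models = lapply(config$models, unclass),
         files = sort(basename(unique(files)))),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dataset = fps, performance = trained$performance,
                 attributions = pool, stats = statsOut, roar = roarOut,
                 manifest = manifest, files = files))
}
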