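# ShapCompare

Do different Shapley-value attribution methods tell the same story about
*why* a compound activity model predicts what it predicts? ShapCompare is
an R package for answering that question quantitatively. It is aimed at
cheminformaticians and ML practitioners who train binary activity
classifiers on molecular fingerprints and want to audit the consistency
of their model explanations rather than trust a single attribution tool.

## What it computes

The core quantity is the Shapley value of a fingerprint bit *p* for one
prediction: with *T* the feature set and ν(𝒮) the expected model output
when only the coalition 𝒮 is fixed to the compound's bits (the rest
marginalised over a training background),

    φ_p = Σ_{𝒮 ⊆ T∖{p}}  |𝒮|! (|T|−|𝒮|−1)! / |T|!  · (ν(𝒮∪{p}) − ν(𝒮))

The package computes φ two ways — exact coalition enumeration (≤ 16
features) and KernelSHAP, the Shapley-kernel weighted regression with
exact efficiency constraint — and then compares the resulting
importance distributions with the statistics used for this purpose in
molecular machine learning: cumulative present/absent-feature sums,
Gini coefficients, compacity curves, per-feature consistency,
between-method Pearson correlation, faithfulness against single-bit
flips, remove-and-retrain (ROAR) curves, and Wilcoxon signed-rank tests
with Holm–Bonferroni correction.

Around that core it provides everything needed to run the study
end-to-end without external data: a seeded generator of balanced
fingerprint datasets with planted discriminative bits, activity-record
curation filters (mass, activity comments, measurement type, "=" 
relation, 10 pM–10 µM potency window, direct single-protein assays,
confidence score 9), and four classifier families — random forest,
feed-forward network, RBF- and Tanimoto-kernel SVMs — with stratified
shuffle-split trials and grid-search tuning.

## Worked example

```r
library(ShapCompare)

fps <- generateFingerprints(syntheticConfig(nPerClass = 40, nFeatures = 16,
                                            nInformative = 4, seed = 7))
sp <- splitTrials(compoundLabels(fps), nTrials = 1, seed = 3)[[1]]
X <- bitMatrix(fps)
model <- trainModel(X[sp$train, ], compoundLabels(fps)[sp$train],
                    "SVM_TAN", list(C = 1), seed = 11)
evaluateModel(model, fps, sp$test)
#> PerformanceReport  TP: 4  FP: 1  TN: 3  FN: 0
#>         precision            recall balanced_accuracy                f1
#>            0.8000            1.0000            0.8750            0.8889
#>               mcc
#>            0.7746

bg <- sampleBackground(X[sp$train, ], 50, seed = 5)
exact <- exactShapley(marginalValueFunction(model, X[sp$test[1], ], bg))
exact
#> ShapleyResult [ exact_enumeration ] over 16 features
#>   base = 0.04852  f(x) = 1  sum(phi) = 0.9515

approx <- kernelShap(model, X[sp$test[1], ], bg, nSamples = 64, seed = 2)
max(abs(exact@phi - approx@phi))
#> [1] 0.0607

informativeFeatures(fps)                          # planted ground truth
#> [1] 2 6 9 11
order(abs(exact@phi), decreasing = TRUE)[1:4] - 1 # top bits by |phi|
#> [1] 11 2 6 9
```

Read it as: the Tanimoto SVM classifies the held-out compounds well
(MCC 0.77 on a small test split); the exact attribution satisfies
efficiency (base + Σφ = f(x) = 1); a sampled KernelSHAP run with a
64-coalition budget lands within 0.06 of the exact values; and the four
bits the generator planted are exactly the four largest attributions.

`runPipeline(pipelineConfig(), "out/")` runs the whole protocol —
generate, curate, train, explain with both methods, compare, ROAR — and
writes plot-ready CSV tables plus a JSON manifest. A thin command-line
wrapper over the same functions is installed at
`inst/scripts/shapcompare`.

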