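---
title: "Comparing Shapley-value explanations of fingerprint activity models"
author: "ShapCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing Shapley-value explanations of fingerprint activity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShapCompare)
```

## The problem

Feature attribution assigns each input feature of a trained classifier a
share of an individual prediction. The Shapley value from cooperative
game theory is the canonical way to do this: treating features as
players and the prediction as the payoff, the value of feature $p$ is

$$\varphi_p \;=\; \sum_{\mathcal{S}\subseteq T\setminus\{p\}}
\frac{|\mathcal{S}|!\,(|T|-|\mathcal{S}|-1)!}{|T|!}\,
\bigl(\nu(\mathcal{S}\cup\{p\})-\nu(\mathcal{S})\bigr),$$

the average marginal contribution of $p$ over all $2^{|T|}$ coalitions
$\mathcal{S}$. Exact evaluation is exponential in the feature count and
a model cannot be queried on a feature subset directly, so practical
tools approximate both the sum (by sampling) and the coalition value
$\nu$ (by marginalising the off-coalition features over a background
sample). Different approximations can disagree, and for compound
activity models — where explanations drive medicinal-chemistry
decisions — that disagreement is worth measuring.

ShapCompare builds a complete, desk-scale test bed for that question:

* a seeded generator of binary fingerprint datasets with planted
  class-discriminative bits (ground truth for recovery analyses),
* activity-record curation filters and balanced-set construction,
* four classifier families — random forest (RFC), a single-hidden-layer
  feed-forward network (FFNN), and SVMs with RBF or Tanimoto kernels —
  trained with stratified shuffle-split trials and grid search,
* exact Shapley values by full coalition enumeration, and a KernelSHAP
  approximator solving the Shapley-kernel weighted regression,
* the comparison statistics: cumulative present/absent sums, Gini
  coefficients, compacity, consistency, between-method Pearson
  correlation, faithfulness, remove-and-retrain (ROAR), and Wilcoxon
  signed-rank tests with Holm–Bonferroni correction.

## The value function

Both attribution routes share one value function
(`marginalValueFunction`): for a coalition $\mathcal{S}$, features in
$\mathcal{S}$ take their bits from the explained compound and the
remaining features are replaced by the corresponding bits of background
training compounds; $\nu(\mathcal{S})$ is the mean model score over
those composites. This is the *marginal* (interventional) expectation,
which assumes feature independence; the conditional alternative is out
of scope here. Two identities pin the ends of the scale:
$\nu(\emptyset)$ is the mean background score (the base value) and
$\nu(T)$ is the model output for the compound, so exact attributions
satisfy the efficiency axiom
$\sum_p \varphi_p + \nu(\emptyset) = f(x)$ to within $10^{-10}$.

The explained scalar $f(x)$ is the probability of the active class for
RFC and FFNN and the signed decision value (positive = active) for the
SVMs — the decision value is the natural additive scale for kernel
machines, and the choice is configurable per model because it changes
the scale of every attribution downstream.

The background is a seeded sample of at most 100 training rows. That
cap is a cost/stability compromise: the value function averages one
model call per background row per coalition, and 100 rows already make
the base value stable to a few percent on the desk datasets.

## Exact enumeration and KernelSHAP

`exactShapley` enumerates all $2^M$ coalitions and applies the weight
formula directly; it is capped at $M \le 16$ features. The same
enumerator doubles as the oracle for cooperative games given as
explicit payoff tables (`makeToyGame`), where the test suite checks it
against an independent permutation-average implementation and the
efficiency, symmetry and dummy axioms.

`kernelShap` solves the weighted least-squares problem with the
Shapley kernel $\pi(s) = (M-1)/\binom{M}{s}s(M-s)$ over coalitions of
size $s$, with the efficiency constraint imposed exactly by variable
elimination and no regularisation. Coalitions are chosen by the hybrid
scheme used by reference implementations: complete coalition sizes are
enumerated outward from the extremes ($s = 1, M-1, 2, M-2, \dots$)
while the budget allows — with their exact kernel weights — and any
remaining budget is spent on paired random draws (a coalition always
enters with its complement) from the leftover sizes. Two consequences
matter:

* when the budget covers all $2^M - 2$ proper coalitions the solution
  equals exact enumeration to numerical precision (the regression is
  then exactly determined), which is the package's oracle-equivalence
  test across all four model families;
* at the minimum budget $2M$ the design consists of all singletons and
  their complements, which is full-rank and dominated by per-feature
  marginals — small budgets are stable rather than degenerate.

Sampled runs are seeded and bit-reproducible. Mean absolute error
against the exact values decreases as the budget doubles within the
sampling regime; a budget that exactly exhausts an enumerated size pair
is deterministic, so the error curve is compared between genuinely
sampled budgets in the tests.

At the production fingerprint width (2048 bits, available via
`syntheticConfig(nFeatures = 2048)`) exact enumeration is impossible;
the package's scaled-down protocol retrains a model on the top-$M$
features of the KernelSHAP ranking (default $M = 12$) and explains that
reduced model exactly, giving every pipeline run two attribution
methods per model at comparable cost.

## What the generator emulates — and what it does not

`generateFingerprints` draws balanced active/inactive sets of sparse
binary vectors. A planted subset of bits is on with probability 0.8 in
actives and 0.1 in inactives; all other bits are on with probability
0.05 in both classes. This mirrors the structure of curated
target-based activity classes represented as folded ECFP4 fingerprints
— sparse on-bits, balanced classes, a minority of discriminative
features — at a desk default of 256 features and 100 compounds per
class so that exact-enumeration comparisons and ROAR retraining finish
in minutes on one CPU.

It does **not** emulate real fingerprints' bit correlations (real atom
environments co-occur), hashing collisions, class-specific bit
sparsity, or any molecular graph structure; bits are independent given
the class. Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted signal under feature
independence — exactly the assumption of the marginal value function —
not performance claims about real compound data. The background on-rate
is a free parameter, not a calibration to any database.

Label noise, when enabled, flips labels *after* bit generation, so the
planted bits remain tied to the pre-noise class and parameter-recovery
ground truth stays valid.

## Trial design and model settings

Each dataset is split into 10 independent stratified shuffle-split
trials (90% train / 10% test; trials may overlap, deliberately not
K-fold). Hyperparameters are selected per trial by grid search with an
inner 10-fold stratified shuffle split on the training data and F1 as
the selection metric, ties broken by grid order for reproducibility.
The full default grids are: RFC — minimum leaf size 1/2/5/10, minimum
split size 2/3/5/10, 25–400 trees; SVMs — C from 0.001 to 10000 (RBF
additionally gamma from 0.0001 to 100); FFNN — initial learning rate
0.01/0.001/0.0001. The FFNN has one 256-unit ReLU hidden layer, a
sigmoid output (an assumption; calibration is not attempted), binary
cross-entropy, Adam, batch size 16, at most 400 epochs, and stops early
when validation loss has not improved by at least $10^{-4}$ for 20
epochs, keeping the best-validation weights. All of its randomness is
seeded.

Two numerical conventions deserve a note. The Tanimoto similarity of
two all-zero fingerprints is defined as 1 (the self-similarity limit),
which keeps kernel matrices positive semi-definite on degenerate
fixtures. And because the sign convention of SVM decision values is an
implementation detail of the solver, each fitted SVM's decision is
aligned after training so that positive always means active.

## The statistics, and their small print

* **Cumulative analysis** sums each correctly predicted test compound's
  attributions separately over present (bit = 1) and absent (bit = 0)
  features, by true class. Whether such sums should be normalised per
  compound is ambiguous in general, so both raw and
  absolute-sum-normalised columns are emitted.
* **Gini** is computed on absolute values (the rank formula presumes
  non-negative inputs; signed inputs can leave $[0,1]$), zeros removed
  first; a single surviving value gives 0.
* **Compacity** reports, per threshold $t \in \{0.1,\dots,0.9\}$, the
  smallest share of features whose cumulative absolute attribution
  reaches $t$ of the total; the curve is non-decreasing and bounded by
  100%.
* **Consistency** normalises each row by its absolute sum and reports
  the per-feature *sample* standard deviation (the $n-1$ choice is a
  convention; nothing downstream depends on it) across instances where
  the feature's value is non-zero; fewer than two qualifying instances
  give NA.
* **Correlation** pools all (instance, feature) pairs — all trials and
  classes together — restricted to all/present/absent features, and is
  NA when either pooled vector is constant.
* **Faithfulness** correlates attributions with single-bit-flip effects
  $f(x) - f(x^{\text{flip}_i})$ over a feature subset.
* **Wilcoxon + Holm**: two-sided signed-rank per labelled pair, Holm
  step-down across the family, tiers ns/*/**/***/**** at adjusted
  p boundaries 0.05, 0.01, 0.001, 0.0001. All-zero difference vectors
  are degenerate and excluded from the family.
* Per-instance statistics are restricted to correctly predicted
  compounds by default (`correctOnly = FALSE` includes all).

## ROAR

`globalFeatureRanking` normalises rows by absolute sum, sums absolute
values per feature, and orders ascending (ties by feature id).
`roarRun` deletes the least-important $n$ features — deletion means
shorter vectors, not zero-masking, so models are genuinely retrained on
the reduced representation — refits with the hyperparameters selected
on the full representation (no re-tuning; it bounds compute and keeps
the comparison about the ranking, not the grid), and records test MCC,
against seeded random removals of the same size. The 256-feature desk
schedule (25, 128, 192, 224, 240, 248, 251, 253, 254, 255) mirrors the
2048-feature production geometry, dense near full removal; its last
step leaves a single feature, which is allowed by design — only a step
that would remove everything is an error.

## Worked example

```{r example, eval = FALSE}
fps <- generateFingerprints(syntheticConfig(nPerClass = 40, nFeatures = 16,
                                            nInformative = 4, seed = 7))
sp <- splitTrials(compoundLabels(fps), nTrials = 1, seed = 3)[[1]]
X <- bitMatrix(fps)
model <- trainModel(X[sp$train, ], compoundLabels(fps)[sp$train],
                    "SVM_TAN", list(C = 1), seed = 11)
evaluateModel(model, fps, sp$test)

bg <- sampleBackground(X[sp$train, ], 50, seed = 5)
exact <- exactShapley(marginalValueFunction(model, X[sp$test[1], ], bg))
approx <- kernelShap(model, X[sp$test[1], ], bg, nSamples = 64, seed = 2)
max(abs(exact@phi - approx@phi))
```

## Problem sizes used by the checks

The shipped tests and the acceptance script run, as the package's
standard desk protocol: the default generator conditions (256 features,
20 planted bits, 100 compounds per class), 10 trials, a Tanimoto-kernel
SVM at C = 1 per trial, KernelSHAP with a budget of 512 coalitions
(2 x features, the documented minimum) over a 100-row background, five
correctly predicted test compounds attributed per trial, and ROAR on
the desk schedule with five random-control seeds. Oracle-equivalence
checks run all four families at 12 features, where full enumeration is
exact. These sizes were fixed as part of the protocol design.

## Known limitations

* The marginal value function assumes feature independence; on real
  fingerprints with correlated bits it can average the model over
  off-manifold composites.
* Exact enumeration is limited to 16 features; wider exactness is only
  available through the top-$M$ retraining protocol, which explains a
  *different* (retrained) model.
* The FFNN is a minimal implementation sized for fingerprint inputs; it
  is not a general deep-learning stack.
* Model-specific fast Shapley algorithms (tree-path methods, kernel
  closed forms, backprop rules) are deliberately out of scope; exact
  enumeration is the model-specific reference at desk scale.
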