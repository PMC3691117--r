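---
title: "Gene-panel class prediction with nested cross-validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-panel class prediction with nested cross-validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcv)
```

## The problem panelcv addresses

Small-sample transcriptomic biomarker studies — for example, classifying a
psychiatric diagnosis from peripheral blood leukocyte expression — face three
statistical hazards at once: tens of thousands of transcripts measured on a
few dozen subjects, technical replication that must be verified before
samples are pooled, and a strong temptation to estimate classifier accuracy
with procedures that quietly reuse the test samples during feature
selection. `panelcv` implements a complete discovery workflow that takes
these hazards seriously:

1. **Replicate quality control.** Each subject may contribute an "A" sample
   and a technical replicate "B". A pair is checked three ways — whole-
   transcriptome clustering adjacency, global Spearman correlation, and the
   replicate difference of a designated control gene — and the B sample is
   dropped when at least two checks fail.
2. **Enrichment filtering.** A univariate moderated t-test (the
   random-variance model) is run on a dedicated *enrichment* cohort that is
   disjoint from the training samples, and transcripts with unadjusted
   p < 0.05 are carried forward. In the motivating design the enrichment
   cohort contains never-medicated patients, so this step also depletes
   medication-driven transcription.
3. **Panel selection and training.** SVM recursive feature elimination
   reduces the enriched set to a fixed small panel (default 10 genes) on the
   training cohort, and a classifier — DLDA by default — is trained on that
   panel.
4. **Honest error estimation.** Leave-one-out cross-validation repeats the
   panel selection *inside every fold*, and the error rate's significance is
   the proportion of label permutations that achieve an error no greater
   than the observed one.
5. **Frozen-model evaluation.** The trained panel and parameters are then
   applied, unchanged, to the enrichment, replicate and test cohorts, with
   per-cohort sensitivity/specificity summaries and permutation p-values.

## The random-variance moderated t-test

With a handful of samples per class, per-gene variance estimates are noisy
and ordinary t-tests are unstable. The random-variance model assumes the
gene-wise precision is drawn from a gamma prior,

$$ 1/\sigma_g^2 \sim \mathrm{Gamma}(a,\ \mathrm{scale} = b), $$

which implies that the pooled variance $s_g^2$ on $d = n_1+n_2-2$ degrees of
freedom has the marginal distribution $s_g^2\,ab \sim F(d,\ 2a)$. The
package fits $(a, b)$ by maximizing this marginal likelihood over
$(\log a, \log b)$ (L-BFGS-B; the log parameterization keeps the search
unconstrained in effect). Each gene's variance is then shrunk toward the
prior,

$$ \tilde\sigma_g^2 = \frac{d\, s_g^2 + 2/b}{d + 2a}, \qquad
   \tilde t_g = \frac{\bar x_{g,\mathrm{case}} - \bar x_{g,\mathrm{control}}}
   {\sqrt{\tilde\sigma_g^2 (1/n_1 + 1/n_2)}}, $$

and $\tilde t_g$ is referred to a Student t with $d + 2a$ degrees of freedom
(two-sided). Two limits anchor the implementation: as $a \to 0$ with
$1/b \to 0$ the statistic reduces exactly to the ordinary pooled t (tested
to 1e-8), and when all variances are equal the likelihood drives $a$ upward
without bound — the fit caps $a$ at $10^6$ and flags the prior as
near-degenerate rather than failing. Genes with zero pooled variance are
kept, receiving the pure prior variance $(2/b)/(d+2a)$, so degenerate
synthetic inputs do not puncture the feature space. Two-sided p-values are
used throughout.

## SVM-RFE and the classifier suite

RFE standardizes each candidate gene to zero mean and unit variance on the
training samples, fits a linear soft-margin SVM (cost $C = 1$; the cost is
configurable but no kernel is offered), and removes the genes with the
smallest squared weights. While more than twice the target panel size
survives, 10% (rounded up) are removed per iteration; after that, one per
iteration, which keeps runtime bounded without materially changing the
outcome near the end, where it matters. A `strict` switch forces
one-at-a-time elimination throughout. All ties — equal weights, equal
distances, equal scores — resolve by the lower gene or sample index, and
prediction ties resolve to the control class (the "negative" call), so every
result is reproducible bit for bit.

The suite contains the six classical predictors used with fixed panels:

* **DLDA** — nearest centroid under per-gene pooled-variance scaling
  (diagonal covariance): assign $\arg\min_k \sum_g (x_g - \bar
  x_{kg})^2/s_g^2$. A zero pooled variance is replaced by the smallest
  positive variance in the panel (with a warning) so tiny LOOCV folds keep
  running.
* **CCP** — compound covariate predictor: score $\sum_g t_g x_g$ with
  pooled-t weights, thresholded at the midpoint of the two class-mean
  scores. Note that prose descriptions of "DLDA" in the applied literature
  sometimes describe this t-weighted linear combination; the two are not the
  same classifier, and both are provided — DLDA here always means the
  variance-scaled-distance rule.
* **Nearest centroid** and **1-/3-nearest neighbours** on Euclidean
  distance (odd k, so no vote ties; distance ties break by training index).
* **Linear SVM** on standardized features.

## Nested LOOCV and permutation significance

The cross-validation contract is strict: within each fold the RFE panel
search is redone on the n−1 training samples, and the held-out sample is
touched only by the final trained model. The enrichment-cohort univariate
filter is *not* refit per fold by default, because in the staged design it
was computed on disjoint samples; `refit_filter = TRUE` additionally refits
it in-fold for single-cohort use. The test suite keeps a deliberately
broken, non-nested variant (panel selected once on all samples) purely to
demonstrate the bias this contract avoids: on pure-noise data with 19 + 19
samples and 2000 genes the nested error stays statistically
indistinguishable from 50% while the non-nested shortcut reports nearly
perfect accuracy.

The permutation p-value is the plain proportion of label permutations whose
cross-validated error is no greater than the observed error — so 15 of 1000
permutations gives p = 0.015, and p = 0 is possible. The (k+1)/(B+1)
convention is available behind `plus_one`. Permutations are drawn uniformly
over label orderings, not stratified. For cohorts evaluated with a frozen
model the predictions are fixed, and the permutation distribution of the
error depends only on the hypergeometric overlap between predicted-case
calls and permuted case labels; `frozen_model_permutation(exact = TRUE)`
enumerates it exactly. Which scheme produced any given published cohort
p-value is generally not recoverable from a study's write-up, so both are
exposed as explicit options rather than a guess.

## Replicate QC decisions

The three checks and the 2-of-3 drop rule follow the published thresholds
(Spearman rho < 0.985 fails; control-gene difference beyond ±2.3 SD of the
mean difference fails). Three details were genuinely open and were fixed as
follows:

* Clustering distance is 1 − Pearson correlation of the log2 profiles
  (configurable to Euclidean); "the pair clusters together" is
  operationalized as the pair being merged with each other before either
  merges with anything else under average linkage, which is equivalent to
  being mutual nearest neighbours — a well-defined, testable condition.
* The control-gene SD uses the n−1 denominator, with mean and SD computed
  over all pairs including the pair under test. A consequence worth knowing:
  $|z|$ cannot exceed $(n-1)/\sqrt{n}$, so with 7 or fewer pairs the control
  check can never fail at 2.3 SD.
* A missing control gene marks that check not-run and counts it as a pass,
  with a warning, rather than silently converting it into a failure.

## Normalization

Quantile normalization (average-ties dialect) and Tukey median-polish
summarization (log2 scale, rows-then-columns sweeps, relative tolerance
1e-8 on the total absolute residual, at most 20 iterations) are provided
for probe-level input; the pipeline equally accepts pre-normalized
matrices, and the convolution background-correction step of full RMA is
deliberately out of scope. The quantile step delegates to
`limma::normalizeQuantiles` and the polish to `stats::medpolish`; both are
cross-checked in the tests against hand computations and an independently
coded median-sweep oracle.

## What the synthetic generator emulates — and what it does not

`sim_params()` / `generate_study()` produce cohorts with the statistical
structure the analysis assumes: gene variances drawn from the same scaled
inverse-gamma prior the moderated t-test fits (defaults a = 3, b = 1, so a
typical gene sd is ~0.6 log2 units); baseline means Uniform(4, 12) log2 to
mimic array intensity range; a planted set of differential transcripts with
additive log2 effects (optionally specified in per-gene sd units via
`delta_standardized`, so a stated standardized effect size is realized
exactly); A/B technical replicates with Normal technical noise (default
tau = 0.05 log2); and optional corrupted replicates in which a fraction
(default 30%) of B-sample genes are rank-scrambled — degrading rank
concordance and clustering without changing the marginal distribution,
which is exactly the failure mode the QC stage must catch.

The default study scale is 1000 genes with 50 planted transcripts and the
staged cohort sizes 3+13 (enrichment), 26+12 (training), 34 replicate
pairs, and 3+3 (test); simulation-heavy checks in the test suite use 2000
to 5000 genes where the property being tested demands it. These scales were
chosen once as a realistic desk-scale emulation of a two-class array study.

The generator deliberately omits much of what real arrays contain: no
probe-level background or mismatch structure, no batch or scanner effects,
no correlation between genes, no heavy-tailed or intensity-dependent noise.
Passing tests on this data therefore demonstrates that the *procedures* are
correct and honest under the model's own assumptions — calibrated type-I
error, unbiased nested CV, exact QC decisions — not that any particular
accuracy will be achieved on real cohorts, where inter-gene correlation and
batch structure typically reduce effective information.

## Determinism

Every stochastic step flows from a single integer seed through one
generator: cohort generation, replicate noise, corruption, permutations.
Rerunning any function, the full pipeline, or the whole study with the same
seed produces byte-identical artifacts; the run directory's manifest
records the effective configuration and its hash.

## Known limitations

* Only two-class problems; no probability calibration, no nonlinear
  kernels, no k-fold or split-sample validation modes (leave-one-out is the
  design's estimator; split-sample is explicitly avoided at these sample
  sizes).
* The Bayesian variant of the compound covariate predictor is not
  implemented.
* The RVM fit assumes variances are exchangeable across genes; strong
  variance-intensity trends would argue for an intensity-stratified prior,
  which is not provided.
* The linkage-region contingency comparison is provided as a generic
  two-proportion chi-square/Fisher computation; mapping transcripts to
  genomic loci is outside the package.
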