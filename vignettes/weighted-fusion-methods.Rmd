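---
title: "Methods: adaptive-weight soft voting, Cuckoo Search, and the evaluation suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-weight soft voting, Cuckoo Search, and the evaluation suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuckoofuse)
```

## The model

`cuckoofuse` operates entirely on classifier *outputs*: each member
model contributes an N x K matrix of per-sample class probabilities over
a fixed, ordered class scheme. The ensemble score is the literal
weighted sum

$$P_{\text{final}} = \sum_m w_m P_m, \qquad w_m \in [0, 1],$$

and the predicted class is the row argmax of $P_{\text{final}}$. Two
modelling commitments follow from how such ensembles are used in
practice:

* **No simplex constraint on the weights.** Weight vectors are searched
  in the free box $[0,1]^M$; well-performing pairs need not sum to one
  (e.g. $(0.5, 0.45)$). Because only the argmax is consumed, the
  decision is invariant to rescaling all weights by a positive constant,
  so the box parameterization loses nothing and keeps the search simple.
* **No renormalization of fused rows.** Fused rows sum to $\sum_m w_m$.
  Renormalizing would not change any argmax, and ROC-AUC on fused scores
  is likewise unaffected (AUC is rank-based and the per-row scaling here
  is global). When fused scores are *written back* as a prediction
  table, rows are rescaled to unit sum purely to satisfy the file
  contract, with the raw weights recorded in a sidecar.

Ties in the argmax go to the lowest class index, i.e. the least severe
stage. Any deterministic rule would do for reproducibility; this one is
also the clinically conservative choice when the classes are ordered
severity stages.

## Weight selection by Cuckoo Search

The fitness of a weight vector is the accuracy of the fused argmax
labels on held-out validation predictions (Scott's Pi against the truth
is available as an alternative objective via `make_agreement_fitness()`;
accuracy is the default because it is the quantity the search is
described as optimizing, while agreement is how results are commonly
*reported* — both are exposed so either protocol can be run explicitly).

One generation of `cs_optimize()`:

1. **Egg laying.** Every nest $x$ proposes
   $x' = x + \alpha_0 \cdot \ell \odot (x - x^\*)$, where $\ell$ is a
   Lévy-flight step and $x^\*$ the incumbent best; $x'$ is clipped to
   bounds and replaces a *randomly chosen* nest if fitter. A nest
   sitting exactly at $x^\*$ would be frozen by the $(x - x^\*)$
   scaling, so it instead takes a pure Lévy step of magnitude
   $\alpha_0$.
2. **Abandonment.** The worst $\lceil p_a \, n_{\text{nests}} \rceil$
   nests are discarded and re-drawn uniformly in bounds.
3. **Bookkeeping.** The best-so-far solution (tracked outside the
   population, so the fitness history is non-decreasing by
   construction) and an archive of the top `archive_size` distinct
   weight vectors are updated.

Lévy steps use the Mantegna construction: each component is
$u / |v|^{1/\beta}$ with $u \sim N(0, \sigma_u^2(\beta))$,
$v \sim N(0,1)$, and

$$\sigma_u(\beta) = \left[\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
{\Gamma\!\big(\tfrac{1+\beta}{2}\big)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta}
\;\; (\approx 0.6966 \text{ at } \beta = 1.5).$$

This mixes many small refinements with occasional large jumps, which is
what lets a 25-nest population escape the plateaus that an
accuracy-valued objective produces (accuracy is piecewise constant in
$w$, so gradient methods are unusable and pure local search stalls).

### Tunable parameters

| parameter | default | units / range | why this default |
|---|---|---|---|
| `n_nests` | 25 | count | standard small-population CS; ample for 2–3 weights |
| `pa` | 0.25 | fraction [0,1) | classic abandonment rate; keeps exploration alive |
| `levy_beta` | 1.5 | exponent (0,2] | the usual Lévy stability index for CS |
| `step_scale` | 0.05 | weight units | steps of a few percent of the box per move |
| `max_generations` | 200 | count | upper bound; convergence usually stops earlier |
| `tol`, `patience` | 1e-6, 10 | fitness units, generations | "negligible improvement" stop: 10 stalled generations |
| `archive_size` | 10 | count | enough to inspect the near-optimal weight region |

Fitness ties in the archive are broken by smaller Euclidean norm, then
lexicographically — archives are therefore byte-stable across reruns.
Everything is driven by one integer seed; two runs with the same
configuration are identical.

`weight_sweep()` evaluates the objective on a uniform 0.05-pitch grid —
the manual-sweep protocol — and `snap_to_grid()` maps a continuous
optimum onto that grid for side-by-side comparison. The search itself is
continuous: there is no reason to constrain it to the grid used for
manual sweeps.

## The evaluation suite

* **Confusion counts** are one-vs-rest per class; accuracy is read as
  correct/total (its one-vs-rest average carries no information beyond
  the micro metrics).
* **Zero denominators** (a class never predicted, or absent from the
  truth) yield a metric value of 0 with a `*_defined = FALSE` flag
  instead of an exception, so batch evaluation of many models never
  aborts on a degenerate one.
* **Micro averages** pool TP/FP/FN before the formulas. For
  single-label predictions, pooled FP = pooled FN, hence micro
  P = R = F1 = accuracy — the suite reports them separately anyway
  because the identity is a useful internal consistency check.
* **Micro ROC-AUC** flattens the N x K one-hot truth and score matrices
  into N·K binary decisions and computes the rank-based (Mann–Whitney)
  AUC, ties counted one half. Per-class one-vs-rest AUCs are also
  emitted.
* **Scott's Pi** uses the pooled-marginal chance correction
  $P_e = \sum_k m_k^2$, $m_k = (n^a_k + n^b_k)/2N$ — this is what
  distinguishes it from Cohen's kappa, and the two coincide exactly
  when the two streams have identical marginals. The unweighted form is
  the default; linear ($1 - |i-j|/(K-1)$) and quadratic ordinal
  weightings are opt-in, since ordinality arguments motivate but do not
  fix a particular weighted formula. When both streams are degenerate
  on one class, $P_e = 1$ and pi is reported as undefined (NA with a
  flag), not an error; the agreement *fitness* maps this case to −1 so
  the optimizer treats degeneracy as maximally bad.

Agreement is exposed in both modes — model-vs-model (pairwise matrix
over argmax streams, for choosing complementary ensemble members) and
prediction-vs-truth (in the metrics report) — because both protocols are
in common use and they answer different questions.

## The class-imbalance protocol

The motivating datasets are heavily skewed (e.g. severity histogram
67,222 / 13,725 / 5,002 / 488 — the smallest class under 1% of the
largest). The pipeline order is fixed and significant:

1. **Test reservation first.** Each class reserves an absolute count or
   a fraction (fractions rounded half-up by default; configurable)
   *before* any resampling, so the test set contains only original
   samples. The default rules reserve 770 per common class and 20% of
   the rare class — 98 of 488.
2. **Rebalancing** to a per-class target (default 6,000): majorities
   subsampled without replacement, minorities kept in full plus
   duplicates drawn with replacement. Duplicates get replica ids
   `<id>#r<k>`, so leakage checks can verify no replica ever reaches a
   test manifest. Duplication, not synthetic interpolation: for medical
   scans, geometric or interpolated augmentation risks destroying the
   structures being diagnosed, so plain duplication is the conservative
   mode, and it is the only oversampling mode offered.
3. **Stratified splitting** with largest-remainder per-class allocation,
   so arbitrary totals split exactly; on the balanced 24,000-entry pool
   the default 19,000/5,000 split contributes 4,750/1,250 per class.
   Stratification preserves the balance the previous step just created.

## What the synthetic generator emulates — and what it does not

`simulate_model_predictions()` draws, per sample, a modal class (correct
with probability `skill`, otherwise a wrong class preferring adjacent
severity stages — errors between neighbouring stages are the typical
failure mode of real stage classifiers) and then a probability row from
a Dirichlet distribution concentrated on the modal class. The row is
constructed so its argmax *is* the modal class, which makes empirical
argmax accuracy an unbiased estimator of `skill` — the property the
recovery tests check. The default concentration of 20 keeps rows sharp
but not one-hot, so ROC-AUC remains informative rather than saturating
at 1.

`simulate_correlated_pair()` couples two models' error events through a
shared latent difficulty draw used with probability `rho`: at
$\rho = 1$ and equal skills the error sets coincide exactly, at
$\rho = 0$ errors are independent, and model-vs-model agreement rises
monotonically in between. This reproduces the *agreement structure* of
real model pairs.

What the generator does **not** emulate: calibration pathologies
(systematic over/under-confidence), class-conditional skill (real
models are usually better on majority classes), non-exchangeable
samples (scans from the same participant are correlated), and
architecture-specific error profiles. Passing tests therefore
demonstrate that the fusion/search/evaluation machinery is correct and
recovers known ground truth — not that any particular real ensemble
will reach any particular score.

## Numerical choices

* Row sums of probability tables must lie in $1 \pm 10^{-6}$;
  out-of-tolerance rows are errors naming the sample id, with an
  explicit `renormalize = TRUE` opt-in. Silent renormalization would
  mask upstream bugs that then bias every downstream metric.
* Tables are CSV, UTF-8, `.` decimal point, mandatory header, class
  columns fixed by the configured scheme (never inferred from the
  file); probabilities serialize at 17 significant digits so
  write-then-read is bit-identical.
* Fused row sums are conserved to $10^{-9}$; the AUC oracle agreement
  is asserted to $10^{-12}$.
* The all-zero corner of the weight box is not a valid weight vector
  (no model would contribute); the optimizer discards proposals that
  clip onto it.
* Degenerate inputs are defined, not crashed on: `max_generations = 0`
  returns the best of the initial population; a `(total, 0)` split
  returns an empty validation set; an all-constant label pair yields an
  undefined (flagged) pi.

## Problem sizes in the test suite

The suite exercises the balancing protocol at its full 86,437-entry
scale (it is cheap — manifest operations only) and sizes the stochastic
checks for tight-but-honest statistics: fusion identities over 1,000
random fixtures; metric identities over 1,000 label tasks plus 100 AUC
fixtures with $NK \le 200$ against an exhaustive pairwise oracle;
optimizer-vs-grid-oracle comparisons on 20 seeded two-model problems of
200 validation samples each (0.01-pitch grid, tolerance 0.005, plus an
equal-budget random-search baseline); simulator recovery at 10,000
samples within three binomial standard errors. The end-to-end pipeline
tests run a reduced configuration (1,500-entry manifests, 150-sample
evaluation sets) chosen to keep the whole suite comfortably fast while
still crossing every module boundary.

## Known limitations

* Fusion is probability-level soft voting only — no stacking,
  rank-based or vote-based fusion.
* The optimizer is single-objective Cuckoo Search; no other
  metaheuristics, no parallel evaluation (determinism per seed is the
  contract), no multi-objective trade-offs.
* Scott's Pi confidence intervals and macro-averaged AUC variants are
  not provided.
* The package never touches images or model weights; if upstream
  probabilities are mis-calibrated, fusion inherits that without
  warning.
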