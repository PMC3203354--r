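---
title: "Signature association search: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature association search: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigsearch)
```

## The model

A query signature is a pair of disjoint gene sets: `up` genes expected to be
induced and `down` genes expected to be repressed under some reference
perturbation. The question `sigsearch` answers is not "which genes are
differentially expressed in this contrast" but "which samples, and which
whole datasets, anywhere in a compendium, show the signature's coordinate
up/down pattern" — with no phenotype labels involved.

Three layers make that work:

1. **Within-dataset normalization.** Each dataset (a series/platform block)
   is z-score normalized per gene across its own samples. This converts
   incomparable absolute intensities into relative expression; a sample's
   z-scores say how each gene sits relative to the other samples *of the
   same dataset*. Ranks of these values are therefore only comparable within
   a normalization block, which is why blocks never span platforms.

2. **Per-sample SA score.** For one sample, the z-scores of the effective
   signature genes (those present in the dataset) are pooled and midranked.
   The rank-sum statistic `W = sum(r_up) - n_up(n_up+1)/2` is standardized
   by the null moments `mu = n_up*n_down/2`,
   `sigma = sqrt(n_up*n_down*(n_up+n_down+1)/12)` to give
   `SA = (W - mu)/sigma`. SA is antisymmetric in the up/down sets, invariant
   to any strictly increasing transform of the sample's values, and its
   exhaustive tie-free null has mean 0 and variance 1 exactly (the test
   suite enumerates all `choose(n_up+n_down, n_up)` rank assignments up to
   total size 10 to check this). Two-sided p-values use a t reference with
   `n_up + n_down - 2` degrees of freedom — the stated approximation, kept
   as the contract even for large sets.

3. **Dataset enrichment.** Per-sample q-values are Benjamini–Hochberg over
   *all* defined scores in the compendium, and q ≤ 0.1 defines the
   significantly-positive / significantly-negative / not-significant
   categories. Each dataset is then compared to the pooled background by a
   two-sample two-sided K-S test on SA scores and by an exact 2×3 Fisher
   (Freeman–Halton) test on category counts; each p-value vector is
   BH-adjusted across datasets and output is sorted by K-S q, then Fisher q,
   then dataset id.

The two enrichment tests are deliberately complementary: Fisher sees only
the extreme tail (samples crossing the q cutoff) and is very sensitive when
a dataset concentrates such samples; K-S sees the whole distribution and
wins when many samples shift modestly without any crossing the cutoff. The
test suite reproduces both regimes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `q_threshold` | 0.1 | per-sample FDR cutoff defining categories |
| `min_per_set` | 2 | minimum effective genes per direction; below it the score is undefined (df would be meaningless), excluded — not imputed |
| sd divisor | n−1 | "standard deviation of one" does not fix the divisor; sample sd is the conventional choice, and ranks downstream are unaffected |
| tie handling | midranks, untied σ | z-scores are continuous so ties are rare; the printed σ has no tie correction and none is added, as a fidelity choice |
| Fisher mode | `exact_2x3` | Freeman–Halton by enumeration over the dataset row (≈ n²/2 tables); Monte-Carlo fallback (1e5 draws, fixed seed) above 1e7 tables; `collapse_2x2` (significant vs not) available as a documented alternative |
| background | includes tested dataset | "all samples in all datasets" has no stated exclusion; including the dataset biases slightly toward the null |

Zero-variance genes normalize to 0 rather than NaN: a gene constant within
a dataset carries only mid-rank information, and an all-zero row represents
that honestly while keeping matrices dense.

## The synthetic generator: what it emulates and what it does not

`simulate_compendium()` draws each dataset i.i.d. standard normal
(genes × samples), optionally adds `+effect_size` to up genes and
`-effect_size` to down genes in a chosen fraction of samples, then z-score
normalizes each gene row — the same simulation protocol used for the
original method's specificity evaluation. Two consequences worth
internalizing:

- the effect size is **nominal**: normalization rescales it, so the realized
  z-shift depends on `affected_fraction` (at fraction 0.5 a nominal shift of
  2 realizes as roughly ±0.7σ on each side);
- normalization **centers each gene**, so unaffected samples in a perturbed
  dataset are pushed in the opposite direction; a half-affected dataset
  shows a symmetric bimodal SA pattern (`direction = "mixed"`), which is a
  feature of relative expression, not an artifact.

The generator does not emulate probe-level noise, platform batch effects,
correlated gene modules, or heavy-tailed intensity distributions. A green
test on synthetic data therefore establishes the statistical machinery
(calibration, power ordering, determinism), not robustness to real
microarray pathology.

Each dataset gets its own RNG stream derived from the master seed and the
dataset index, so generation is bit-reproducible and order-independent;
every seed derived this way stays below 2³¹.

## Evaluation protocols

`power_sweep()` regenerates the varied ingredient per replicate — random
sample subsets of the dataset under test (re-z-normalized within the
subset, matching how a smaller series would have been deposited; keeping
full-set scores is exposed as `renormalize = FALSE` for sensitivity
analysis), or random signature subsets at fixed composition or fixed size —
runs the full score/categorize/enrichment path against the compendium
background, and tabulates the fraction of replicates below each p threshold
(0.05, 0.01, 0.001, matching the presentation of the original sweeps).
Replicates default to 200 for suite speed; the count is a plain argument
for larger runs.

`roc_from_scores()` groups tied scores, integrates by trapezoid, and hence
equals the Mann–Whitney pair probability (ties as 1/2); it exists so
labeled evaluations (e.g. distinguishing treated from untreated samples by
SA score) can be reproduced. The published external benchmark of this kind
requires a third-party ranked-fold-change download and is out of scope; the
machinery is tested against a brute-force U-statistic oracle instead.

## Design choices made where the design was open

- **Rounding** in `subsample_signature` is half-away-from-zero on
  `n_total * up_fraction`; no rounding rule was stated, so one is fixed and
  documented for reproducibility.
- **Planted-signal world.** The recovery benchmark (one perturbed dataset
  among 49 nulls, nominal effect 2, half the samples of a 20-sample
  dataset) does not pin signature size or gene count; the planted signature
  uses the published estrogen-response composition (34 up / 77 down) on a
  200-gene namespace, chosen a priori as the realistic signature scale this
  tool is built for, and 20-sample null datasets matching the perturbed
  one.
- **Fisher build-vs-buy.** The 2×3 exact test is implemented here by direct
  enumeration over the two free cells of the dataset row (the dataset, not
  the background, bounds the enumeration), with `stats::fisher.test` kept
  as an independent cross-check oracle in the tests. The excess
  non-significant override (p := 1) is applied after the test, exactly.
- **Per-sample BH pooling** is compendium-wide, mirroring the definition of
  the background as all samples in all datasets.
- **Undefined scores** (poor platform coverage) are flagged and excluded
  from background, BH, and enrichment; datasets with no defined score are
  skipped and logged.
- **Single-sample datasets** are rejected at normalization: a one-sample
  dataset carries no relative-expression information.

## Known limitations

- The t reference for SA is an approximation; no exact enumeration p-value
  is offered for large sets, by contract.
- K-S p-values against a background containing the dataset's own samples
  involve ties, so they are asymptotic, and the inclusion biases slightly
  conservative.
- Gene identifiers are opaque strings; no cross-namespace or cross-species
  mapping is performed, and upstream summarization (RMA-style) is assumed
  done.
- Real-data intake is limited to already-summarized gene × sample matrices;
  no repository crawling.
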