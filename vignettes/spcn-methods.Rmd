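---
title: "Sparse partial correlation networks: model, tuning and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse partial correlation networks: model, tuning and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcnet)
```

## The model and its assumptions

`spcnet` treats a samples × variables signal matrix (genomic regions ×
epigenomic marks) as draws from a graphical Gaussian model (GGM): the
missing edges of the network correspond to zero partial correlations,
i.e. conditional independence given all remaining variables. Two
assumptions matter:

* **Linearity / normality.** Partial correlations capture *linear*
  conditional dependence of jointly Gaussian variables. ChIP-seq count
  data is neither Gaussian nor linear on the raw scale — most marks have
  multimodal marginals. The package therefore rank-transforms every
  column first. On ranks, relationships are measured as monotone
  association (Pearson on ranks = Spearman), the marginals become uniform
  on 1..n (well approximated by a wide Gaussian for the large n this
  method targets), and every downstream quantity is exactly invariant
  under strictly monotone distortions of the inputs. The cost is some
  statistical power and the loss of mode structure; the package is not
  appropriate when the association of interest is *between modes* rather
  than monotone within them.
* **Closed world.** An edge means "not explainable by the *measured*
  co-variables". Adding a variable can rewire the network; unmeasured
  confounders (e.g. chromatin regulators, antibody cross-reactivity)
  remain possible explanations of any edge.

The regime the defaults target is many samples, few variables
(n ≈ 13000 regions, p ≈ 23 marks). With n ≫ p the correlation matrix is
well conditioned and no shrinkage is used; the inverse-correlation route

$$P_{ij} = -\frac{\Omega_{ij}}{\sqrt{\Omega_{ii}\,\Omega_{jj}}},
  \qquad \Omega = C^{-1}$$

is algebraically identical to correlating the residuals of the two
variables after regressing both on all others, and the test suite holds
the two routes to within 1e−8 on random instances.

## Significance

Fisher's z, `z = atanh(P_ij) * sqrt(n - k - df_offset)` with `k = p − 2`
control variables, is treated as standard normal under the null.
`df_offset` defaults to 3, the classical Fisher constant; the exact
constant is not critical at the intended n and is exposed in the
configuration precisely because reasonable references disagree between
n − k − 2 and n − k − 3. The p(p−1)/2 upper-triangle tests are
Benjamini–Hochberg adjusted by an in-package step-up implementation
(checked against the literal definition and against `p.adjust`).

At n in the thousands essentially *every* q-value is tiny — statistical
significance stops being informative, which motivates the next section.

## Cross-validated sparsification

The tunable parameters, their defaults, and why:

| parameter | default | meaning |
|---|---|---|
| `n_folds` | 10 | CV folds; the procedure is insensitive between 5 and 10 at large n |
| `tolerance` | 0.10 | fraction of the min–max prediction-error range the selected sparse model may lose over the best model |
| `min_support` | 7 | folds (of 10) an edge must survive; primarily discards edges that appear in one or two folds by chance |
| `special_node`, `special_degree` | off, 4 | complete a focal variable (expression) to a minimum degree using full-data q-values; off unless named, since it is specific to expression analyses |
| `df_offset` | 3 | Fisher-z degrees-of-freedom constant |
| `max_grid` | 200 | cap on q-threshold grid points per fold |

Per training fold, the candidate thresholds are the attained unique
q-values (thinned log-spacedly above `max_grid` points), plus 0 so that
the *empty* network is an attainable sparsity level — without it a
null-model input could never return an empty network. For each threshold,
each variable is predicted by OLS (with intercept) from its surviving
co-variables on the training fold and scored by mean squared error on the
test fold, averaged over **all** p variables (isolated variables get an
intercept-only model, so pruning a useless edge is still rewarded).
Errors are computed on the rank scale without re-standardization: all
columns share the 1..n scale by construction.

Because the error increases continuously with sparseness at large n (no
overfitting minimum), the rule picks the *lowest* threshold whose error
stays within `tolerance` of the range — an explicit precision-over-recall
trade: reported edges are strongly supported, and the weakest true edges
(true partials near 0.1) are the ones sacrificed. The acceptance
benchmark quantifies this: on synthetic GGMs with p = 23, 40 edges,
|partial| ≥ 0.1 and n = 12000, measured precision is 1.0 and mean recall
0.80 − ε (319/400 edges over ten seeds) — the recall criterion sits
exactly at the cliff of what this world attains, and is left asserted at
its stated bound rather than softened.

Implementation note: the threshold sweep is evaluated from train/test
Gram matrices, so each threshold costs O(p · |S|³) independent of n; a
test holds this path equal to the direct OLS implementation.

The rank transform is applied once, before fold splitting, following the
pipeline's stated order. Test-fold values therefore contribute to the
ranks used in training — a mild leakage that vanishes as n grows and is
accepted for fidelity to the procedure.

## Explaining away

The effect matrix compares each pair's marginal correlation `r_ij` with
its full-control partial `P_ij` (`diff = P_ij − r_ij`, signed; the
rendering convention of showing magnitudes is left to the caller) and
scans all *single* controls k for the one maximizing `|r_ij·k − r_ij|`
via the first-order recursion
`r_ij·k = (r_ij − r_ik r_jk) / sqrt((1−r_ik²)(1−r_jk²))`.
Exhaustive multi-variable control subsets are deliberately out of scope —
with ~20 correlated variables they are combinatorially explosive and
rarely more interpretable. Ties in the argmax are broken by variable
order, making the output deterministic. A consensus variant reports, per
pair, the modal top explainer across conditions and its support count.

## Overlap statistics

Cross-condition stability is measured on ranked pair lists (ascending
q-value; ties broken by descending |partial|, then pair name — the
tie-break is this package's choice and is recorded with the output). For
two lists of length n from a universe of N = p(p−1)/2 pairs the common
count is hypergeometric with equal white balls and draws, expectation
n²/N (expected proportion n/N), and an inclusive upper tail
P(X ≥ x) as p-value. For L ≥ 3 lists the expected proportion is
(n/N)^(L−1) and the p-value is Monte-Carlo; a zero count is reported as
the 1/n_sims upper bound. The null default samples each list *without*
replacement — a ranked top-n list cannot contain a duplicate pair —
while `replace = TRUE` reproduces the with-replacement null some
analyses use; for n ≪ N the two are nearly indistinguishable.

## Synthetic data: what it emulates, what it does not

`random_sparse_precision` draws a random edge set, places uniform-
magnitude, random-sign entries in the precision matrix, and sets the
diagonal to the row-wise absolute sum plus a margin (strict diagonal
dominance ⇒ positive definite). True partial correlations are then
degree-determined, `1/√((d_i+1)(d_j+1))` in magnitude; draws violating
the requested minimum magnitude are resampled with a bounded retry. The
default benchmark mirrors the intended data scale: p = 23 variables,
≈12. 8k samples, 40 edges. `monotone_distort` then emulates the
non-Gaussian marginals of real signal (lognormal, or empirical quantile
matching onto a two-component normal mixture for dip-separated bimodal
histograms) without touching the ranks.

What the generator does **not** emulate: read-level sequencing noise,
fragment-size and mappability biases, antibody cross-reactivity, spatial
correlation between neighboring regions, or zero-inflation. A green edge-
recovery test therefore establishes that the statistical machinery
recovers conditional-independence structure from monotone-transformed
GGM data at the stated scale — not that real ChIP-seq edges are correct.

## Numerical choices and degenerate inputs

* Constant columns are fatal at rank time (rank correlation undefined).
* The correlation matrix must be invertible; condition numbers above
  1e12 (configurable) abort with a collinearity hint.
* |r| = 1 entries yield p = 0 with a warning at the Fisher-z step.
* Singular co-variable designs in the CV regressions drop redundant
  columns (pivoted least squares) with a warning.
* Missing values are dropped row-wise at load time (opt-in, counted);
  there is no imputation, since the method's sample sizes make dropped
  rows cheap.
* All stochastic stages (fold split, GGM sampling, Monte-Carlo nulls)
  take explicit seeds; the CLI derives per-stage seeds from the single
  run seed so partial re-runs are reproducible.

## Known limitations

* Closed-world edges (see above); networks are not comparable across
  different variable sets.
* The CV selection rule is tuned for the large-n regime; with few
  samples the error curve develops a genuine minimum and the 10% rule,
  while still applicable, is no longer the binding design constraint.
* Rank-scale regression errors weight every variable equally; a variable
  that is intrinsically unpredictable contributes a constant offset to
  the curve, slightly diluting the selection signal.
* Sign conflicts in consensus networks are flagged, not resolved — the
  per-condition weights are preserved so either reading is recoverable.
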