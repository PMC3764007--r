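# spcnet — sparse partial correlation networks for epigenomic signal matrices

`spcnet` builds undirected networks of **direct** associations among
variables measured over many genomic regions — typically histone
modifications, DNase I hypersensitivity (open chromatin) and mRNA levels
quantified around transcription start sites. An ordinary correlation
between two marks may be entirely induced by a third variable (expression,
chromatin openness, antibody cross-reactivity); partial correlations
control for all other variables at hand, so edges represent associations
that cannot be explained away by the measured confounders.

## Who it is for

Anyone with a samples × variables signal matrix (regions × marks read
counts, or any comparable many-samples / few-variables data) who wants a
robust conditional-independence network rather than a co-occurrence
network: chromatin biologists comparing marks across cell types, and
method developers who need a rank-based, cross-validated alternative to
L1-penalized precision estimation.

## The method

Given a data matrix with n samples and p variables:

1. **Rank transform.** Each column is replaced by its ranks (midranks for
   ties). All downstream statistics become invariant under strictly
   monotone marginal transforms, which neutralizes the multimodal,
   heavy-tailed distributions of ChIP-seq counts. Pearson correlation on
   ranks is Spearman correlation of the raw data.
2. **Partial correlation matrix (PCM).** With C the correlation matrix
   and Ω = C⁻¹ its inverse, the partial correlation of variables i and j
   given all others is

       P_ij = −Ω_ij / √(Ω_ii · Ω_jj),   P_ii = 1.

3. **Significance.** Fisher's z-transform with control-adjusted degrees of
   freedom, z = atanh(P_ij) · √(n − k − 3) with k = p − 2 controls, is
   approximately standard normal under the null; two-sided p-values are
   Benjamini–Hochberg adjusted over the p(p−1)/2 edge tests.
4. **Cross-validated sparsification.** With large n every entry is
   "significant", so q-value thresholds are instead scored by prediction
   error: per fold (10-fold CV), a decreasing sweep of q-thresholds
   produces sparser matrices; each variable is predicted by OLS from its
   surviving co-variables, and the sparsest threshold whose mean test
   error stays within 10% of the min–max error range is selected. An edge
   is kept if it survives in at least 7 of 10 folds. Optionally a special
   node (e.g. `mRNA`) is completed up to 4 edges using full-data q-values.
5. **Downstream analyses.** An explaining-away *effect matrix* (which
   single control changes each pairwise correlation the most), *top-n
   overlap* statistics between conditions (hypergeometric null for two
   lists, Monte-Carlo for three or more), and *consensus networks* keeping
   edges supported by several condition-specific networks.

## Worked example

```r
library(spcnet)

truth <- random_sparse_precision(p = 8, n_edges = 10, seed = 3)  # known GGM
X     <- sample_ggm(truth, n = 2000, seed = 4)                   # 2000 regions
net   <- spcn(X, seed = 7)
net
#> sparse partial correlation network: 8 variables, 8 edges (of 28 possible)
#> folds = 10, min support = 7, tolerance = 0.10, seed = 7
spcn_edges(net)
#>   var_a var_b partial_correlation      q_value support_count provenance
#> 1    V3    V4          -0.2909338 6.535296e-40            10     masked
#> 2    V3    V5           0.2717610 9.028997e-35            10     masked
#> 3    V1    V6           0.1827320 5.721375e-16             8     masked
#> 4    V2    V6           0.2927268 2.679270e-40            10     masked
#> 5    V1    V7           0.2025573 1.982217e-19            10     masked
#> 6    V2    V7          -0.3016634 1.772066e-42            10     masked
#> 7    V3    V7          -0.2073812 2.808990e-20            10     masked
#> 8    V1    V8           0.3008034 1.772066e-42            10     masked
```

Each row is a kept edge: the signed partial correlation (sign
distinguishes co-occurrence from mutual exclusivity), its BH q-value on
the full data, how many of the 10 folds retained it, and whether it came
from the mask vote (`masked`) or special-node completion
(`mrna_completed`). All 8 reported edges are true edges of the generating
model — the pipeline favors precision over completeness, so weak true
edges may be missed but reported edges are strongly supported.

The explaining-away analysis on the same data:

```r
em <- effect_matrix(X)
em$top_explainer["V1", "V6"]   # "V3": the single control that most changes r(V1,V6)
em$top_effect["V1", "V6"]      # 0.0645: by how much
```

## Command line

```sh
spcn simulate --p 23 --edges 40 --n 12757 --seed 1 --out sim.tsv --truth truth.tsv
spcn network  --input sim.tsv --folds 10 --min-support 7 --tolerance 0.10 --seed 1 --out-prefix run1
spcn effects  --input sim.tsv --out effects.tsv
spcn overlap  --inputs m1.tsv,m2.tsv --out overlap.tsv
spcn consensus --inputs n1_edges.tsv,n2_edges.tsv --min-conditions 2 --out consensus.tsv
```

Each command writes its outputs plus a JSON metadata file (config, seed,
package version, input checksums) so every artifact is reproducible.
The `spcn` script is installed under the package's `exec/` directory
(`system.file("exec", "spcn", package = "spcnet")`); equivalently, call
`spcnet::spcn_main(c("network", "--input", ...))` from R.

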