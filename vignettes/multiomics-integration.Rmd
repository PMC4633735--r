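---
title: "Integrating metabolome and transcriptome layers by principal-component correlation clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating metabolome and transcriptome layers by principal-component correlation clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcaufe)
```

## The analysis problem

The package targets cohorts in which the same tissue samples are profiled
on several omics platforms of very different dimensionality — here a liver
cohort with four sample classes: intrahepatic cholangiocarcinoma (ICC) and
hepatocellular carcinoma (HCC) tumors plus their matched surrounding
non-tumor tissues (ICC_NT, HCC_NT), measured as metabolite abundances
(~10^2 compounds), mRNA probes (~10^3–10^4) and miRNA probes (~10^2).
The scientific questions are (i) which axes of between-sample variation
are shared across the layers, (ii) which individual features drive those
axes, and (iii) how well a small feature panel diagnoses the three
clinically relevant groups (ICC, HCC, non-tumor).

All steps up to the final validation are unsupervised: class labels never
enter the component selection or the feature selection.

## Feature-space PCA

Each layer is an N × M feature-by-sample matrix X. Rather than treating
samples as points in feature space, every *feature* is a point in the
M-dimensional sample space. From the SVD of the (feature-centered) matrix,
X = U D Vᵀ, component k carries

* a **sample contribution vector** CXᵏ (the k-th right singular vector):
  an M-vector, one entry per sample, describing the between-sample
  contrast the component encodes; and
* a **feature score** PCXᵢᵏ = (U D)ᵢₖ: feature i's coordinate along the
  component.

There are at most M components per layer, so a 32-sample cohort yields at
most 32 per layer regardless of N. Feature-mean centering is the default:
it removes each feature's baseline so that components describe
between-sample contrast, and it makes the contribution vectors exactly
zero-mean, hence exactly uncorrelated within a layer. Uncentered analysis
(`center = "none"`) is kept first-class because vendor-normalized
intensities are sometimes analysed raw; the choice is recorded in the
decomposition object. The SVD sign is fixed by orienting each contribution
vector so its largest-magnitude entry is positive; singular-value ties are
left in input order. Components with numerically zero singular values
(below 1e-12 of the largest) are dropped and the realized count reported.

## Correlation clustering of pooled components

Contribution vectors from all layers are pooled (3 × 32 = 96 vectors in
the motivating cohort) and compared by Pearson correlation r over the
shared samples. The dissimilarity is d = 1 − |r|: anticorrelated
components describe the same sample contrast with flipped orientation, so
|r| is the right notion of proximity, and the affine shift to [0, 1] gives
a proper dissimilarity without changing average-linkage topology or merge
order. Clustering is UPGMA (`stats::hclust`, average linkage).

Because same-layer components are exactly uncorrelated under centering
(asserted on every run), any cluster structure is necessarily *cross-layer*
agreement — the signature of biology shared by the platforms rather than
platform-specific variance.

**Cluster selection** formalizes two visual criteria — take the most
tightly correlated cluster, and prefer low component indices — as: cut the
tree at `cut_height`, keep clusters spanning at least `min_layers` distinct
layers, choose the one maximizing mean pairwise |r|, and break ties by the
smallest sum of member indices k. The default `cut_height = 0.6` admits
clusters whose average |r| exceeds 0.4, the conventional boundary for a
moderate correlation; it is deliberately permissive because the mean-|r|
maximization, not the cut, does the real work. When no cluster qualifies,
the error reports the nearest feasible cut so the threshold can be revised
deliberately rather than silently.

## Validating selected components: categorical regression

Class separation along a selected component is quantified by regressing
CXᵏ on the four class indicators δ_{a,i} (1 if sample i is in class a)
with cell-means coding and no intercept. The coefficient b_a is then the
class-a mean contribution, and the F test of this model against the
grand-mean-only model is algebraically one-way ANOVA across the four
classes — the package's tests hold the two routes equal to 1e-10.
Categorical coding is used instead of a numeric class score because
neither the ordering nor the spacing of the four groups is known a priori.
Degenerate inputs are handled explicitly: constant contributions give
F = 0, p = 1; zero residual variance reports p as a 0-limit with a
warning.

## Unsupervised outlier feature selection

For a layer with selected components k₁ (and possibly k₂), each feature's
scores along those axes are standardized by the across-feature spread of
the axis, and the feature's statistic is the sum of squared standardized
scores. Under the null of no signal the statistic is approximately
chi-squared with one degree of freedom per axis; upper-tail p-values are
Benjamini–Hochberg adjusted within the layer and features with adjusted
p < 0.01 are selected. A quantile rule (`score_quantile`) is available as
a model-free alternative. Empty selections are reported, not raised.

**Spread estimation matters more than the threshold.** With the default
standard deviation, the planted or real outliers themselves inflate the
axis spread: if n of N features carry signal z, the spread grows like
√(1 + n·z²/N), so the standardized statistic *saturates* near N/n no
matter how strong the signal. With 10 % of a 150-compound layer outlying —
exactly the regime of the motivating cohort, which flagged 14 of ~150
compounds and 17 of ~300 miRNAs — the saturated statistic never clears a
BH threshold at α = 0.01. The `robust = TRUE` flag replaces the standard
deviation with the MAD, whose 50 % breakdown point ignores such
contamination; it is the recommended setting whenever more than a few
percent of a layer is expected to be outlying, and it is what the
package's own synthetic-recovery checks use. The sd remains the default
because it matches the chi-squared null exactly under sparse
contamination.

## Diagnosis by leave-one-out cross-validation

The four design classes collapse to three diagnostic labels (both NT
groups pool to "non-tumor"). For each held-out sample the classifier is
trained on the remaining samples restricted to the feature panel, with
log-transformation (if configured) and per-feature standardization using
training-fold statistics only — no information from the held-out sample
reaches the model. The default classifier is linear discriminant analysis
with equal priors, the conventional choice for small-cohort microarray
LOOCV; nearest-centroid is a lighter alternative with deterministic
tie-breaking (larger training class, then label order). Folds with
singular within-class structure fall back to a diagonal-covariance
discriminant and the fallback is logged in the report. The confusion
matrix is reported with rows = predicted and columns = true, and accuracy
as 100 × trace / total rounded half *up* to two decimals (so 25/32 prints
78.13, not the banker's 78.12); the exact value is retained alongside.

## What the synthetic generator emulates

`synthetic_config()` defaults encode the motivating study conditions:
32 samples (10 ICC, 10 ICC_NT, 6 HCC, 6 HCC_NT); three layers of 150
compounds, 5000 mRNA probes, 300 miRNA probes; multiplicative noise
(Gaussian on the natural-log scale, sd 1, i.e. ~e^±1-fold scatter) around
per-feature baselines; and two planted signal patterns per layer —
tumor-vs-non-tumor shifts and ICC-only shifts, the latter scaled by 1.5 so
that ICC separates from its matched tissue more strongly than HCC does,
as observed in such cohorts. Planted counts (10/10 compounds, 40/40 mRNA,
12/12 miRNA) mirror the outlier fractions the motivating cohort reported.
Effect sizes default to 3 on the log scale (a ~20-fold median shift):
strong, unambiguous markers of the kind a diagnostic panel is built from,
and comfortably inside the ≥ 2·noise_sd regime in which planted truth is
recoverable. Generation is bit-reproducible for a given seed and restores
the caller's RNG state.

The generator deliberately omits probe-level microarray artifacts,
CE-TOFMS peak-shape effects, missing values, per-feature variance
heterogeneity (available via configuration, off by default), and any
feature-feature correlation beyond the planted class patterns. Passing
recovery tests on this generator therefore demonstrates that the pipeline
recovers planted multiplicative class structure — not that it is robust to
batch effects, missingness, or correlated backgrounds in real data.

Because the generator is log-normal by construction, the pipeline analyses
synthetic data on the log scale (`log2 = TRUE`); file input keeps values
as provided, with an optional log2 flag that is off by default.

## Problem sizes and numerical choices

The test suite exercises reduced layers (60/300/80 features) for unit
checks and the full default conditions (150/5000/300 × 32, twenty seeds)
for the recovery and null-control checks; both complete in seconds.
Tolerances: orthonormality and reconstruction at 1e-8; oracle equivalence
(ANOVA, UPGMA, Gram-matrix eigendecomposition) at 1e-10; exact-arithmetic
checks (confusion accuracy, indicator sums) with no tolerance.

Two caveats found while validating: Pearson correlation between two score
columns of one decomposition is only near zero (≈1e-4), because Pearson
re-centers the columns and score-column means are not exactly zero under
row-wise centering; the exact invariant is the zero inner product, which
is what the tests assert. And on planted two-pattern data the pooled tree
contains *two* tight cross-layer clusters (one per pattern) rather than
one spanning both, because same-layer components are exactly orthogonal;
the selector then returns the tighter of the two. Real cohorts, whose
components mix patterns unevenly across layers, can merge both patterns
into a single cluster below the cut.

## Known limitations

* The cluster selector returns a single cluster; analyses wanting both
  planted patterns should inspect the tree or run selection per pattern
  (the feature-selection stage accepts any axes).
* The chi-squared null for the selection statistic is approximate when
  scores are heavy-tailed or the spread is MAD-estimated.
* LDA on panels approaching the training-fold size relies on the
  diagonal-covariance fallback; very small classes (< 2 per diagnostic
  label) are rejected rather than modelled.
* No batch-effect handling and no missing-value support: inputs must be
  complete and finite.
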