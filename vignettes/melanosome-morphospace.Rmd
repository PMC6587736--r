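---
title: "Melanosome morphospace, convergence, and paleocolor prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melanosome morphospace, convergence, and paleocolor prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

Melanosomes — the melanin-bearing organelles preserved in feathers and in
exceptional fossils — differ systematically in size and shape between black,
brown, grey and iridescent plumage. Iridescent feathers additionally contain
four derived melanosome types (solid/hollow crossed with
cylindrical/flattened) that have evolved repeatedly across the bird tree.
`melanomorph` implements the quantitative chain that turns per-melanosome
measurements into (i) a morphospace shared by quantitative and qualitative
shape variables, (ii) disparity and phylogenetic-signal statistics on that
morphospace, (iii) a convergence score per melanosome type, and (iv) a
calibrated classifier that predicts the color class of unlabelled (fossil)
samples.

The unit of analysis throughout is the *sample*: all melanosomes measured
from one feather sample of one species. `summarize_samples()` collapses
measurements to the feature vector (mean length, mean width/diameter, aspect
ratio, CVs, flatness, hollowness, count). Aspect ratio is computed as the
mean of per-melanosome length/width ratios by default; the ratio-of-means
convention is available via the `aspect` argument because the field's usage
is ambiguous. Skew statistics are deliberately absent, and the CV of length
is computed but excluded from ordination and classification defaults: a
subsampling analysis (`subsample_stability()`) shows the CV of the sample
mean at $n = 10$ melanosomes is about $0.2/\sqrt{10} \approx 6\%$ while the
CV of the CV-of-length statistic is around 25%, far too unstable for the
small samples typical of fossil material.

# Mixed ordination

`fit_pcamix()` implements the one-SVD formulation of principal component
analysis of mixed data: quantitative columns are centered and divided by
their population standard deviation; each qualitative level contributes a
centered indicator column weighted by $n/n_s$; rows carry uniform weight
$1/n$. The total inertia is then $p_1 + (m - p_2)$ ($p_1$ quantitative
variables, $p_2$ qualitative variables with $m$ levels in total), which the
tests verify to $10^{-8}$; with no qualitative variables the method reduces
exactly to correlation PCA. Squared loadings are squared correlations
(quantitative) or correlation ratios (qualitative). Axis signs are
canonicalized by making the largest-magnitude loading on each axis positive,
so results are reproducible across platforms. Projection of new samples
standardizes with the *training* means, standard deviations and level
frequencies; projecting the training data reproduces the training scores
identically, which is the property fossil projection relies on.

A note on one edge case: a new sample sitting at the training centroid
projects to the origin only in the all-quantitative case. A qualitative
level, even the modal one, carries a nonzero centered indicator, so mixed
ordinations place such a sample near — not at — the origin. The package
documents rather than "fixes" this, since it is inherent to the MCA part of
the method.

Species with multiple samples appear as separate points in the sample-level
morphospace, but all phylogenetic analyses (pPCA, $K_{mult}$, Wheatsheaf)
use per-species means, computed by the pipeline before those stages.
`fit_ppca()` computes the GLS phylogenetic mean
$a = (1'C^{-1}1)^{-1} 1'C^{-1}X$ and evolutionary covariance
$R = (X-1a)' C^{-1} (X-1a)/(n-1)$ under the Brownian tree covariance $C$;
with three quantitative traits its scores are a rotation (plus a small
recentering) of ordinary PCA scores, so convex-hull volumes from the two
ordinations agree closely — the package's check that disparity estimates
are not artifacts of phylogenetic structure.

# Disparity geometry

Morphospace occupation is measured on the first three axes. Convex-hull
volumes come from an incremental hull construction; alpha-shape volumes
come from a Bowyer–Watson Delaunay tetrahedralization in which tetrahedra
with circumradius above `alpha` are erased — small alpha scoops out empty
space, large alpha recovers the hull. Numerical choices: the Delaunay code
applies a deterministic relative jitter of $10^{-7}$ of the point-cloud
extent to break cosphericity ties (regular grids, cube-corner fixtures);
volumes are therefore accurate to roughly one part in $10^{3}$, while hull
volumes (computed without jitter) are exact to floating-point. Alpha values
default to 1.3, 2 and 5 in score units. Degenerate clouds (fewer than four
points, or affinely dependent) raise an error from the user-facing
functions but score volume 0 inside the randomization loop, where label
permutations can make a category arbitrarily small; such permutations are
counted and reported.

The significance of the focal category's occupation is assessed by
`randomization_test()`: the statistic is the ratio of the focal (iridescent)
volume to the volume of the pooled remaining points — pooled, rather than a
sum of per-category volumes, because the scientific claim is "more volume
than everything else combined"; a switch to per-category alternatives is a
one-line change in the caller. The null shuffles labels preserving category
sizes, and $p = (1 + \#\{null \ge obs\})/(1 + n_{iter})$ with 5000
iterations by default. Sum of variances (all axes, $n-1$ denominators) with
a stratified percentile bootstrap (1000 iterations, 95% intervals)
complements the volumes because it is robust to sample-size differences.

# Phylogenetic signal

`kmult()` implements the multivariate Blomberg statistic: the ratio of the
observed mean squared distance to the phylogenetic mean over its
phylogenetically standardized counterpart ($u = C^{-1/2}(Y-1a)$), scaled by
$(\mathrm{tr}\,C - n/(1'C^{-1}1))/(n-1)$ so that Brownian motion gives
$K = 1$. $C^{-1/2}$ is built by eigendecomposition with an eigenvalue floor
of $10^{-12}$; trees with duplicated zero-length terminals are rejected
with a suggestion to jitter branch lengths. The permutation test (999
permutations by default, seeded) shuffles the species-to-tip assignment.
With one trait the statistic reduces to the univariate Blomberg $K$, which
the tests verify against an independently coded scalar formula at
$10^{-10}$ and against `phytools::phylosig` at $10^{-8}$; calibration tests
confirm the mean $\hat K_{mult}$ over 500 Brownian simulations on a fixed
32-tip tree lies in $[0.9, 1.1]$. Pagel's $\lambda$ is delegated to
`phytools::phylosig(method = "lambda")` — a standard maximum-likelihood
profile — and reported per axis alongside $K_{mult}$. Ancestral states for
the phylomorphospace are joint GLS estimates
$a + C_{nt} C_{tt}^{-1}(y - a)$, whose root equals the phylogenetic mean.

# Convergence

The Wheatsheaf index divides the mean phylogenetically corrected pairwise
phenotypic distance among all species by the same mean among the focal
(putatively convergent) species; $w > 1$ means the focal species cluster
more tightly than average. The published correction defers to its original
software; this package makes the penalty explicit and pluggable:
$d'_{ij} = d_{ij}(1 + s_{ij})$ where $s_{ij}$ is the pair's shared
root-to-tip path length as a fraction of tree depth. The form was chosen
because it inflates the distances of close relatives (convergence between
relatives is weak evidence) and vanishes on a star tree. Because the
penalty is not guaranteed to equal the original implementation's, published
$w$ values should be treated as directional, not numeric, references — the
package's own tests are therefore directional too (a tight scattered focal
group scores $w \gg 1$ and significant; a focal group spanning the extremes
of morphospace scores $w < 1$). Confidence intervals bootstrap species with
focal membership fixed; the significance null redraws focal sets of equal
size, because the hypothesis under test is about focal-set membership. The
focal group takes one species per independent origin.

# Color classification

Two models are fitted on sample summaries: quadratic discriminant analysis
(`MASS::qda`; quantitative variables only, class-frequency priors) and
multinomial logistic regression (`nnet::multinom`, softmax link, reference
class black), with variable sets chosen by exhaustive AIC ranking over all
$2^5-1$ subsets of length, diameter, aspect ratio, flatness and hollowness
(`select_variables()`; QDA subsets containing flags are skipped with a
note, and a QDA flag-rule variant instead short-circuits flagged samples to
iridescent). Performance is estimated by repeated stratified $k$-fold
cross-validation — $k = 10$ with 5 repeats by default; the repeat count is
conventional for this analysis and the fold count is the package's choice,
reduced automatically (with a warning) when a class is smaller than $k$ —
with accuracy, Cohen's $\kappa$ from the pooled confusion matrix, and a
one-sided exact binomial test against the no-information rate. Robustness
to fossilization is the *model decay*: a fixed fitted model (no
retraining, mirroring how a fossil would actually be scored) is re-applied
after shrinking length and width by 10/20/30%, and the percentage of
changed predictions at 30% is reported. Models built on aspect ratio and
flags are shrinkage-invariant by construction; size-driven models decay
substantially — the ordering the synthetic tests assert. Fossil calls
require a posterior of at least 0.5 by default; anything lower is reported
as inconclusive.

# The synthetic generator

Because the empirical measurement tables live in a paper supplement rather
than a public archive, every stage is exercised on synthetic data with the
structure the analyses assume, generated by seeded, bit-reproducible code:

* **Tree**: forward Yule simulation conditioned on the tip count, depth
  rescaled to 1 (so rates are per unit depth). Default 96 species.
* **Species traits**: log length and log width evolve by Brownian motion
  (rate 0.05 per unit depth, giving a plausible ~25% between-species spread
  before displacement). Each iridescent melanosome type is painted onto
  phylogenetically disjoint clades (2–3 independent origins per type,
  clade sizes chosen to realize an iridescent share of ~54%, matching a
  survey that oversamples iridescence); painted species are displaced a
  fraction $\gamma = 0.8$ toward the type optimum, and non-iridescent
  species toward their category optimum. Optima (length x width, µm):
  black 1.10 x 0.26, brown 0.72 x 0.36, grey 0.85 x 0.45, solid
  cylindrical 1.1 x 0.22, solid flat 1.2 x 0.45, hollow cylindrical
  1.3 x 0.35, hollow flat 2.0 x 0.90 — means near 1 µm with hollow-flat
  forms extending toward 2.5 µm, and aspect ratios from ~2 (brown) to ~5
  (solid cylindrical).
* **Measurements**: lognormal length and width around the species means
  with within-species CV 0.2 (the value empirical surveys report), 30
  melanosomes per sample, width > length resolved by swapping.

The single-step displacement is deliberately simpler than an
Ornstein–Uhlenbeck process: the package *tests* for convergence, it does
not model its generating mechanism, and the displacement suffices to make
Wheatsheaf-positive fixtures with controlled strength. What the generator
does **not** emulate: measurement error between human measurers,
correlated evolution between length and width, unbalanced per-species
sample counts, and within-category multimodality of real plumage colors.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated — not that real melanosome data will be classified
with the synthetic accuracy, which is higher than empirical accuracy
because the synthetic classes are cleaner.

# Problem sizes and defaults

Analyses default to the scale of the motivating study: ~96 species / ~100
samples, 5000 randomization iterations, 1000 bootstrap iterations, 999
permutations, 10-fold x 5-repeat CV. Calibration tests use 500 Brownian
replicates on 32 tips ($K_{mult}$), 200 replicates for type-I error and
$\lambda$ recovery, and 50 random geometry fixtures; these sizes give
Monte-Carlo error comfortably inside the asserted bands. Grafting missing
species into a reference tree attaches them at their genus crown with a
branch length equal to the crown age (preserving ultrametricity), or
halfway down a singleton congener's terminal branch (`graft_fraction`,
configurable) — the reference analyses say only that missing species were
added as generic polytomies, so the attachment depth is an explicit knob
here.

# Known limitations

* Alpha-shape volumes inherit the $\sim 0.1\%$ jitter tolerance above;
  they are not suitable for exact-geometry assertions (hull volumes are).
* The Wheatsheaf penalty is this package's explicit choice, not a
  re-derivation of the original software's internals.
* QDA assumes class-conditional normality; aspect ratios are right-skewed,
  which is one reason the multinomial model wins on every synthetic and
  reported comparison.
* The pipeline's fossil stand-ins (synthetic mode) are shrunken relabelled
  extant samples — adequate for exercising the projection/prediction path,
  not a taphonomic model.
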