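# melanomorph

Quantitative analysis of melanosome morphology in bird feathers, and
reconstruction of plumage color in fossils.

Melanosomes — the melanin-bearing organelles that survive in fossil
feathers — have sizes and shapes that track the color class of the plumage
they came from: black, brown, grey, or iridescent. Iridescent feathers
additionally carry four derived melanosome types (solid/hollow crossed with
cylindrical/flat) that evolved convergently in many bird lineages.
`melanomorph` implements the full analysis chain for this system, for
researchers working on paleocolor reconstruction and melanosome evolution:

* **Morphometrics** — collapse per-melanosome measurement tables to
  per-sample feature vectors (mean length, diameter, aspect ratio, CVs,
  flatness/hollowness flags), with a subsampling analysis of statistic
  stability at small *n*.
* **Mixed ordination** — PCA of mixed quantitative/qualitative data
  (PCAmix-type: PCA merged with multiple correspondence analysis via one
  weighted SVD), with projection of new (fossil) samples, plus phylogenetic
  PCA for bias assessment. Total inertia satisfies
  $\sum_k \lambda_k = p_1 + (m - p_2)$.
* **Disparity** — per-category convex-hull and alpha-shape volumes in 3-D
  score space (own Rcpp geometry: incremental hull, Bowyer–Watson
  Delaunay), a 5000-iteration label-randomization test, and sum of
  variances with bootstrap CIs.
* **Phylogenetic signal** — multivariate Blomberg $K_{mult}$ with
  permutation test, Pagel's $\lambda$, joint-GLS ancestral states and a
  phylomorphospace edge list.
* **Convergence** — the Wheatsheaf index
  $w = \overline{d'}_{\text{all pairs}} / \overline{d'}_{\text{focal pairs}}$
  with a phylogenetic distance penalty, bootstrap CIs, and a random-focal-set
  significance test, per melanosome type.
* **Color prediction** — QDA and multinomial logistic regression with
  exhaustive AIC variable selection, repeated stratified k-fold CV (accuracy,
  Cohen's kappa, exact test), fossilization-shrinkage decay analysis
  (10/20/30%), and posterior-threshold fossil calls.
* **Synthetic data** — a seeded generator (Yule trees, Brownian log-size
  evolution, convergent regimes painted on disjoint clades, lognormal
  within-species sampling at CV 20%) so the whole pipeline is testable
  without any external dataset.

## Worked example

```r
library(melanomorph)

sim <- simulate_dataset(simulation_config(), seed = 42)   # 96 species
summaries <- summarize_samples(sim$measurements)

ord <- fit_pcamix(summaries)
ord
#> PCAmix ordination: 96 samples, 3 quantitative + 2 qualitative variables
#> eigenvalues: 2.785, 1.417, 0.663, 0.129, 0.007
#> variance explained (%): 55.7, 28.3, 13.3, 2.6, 0.1

disp <- disparity_analysis(ord$scores, summaries$color_category, seed = 42)
disp$randomization
#> disparity randomization test (focal = iridescent )
#> observed volume ratio: 1701  p = 2e-04  ( 5000 iterations )

scores_sp <- ord$scores; rownames(scores_sp) <- summaries$species
kmult(scores_sp[sim$tree$tip.label, ], sim$tree, seed = 42)
#> K_mult = 0.2391  p = 0.001

cross_validate(summaries, "mlr", seed = 42)
#> repeated 10-fold CV (5 repeats): accuracy 96.2%, kappa 0.94, exact p 4.1e-121

mlr <- fit_color_classifier(summaries, "mlr")
model_decay(mlr, summaries)$decay_pct   # % of calls changed at 30% shrinkage
#> [1] 34.375

fossil <- data.frame(sample_id = "fossil_1", mean_length_um = 1.05,
                     mean_width_um = 0.31, aspect_ratio = 3.4,
                     flatness = FALSE, hollowness = TRUE)
predict_fossil(mlr, fossil)
#>   sample_id   p_black  p_brown   p_grey p_iridescent       call threshold
#> 1  fossil_1 2.97e-107 2.64e-77 1.1e-171            1 iridescent       0.5
```

Reading the output: the mixed ordination spreads 5 units of inertia over
five axes (3 quantitative variables + 2 binary flags); the first two axes
carry 84% of the variation. Iridescent samples occupy vastly more of the
3-D morphospace than all other categories pooled (ratio 1701, permutation
p = 2e-4 — the synthetic regimes are deliberately well separated).
Phylogenetic signal on the score space is well below the Brownian
expectation of 1, as expected when convergent optima dominate trait values,
but still significant. The multinomial classifier recovers the color class
of held-out samples far above the no-information rate, and changes about a
third of its calls under 30% linear shrinkage; a hollow-flagged fossil with
~1 µm melanosomes is called iridescent.

Real measurement tables (CSV/TSV with columns `sample_id, species,
color_category, melanosome_type, length_um, width_um`) and a Newick
reference tree run through the same chain via `run_pipeline()` /
`pipeline_config()`, or from a shell through
`inst/scripts/run_pipeline.R`; missing species are grafted into the tree as
generic polytomies by `prune_and_graft()`.

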