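Package: melanomorph
Title: Melanosome Morphospace, Convergence, and Paleocolor Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework for analysing melanosome morphology in
    bird feathers and reconstructing plumage color in fossils. Places
    per-sample melanosome morphometrics (mean length, width, aspect ratio,
    flatness, hollowness) in a mixed quantitative/qualitative morphospace
    (PCAmix-type ordination with projection of new samples), quantifies
    morphological disparity per color category via 3-D convex-hull and
    alpha-shape volumes, sum of variances with bootstrap intervals, and a
    label-randomization test, measures multivariate phylogenetic signal
    (K_mult) and Pagel's lambda, scores strength of convergent evolution of
    iridescence-generating melanosome types with the Wheatsheaf index, and
    trains quadratic discriminant and multinomial logistic classifiers to
    predict color class (black, brown, grey, iridescent) of fossil
    melanosome samples, including sensitivity to fossilization shrinkage.
    A seeded synthetic-data generator (pure-birth trees, Brownian trait
    evolution with convergent regimes, lognormal within-species sampling)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    MASS,
    nnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
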