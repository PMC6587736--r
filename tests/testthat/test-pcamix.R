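random_summaries <- function(n, seed, with_flags = TRUE) {
  set.seed(seed)
  df <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    species = sprintf("sp%03d", seq_len(n)),
    color_category = sample(COLOR_CATEGORIES, n, replace = TRUE),
    mean_length_um = exp(rnorm(n, 0, 0.3)),
    mean_width_um = exp(rnorm(n, -1, 0.3)),
    aspect_ratio = exp(rnorm(n, 1, 0.4)),
    stringsAsFactors = FALSE)
  if (with_flags) {
    df$flatness <- runif(n) < 0.3
    df$hollowness <- runif(n) < 0.3
    # guard against a constant flag in small draws
    if (length(unique(df$flatness)) == 1) df$flatness[1] <- !df$flatness[1]
    if (length(unique(df$hollowness)) == 1)
      df$hollowness[1] <- !df$hollowness[1]
  }
  df
}

test_that("all-quantitative PCAmix equals correlation PCA", {
  for (seed in c(1, 2, 3)) {
    s <- random_summaries(60, seed, with_flags = FALSE)
    ord <- fit_pcamix(s, qualitative = character(0))
    X <- as.matrix(s[, c("mean_length_um", "mean_width_um", "aspect_ratio")])
    oracle <- eigen(cor(X), symmetric = TRUE)$values
    expect_equal(ord$eigenvalues, oracle, tolerance = 1e-8)
    expect_equal(sum(ord$eigenvalues), 3, tolerance = 1e-8)
  }
})

test_that("mixed ordination satisfies the inertia accounting", {
  s <- random_summaries(80, 4)
  ord <- fit_pcamix(s)
  # 3 quantitative + 2 binary -> exactly five positive-inertia axes
  expect_equal(length(ord$eigenvalues), 5)
  expect_equal(sum(ord$eigenvalues), 5, tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  # scores are centered per axis
  expect_lt(max(abs(colMeans(ord$scores))), 1e-10)
  # squared loadings of qualitative variables are correlation ratios in [0,1]
  expect_true(all(ord$sqloadings >= -1e-10 & ord$sqloadings <= 1 + 1e-10))

  # a 3-level qualitative variable contributes m_s - 1 = 2 to inertia
  s$shape3 <- sample(c("a", "b", "c"), nrow(s), replace = TRUE)
  ord3 <- fit_pcamix(s, qualitative = c("flatness", "hollowness", "shape3"))
  expect_equal(sum(ord3$eigenvalues), 7, tolerance = 1e-8)

  # duplicating every sample leaves the spectrum unchanged
  dup <- rbind(s, s)
  dup$sample_id <- sprintf("s%03d", seq_len(nrow(dup)))
  expect_equal(fit_pcamix(dup)$eigenvalues, ord$eigenvalues,
               tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  s <- random_summaries(30, 5)
  s$mean_width_um <- 1
  expect_error(fit_pcamix(s), "constant")
  s2 <- random_summaries(30, 6)
  s2$flatness <- FALSE
  expect_error(fit_pcamix(s2), "constant")
  expect_error(fit_pcamix(random_summaries(2, 7)), "at least 3")
})

test_that("projection reproduces training scores and locates new samples", {
  s <- random_summaries(100, 8)
  ord <- fit_pcamix(s)
  pr <- predict(ord, s)
  expect_lt(max(abs(pr - ord$scores)), 1e-10)

  # quantitative-only: the training centroid projects to the origin
  ordq <- fit_pcamix(s, qualitative = character(0))
  centroid <- data.frame(mean_length_um = mean(s$mean_length_um),
                         mean_width_um = mean(s$mean_width_um),
                         aspect_ratio = mean(s$aspect_ratio))
  expect_lt(max(abs(predict(ordq, centroid))), 1e-10)

  expect_error(predict(ord, centroid), "missing")
  unseen <- s[1, ]
  unseen$flatness <- "maybe"
  expect_error(predict(ord, unseen), "unseen")
})

test_that("a fossil with a cluster's morphology projects into that cluster", {
  sim <- simulate_dataset(simulation_config(n_species = 96, gamma = 1),
                          seed = 15)
  s <- summarize_samples(sim$measurements)
  ord <- fit_pcamix(s)
  groups <- ifelse(s$color_category == "iridescent",
                   sim$species_traits$melanosome_type[
                     match(s$species, sim$species_traits$species)],
                   s$color_category)
  centroids <- apply(ord$scores, 2, function(sc) tapply(sc, groups, mean))

  hc <- s[groups == "hollow_cylindrical", ][1, ]
  fossil <- data.frame(mean_length_um = hc$mean_length_um,
                       mean_width_um = hc$mean_width_um,
                       aspect_ratio = hc$aspect_ratio,
                       flatness = FALSE, hollowness = TRUE)
  fsc <- predict(ord, fossil)
  dists <- apply(centroids, 1, function(ce) sqrt(sum((fsc - ce)^2)))
  expect_equal(names(which.min(dists)), "hollow_cylindrical")
})

test_that("ordination JSON round-trip preserves the projection", {
  s <- random_summaries(50, 9)
  ord <- fit_pcamix(s)
  path <- withr::local_tempfile(fileext = ".json")
  write_ordination(ord, path)
  back <- read_ordination(path)
  expect_equal(predict(back, s), predict(ord, s), tolerance = 1e-12)
  expect_equal(back$eigenvalues, ord$eigenvalues, tolerance = 1e-12)
})

test_that("phylogenetic PCA matches its closed forms and phytools", {
  # star tree with unit branches: C = I, so pPCA is covariance PCA
  star <- ape::stree(20, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3,
              dimnames = list(star$tip.label,
                              c("mean_length_um", "mean_width_um",
                                "aspect_ratio")))
  pp <- fit_ppca(X, star)
  Xc <- scale(X, scale = FALSE)
  oracle <- eigen(cov(Xc), symmetric = TRUE)$values
  expect_equal(pp$values, oracle[oracle > 1e-12], tolerance = 1e-10)
  expect_equal(unname(pp$evol_mean), unname(colMeans(X)), tolerance = 1e-10)

  # general tree: agree with the reference implementation
  tree <- simulate_tree(simulation_config(n_species = 24), seed = 11)
  set.seed(12)
  Y <- matrix(rnorm(72), 24, 3, dimnames = list(tree$tip.label, NULL))
  pp2 <- fit_ppca(Y, tree)
  ref <- phytools::phyl.pca(tree, Y, method = "BM", mode = "cov")
  expect_equal(pp2$values, unname(diag(ref$Eval)), tolerance = 1e-8)
  expect_equal(abs(unname(pp2$scores)), abs(unname(ref$S)),
               tolerance = 1e-8)

  expect_error(fit_ppca(Y[1:10, ], tree), "mismatch")
  # two species: rank <= 1 spectrum
  tree2 <- ape::read.tree(text = "(a:1,b:1);")
  X2 <- matrix(c(1, 2, 0, 1, 3, 5), 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_lte(length(fit_ppca(X2, tree2)$values), 1)
})

test_that("pPCA and PCA give similar hull volumes (rigid-rotation check)", {
  sim <- simulate_dataset(simulation_config(n_species = 96), seed = 16)
  s <- summarize_samples(sim$measurements)
  X <- as.matrix(s[, c("mean_length_um", "mean_width_um", "aspect_ratio")])
  rownames(X) <- s$species
  X <- scale(X)
  pp <- fit_ppca(X, sim$tree)
  pca_scores <- prcomp(X)$x
  v_pca <- hull_volume(pca_scores[, 1:3])
  v_ppca <- hull_volume(pp$scores[, 1:3])
  expect_lt(abs(v_pca - v_ppca) / v_pca, 0.10)
})
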