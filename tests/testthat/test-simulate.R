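no_regime_config <- function(...) {
  simulation_config(type_regimes = default_type_regimes()[0, ],
                    category_proportions = c(black = 0.4, brown = 0.3,
                                             grey = 0.3, iridescent = 0),
                    ...)
}

test_that("simulate_tree produces seeded ultrametric pure-birth trees", {
  cfg <- simulation_config(n_species = 2)
  tr <- simulate_tree(cfg, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(depths[1], depths[2]) # a single cherry, contemporaneous tips

  cfg <- simulation_config(n_species = 40)
  t1 <- simulate_tree(cfg, seed = 9)
  t2 <- simulate_tree(cfg, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1)

  expect_error(simulation_config(n_species = 1))
})

test_that("lineage counts at half depth match a brute-force Yule simulator", {
  # same conditioned process, two independent code paths
  cfg <- simulation_config(n_species = 64)
  set.seed(101)
  mine <- replicate(400, lineages_at(simulate_tree(cfg), 0.5))
  set.seed(202)
  oracle <- replicate(2000, yule_lineage_count_at(64, 1, 0.5))
  # means agree within Monte-Carlo error
  se <- sqrt(var(mine) / length(mine) + var(oracle) / length(oracle))
  expect_lt(abs(mean(mine) - mean(oracle)), 4 * se + 0.5)
})

test_that("species traits follow Brownian motion with the tree covariance", {
  cfg <- no_regime_config(n_species = 32, bm_rate = 0.1, gamma = 0)
  tree <- simulate_tree(cfg, seed = 5)
  C <- ape::vcv(tree)

  reps <- 600
  lens <- matrix(NA_real_, reps, 32)
  for (r in seq_len(reps)) {
    tr <- simulate_species_traits(tree, cfg, seed = 1000 + r)
    lens[r, ] <- tr$true_mean_log_length[match(tree$tip.label, tr$species)]
  }
  emp <- cov(lens)
  expect_lt(max(abs(emp - 0.1 * C)), 0.025) # elementwise, MC tolerance

  # degenerate rate: every species at the root state
  cfg0 <- no_regime_config(n_species = 16, bm_rate = 0, gamma = 0)
  tr0 <- simulate_species_traits(simulate_tree(cfg0, seed = 2), cfg0, seed = 3)
  expect_equal(var(tr0$true_mean_log_length), 0)
  expect_equal(var(tr0$true_mean_log_width), 0)
})

test_that("gamma = 1 pins painted species at the regime optimum", {
  cfg <- simulation_config(n_species = 48, gamma = 1)
  tree <- simulate_tree(cfg, seed = 7)
  tr <- simulate_species_traits(tree, cfg, seed = 8)
  reg <- cfg$type_regimes
  for (r in seq_len(nrow(reg))) {
    painted <- tr[!is.na(tr$melanosome_type) &
                    tr$melanosome_type == reg$melanosome_type[r], ]
    expect_gt(nrow(painted), 0)
    expect_equal(painted$true_mean_log_length,
                 rep(log(reg$optimum_length_um[r]), nrow(painted)))
    expect_equal(painted$true_mean_log_width,
                 rep(log(reg$optimum_width_um[r]), nrow(painted)))
  }
  # each regime got its requested number of independent origins
  origins <- table(tr$melanosome_type[!duplicated(tr$origin_id) &
                                        !is.na(tr$origin_id)])
  expect_equal(as.integer(origins[reg$melanosome_type]), reg$n_origins)
})

test_that("melanosome sampling honors the within-species CV", {
  cfg <- simulation_config(n_species = 4, within_species_cv = 0.2,
                           melanosomes_per_sample = 2000, gamma = 1)
  traits <- data.frame(species = "spA", color_category = "black",
                       melanosome_type = NA_character_, origin_id = NA,
                       true_mean_log_length = log(1.0),
                       true_mean_log_width = log(0.3))
  tab <- sample_melanosomes(traits, cfg, seed = 11)
  expect_equal(nrow(tab), 2000)
  cv <- sd(tab$length_um) / mean(tab$length_um)
  expect_gt(cv, 0.18); expect_lt(cv, 0.22)
  expect_lt(abs(mean(tab$length_um) - 1.0), 0.02)

  # degenerate CV: identical melanosomes
  cfg0 <- simulation_config(within_species_cv = 0,
                            melanosomes_per_sample = 50)
  tab0 <- sample_melanosomes(traits, cfg0, seed = 12)
  expect_equal(var(tab0$length_um), 0)

  # hollow-flat-like optimum of 2.5 um shows up in the sample means
  big <- traits
  big$true_mean_log_length <- log(2.5)
  tabb <- sample_melanosomes(big, cfg, seed = 13)
  expect_lt(abs(mean(tabb$length_um) - 2.5), 0.1)
})

test_that("shrinkage scales dimensions and leaves aspect ratios unchanged", {
  tab <- make_measurement_table(n_samples = 4, n_per_sample = 10, seed = 6)
  expect_equal(apply_shrinkage(tab, 0), tab)
  shr <- apply_shrinkage(tab, 0.3)
  expect_equal(shr$length_um, tab$length_um * 0.7)
  expect_equal(shr$length_um / shr$width_um, tab$length_um / tab$width_um)
  expect_error(apply_shrinkage(tab, 1))
})

test_that("generated composition matches configured proportions", {
  cfg <- simulation_config(n_species = 64)
  tree <- simulate_tree(cfg, seed = 20)
  counts <- c(black = 0, brown = 0, grey = 0)
  irid_share <- numeric(200)
  for (r in 1:200) {
    tr <- simulate_species_traits(tree, cfg, seed = 3000 + r)
    tt <- table(factor(tr$color_category, levels = COLOR_CATEGORIES))
    counts <- counts + tt[c("black", "brown", "grey")]
    irid_share[r] <- tt["iridescent"] / 64
  }
  p3 <- cfg$category_proportions[c("black", "brown", "grey")]
  p3 <- p3 / sum(p3)
  chi <- suppressWarnings(stats::chisq.test(counts, p = p3))
  expect_gt(chi$p.value, 0.01)
  # iridescent share realized through painted clades tracks its proportion
  expect_lt(abs(mean(irid_share) -
                  cfg$category_proportions["iridescent"]), 0.12)
})

test_that("the full synthetic dataset is bit-reproducible given the seed", {
  cfg <- simulation_config(n_species = 24)
  d1 <- simulate_dataset(cfg, seed = 77)
  d2 <- simulate_dataset(cfg, seed = 77)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$species_traits, d2$species_traits)
  expect_identical(d1$measurements, d2$measurements)
  expect_error(simulate_dataset(cfg), "seed")
})
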