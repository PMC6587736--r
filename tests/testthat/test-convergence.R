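test_that("Wheatsheaf index has its defining fixed points", {
  tree <- simulate_tree(simulation_config(n_species = 12), seed = 70)
  set.seed(71)
  X <- matrix(rnorm(36), 12, 3, dimnames = list(tree$tip.label, NULL))
  # focal = everyone: numerator and denominator coincide
  res <- wheatsheaf(X, tree, focal = tree$tip.label, n_boot = 50, seed = 1)
  expect_equal(res$w, 1)
  expect_error(wheatsheaf(X, tree, focal = tree$tip.label[1]), ">= 2")
  expect_error(wheatsheaf(X, tree, focal = c("nope", "nah")), "not in data")
})

test_that("Wheatsheaf equals the brute-force pairwise oracle", {
  tree <- simulate_tree(simulation_config(n_species = 12), seed = 72)
  set.seed(73)
  X <- matrix(rnorm(48), 12, 4, dimnames = list(tree$tip.label, NULL))
  for (k in c(2, 4, 6)) {
    focal <- sample(tree$tip.label, k)
    mine <- wheatsheaf(X, tree, focal, n_boot = 10, seed = 2)$w
    expect_equal(mine, wheatsheaf_brute(X, tree, focal), tolerance = 1e-12)
  }
  # dropping a non-focal species still matches a from-scratch computation
  focal <- sort(tree$tip.label)[1:3]
  keep <- setdiff(tree$tip.label, sort(tree$tip.label)[10])
  sub_tree <- ape::keep.tip(tree, keep)
  mine <- wheatsheaf(X[keep, ], sub_tree, focal, n_boot = 10, seed = 3)$w
  expect_equal(mine, wheatsheaf_brute(X[keep, ], sub_tree, focal),
               tolerance = 1e-12)
})

test_that("convergent focal groups score w >> 1 and significant", {
  tree <- simulate_tree(simulation_config(n_species = 24), seed = 74)
  set.seed(75)
  X <- matrix(rnorm(48, sd = 2), 24, 2, dimnames = list(tree$tip.label, NULL))
  # phylogenetically scattered focal species with near-identical phenotypes
  focal <- tree$tip.label[c(1, 8, 16, 23)]
  X[focal, ] <- matrix(rep(c(5, 5), each = 4), 4, 2) +
    matrix(rnorm(8, sd = 0.05), 4, 2)
  res <- wheatsheaf(X, tree, focal, n_boot = 1000, seed = 4)
  expect_gt(res$w, 2)
  expect_lte(res$p_value, 0.05)
  expect_lte(res$ci95[1], res$w); expect_gte(res$ci95[2], res$w)

  # determinism
  res2 <- wheatsheaf(X, tree, focal, n_boot = 1000, seed = 4)
  expect_identical(res$w, res2$w)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$ci95, res2$ci95)
})

test_that("a focal group spanning the extremes of morphospace has w < 1", {
  tree <- simulate_tree(simulation_config(n_species = 20), seed = 76)
  set.seed(77)
  X <- matrix(rnorm(40, sd = 0.3), 20, 2,
              dimnames = list(tree$tip.label, NULL))
  focal <- tree$tip.label[c(2, 9, 17)]
  X[focal, ] <- rbind(c(-6, -6), c(6, 6), c(6, -6)) # extreme corners
  res <- wheatsheaf(X, tree, focal, n_boot = 200, seed = 5)
  expect_lt(res$w, 1)
})

test_that("w is invariant to uniform scaling (and rotation, unstandardized)", {
  tree <- simulate_tree(simulation_config(n_species = 16), seed = 78)
  set.seed(79)
  X <- matrix(rnorm(48), 16, 3, dimnames = list(tree$tip.label, NULL))
  focal <- tree$tip.label[c(3, 11)]
  w0 <- wheatsheaf(X, tree, focal, n_boot = 10, seed = 6)$w
  expect_equal(wheatsheaf(X * 4.2, tree, focal, n_boot = 10, seed = 6)$w,
               w0, tolerance = 1e-12)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  wu <- wheatsheaf(X, tree, focal, n_boot = 10, seed = 6,
                   standardize = FALSE)$w
  expect_equal(wheatsheaf(X %*% R, tree, focal, n_boot = 10, seed = 6,
                          standardize = FALSE)$w, wu, tolerance = 1e-10)
})

test_that("convergence_report flags the convergent types, skips singletons", {
  tree <- simulate_tree(simulation_config(n_species = 32), seed = 80)
  sp <- tree$tip.label
  set.seed(81)
  scores <- matrix(rnorm(32 * 5, sd = 1.5), 32, 5,
                   dimnames = list(sp, NULL))
  traits <- matrix(rnorm(32 * 3, sd = 1.5), 32, 3, dimnames = list(sp, NULL))
  # three tightly convergent types (2 origins each), one diffuse type
  assign <- data.frame(species = sp, melanosome_type = NA, origin_id = NA)
  put <- function(idx, type, ids, center) {
    assign$melanosome_type[idx] <<- type
    assign$origin_id[idx] <<- ids
    scores[idx, ] <<- matrix(rep(center, each = length(idx)),
                             length(idx)) + rnorm(length(idx) * 5, sd = 0.05)
    traits[idx, ] <<- center[1:3] + rnorm(length(idx) * 3, sd = 0.05)
  }
  put(c(1, 15), "solid_cylindrical", 1:2, rep(4, 5))
  put(c(4, 20), "solid_flat", 3:4, rep(-4, 5))
  put(c(8, 26), "hollow_cylindrical", 5:6, c(4, -4, 4, -4, 4))
  # hollow_flat: two origins at opposite extremes -> no convergence
  assign$melanosome_type[c(11, 30)] <- "hollow_flat"
  assign$origin_id[c(11, 30)] <- 7:8
  scores[11, ] <- rep(9, 5); scores[30, ] <- rep(-9, 5)
  traits[11, ] <- rep(9, 3); traits[30, ] <- rep(-9, 3)

  rep_out <- convergence_report(scores, traits, tree, assign,
                                n_boot = 500, seed = 82)
  sc <- rep_out[rep_out$trait_space == "scores", ]
  expect_true(all(sc$p_value[sc$melanosome_type != "hollow_flat"] <= 0.05))
  expect_gt(min(sc$w[sc$melanosome_type != "hollow_flat"]), 1)
  expect_gt(sc$p_value[sc$melanosome_type == "hollow_flat"], 0.05)
  expect_lt(sc$w[sc$melanosome_type == "hollow_flat"], 1)

  # a single-origin type is skipped with a note
  assign2 <- assign
  assign2$origin_id[assign2$species == sp[15]] <- 1 # merge the two origins
  assign2 <- assign2[assign2$species %in% sp[c(1, 15)] |
                       is.na(assign2$melanosome_type), ]
  rep2 <- convergence_report(scores, traits, tree, assign2,
                             n_boot = 50, seed = 83)
  expect_match(rep2$note[rep2$melanosome_type == "solid_cylindrical"],
               "single origin")

  # seeded rerun is identical
  rep3 <- convergence_report(scores, traits, tree, assign,
                             n_boot = 500, seed = 82)
  expect_identical(rep_out, rep3)
})
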