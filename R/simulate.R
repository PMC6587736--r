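# Synthetic data generator: pure-birth trees, Brownian species traits with
# convergent regimes painted onto disjoint clades, and lognormal
# per-melanosome sampling. These emulate the statistical structure of a
# multi-order survey of feather melanosomes: four color categories with
# distinct size distributions, four iridescence-generating melanosome types
# (solid/hollow x cylindrical/flat) each arising convergently several times,
# within-species measurement CV near 20%, mean lengths near 1 micrometre
# with hollow-flat forms reaching 2.5 micrometres.

#' Default regimes for the four iridescence-generating melanosome types
#'
#' Optima are species mean length/width in micrometres (stored on the log
#' scale); each regime is painted onto `n_origins` phylogenetically disjoint
#' clades to mimic independent origins.
#'
#' @export
default_type_regimes <- function() {
  data.frame(
    melanosome_type = MELANOSOME_TYPES,
    n_origins = c(3L, 2L, 3L, 2L),
    optimum_length_um = c(1.1, 1.2, 1.3, 2.0),
    optimum_width_um = c(0.22, 0.45, 0.35, 0.90),
    flatness = c(FALSE, TRUE, FALSE, TRUE),
    hollowness = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults mirror
#' the scale of the empirical study the analyses are designed for: ~100
#' species across many orders; four color categories; iridescent types with
#' 2-3 independent origins each; within-species coefficient of variation of
#' 0.2; ~30 melanosomes measured per sample.
#'
#' @param n_species number of species (tree tips).
#' @param birth_rate pure-birth speciation rate (tree depth is rescaled to
#'   1, so this only shapes relative node ages).
#' @param category_proportions 4-simplex over black/brown/grey/iridescent;
#'   the iridescent share is realized through painted clades, the other
#'   three are renormalized over the remaining tips.
#' @param type_regimes data.frame as [default_type_regimes()].
#' @param bm_rate Brownian-motion variance per unit tree depth on the log
#'   size scale.
#' @param gamma displacement fraction toward a regime/category optimum
#'   (1 = species sit exactly at the optimum).
#' @param within_species_cv coefficient of variation of melanosome length
#'   and width within a species.
#' @param melanosomes_per_sample melanosomes drawn per sample.
#' @param max_clade_size largest clade a single regime origin may paint.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_species = 96,
                              birth_rate = 1,
                              category_proportions = c(black = 0.18,
                                                       brown = 0.14,
                                                       grey = 0.14,
                                                       iridescent = 0.54),
                              type_regimes = default_type_regimes(),
                              bm_rate = 0.05,
                              gamma = 0.8,
                              within_species_cv = 0.2,
                              melanosomes_per_sample = 30,
                              max_clade_size = 6) {
  stopifnot(n_species >= 2, birth_rate > 0, bm_rate >= 0,
            gamma >= 0, gamma <= 1, within_species_cv >= 0,
            melanosomes_per_sample >= 1)
  if (abs(sum(category_proportions) - 1) > 1e-8)
    stop("category_proportions must sum to 1")
  if (!all(names(category_proportions) == COLOR_CATEGORIES))
    stop("category_proportions must be named black, brown, grey, iridescent")
  if (any(type_regimes$n_origins < 1)) stop("n_origins must be >= 1")
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 category_proportions = category_proportions,
                 type_regimes = type_regimes, bm_rate = bm_rate,
                 gamma = gamma, within_species_cv = within_species_cv,
                 melanosomes_per_sample = melanosomes_per_sample,
                 max_clade_size = max_clade_size),
            class = "sim_config")
}

# category optima for the non-iridescent classes (mean length/width, um);
# aspect ratios span roughly 2 (brown) to 4+ (black), as in feather
# melanosome surveys
CATEGORY_OPTIMA <- list(
  black = c(length = 1.10, width = 0.26),
  brown = c(length = 0.72, width = 0.36),
  grey  = c(length = 0.85, width = 0.45)
)

#' Simulate an ultrametric pure-birth tree
#'
#' Forward (event-by-event) Yule simulation: starting from two lineages,
#' each lineage splits at rate `birth_rate`; after the tree reaches
#' `n_species` lineages one further exponential waiting time is appended and
#' all lineages are cut there, giving an ultrametric tree. Depth is rescaled
#' to 1. Bit-reproducible given `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return an ultrametric `phylo` with `n_species` tips, depth 1.
#' @export
simulate_tree <- function(config, seed = NULL) {
  n <- config$n_species
  if (n < 2) stop("n_species must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  b <- config$birth_rate
  # lineage records: birth time, children (0 = leaf), split time
  btime <- c(0, 0)
  child1 <- c(NA_integer_, NA_integer_)
  child2 <- c(NA_integer_, NA_integer_)
  stime <- c(NA_real_, NA_real_)
  active <- c(1L, 2L)
  t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + rexp(1, rate = k * b)
    who <- active[sample.int(k, 1)]
    stime[who] <- t
    id1 <- length(btime) + 1L
    id2 <- id1 + 1L
    btime <- c(btime, t, t)
    child1 <- c(child1, NA_integer_, NA_integer_)
    child2 <- c(child2, NA_integer_, NA_integer_)
    stime <- c(stime, NA_real_, NA_real_)
    child1[who] <- id1
    child2[who] <- id2
    active <- c(setdiff(active, who), id1, id2)
  }
  t_end <- t + rexp(1, rate = n * b)
  labels <- sprintf("sp%03d", seq_len(n))
  leaf_counter <- 0L
  newick <- function(id) {
    end_t <- if (is.na(stime[id])) t_end else stime[id]
    bl <- (end_t - btime[id]) / t_end
    if (is.na(child1[id])) {
      leaf_counter <<- leaf_counter + 1L
      paste0(labels[leaf_counter], ":", format(bl, digits = 17))
    } else {
      paste0("(", newick(child1[id]), ",", newick(child2[id]), "):",
             format(bl, digits = 17))
    }
  }
  txt <- paste0("(", newick(1L), ",", newick(2L), ");")
  tree <- ape::read.tree(text = txt)
  validate_tree(tree)
  tree
}

#' Simulate species-level traits with convergent regimes
#'
#' Log mean length and log mean width evolve by Brownian motion along the
#' tree (rate `bm_rate` per unit depth). Each iridescent melanosome-type
#' regime is painted onto `n_origins` phylogenetically disjoint clades;
#' painted species are displaced a fraction `gamma` toward the regime
#' optimum. Remaining species receive a non-iridescent category
#' (black/brown/grey, renormalized proportions) and the same single-step
#' displacement toward that category's optimum, giving the four categories
#' distinct size distributions.
#'
#' @param tree ultrametric `phylo`.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return data.frame with one row per species: `species`,
#'   `color_category`, `melanosome_type` (`NA` for non-iridescent),
#'   `origin_id` (regime origin index, `NA` otherwise),
#'   `true_mean_log_length`, `true_mean_log_width`.
#' @export
simulate_species_traits <- function(tree, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  C <- ape::vcv(tree)
  root <- c(length = log(0.90), width = log(0.33))
  L <- chol(config$bm_rate * C + diag(1e-12, n))
  dev_len <- as.numeric(t(L) %*% rnorm(n))
  dev_wid <- as.numeric(t(L) %*% rnorm(n))
  log_len <- setNames(root["length"] + dev_len, rownames(C))
  log_wid <- setNames(root["width"] + dev_wid, rownames(C))

  # pick disjoint clades for the regime origins
  regimes <- config$type_regimes
  total_origins <- sum(regimes$n_origins)
  if (n < total_origins)
    stop("tree has fewer tips than total regime origins")
  clade_tips <- tip_sets(tree)
  sizes <- vapply(clade_tips, length, integer(1))
  candidates <- which(sizes >= 1 & sizes <= config$max_clade_size)
  # prefer clade sizes that realize the configured iridescent share
  target_total <- round(config$category_proportions["iridescent"] * n)
  per_origin <- max(1, round(target_total / max(total_origins, 1)))
  pref <- abs(sizes[candidates] - per_origin) + runif(length(candidates))
  candidates <- candidates[order(pref)]
  used <- character(0)
  assignment <- data.frame(species = tree$tip.label,
                           color_category = NA_character_,
                           melanosome_type = NA_character_,
                           origin_id = NA_integer_,
                           stringsAsFactors = FALSE)
  origin_counter <- 0L
  for (r in seq_len(nrow(regimes))) {
    placed <- 0L
    for (cand in candidates) {
      if (placed >= regimes$n_origins[r]) break
      tips <- clade_tips[[cand]]
      if (length(intersect(tips, used)) > 0) next
      used <- c(used, tips)
      origin_counter <- origin_counter + 1L
      idx <- match(tips, assignment$species)
      assignment$color_category[idx] <- "iridescent"
      assignment$melanosome_type[idx] <- regimes$melanosome_type[r]
      assignment$origin_id[idx] <- origin_counter
      placed <- placed + 1L
    }
    if (placed < regimes$n_origins[r])
      stop("could not place ", regimes$n_origins[r], " disjoint origins for ",
           regimes$melanosome_type[r], "; reduce n_origins or max_clade_size")
  }
  # non-iridescent categories for the remaining tips
  rest <- which(is.na(assignment$color_category))
  p3 <- config$category_proportions[c("black", "brown", "grey")]
  p3 <- p3 / sum(p3)
  assignment$color_category[rest] <-
    sample(names(p3), length(rest), replace = TRUE, prob = p3)

  # single-step displacement toward the regime/category optimum
  g <- config$gamma
  for (i in seq_len(n)) {
    sp <- assignment$species[i]
    if (assignment$color_category[i] == "iridescent") {
      r <- match(assignment$melanosome_type[i], regimes$melanosome_type)
      opt <- c(log(regimes$optimum_length_um[r]),
               log(regimes$optimum_width_um[r]))
    } else {
      o <- CATEGORY_OPTIMA[[assignment$color_category[i]]]
      opt <- log(o)
    }
    log_len[sp] <- log_len[sp] + g * (opt[1] - log_len[sp])
    log_wid[sp] <- log_wid[sp] + g * (opt[2] - log_wid[sp])
  }
  assignment$true_mean_log_length <- unname(log_len[assignment$species])
  assignment$true_mean_log_width <- unname(log_wid[assignment$species])
  assignment
}

# tips descending from each node (tips themselves included as singletons)
tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  children <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", n + nn)
  fill <- function(node) {
    if (node <= n) {
      sets[[node]] <<- tree$tip.label[node]
    } else {
      kids <- children[[as.character(node)]]
      for (k in kids) fill(k)
      sets[[node]] <<- unlist(sets[kids], use.names = FALSE)
    }
  }
  fill(n + 1L)
  sets
}

#' Draw per-melanosome measurements for simulated species
#'
#' For each species, melanosome length and width are lognormal around the
#' species means with the configured within-species coefficient of
#' variation; rows where width exceeds length are fixed by swapping.
#'
#' @param species_traits output of [simulate_species_traits()].
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return a validated measurement table (one sample per species,
#'   `sample_id = <species>_s1`).
#' @export
sample_melanosomes <- function(species_traits, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cv <- config$within_species_cv
  sdlog <- sqrt(log(1 + cv^2))
  out <- vector("list", nrow(species_traits))
  for (i in seq_len(nrow(species_traits))) {
    n <- config$melanosomes_per_sample
    mean_len <- exp(species_traits$true_mean_log_length[i])
    mean_wid <- exp(species_traits$true_mean_log_width[i])
    len <- rlnorm(n, meanlog = log(mean_len) - sdlog^2 / 2, sdlog = sdlog)
    wid <- rlnorm(n, meanlog = log(mean_wid) - sdlog^2 / 2, sdlog = sdlog)
    swap <- wid > len
    if (any(swap)) {
      tmp <- len[swap]
      len[swap] <- wid[swap]
      wid[swap] <- tmp
    }
    out[[i]] <- data.frame(
      sample_id = paste0(species_traits$species[i], "_s1"),
      species = species_traits$species[i],
      color_category = species_traits$color_category[i],
      melanosome_type = species_traits$melanosome_type[i],
      length_um = len, width_um = wid,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  validate_measurements(tab)
  tab
}

#' Shrink melanosome dimensions to mimic fossilization
#'
#' Multiplies length and width by `1 - fraction`; type flags and therefore
#' aspect ratios are unchanged.
#'
#' @param table measurement table.
#' @param fraction shrinkage fraction in `[0, 1)`.
#' @export
apply_shrinkage <- function(table, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  validate_measurements(table)
  table$length_um <- table$length_um * (1 - fraction)
  table$width_um <- table$width_um * (1 - fraction)
  table
}

#' Simulate a complete dataset (tree, species traits, measurements)
#'
#' Convenience wrapper chaining [simulate_tree()],
#' [simulate_species_traits()] and [sample_melanosomes()] with seeds derived
#' from `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `tree`, `species_traits`, `measurements`.
#' @export
simulate_dataset <- function(config, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  tree <- simulate_tree(config, seed = seed)
  traits <- simulate_species_traits(tree, config, seed = seed + 1L)
  meas <- sample_melanosomes(traits, config, seed = seed + 2L)
  list(tree = tree, species_traits = traits, measurements = meas)
}
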