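# Independent oracles used to verify the package's implementations.
# Each deliberately takes a different computational route than the code it
# checks (brute-force enumeration, closed forms, naive simulation).

# brute-force 3-D convex hull volume: enumerate all facet candidates
# (triples with every other point strictly on one side), then sum signed
# tetrahedra from the centroid. O(n^4); fine for n <= ~80.
brute_hull_volume <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  ctr <- colMeans(pts)
  triples <- combn(n, 3)
  vol <- 0
  for (t in seq_len(ncol(triples))) {
    i <- triples[1, t]; j <- triples[2, t]; k <- triples[3, t]
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    d <- (pts[-c(i, j, k), , drop = FALSE] %*% nrm) - sum(nrm * a)
    scale <- sqrt(sum(nrm^2)) * 1e-10
    if (all(d <= scale) || all(d >= -scale)) {
      # facet: add tetra (centroid, a, b, c) with outward orientation
      v6 <- sum(nrm * (ctr - a))
      vol <- vol + abs(v6) / 6
    }
  }
  vol
}

# univariate Blomberg K, scalar formula coded directly
blomberg_k_scalar <- function(x, tree) {
  x <- x[tree$tip.label]
  C <- ape::vcv(tree)
  n <- length(x)
  Cinv <- solve(C)
  a <- sum(Cinv %*% x) / sum(Cinv)
  num <- sum((x - a)^2)
  den <- as.numeric(t(x - a) %*% Cinv %*% (x - a))
  (num / den) / ((sum(diag(C)) - n / sum(Cinv)) / (n - 1))
}

# Wheatsheaf index by explicit pair loops
wheatsheaf_brute <- function(X, tree, focal) {
  X <- X[tree$tip.label, , drop = FALSE]
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
  C <- ape::vcv(tree)[rownames(X), rownames(X)]
  depth <- max(diag(C))
  sp <- rownames(X)
  num <- c(); den <- c()
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (j <= i) next
    d <- sqrt(sum((X[i, ] - X[j, ])^2)) * (1 + C[i, j] / depth)
    num <- c(num, d)
    if (sp[i] %in% focal && sp[j] %in% focal) den <- c(den, d)
  }
  mean(num) / mean(den)
}

# event-by-event pure-birth simulator tracking only the lineage count;
# returns the number of lineages at a given fraction of the final depth
yule_lineage_count_at <- function(n, birth_rate, frac) {
  k <- 2
  times <- c(0)
  t <- 0
  while (k < n) {
    t <- t + rexp(1, k * birth_rate)
    times <- c(times, t)
    k <- k + 1
  }
  t_end <- t + rexp(1, n * birth_rate)
  sum(times <= frac * t_end) + 1 # k starts at 2 at time 0
}

# lineages crossing a given depth fraction in an ultrametric phylo
lineages_at <- function(tree, frac) {
  depths <- ape::node.depth.edgelength(tree)
  cut <- frac * max(depths)
  sum(depths[tree$edge[, 1]] < cut & depths[tree$edge[, 2]] >= cut)
}

# small labelled measurement table for IO tests
make_measurement_table <- function(n_samples = 4, n_per_sample = 5,
                                   seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_samples), function(i) {
    cat <- COLOR_CATEGORIES[(i - 1) %% 4 + 1]
    type <- if (cat == "iridescent") "solid_cylindrical" else NA_character_
    data.frame(sample_id = sprintf("samp%02d", i),
               species = sprintf("Genus%d_species%d", (i - 1) %/% 2 + 1, i),
               color_category = cat, melanosome_type = type,
               length_um = round(runif(n_per_sample, 0.5, 2), 4),
               width_um = round(runif(n_per_sample, 0.1, 0.45), 4),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
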