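# Phylogenetic signal: multivariate Blomberg K (K_mult), Pagel's lambda,
# and ancestral-state estimation for the phylomorphospace.

match_species_matrix <- function(data, tree) {
  X <- as.matrix(data)
  if (is.null(rownames(X))) stop("data must have species rownames")
  unmatched <- c(setdiff(rownames(X), tree$tip.label),
                 setdiff(tree$tip.label, rownames(X)))
  if (length(unmatched) > 0)
    stop("species/tip mismatch: ", paste(unique(unmatched), collapse = ", "))
  X[tree$tip.label, , drop = FALSE]
}

#' Multivariate Blomberg K (K_mult)
#'
#' Measures phylogenetic signal of a multivariate trait relative to the
#' Brownian-motion expectation (K = 1). With
#' `a` the GLS phylogenetic mean and `u = C^{-1/2}(Y - 1a)` the
#' phylogenetically standardized residuals under tree covariance `C`,
#' \deqn{K = \frac{\sum_i d^2(y_i, a) / \sum_i d^2(u_i, 0)}
#'            {(\mathrm{tr}\,C - n/(1'C^{-1}1)) / (n-1)}}
#' where distances run across axes. Significance comes from permuting the
#' species-to-tip assignment; `p = (1 + #\{K_perm >= K_obs\})/(1 + n_perm)`.
#' With one axis this reduces exactly to the univariate Blomberg K.
#'
#' @param data species x axes matrix, rownames = species.
#' @param tree `phylo` matching the species.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list of class `signal_result`: `statistic`, `value`, `p_value`,
#'   `n_permutations`.
#' @export
kmult <- function(data, tree, n_perm = 999, seed = NULL) {
  Y <- match_species_matrix(data, tree)
  n <- nrow(Y)
  C <- ape::vcv(tree)[rownames(Y), rownames(Y)]
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values))
    stop("tree covariance near-singular (zero-length terminal duplicates?); ",
         "jitter branch lengths")
  Cinv <- eg$vectors %*% diag(1 / eg$values, n) %*% t(eg$vectors)
  Cmhalf <- eg$vectors %*% diag(1 / sqrt(eg$values), n) %*% t(eg$vectors)
  denom_scalar <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  stat <- function(Y) {
    a <- colSums(Cinv %*% Y) / sum(Cinv)
    Yc <- sweep(Y, 2, a)
    U <- Cmhalf %*% Yc
    (sum(Yc^2) / sum(U^2)) / denom_scalar
  }
  observed <- stat(Y)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    perms <- vapply(seq_len(n_perm), function(i) {
      stat(Y[sample.int(n), , drop = FALSE])
    }, numeric(1))
    p <- (1 + sum(perms >= observed)) / (1 + n_perm)
  }
  structure(list(statistic = "K_mult", value = observed, p_value = p,
                 n_permutations = n_perm),
            class = "signal_result")
}

#' Pagel's lambda for a univariate trait
#'
#' Maximum-likelihood lambda: off-diagonal elements of the Brownian tree
#' covariance are multiplied by lambda (0 = no signal / star tree, 1 =
#' Brownian expectation) and the profile likelihood is maximized. The
#' computation is delegated to [phytools::phylosig()]; the p-value is the
#' likelihood-ratio test against lambda = 0.
#'
#' @param x named numeric vector (names = species).
#' @param tree `phylo`.
#' @return `signal_result` with `statistic = "lambda"`.
#' @export
pagels_lambda <- function(x, tree) {
  if (is.matrix(x) || is.data.frame(x)) {
    if (NCOL(x) != 1) stop("pagels_lambda is univariate")
    x <- setNames(as.numeric(as.matrix(x)[, 1]), rownames(x))
  }
  if (is.null(names(x))) stop("x must be named by species")
  unmatched <- c(setdiff(names(x), tree$tip.label),
                 setdiff(tree$tip.label, names(x)))
  if (length(unmatched) > 0)
    stop("species/tip mismatch: ", paste(unique(unmatched), collapse = ", "))
  if (length(x) < 4)
    warning("too few species for a well-behaved lambda profile; ",
            "estimate may sit on a boundary")
  fit <- phytools::phylosig(tree, x, method = "lambda", test = TRUE)
  structure(list(statistic = "lambda", value = unname(fit$lambda),
                 p_value = unname(fit$P), n_permutations = NA_integer_),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(x$statistic, "=", signif(x$value, 4), " p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Ancestral states under Brownian motion
#'
#' Maximum-likelihood (equivalently joint GLS) estimates of internal-node
#' values for each axis: with `a` the GLS phylogenetic mean, tip covariance
#' `C_tt` and node-tip covariance `C_nt` (shared root-to-node path
#' lengths), the estimate is `a + C_nt C_tt^{-1} (y - a)`. The root
#' estimate equals the phylogenetic mean.
#'
#' @param data species x axes matrix, rownames = species.
#' @param tree `phylo`.
#' @return internal node x axes matrix (rownames = ape node numbers).
#' @export
ancestral_states <- function(data, tree) {
  Y <- match_species_matrix(data, tree)
  n <- length(tree$tip.label)
  full_mrca <- ape::mrca(tree, full = TRUE)
  depths <- ape::node.depth.edgelength(tree)
  Call <- matrix(depths[as.numeric(full_mrca)], nrow(full_mrca))
  tips <- seq_len(n)
  nodes <- n + seq_len(tree$Nnode)
  Cinv <- solve(Call[tips, tips])
  W <- Call[nodes, tips, drop = FALSE] %*% Cinv
  anc <- apply(Y, 2, function(col) {
    a <- sum(Cinv %*% col) / sum(Cinv)
    a + as.numeric(W %*% (col - a))
  })
  matrix(anc, ncol = ncol(Y), dimnames = list(nodes, colnames(Y)))
}

#' Phylomorphospace edge list
#'
#' Node coordinates (tips = observed scores, internal nodes = ancestral
#' estimates) joined with the tree's edges, ready for plotting or export.
#'
#' @param data species x axes score matrix.
#' @param tree `phylo`.
#' @return data.frame: parent, child, then paired start/end coordinates of
#'   the first two axes.
#' @export
phylomorphospace_edges <- function(data, tree) {
  Y <- match_species_matrix(data, tree)
  anc <- ancestral_states(Y, tree)
  n <- length(tree$tip.label)
  coords <- rbind(Y[tree$tip.label, 1:2, drop = FALSE],
                  anc[, 1:2, drop = FALSE])
  rownames(coords) <- c(as.character(seq_len(n)),
                        as.character(n + seq_len(tree$Nnode)))
  e <- tree$edge
  data.frame(parent = e[, 1], child = e[, 2],
             x0 = coords[as.character(e[, 1]), 1],
             y0 = coords[as.character(e[, 1]), 2],
             x1 = coords[as.character(e[, 2]), 1],
             y1 = coords[as.character(e[, 2]), 2])
}
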