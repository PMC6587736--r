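# Mixed quantitative/qualitative ordination (the PCAmix method: PCA merged
# with multiple correspondence analysis via one weighted SVD), projection of
# new (fossil) samples, and phylogenetic PCA for bias assessment.

#' Fit a mixed quantitative/qualitative ordination (PCAmix)
#'
#' Builds the preprocessed matrix `[Z1 | Z2]`: `Z1` holds the quantitative
#' variables centered and standardized (population standard deviation), `Z2`
#' the centered indicator columns of the qualitative levels weighted by
#' `n/n_s` for a level seen `n_s` times; rows carry uniform weight `1/n`.
#' One singular value decomposition of the weighted matrix yields scores,
#' loadings and eigenvalues. Total inertia is `p1 + (m - p2)` for `p1`
#' quantitative variables and `p2` qualitative variables with `m` levels in
#' total; with only quantitative variables the method reduces exactly to
#' PCA of the correlation matrix. Axis signs are canonicalized (the largest
#' absolute loading on each axis is positive).
#'
#' @param summaries SampleSummary data.frame (no missing values).
#' @param quantitative names of quantitative columns. `cv_length` is not a
#'   default: it is too sensitive to sample size.
#' @param qualitative names of qualitative (factor/logical) columns.
#' @param tol eigenvalues below `tol` are dropped as null axes.
#' @return object of class `pcamix`: `scores` (sample x axis),
#'   `eigenvalues`, `sqloadings` (variable x axis squared loadings:
#'   squared correlation for quantitative variables, correlation ratio for
#'   qualitative ones), plus the standardization parameters needed by
#'   [predict.pcamix()].
#' @export
fit_pcamix <- function(summaries,
                       quantitative = c("mean_length_um", "mean_width_um",
                                        "aspect_ratio"),
                       qualitative = c("flatness", "hollowness"),
                       tol = 1e-9) {
  n <- nrow(summaries)
  if (n < 3) stop("need at least 3 samples")
  miss <- setdiff(c(quantitative, qualitative), names(summaries))
  if (length(miss) > 0)
    stop("variable(s) missing from summaries: ", paste(miss, collapse = ", "))
  X1 <- as.matrix(summaries[, quantitative, drop = FALSE])
  if (any(!is.finite(X1))) stop("missing values in quantitative variables")
  means <- colMeans(X1)
  sds <- apply(X1, 2, function(x) sqrt(mean((x - mean(x))^2)))
  if (any(sds == 0))
    stop("degenerate (constant) quantitative variable: ",
         paste(quantitative[sds == 0], collapse = ", "))
  Z1 <- sweep(sweep(X1, 2, means), 2, sds, "/")

  levels_list <- list()
  props_list <- list()
  Z2cols <- list()
  colnames2 <- character(0)
  for (v in qualitative) {
    f <- factor(as.character(summaries[[v]]))
    if (nlevels(f) < 2)
      stop("degenerate (constant) qualitative variable: ", v)
    levels_list[[v]] <- levels(f)
    G <- stats::model.matrix(~ f - 1)
    p_s <- colMeans(G)
    props_list[[v]] <- setNames(p_s, levels(f))
    # column of B: (indicator - p_s) / sqrt(n_s); u-row at predict time is
    # (indicator - p_s) / sqrt(p_s)
    Z2cols[[v]] <- sweep(sweep(G, 2, p_s), 2, sqrt(p_s), "/")
    colnames2 <- c(colnames2, paste(v, levels(f), sep = ":"))
  }
  U2 <- if (length(Z2cols) > 0) do.call(cbind, Z2cols) else NULL
  Urows <- cbind(Z1, U2) # "u" representation: score = u %*% V
  colnames(Urows) <- c(quantitative, colnames2)
  B <- Urows / sqrt(n)
  sv <- svd(B)
  ev <- sv$d^2
  keep <- which(ev > tol)
  ev <- ev[keep]
  V <- sv$v[, keep, drop = FALSE]
  # canonical signs
  for (k in seq_along(keep)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- colnames(Urows)
  colnames(V) <- paste0("PC", seq_along(keep))
  scores <- Urows %*% V
  rownames(scores) <- if ("sample_id" %in% names(summaries))
    summaries$sample_id else rownames(summaries)

  sqload <- matrix(NA_real_, nrow = length(quantitative) + length(qualitative),
                   ncol = length(keep),
                   dimnames = list(c(quantitative, names(levels_list)),
                                   colnames(V)))
  for (j in seq_along(quantitative))
    sqload[j, ] <- cor(X1[, j], scores)^2
  for (v in names(levels_list)) {
    f <- factor(as.character(summaries[[v]]))
    eta2 <- apply(scores, 2, function(s) {
      gm <- tapply(s, f, mean)
      sum(table(f) * (gm - mean(s))^2) / sum((s - mean(s))^2)
    })
    sqload[v, ] <- eta2
  }

  structure(list(
    n = n, quantitative = quantitative, qualitative = qualitative,
    means = means, sds = sds, levels = levels_list, level_props = props_list,
    V = V, eigenvalues = ev, total_inertia = length(quantitative) +
      sum(vapply(levels_list, length, integer(1))) - length(levels_list),
    scores = scores, sqloadings = sqload
  ), class = "pcamix")
}

#' @export
print.pcamix <- function(x, ...) {
  cat("PCAmix ordination:", x$n, "samples,",
      length(x$quantitative), "quantitative +",
      length(x$qualitative), "qualitative variables\n")
  pct <- round(100 * x$eigenvalues / sum(x$eigenvalues), 1)
  cat("eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  cat("variance explained (%):", paste(pct, collapse = ", "), "\n")
  invisible(x)
}

#' Percent variance explained per ordination axis
#' @param ord a `pcamix` or `ppca` object.
#' @export
variance_explained <- function(ord) {
  ev <- if (inherits(ord, "pcamix")) ord$eigenvalues else ord$values
  100 * ev / sum(ev)
}

#' Project new samples into a fitted PCAmix morphospace
#'
#' Standardizes new samples with the training means, standard deviations
#' and level frequencies, so projecting the training data reproduces the
#' training scores exactly. Fossil samples carry the same variables; their
#' flags may come from cross-sectioning evidence.
#'
#' @param object fitted `pcamix`.
#' @param newdata data.frame carrying all fit-time variables.
#' @param ... unused.
#' @return score matrix (rows = new samples, columns = axes).
#' @export
predict.pcamix <- function(object, newdata, ...) {
  miss <- setdiff(c(object$quantitative, object$qualitative), names(newdata))
  if (length(miss) > 0)
    stop("variable(s) missing from newdata: ", paste(miss, collapse = ", "))
  X1 <- as.matrix(newdata[, object$quantitative, drop = FALSE])
  Z1 <- sweep(sweep(X1, 2, object$means), 2, object$sds, "/")
  cols <- list(Z1)
  for (v in object$qualitative) {
    vals <- as.character(newdata[[v]])
    levs <- object$levels[[v]]
    unseen <- setdiff(unique(vals), levs)
    if (length(unseen) > 0)
      stop("level(s) of ", v, " unseen at fit time: ",
           paste(unseen, collapse = ", "))
    G <- matrix(0, nrow(newdata), length(levs))
    G[cbind(seq_len(nrow(newdata)), match(vals, levs))] <- 1
    p_s <- object$level_props[[v]]
    cols[[length(cols) + 1]] <- sweep(sweep(G, 2, p_s), 2, sqrt(p_s), "/")
  }
  U <- do.call(cbind, cols)
  scores <- U %*% object$V
  rownames(scores) <- if ("sample_id" %in% names(newdata))
    newdata$sample_id else rownames(newdata)
  scores
}

#' Save / load a fitted ordination as JSON
#'
#' Stores the standardization parameters, loadings and eigenvalues so
#' fossil samples can be projected in a later invocation.
#'
#' @param ord fitted `pcamix`.
#' @param path JSON path.
#' @export
write_ordination <- function(ord, path) {
  payload <- list(
    n = ord$n, quantitative = ord$quantitative,
    qualitative = ord$qualitative,
    means = as.list(ord$means), sds = as.list(ord$sds),
    levels = ord$levels,
    level_props = lapply(ord$level_props, as.list),
    V = list(values = as.numeric(ord$V), nrow = nrow(ord$V),
             rownames = rownames(ord$V), colnames = colnames(ord$V)),
    eigenvalues = ord$eigenvalues, total_inertia = ord$total_inertia
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ordination
#' @export
read_ordination <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- matrix(p$V$values, nrow = p$V$nrow,
              dimnames = list(p$V$rownames, p$V$colnames))
  structure(list(
    n = p$n, quantitative = p$quantitative, qualitative = p$qualitative,
    means = unlist(p$means), sds = unlist(p$sds),
    levels = lapply(p$levels, unlist),
    level_props = lapply(p$level_props, unlist),
    V = V, eigenvalues = p$eigenvalues, total_inertia = p$total_inertia,
    scores = NULL, sqloadings = NULL
  ), class = "pcamix")
}

#' Phylogenetic PCA of species mean traits
#'
#' Computes the GLS phylogenetic mean `a = (1'C^-1 1)^-1 1'C^-1 X` and the
#' evolutionary covariance `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)` under the
#' Brownian tree covariance `C`, then eigen-decomposes `R`; scores are
#' `(X - 1a) V`. With a star tree (`C = I`, equal branches) this is
#' ordinary covariance PCA of centered data. Quantitative variables only.
#'
#' @param X matrix or data.frame of species mean traits, rownames =
#'   species matching the tree tips.
#' @param tree `phylo` with branch lengths.
#' @return object of class `ppca`: `evol_mean`, `evol_vcv`, `vectors`,
#'   `values`, `scores`.
#' @export
fit_ppca <- function(X, tree) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("X must have species rownames")
  unmatched <- c(setdiff(rownames(X), tree$tip.label),
                 setdiff(tree$tip.label, rownames(X)))
  if (length(unmatched) > 0)
    stop("species/tip mismatch: ", paste(unique(unmatched), collapse = ", "))
  X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  C <- ape::vcv(tree)
  Cinv <- solve(C)
  ones <- rep(1, n)
  a <- as.numeric(solve(t(ones) %*% Cinv %*% ones) %*% t(ones) %*% Cinv %*% X)
  Xc <- sweep(X, 2, a)
  R <- t(Xc) %*% Cinv %*% Xc / (n - 1)
  eg <- eigen(R, symmetric = TRUE)
  keep <- which(eg$values > 1e-12 * max(eg$values, 1e-300))
  V <- eg$vectors[, keep, drop = FALSE]
  for (k in seq_along(keep)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("pPC", seq_along(keep))
  scores <- Xc %*% V
  structure(list(evol_mean = setNames(a, colnames(X)), evol_vcv = R,
                 vectors = V, values = eg$values[keep], scores = scores),
            class = "ppca")
}

#' @export
print.ppca <- function(x, ...) {
  cat("phylogenetic PCA:", nrow(x$scores), "species,",
      length(x$values), "axes\n")
  cat("eigenvalues:", paste(signif(x$values, 4), collapse = ", "), "\n")
  invisible(x)
}
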