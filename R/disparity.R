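# Morphospace occupation per color category: 3-D convex hull and
# alpha-shape volumes, label-randomization significance, sum of variances.

as_points3 <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("points must have exactly 3 columns")
  storage.mode(pts) <- "double"
  pts
}

#' Volume of the 3-D convex hull of a point cloud
#'
#' @param points numeric matrix with 3 columns (ordination scores).
#' @return hull volume (score units cubed).
#' @export
hull_volume <- function(points) {
  pts <- as_points3(points)
  if (nrow(pts) < 4) stop("degenerate geometry: need >= 4 points")
  v <- .hull_volume_cpp(pts)
  if (v < 0) stop("degenerate geometry: points are affinely dependent")
  v
}

# pipeline mode: degenerate sets give volume 0 (optionally with a warning)
hull_volume_safe <- function(points, warn = FALSE) {
  pts <- as_points3(points)
  if (nrow(pts) < 4) {
    if (warn) warning("fewer than 4 points; reporting volume 0")
    return(0)
  }
  v <- .hull_volume_cpp(pts)
  if (v < 0) {
    if (warn) warning("degenerate point set; reporting volume 0")
    return(0)
  }
  v
}

#' Volume of the 3-D alpha shape of a point cloud
#'
#' The alpha shape keeps the tetrahedra of the Delaunay tetrahedralization
#' whose circumradius does not exceed `alpha` (the eraser-sphere radius):
#' small alpha scoops out empty regions, large alpha recovers the convex
#' hull. Volume is nondecreasing in alpha and never exceeds the hull volume.
#'
#' @param points numeric matrix with 3 columns.
#' @param alpha positive eraser-sphere radius, in score units. May be a
#'   vector; a named vector of volumes is then returned.
#' @export
alpha_volume <- function(points, alpha) {
  pts <- as_points3(points)
  if (nrow(pts) < 4) stop("degenerate geometry: need >= 4 points")
  if (any(alpha <= 0)) stop("alpha must be positive")
  d <- .delaunay_cpp(pts)
  out <- vapply(alpha, function(a) sum(d$volume[d$circumradius <= a]),
                numeric(1))
  names(out) <- as.character(alpha)
  if (length(out) == 1) unname(out) else out
}

#' Label-randomization test of disparity
#'
#' The observed statistic is the ratio of the hull (or alpha-shape) volume
#' of the focal category to the volume of the pooled points of all other
#' categories. The null distribution reassigns category labels at random,
#' preserving category sizes; `p = (1 + #\{null >= observed\}) / (1 + n_iter)`.
#' Permutations in which a group is too small or degenerate for a hull are
#' computed with volume 0 and counted in `n_degenerate`.
#'
#' @param scores sample x 3 score matrix.
#' @param labels category per sample.
#' @param n_iter number of label permutations (default 5000).
#' @param seed integer seed.
#' @param focal focal category (default `"iridescent"`).
#' @param alpha optional alpha radius; when given, alpha-shape volumes
#'   replace hull volumes in the statistic.
#' @return list of class `randomization_test`: `observed_ratio`,
#'   `null_ratios`, `p_value`, `n_degenerate`.
#' @export
randomization_test <- function(scores, labels, n_iter = 5000, seed = NULL,
                               focal = "iridescent", alpha = NULL) {
  pts <- as_points3(scores)
  labels <- as.character(labels)
  if (length(labels) != nrow(pts)) stop("labels must match rows of scores")
  if (!focal %in% labels) stop("focal category not present: ", focal)
  if (length(unique(labels)) < 2) stop("need >= 2 categories")
  if (!is.null(seed)) set.seed(seed)
  volfun <- if (is.null(alpha)) {
    hull_volume_safe
  } else {
    function(p) {
      if (nrow(p) < 4) return(0)
      v <- tryCatch(alpha_volume(p, alpha), error = function(e) 0)
      v
    }
  }
  ratio_of <- function(lab) {
    vf <- volfun(pts[lab == focal, , drop = FALSE])
    vo <- volfun(pts[lab != focal, , drop = FALSE])
    if (vo <= 0) return(NA_real_)
    vf / vo
  }
  observed <- ratio_of(labels)
  if (is.na(observed)) stop("degenerate geometry in observed data")
  null_ratios <- numeric(n_iter)
  n_degenerate <- 0L
  for (i in seq_len(n_iter)) {
    r <- ratio_of(sample(labels))
    if (is.na(r)) {
      r <- 0
      n_degenerate <- n_degenerate + 1L
    }
    null_ratios[i] <- r
  }
  p <- (1 + sum(null_ratios >= observed)) / (1 + n_iter)
  structure(list(observed_ratio = observed, null_ratios = null_ratios,
                 p_value = p, n_degenerate = n_degenerate,
                 focal = focal, n_iter = n_iter),
            class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat("disparity randomization test (focal =", x$focal, ")\n")
  cat("observed volume ratio:", signif(x$observed_ratio, 4),
      " p =", signif(x$p_value, 3), " (", x$n_iter, "iterations )\n")
  invisible(x)
}

#' Sum of variances per category with bootstrap confidence intervals
#'
#' `sov = sum over axes of the within-category variance` (n-1 denominator),
#' a disparity measure robust to sample-size differences. Percentile
#' bootstrap intervals resample samples within each category.
#'
#' @param scores sample x axis score matrix (all axes, not only 3).
#' @param labels category per sample.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame: category, n, sov, ci_low, ci_high.
#' @export
sum_of_variances <- function(scores, labels, n_boot = 1000, seed = NULL,
                             conf = 0.95) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (length(labels) != nrow(scores)) stop("labels must match rows of scores")
  sizes <- table(labels)
  if (any(sizes < 2)) stop("singleton category: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  sov_of <- function(m) sum(apply(m, 2, var))
  cats <- sort(unique(labels))
  out <- data.frame(category = cats, n = as.integer(sizes[cats]),
                    sov = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE)
  a <- (1 - conf) / 2
  for (i in seq_along(cats)) {
    m <- scores[labels == cats[i], , drop = FALSE]
    out$sov[i] <- sov_of(m)
    boots <- vapply(seq_len(n_boot), function(b) {
      sov_of(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE])
    }, numeric(1))
    ci <- quantile(boots, c(a, 1 - a), names = FALSE)
    out$ci_low[i] <- ci[1]
    out$ci_high[i] <- ci[2]
  }
  out
}

#' Full disparity analysis of a morphospace
#'
#' Per-category convex hull volumes and alpha-shape volumes on the first
#' three axes, the label-randomization test of the focal/other volume
#' ratio, and sum of variances (on all supplied axes) with bootstrap CIs.
#'
#' @param scores sample x axis score matrix (>= 3 axes; the first three are
#'   used for volumes).
#' @param labels category per sample.
#' @param alphas alpha radii for the alpha shapes (default `c(1.3, 2, 5)`).
#' @param n_iter randomization iterations (default 5000).
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param focal focal category for the randomization test.
#' @return list of class `disparity_result`.
#' @export
disparity_analysis <- function(scores, labels, alphas = c(1.3, 2, 5),
                               n_iter = 5000, n_boot = 1000, seed = NULL,
                               focal = "iridescent") {
  scores <- as.matrix(scores)
  if (ncol(scores) < 3) stop("need at least 3 score axes")
  if (!is.null(seed)) set.seed(seed)
  s3 <- scores[, 1:3, drop = FALSE]
  labels <- as.character(labels)
  cats <- sort(unique(labels))
  volumes <- lapply(setNames(cats, cats), function(cat) {
    p <- s3[labels == cat, , drop = FALSE]
    hv <- hull_volume_safe(p, warn = TRUE)
    av <- if (nrow(p) >= 4 && hv > 0)
      alpha_volume(p, alphas) else setNames(rep(0, length(alphas)),
                                            as.character(alphas))
    list(n = nrow(p), hull_volume = hv, alpha_volumes = as.list(av))
  })
  rand <- randomization_test(s3, labels, n_iter = n_iter, focal = focal)
  sov <- sum_of_variances(scores, labels, n_boot = n_boot)
  structure(list(volumes = volumes, randomization = rand,
                 sum_of_variances = sov, alphas = alphas),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("morphospace disparity (first three axes)\n")
  for (cat_name in names(x$volumes)) {
    v <- x$volumes[[cat_name]]
    cat(sprintf("  %-11s n=%3d hull=%8.4f alpha(%s)=%s\n", cat_name, v$n,
                v$hull_volume, paste(x$alphas, collapse = ","),
                paste(signif(unlist(v$alpha_volumes), 4), collapse = ",")))
  }
  print(x$randomization)
  invisible(x)
}

#' Serialize a disparity result to JSON
#' @param result `disparity_result`.
#' @param path output path.
#' @export
write_disparity <- function(result, path) {
  payload <- list(
    volumes = result$volumes,
    randomization = list(observed_ratio = result$randomization$observed_ratio,
                         p_value = result$randomization$p_value,
                         n_iter = result$randomization$n_iter,
                         n_degenerate = result$randomization$n_degenerate),
    sum_of_variances = result$sum_of_variances
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
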