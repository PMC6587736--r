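# Color-prediction models: AIC-based variable selection, QDA and
# multinomial logistic regression, repeated stratified cross-validation,
# Cohen's kappa, shrinkage decay, and fossil prediction.

QUANT_FEATURES <- c("mean_length_um", "mean_width_um", "aspect_ratio")
QUAL_FEATURES <- c("flatness", "hollowness")

mvn_loglik <- function(X, mu, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  d <- ncol(X)
  Xc <- sweep(X, 2, mu)
  q <- rowSums((Xc %*% chol2inv(ch)) * Xc)
  sum(-0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + q))
}

qda_aic <- function(X, y) {
  classes <- levels(y)
  n <- nrow(X)
  d <- ncol(X)
  ll <- 0
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    if (nrow(Xi) <= d) return(list(aic = NA_real_, feasible = FALSE))
    mu <- colMeans(Xi)
    Sigma <- cov(Xi) * (nrow(Xi) - 1) / nrow(Xi) # ML covariance
    li <- mvn_loglik(Xi, mu, Sigma)
    if (!is.finite(li)) return(list(aic = NA_real_, feasible = FALSE))
    ll <- ll + li + nrow(Xi) * log(nrow(Xi) / n)
  }
  k <- length(classes) * (d + d * (d + 1) / 2) + (length(classes) - 1)
  list(aic = 2 * k - 2 * ll, feasible = TRUE)
}

#' Rank candidate variable subsets by AIC
#'
#' Enumerates every nonempty subset of the candidate features and ranks it
#' by AIC. For the multinomial logistic regression the AIC is the model's
#' own; for QDA the AIC is computed from the class-conditional Gaussian
#' likelihood (with class-frequency priors), and subsets containing
#' qualitative variables are skipped with a note, since binary flags cannot
#' enter a QDA.
#'
#' @param summaries SampleSummary data.frame with a `color_category` column.
#' @param model_kind `"qda"` or `"mlr"`.
#' @param candidates feature names (default: length, width/diameter, aspect
#'   ratio, flatness, hollowness).
#' @return data.frame ranked by AIC: `variables`, `k`, `aic`, `delta_aic`,
#'   `feasible`, `note`.
#' @export
select_variables <- function(summaries, model_kind = c("mlr", "qda"),
                             candidates = c(QUANT_FEATURES, QUAL_FEATURES)) {
  model_kind <- match.arg(model_kind)
  if (length(candidates) == 0) stop("candidates must be nonempty")
  y <- factor(summaries$color_category,
              levels = intersect(COLOR_CATEGORIES,
                                 unique(summaries$color_category)))
  subsets <- unlist(lapply(seq_along(candidates), function(k)
    combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(vars) {
    note <- ""
    aic <- NA_real_
    feasible <- FALSE
    if (model_kind == "qda" && any(vars %in% QUAL_FEATURES)) {
      note <- "skipped: qualitative variable cannot enter a QDA"
    } else if (model_kind == "qda") {
      res <- qda_aic(as.matrix(summaries[, vars, drop = FALSE]), y)
      aic <- res$aic
      feasible <- res$feasible
      if (!feasible) note <- "infeasible: singular class covariance"
    } else {
      df <- data.frame(color_category = stats::relevel(y, ref = levels(y)[1]),
                       summaries[, vars, drop = FALSE])
      fit <- tryCatch(nnet::multinom(color_category ~ ., data = df,
                                     trace = FALSE, maxit = 500),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        aic <- fit$AIC
        feasible <- TRUE
      } else note <- "infeasible: fit failed"
    }
    data.frame(variables = paste(vars, collapse = "+"),
               k = length(vars), aic = aic, feasible = feasible,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$feasible, out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - min(out$aic, na.rm = TRUE)
  rownames(out) <- NULL
  out[, c("variables", "k", "aic", "delta_aic", "feasible", "note")]
}

#' Default model variables
#'
#' The QDA uses length, aspect ratio and diameter (mean width); the MLR
#' additionally admits the binary flags: diameter, aspect ratio, flatness
#' and hollowness.
#'
#' @param model_kind `"qda"` or `"mlr"`.
#' @export
default_variables <- function(model_kind = c("mlr", "qda")) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "qda")
    c("mean_length_um", "aspect_ratio", "mean_width_um")
  else
    c("mean_width_um", "aspect_ratio", "flatness", "hollowness")
}

#' Fit a color classifier (QDA or multinomial logistic regression)
#'
#' @param summaries SampleSummary data.frame with `color_category`.
#' @param model_kind `"qda"` (class-specific Gaussian densities,
#'   class-frequency priors) or `"mlr"` (softmax-linked multinomial logit,
#'   reference class black).
#' @param variables feature names; see [default_variables()]. QDA accepts
#'   quantitative variables only.
#' @param flag_rule QDA-with-flags variant: samples whose hollow or flat
#'   flag is set are called iridescent before the QDA runs, mirroring the
#'   situation where hollowness/flatness is already known from
#'   cross-sectioning.
#' @return object of class `color_classifier`.
#' @export
fit_color_classifier <- function(summaries,
                                 model_kind = c("mlr", "qda"),
                                 variables = default_variables(model_kind),
                                 flag_rule = FALSE) {
  model_kind <- match.arg(model_kind)
  classes <- intersect(COLOR_CATEGORIES, unique(summaries$color_category))
  if (length(classes) < 2) stop("need >= 2 classes")
  y <- factor(summaries$color_category, levels = classes)
  miss <- setdiff(variables, names(summaries))
  if (length(miss) > 0)
    stop("variable(s) missing: ", paste(miss, collapse = ", "))
  if (model_kind == "qda") {
    if (any(variables %in% QUAL_FEATURES))
      stop("qualitative variables cannot be included in a QDA")
    X <- as.matrix(summaries[, variables, drop = FALSE])
    if (any(table(y) <= ncol(X)))
      stop("a class has too few samples for a QDA covariance; ",
           "reduce the variable set")
    fit <- MASS::qda(X, grouping = y)
  } else {
    df <- data.frame(color_category = y, summaries[, variables, drop = FALSE])
    fit <- nnet::multinom(color_category ~ ., data = df, trace = FALSE,
                          maxit = 1000, reltol = 1e-12)
  }
  structure(list(model_kind = model_kind, variables = variables,
                 classes = classes, fit = fit, flag_rule = flag_rule,
                 n_per_class = as.list(table(y))),
            class = "color_classifier")
}

#' @export
print.color_classifier <- function(x, ...) {
  cat("color classifier (", x$model_kind, ") on ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  cat("training n per class:",
      paste(names(x$n_per_class), unlist(x$n_per_class), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Posterior class probabilities for new samples
#'
#' @param object `color_classifier`.
#' @param newdata data.frame carrying the classifier variables.
#' @param ... unused.
#' @return matrix (samples x classes) of posterior probabilities, rows
#'   summing to 1.
#' @export
predict.color_classifier <- function(object, newdata, ...) {
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss) > 0)
    stop("variable(s) missing: ", paste(miss, collapse = ", "))
  if (object$model_kind == "qda") {
    X <- as.matrix(newdata[, object$variables, drop = FALSE])
    post <- predict(object$fit, X)$posterior
  } else {
    post <- predict(object$fit, newdata = newdata, type = "probs")
    if (length(object$classes) == 2) {
      # binomial case: multinom returns P(second level) as a bare vector
      if (is.null(dim(post))) post <- cbind(1 - post, post)
      colnames(post) <- object$classes
    } else if (is.null(dim(post))) {
      post <- matrix(post, nrow = 1, dimnames = list(NULL, names(post)))
    }
  }
  post <- post[, object$classes, drop = FALSE]
  if (object$flag_rule && all(QUAL_FEATURES %in% names(newdata))) {
    flagged <- newdata$flatness | newdata$hollowness
    if (any(flagged) && "iridescent" %in% colnames(post)) {
      post[flagged, ] <- 0
      post[flagged, "iridescent"] <- 1
    }
  }
  post
}

classify <- function(post) colnames(post)[max.col(post, ties.method = "first")]

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and
#' `p_e` the chance agreement expected from the row/column margins.
#'
#' @param confusion square contingency table, predictions x truth.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  (po - pe) / (1 - pe)
}

#' Repeated stratified k-fold cross-validation
#'
#' Accuracy is the held-out correct fraction pooled over folds and repeats;
#' Cohen's kappa comes from the pooled confusion matrix; significance is a
#' one-sided exact binomial test of the pooled correct count against the
#' no-information rate (the largest class frequency).
#'
#' @param summaries SampleSummary data.frame with `color_category`.
#' @param model_kind,variables,flag_rule as in [fit_color_classifier()].
#' @param k folds (default 10; reduced with a warning if a class is
#'   smaller than `k`).
#' @param repeats repeats of the k-fold split (default 5).
#' @param seed integer seed.
#' @return list of class `cv_result`: `accuracy`, `kappa`, `p_value`,
#'   `confusion`, `no_information_rate`, `k`, `repeats`.
#' @export
cross_validate <- function(summaries, model_kind = c("mlr", "qda"),
                           variables = default_variables(model_kind),
                           k = 10, repeats = 5, seed = NULL,
                           flag_rule = FALSE) {
  model_kind <- match.arg(model_kind)
  if (k < 2) stop("k must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  y <- factor(summaries$color_category,
              levels = intersect(COLOR_CATEGORIES,
                                 unique(summaries$color_category)))
  min_class <- min(table(y))
  if (min_class < k) {
    k <- max(2, min_class)
    warning("class smaller than requested folds; using k = ", k)
  }
  classes <- levels(y)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(predicted = classes, truth = classes))
  for (r in seq_len(repeats)) {
    fold <- integer(nrow(summaries))
    for (cl in classes) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    for (f in seq_len(k)) {
      test <- fold == f
      clf <- fit_color_classifier(summaries[!test, , drop = FALSE],
                                  model_kind, variables,
                                  flag_rule = flag_rule)
      post <- predict(clf, summaries[test, , drop = FALSE])
      pred <- factor(classify(post), levels = classes)
      tab <- table(pred, y[test])
      confusion <- confusion + as.matrix(tab)
    }
  }
  n <- sum(confusion)
  accuracy <- sum(diag(confusion)) / n
  nir <- max(table(y)) / length(y)
  test <- binom.test(sum(diag(confusion)), n, p = nir,
                     alternative = "greater")
  structure(list(accuracy = accuracy, kappa = cohens_kappa(confusion),
                 p_value = test$p.value, confusion = confusion,
                 no_information_rate = nir, k = k, repeats = repeats),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("repeated %d-fold CV (%d repeats): accuracy %.1f%%, kappa %.2f, exact p %.2g\n",
              x$k, x$repeats, 100 * x$accuracy, x$kappa, x$p_value))
  invisible(x)
}

shrink_summaries <- function(summaries, fraction) {
  summaries$mean_length_um <- summaries$mean_length_um * (1 - fraction)
  summaries$mean_width_um <- summaries$mean_width_um * (1 - fraction)
  summaries # aspect ratio, CVs and flags are shrinkage-invariant
}

#' Model decay under simulated fossilization shrinkage
#'
#' Re-applies a fixed fitted classifier to data whose length and width are
#' shrunk by each fraction (aspect ratio and flags unchanged) and reports
#' the percentage of predictions that change at the largest fraction
#' relative to the unaltered data. High decay means the model leans on
#' absolute size, which fossilization can distort.
#'
#' @param classifier fitted `color_classifier`.
#' @param summaries data to predict on.
#' @param fractions shrinkage fractions (default 10/20/30%).
#' @return list: `decay_pct` (at `max(fractions)`), `per_fraction`
#'   (data.frame of percent changed per fraction), `predictions` (list of
#'   per-fraction predicted classes).
#' @export
model_decay <- function(classifier, summaries,
                        fractions = c(0.10, 0.20, 0.30)) {
  base_pred <- classify(predict(classifier, summaries))
  preds <- list(`0` = base_pred)
  changed <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    shr <- shrink_summaries(summaries, fractions[i])
    pred <- classify(predict(classifier, shr))
    preds[[as.character(fractions[i])]] <- pred
    changed[i] <- 100 * mean(pred != base_pred)
  }
  list(decay_pct = changed[which.max(fractions)],
       per_fraction = data.frame(fraction = fractions,
                                 pct_changed = changed),
       predictions = preds)
}

#' Predict color class for fossil samples
#'
#' Posterior probabilities per class and a call under the posterior
#' threshold rule: a category is called only when its posterior reaches the
#' threshold, otherwise the prediction is `"inconclusive"`.
#'
#' @param classifier fitted `color_classifier`.
#' @param fossil_summaries SampleSummary rows for the fossil samples (flags
#'   may come from cross-section evidence, or be imputed as solid
#'   cylindrical with a provenance note).
#' @param threshold minimum posterior for a call (default 0.5).
#' @return data.frame: `sample_id`, one posterior column per class, `call`,
#'   `threshold`.
#' @export
predict_fossil <- function(classifier, fossil_summaries, threshold = 0.5) {
  post <- predict(classifier, fossil_summaries)
  call <- classify(post)
  call[apply(post, 1, max) < threshold] <- "inconclusive"
  out <- data.frame(sample_id = fossil_summaries$sample_id %||%
                      paste0("fossil", seq_len(nrow(post))),
                    stringsAsFactors = FALSE)
  for (cl in colnames(post)) out[[paste0("p_", cl)]] <- post[, cl]
  out$call <- call
  out$threshold <- threshold
  out
}

#' Serialize a trained classifier's parameters to JSON
#'
#' @param classifier fitted `color_classifier`.
#' @param path output path.
#' @export
write_classifier <- function(classifier, path) {
  payload <- list(model_kind = classifier$model_kind,
                  variables = classifier$variables,
                  classes = classifier$classes,
                  flag_rule = classifier$flag_rule,
                  n_per_class = classifier$n_per_class)
  if (classifier$model_kind == "qda") {
    payload$prior <- as.list(classifier$fit$prior)
    payload$means <- as.data.frame(classifier$fit$means)
  } else {
    payload$coefficients <- as.data.frame(stats::coef(classifier$fit))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
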