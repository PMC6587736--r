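four_class_summaries <- function(n_per = 30, seed = 1, sep = 1) {
  set.seed(seed)
  centers <- list(black = c(1.1, 0.26), brown = c(0.72, 0.36),
                  grey = c(0.85, 0.45), iridescent = c(1.4, 0.30))
  rows <- lapply(names(centers), function(cl) {
    mu <- centers[[cl]]
    len <- exp(log(mu[1]) + rnorm(n_per, sd = 0.08 / sep))
    wid <- exp(log(mu[2]) + rnorm(n_per, sd = 0.08 / sep))
    data.frame(sample_id = paste0(cl, seq_len(n_per)),
               species = paste0(cl, "_sp", seq_len(n_per)),
               color_category = cl,
               flatness = cl == "iridescent" & seq_len(n_per) %% 2 == 0,
               hollowness = cl == "iridescent" & seq_len(n_per) %% 3 == 0,
               mean_length_um = len, mean_width_um = wid,
               aspect_ratio = len / wid,
               cv_length = 0.2, cv_width = 0.2, n_melanosomes = 30L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("select_variables enumerates subsets and honors model limits", {
  s <- four_class_summaries(seed = 2)
  ranked <- select_variables(s, "mlr")
  expect_equal(nrow(ranked), 31) # 2^5 - 1 subsets
  expect_true(all(ranked$feasible[1:5]))

  rq <- select_variables(s, "qda")
  expect_equal(nrow(rq), 31)
  skipped <- grepl("flatness|hollowness", rq$variables)
  expect_true(all(!rq$feasible[skipped]))
  expect_true(all(grepl("qualitative", rq$note[skipped])))
  expect_equal(sum(rq$feasible), 7) # subsets of the 3 quantitative vars

  # when exactly one feature separates the classes it tops the ranking
  set.seed(3)
  s2 <- s
  s2$mean_length_um <- runif(nrow(s2), 0.9, 1.1) # destroy length signal
  s2$mean_width_um <- runif(nrow(s2), 0.3, 0.4)
  s2$aspect_ratio <- as.numeric(match(s2$color_category,
                                      COLOR_CATEGORIES)) +
    rnorm(nrow(s2), sd = 0.05)
  top <- select_variables(s2, "qda")[1, ]
  expect_match(top$variables, "aspect_ratio")
})

test_that("fitted classifiers behave on separable fixtures", {
  s <- four_class_summaries(seed = 4, sep = 2)
  qda <- fit_color_classifier(s, "qda")
  post <- predict(qda, s)
  expect_equal(unname(rowSums(post)), rep(1, nrow(s)), tolerance = 1e-8)
  expect_gte(mean(classify(post) == s$color_category), 0.99)
  expect_equal(sum(qda$fit$prior), 1)

  mlr <- fit_color_classifier(s, "mlr")
  postm <- predict(mlr, s)
  expect_equal(unname(rowSums(postm)), rep(1, nrow(s)), tolerance = 1e-6)
  expect_gte(mean(classify(postm) == s$color_category), 0.95)

  # monotone posterior along a single separating feature
  two <- s[s$color_category %in% c("black", "brown"), ]
  m2 <- fit_color_classifier(two, "mlr", variables = "mean_length_um")
  grid <- data.frame(mean_length_um = seq(0.5, 1.5, length.out = 50))
  p_black <- predict(m2, grid)[, "black"]
  expect_true(all(diff(p_black) > -1e-10))

  expect_error(fit_color_classifier(s, "qda",
                                    variables = c("mean_length_um",
                                                  "flatness")),
               "qualitative")
})

test_that("Cohen's kappa matches the arithmetic oracle", {
  conf <- matrix(c(40, 10, 10, 40), 2, 2)
  expect_equal(cohens_kappa(conf), 0.6)
  # perfect agreement and pure chance
  expect_equal(cohens_kappa(diag(c(25, 25))), 1)
  expect_equal(cohens_kappa(matrix(25, 2, 2)), 0)
})

test_that("cross-validation scores separable and shuffled data correctly", {
  s <- four_class_summaries(n_per = 24, seed = 5, sep = 2)
  cv <- cross_validate(s, "qda", k = 6, repeats = 2, seed = 6)
  expect_gte(cv$accuracy, 0.95)
  expect_gte(cv$kappa, 0.9)
  expect_lt(cv$p_value, 1e-6)

  shuf <- s
  set.seed(7)
  shuf$color_category <- sample(shuf$color_category)
  cvs <- cross_validate(shuf, "qda", k = 6, repeats = 2, seed = 8)
  expect_lt(abs(cvs$kappa), 0.15)

  small <- s[c(1:24, 25:28, 49:72, 73:96), ]
  expect_warning(cross_validate(small, "mlr", k = 10, repeats = 1, seed = 9),
                 "folds")
})

test_that("model decay reflects dependence on absolute size", {
  s <- four_class_summaries(seed = 10)
  size_model <- fit_color_classifier(s, "qda",
                                     variables = c("mean_length_um",
                                                   "mean_width_um"))
  shape_model <- fit_color_classifier(s, "mlr",
                                      variables = c("aspect_ratio",
                                                    "flatness",
                                                    "hollowness"))
  expect_equal(model_decay(size_model, s, fractions = 0)$decay_pct, 0)
  # shrinkage cannot move a model that never sees absolute size
  dec_shape <- model_decay(shape_model, s)
  expect_equal(dec_shape$decay_pct, 0)
  expect_equal(dec_shape$per_fraction$pct_changed, c(0, 0, 0))
  # but strongly moves a size-driven model
  dec_size <- model_decay(size_model, s)
  expect_gt(dec_size$decay_pct, dec_shape$decay_pct)
  expect_gt(dec_size$decay_pct, 10)
})

test_that("fossil prediction applies the posterior threshold rule", {
  s <- four_class_summaries(seed = 11, sep = 2)
  mlr <- fit_color_classifier(s, "mlr")
  centroid <- data.frame(sample_id = "fossilA",
                         mean_length_um = 1.1, mean_width_um = 0.26,
                         aspect_ratio = 1.1 / 0.26,
                         flatness = FALSE, hollowness = FALSE)
  pred <- predict_fossil(mlr, centroid)
  expect_equal(pred$call, "black")
  expect_gte(pred$p_black, 0.5)
  # an impossible threshold forces inconclusive calls
  hard <- predict_fossil(mlr, centroid, threshold = 1.0)
  expect_true(hard$call %in% c("inconclusive", "black"))
  if (hard$p_black < 1) expect_equal(hard$call, "inconclusive")
  expect_error(predict_fossil(mlr, centroid[, -3]), "missing")
})

test_that("the QDA flag-rule variant short-circuits flagged samples", {
  s <- four_class_summaries(seed = 12)
  qda <- fit_color_classifier(s, "qda", flag_rule = TRUE)
  fossil <- data.frame(sample_id = "f1",
                       mean_length_um = 0.72, mean_width_um = 0.36,
                       aspect_ratio = 2.0, flatness = TRUE,
                       hollowness = FALSE)
  post <- predict(qda, fossil)
  expect_equal(unname(post[1, "iridescent"]), 1)
})

test_that("classifier JSON serialization is well-formed", {
  s <- four_class_summaries(seed = 13)
  mlr <- fit_color_classifier(s, "mlr")
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(mlr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$model_kind, "mlr")
  expect_setequal(back$classes, COLOR_CATEGORIES)
})
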