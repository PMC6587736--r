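# End-to-end orchestration: simulate (or load) -> summarize -> ordinate ->
# disparity -> signal -> convergence -> classify -> fossil-predict, with a
# manifest and reproducible seeding.

#' Pipeline configuration
#'
#' @param seed integer seed (mandatory; every stochastic stage derives its
#'   own seed from it).
#' @param measurements optional path to a measurement table; when `NULL`
#'   the synthetic generator supplies the data.
#' @param tree optional path to a Newick tree (required with
#'   `measurements`).
#' @param fossils optional path to a fossil measurement table (no color
#'   labels needed).
#' @param sim [simulation_config()] used when no measurement path is given.
#' @param exclude_species species filtered out before analysis.
#' @param alphas alpha-shape radii.
#' @param n_iter_randomization label-randomization iterations.
#' @param n_boot bootstrap iterations (sum of variances, Wheatsheaf).
#' @param n_perm K_mult permutations.
#' @param cv_k,cv_repeats cross-validation folds and repeats.
#' @param shrinkage shrinkage fractions for model decay.
#' @param threshold posterior threshold for fossil calls.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            measurements = NULL, tree = NULL, fossils = NULL,
                            sim = simulation_config(),
                            exclude_species = character(),
                            alphas = c(1.3, 2, 5),
                            n_iter_randomization = 5000,
                            n_boot = 1000,
                            n_perm = 999,
                            cv_k = 10, cv_repeats = 5,
                            shrinkage = c(0.10, 0.20, 0.30),
                            threshold = 0.5,
                            out_dir = "melanomorph_results") {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("config refused: seed is mandatory")
  stopifnot(n_iter_randomization >= 1, n_boot >= 1, n_perm >= 1,
            cv_k >= 2, cv_repeats >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage <- function(obj, path) {
  if (is.data.frame(obj)) {
    write.csv(obj, path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
  }
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either a user-supplied dataset (measurement
#' table + Newick tree, and optionally fossil measurements) or on synthetic
#' data generated from `config$sim`. Each stage's serialized output is
#' written under `config$out_dir` together with a run manifest (package
#' version, seed, config hash, stage file list). Reruns with the same
#' config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("need a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  outputs <- character(0)
  stage_file <- function(name) file.path(config$out_dir, name)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list(status = "failed", failed_stage = name,
                       error = conditionMessage(e), outputs = outputs)
      jsonlite::write_json(manifest, stage_file("manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # -- stage 1: data -------------------------------------------------------
  fossil_measurements <- NULL
  dataset <- run_stage("data", {
    if (!is.null(config$measurements)) {
      tab <- read_measurements(config$measurements)
      tr <- read_tree(config$tree)
      if (!is.null(config$fossils))
        fossil_measurements <- read_measurements(config$fossils)
      list(tree = tr, measurements = tab, species_traits = NULL)
    } else {
      sim <- simulate_dataset(config$sim, seed = seed)
      # a few shrunken, label-stripped species stand in for fossil samples
      set.seed(seed + 3L)
      fossil_sp <- sample(unique(sim$measurements$species), 4)
      fm <- sim$measurements[sim$measurements$species %in% fossil_sp, ]
      fm <- apply_shrinkage(fm, 0.2)
      fm$sample_id <- paste0("fossil_", fm$sample_id)
      fossil_measurements <- fm
      sim
    }
  })
  filt <- run_stage("filter", filter_dataset(dataset$measurements,
                                             exclude_species =
                                               config$exclude_species))
  outputs <- c(outputs, write_stage(filt$table, stage_file("measurements.csv")))
  write_filter_report(filt$report, stage_file("filter_report.json"))
  outputs <- c(outputs, stage_file("filter_report.json"))

  # -- stage 2: summaries --------------------------------------------------
  summaries <- run_stage("summarize", summarize_samples(filt$table))
  outputs <- c(outputs, write_stage(summaries, stage_file("summaries.csv")))

  # -- stage 3: ordination -------------------------------------------------
  ord <- run_stage("ordinate", fit_pcamix(summaries))
  write_ordination(ord, stage_file("ordination.json"))
  outputs <- c(outputs, stage_file("ordination.json"))
  scores <- ord$scores

  # per-species means for the phylogenetic stages
  species_means <- aggregate(
    summaries[, c("mean_length_um", "mean_width_um", "aspect_ratio")],
    by = list(species = summaries$species), FUN = mean)
  rownames(species_means) <- species_means$species
  species_scores <- apply(scores, 2, function(s)
    tapply(s, summaries$species, mean))
  tree <- run_stage("tree", {
    tr <- dataset$tree
    if (!setequal(tr$tip.label, rownames(species_means)))
      tr <- prune_and_graft(tr, rownames(species_means))
    tr
  })
  species_scores <- species_scores[tree$tip.label, , drop = FALSE]

  # -- stage 4: disparity --------------------------------------------------
  disparity <- run_stage("disparity", disparity_analysis(
    scores, summaries$color_category, alphas = config$alphas,
    n_iter = config$n_iter_randomization, n_boot = config$n_boot,
    seed = seed + 10L))
  write_disparity(disparity, stage_file("disparity.json"))
  outputs <- c(outputs, stage_file("disparity.json"))

  # -- stage 5: phylogenetic signal ---------------------------------------
  signal <- run_stage("signal", {
    km <- kmult(species_scores, tree, n_perm = config$n_perm,
                seed = seed + 20L)
    lam <- pagels_lambda(species_scores[, 1], tree)
    list(kmult = unclass(km), lambda_pc1 = unclass(lam))
  })
  outputs <- c(outputs, write_stage(signal, stage_file("signal.json")))
  edges <- run_stage("phylomorphospace",
                     phylomorphospace_edges(species_scores, tree))
  outputs <- c(outputs, write_stage(edges, stage_file("phylomorphospace.csv")))

  # -- stage 6: convergence ------------------------------------------------
  convergence <- run_stage("convergence", {
    types <- if (!is.null(dataset$species_traits)) {
      dataset$species_traits[, c("species", "melanosome_type", "origin_id")]
    } else {
      infer_type_origins(summaries, tree)
    }
    traits <- as.matrix(species_means[, c("mean_length_um", "mean_width_um",
                                          "aspect_ratio")])
    convergence_report(species_scores, traits, tree, types,
                       n_boot = config$n_boot, seed = seed + 30L)
  })
  outputs <- c(outputs, write_stage(convergence, stage_file("convergence.csv")))

  # -- stage 7: classifiers ------------------------------------------------
  training <- run_stage("train", {
    mlr <- fit_color_classifier(summaries, "mlr")
    qda <- fit_color_classifier(summaries, "qda")
    cv_mlr <- cross_validate(summaries, "mlr", k = config$cv_k,
                             repeats = config$cv_repeats, seed = seed + 40L)
    cv_qda <- cross_validate(summaries, "qda", k = config$cv_k,
                             repeats = config$cv_repeats, seed = seed + 41L)
    decay_mlr <- model_decay(mlr, summaries, config$shrinkage)
    decay_qda <- model_decay(qda, summaries, config$shrinkage)
    list(mlr = mlr, qda = qda, cv_mlr = cv_mlr, cv_qda = cv_qda,
         decay_mlr = decay_mlr, decay_qda = decay_qda)
  })
  write_classifier(training$mlr, stage_file("classifier_mlr.json"))
  outputs <- c(outputs, stage_file("classifier_mlr.json"))
  perf <- data.frame(
    model = c("mlr", "qda"),
    accuracy_pct = 100 * c(training$cv_mlr$accuracy, training$cv_qda$accuracy),
    decay_pct = c(training$decay_mlr$decay_pct, training$decay_qda$decay_pct),
    p_value = c(training$cv_mlr$p_value, training$cv_qda$p_value),
    kappa = c(training$cv_mlr$kappa, training$cv_qda$kappa))
  outputs <- c(outputs, write_stage(perf, stage_file("model_performance.csv")))

  # -- stage 8: fossil prediction -----------------------------------------
  fossil_pred <- run_stage("predict", {
    fs <- summarize_samples(fossil_measurements)
    ord_scores <- predict(ord, fs)
    pred <- predict_fossil(training$mlr, fs, threshold = config$threshold)
    pred$pc1 <- ord_scores[, 1]
    pred$pc2 <- ord_scores[, 2]
    pred
  })
  outputs <- c(outputs, write_stage(fossil_pred,
                                    stage_file("fossil_predictions.csv")))

  cfg_path <- stage_file("config.json")
  cfg_json <- config
  cfg_json$sim <- unclass(cfg_json$sim)
  cfg_json$sim$type_regimes <- NULL
  jsonlite::write_json(unclass(cfg_json), cfg_path, auto_unbox = TRUE,
                       force = TRUE, digits = NA)
  manifest <- list(
    package = "melanomorph",
    version = as.character(utils::packageVersion("melanomorph")),
    status = "complete",
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_stages = 8L,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dataset = dataset, summaries = summaries, ordination = ord,
                 disparity = disparity, signal = signal,
                 convergence = convergence, training = training,
                 fossil_predictions = fossil_pred, manifest = manifest))
}

# fallback grouping of iridescent species into type "origins" when no
# simulation truth is available: each maximal clade of same-type species
# counts as one origin
infer_type_origins <- function(summaries, tree) {
  sp <- unique(summaries[, c("species", "color_category", "flatness",
                             "hollowness")])
  type <- rep(NA_character_, nrow(sp))
  irid <- sp$color_category == "iridescent"
  type[irid] <- ifelse(sp$hollowness[irid],
                       ifelse(sp$flatness[irid], "hollow_flat",
                              "hollow_cylindrical"),
                       ifelse(sp$flatness[irid], "solid_flat",
                              "solid_cylindrical"))
  out <- data.frame(species = sp$species, melanosome_type = type,
                    origin_id = NA_integer_, stringsAsFactors = FALSE)
  counter <- 0L
  sets <- tip_sets(tree)
  for (ty in unique(na.omit(type))) {
    members <- out$species[!is.na(out$melanosome_type) &
                             out$melanosome_type == ty]
    remaining <- members
    # greedily peel off maximal monotypic clades
    while (length(remaining) > 0) {
      best <- remaining[1]
      best_set <- best
      for (s in sets) {
        if (best %in% s && all(s %in% members) &&
            length(s) > length(best_set)) best_set <- s
      }
      counter <- counter + 1L
      out$origin_id[out$species %in% best_set] <- counter
      remaining <- setdiff(remaining, best_set)
    }
  }
  out
}
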