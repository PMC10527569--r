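# End-to-end orchestration: enhance -> (augment) -> extract -> fuse ->
# GA-tune -> ALO-MD select -> cross-validated evaluation, from a single
# config, with per-stage timings and a comparative report (individual vs
# fused vs selected feature sets).

#' Default GA search space for a classifier preset
#'
#' A small documented hyperparameter space per preset, used by
#' [ga_tune_classifier()] when no space is supplied.
#'
#' @param classifier_name one of [classifier_presets()].
#' @return a [ga_space()].
#' @export
default_tune_space <- function(classifier_name) {
  switch(classifier_name,
         quadratic_svm = ga_space(ga_param("cost", "log", 0.01, 100)),
         medium_knn = ga_space(ga_param("k", "integer", 1, 25)),
         weighted_knn = ga_space(ga_param("k", "integer", 1, 25)),
         fine_tree = ga_space(ga_param("cp", "log", 1e-5, 0.1),
                              ga_param("minsplit", "integer", 2, 20)),
         bagged_tree = ga_space(ga_param("ntree", "integer", 50, 300)),
         narrow_nn = ga_space(ga_param("decay", "log", 1e-6, 1e-1),
                              ga_param("size", "integer", 5, 20)),
         medium_nn = ga_space(ga_param("decay", "log", 1e-6, 1e-1),
                              ga_param("size", "integer", 15, 40)),
         bilayered_nn = ga_space(ga_param("decay", "log", 1e-6, 1e-1)),
         stop("unknown classifier preset: ", classifier_name, call. = FALSE))
}

#' GA-tune a classifier preset on a feature set
#'
#' Fitness of a chromosome = stratified hold-out accuracy (one fold of
#' `holdout_folds` kept for validation) of the preset fitted with the
#' chromosome's hyperparameters. Replaces manual hyperparameter
#' assignment.
#'
#' @param data a [feature_matrix()].
#' @param classifier_name one of [classifier_presets()].
#' @param space a [ga_space()]; default [default_tune_space()].
#' @param pop_size,generations GA budget. Defaults 12 and 10 (fixture
#'   scale; raise for real data).
#' @param holdout_folds the validation split is `1/holdout_folds` of the
#'   data. Default 4.
#' @param seed integer seed.
#' @return list with `opts` (best hyperparameters, usable as the `opts`
#'   argument of [crossval_classify()]), `fitness` (hold-out accuracy) and
#'   `trace`.
#' @export
ga_tune_classifier <- function(data, classifier_name = "quadratic_svm",
                               space = NULL, pop_size = 12L,
                               generations = 10L, holdout_folds = 4L,
                               seed = 1L) {
  space <- space %||% default_tune_space(classifier_name)
  labels <- droplevels(data$labels)
  fold_id <- make_folds(labels, holdout_folds,
                        seed = derive_seed(seed, "tune_split"))
  val <- fold_id == 1L
  fitness_fn <- function(ch) {
    clf <- .get_classifier(classifier_name, ch)
    with_seed(derive_seed(seed, "tune_fit"), {
      model <- clf$fit(data$values[!val, , drop = FALSE],
                       droplevels(labels[!val]))
      prob <- .reorder_prob(
        clf$predict(model, data$values[val, , drop = FALSE]),
        levels(labels))
      pred <- levels(labels)[max.col(prob, ties.method = "first")]
      mean(pred == as.character(labels[val]))
    })
  }
  res <- ga_evolve(space, fitness_fn, pop_size = pop_size,
                   generations = generations, seed = seed)
  list(opts = res$best, fitness = res$best_fitness, trace = res$trace)
}

#' Pipeline run configuration
#'
#' Collects every stage's parameters and toggles. Defaults run the whole
#' pipeline on bundled synthetic fixtures in a couple of minutes.
#'
#' @param input_dir optional directory of PNG images in one-subdirectory-
#'   per-class layout; `NULL` generates synthetic fixtures instead.
#' @param n_classes,per_class,image_size,haze_strength fixture-generator
#'   settings (see [make_hazy_images()]); ignored when `input_dir` is set.
#' @param enhance run contrast enhancement? Default `TRUE`.
#' @param augment apply flip augmentation (fold-aware: flips inherit their
#'   source image's fold so validation never sees a flip of a training
#'   image)? Default `FALSE`.
#' @param extractors list of [extractor_spec()]s; the defaults emulate
#'   three differently sized CNN backbones.
#' @param fusion_threshold,knn_k correlation cut and fitness neighborhood
#'   for [fuse_select()].
#' @param tune GA-tune the classifier? Default `TRUE`.
#' @param ga_pop,ga_generations GA budget for tuning.
#' @param alpha,n_ants,n_antlions,iters,md_enabled ALO-MD settings (see
#'   [run_alo_md()]).
#' @param classifier preset evaluated in the comparative report.
#' @param folds cross-validation folds. Default 10.
#' @param seed global seed propagated to every stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, n_classes = 7L,
                            per_class = 30L, image_size = c(64L, 64L),
                            haze_strength = 1, enhance = TRUE,
                            augment = FALSE,
                            extractors = list(
                              extractor_spec("toy_dark", 64L),
                              extractor_spec("toy_res", 48L),
                              extractor_spec("toy_incep", 56L)),
                            fusion_threshold = 0.5, knn_k = 1L,
                            tune = TRUE, ga_pop = 12L, ga_generations = 10L,
                            alpha = 0.99, n_ants = 20L, n_antlions = 20L,
                            iters = 30L, md_enabled = TRUE,
                            classifier = "quadratic_svm", folds = 10L,
                            seed = 7L) {
  structure(list(input_dir = input_dir, n_classes = n_classes,
                 per_class = per_class, image_size = image_size,
                 haze_strength = haze_strength, enhance = enhance,
                 augment = augment, extractors = extractors,
                 fusion_threshold = fusion_threshold, knn_k = knn_k,
                 tune = tune, ga_pop = ga_pop,
                 ga_generations = ga_generations, alpha = alpha,
                 n_ants = n_ants, n_antlions = n_antlions, iters = iters,
                 md_enabled = md_enabled, classifier = classifier,
                 folds = folds, seed = seed),
            class = "pipeline_config")
}

.read_image_dir <- function(dir) {
  classes <- list.dirs(dir, recursive = FALSE)
  if (length(classes) == 0) stop("no class subdirectories in ", dir,
                                 call. = FALSE)
  images <- list()
  labels <- character()
  for (cd in classes) {
    files <- list.files(cd, pattern = "\\.png$", full.names = TRUE)
    for (f in files) {
      images[[length(images) + 1L]] <- read_image(f)
      labels <- c(labels, basename(cd))
    }
  }
  list(images = images, labels = factor(labels))
}

#' Run the full lesion-classification pipeline
#'
#' Executes the enabled stages in order on either a directory of images or
#' synthetic fixtures: contrast enhancement, optional fold-aware flip
#' augmentation, multi-extractor feature extraction, serial
#' correlation-based fusion, GA hyperparameter tuning, ALO-MD feature
#' selection, and a comparative cross-validated evaluation of each
#' individual extractor, the full fused set, and the final selected set.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress to stderr? Default `TRUE`.
#' @return an object of class `run_report`: per-stage `timings` (seconds),
#'   `fusion` summary, `tuning` result, `selection` (mask, trace, score),
#'   `evaluations` (named list of `eval_report`s: one per extractor plus
#'   `fused` and `selected`), and `feature_counts`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  inp <- clock("input", {
    if (!is.null(config$input_dir)) {
      .read_image_dir(config$input_dir)
    } else {
      fx <- make_hazy_images(n_classes = config$n_classes,
                             per_class = config$per_class,
                             size = config$image_size,
                             haze_strength = config$haze_strength,
                             seed = config$seed)
      list(images = fx$images, labels = fx$labels)
    }
  })
  say("input", "%d images, %d classes", length(inp$images),
      nlevels(inp$labels))

  images <- inp$images
  labels <- inp$labels
  if (config$enhance) {
    images <- clock("enhance", lapply(images, enhance_image))
    say("enhance", "done in %.1fs", timings$enhance)
  }

  fold_ids <- NULL
  if (config$augment) {
    base_folds <- make_folds(labels, config$folds,
                             seed = derive_seed(config$seed, "pipeline_folds"))
    aug <- clock("augment", augment_flips(images, labels))
    images <- aug$images
    labels <- factor(aug$labels)
    fold_ids <- rep(base_folds, each = 4L)
    say("augment", "%d images after flips", length(images))
  }

  feats <- clock("extract", {
    lapply(config$extractors, function(sp) {
      extract_features(images, labels, sp)
    })
  })
  names(feats) <- vapply(config$extractors, function(sp) sp$name,
                         character(1))
  say("extract", "widths: %s",
      paste(vapply(feats, function(f) ncol(f$values), integer(1)),
            collapse = ", "))

  fus <- clock("fuse", {
    fuse_select(feats, threshold = config$fusion_threshold,
                k = config$knn_k, folds = config$folds,
                seed = derive_seed(config$seed, "fusion"))
  })
  say("fuse", "chosen %s set (%d of %d cols)", fus$chosen,
      ncol(fus$selected$values), ncol(fus$fused$values))

  tuning <- NULL
  clf_opts <- list()
  if (config$tune) {
    tuning <- clock("tune", {
      ga_tune_classifier(fus$selected, config$classifier,
                         pop_size = config$ga_pop,
                         generations = config$ga_generations,
                         seed = derive_seed(config$seed, "tune"))
    })
    clf_opts <- tuning$opts
    say("tune", "holdout accuracy %.3f", tuning$fitness)
  }

  sel <- clock("select", {
    run_alo_md(fus$selected,
               fitness_spec(alpha = config$alpha, k = config$knn_k,
                            folds = config$folds,
                            seed = derive_seed(config$seed, "selfit")),
               n_ants = config$n_ants, n_antlions = config$n_antlions,
               S = config$iters,
               seed = derive_seed(config$seed, "alo"),
               md_enabled = config$md_enabled)
  })
  selected_fm <- fm_select(fus$selected, which(sel$mask == 1L))
  say("select", "%d of %d features kept (elite score %.4f)",
      sel$n_selected, ncol(fus$selected$values), sel$score)

  evaluations <- clock("evaluate", {
    evs <- lapply(feats, function(f) {
      crossval_classify(f, config$classifier, folds = config$folds,
                        seed = config$seed, fold_ids = fold_ids,
                        opts = clf_opts)
    })
    evs$fused <- crossval_classify(fus$fused, config$classifier,
                                   folds = config$folds, seed = config$seed,
                                   fold_ids = fold_ids, opts = clf_opts)
    evs$selected <- crossval_classify(selected_fm, config$classifier,
                                      folds = config$folds,
                                      seed = config$seed,
                                      fold_ids = fold_ids, opts = clf_opts)
    evs
  })
  for (nm in names(evaluations)) {
    say("evaluate", "%-10s accuracy %.3f", nm, evaluations[[nm]]$accuracy)
  }

  structure(list(config = config,
                 timings = timings,
                 fusion = list(chosen = fus$chosen,
                               fitness_positive = fus$fitness_positive,
                               fitness_weak = fus$fitness_weak,
                               n_positive = if (is.null(fus$positive_set)) 0L
                                            else ncol(fus$positive_set$values),
                               n_weak = if (is.null(fus$weak_set)) 0L
                                        else ncol(fus$weak_set$values)),
                 tuning = tuning,
                 selection = sel,
                 evaluations = evaluations,
                 feature_counts = list(
                   individual = vapply(feats, function(f) ncol(f$values),
                                       integer(1)),
                   fused = ncol(fus$fused$values),
                   fusion_chosen = ncol(fus$selected$values),
                   selected = sel$n_selected)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  features: fused %d -> fusion %d -> selected %d\n",
              x$feature_counts$fused, x$feature_counts$fusion_chosen,
              x$feature_counts$selected))
  for (nm in names(x$evaluations)) {
    cat(sprintf("  %-10s accuracy %.3f  f1 %.3f\n", nm,
                x$evaluations[[nm]]$accuracy, x$evaluations[[nm]]$f1))
  }
  invisible(x)
}
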