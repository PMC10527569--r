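# Multiclass evaluation harness: confusion matrix, the full metric panel
# (accuracy, macro sensitivity/precision/F1, FNR, macro one-vs-rest AUC,
# Fowlkes-Mallows index, multiclass MCC, Cohen's kappa) and a stratified
# cross-validation driver over a roster of named classifier presets.

#' Build a confusion matrix
#'
#' `counts[i, j]` = number of samples with true class `i` predicted as
#' class `j`.
#'
#' @param true_labels,predicted_labels equal-length vectors with values in
#'   `class_names`.
#' @param class_names class order for rows/columns; defaults to the sorted
#'   union of observed labels.
#' @return a `C x C` integer matrix with `dimnames = list(true, predicted)`.
#' @export
confusion <- function(true_labels, predicted_labels, class_names = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  class_names <- class_names %||%
    sort(unique(c(as.character(true_labels), as.character(predicted_labels))))
  bad <- setdiff(unique(c(as.character(true_labels),
                          as.character(predicted_labels))), class_names)
  if (length(bad)) {
    stop("labels outside `class_names`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  t_f <- factor(as.character(true_labels), levels = class_names)
  p_f <- factor(as.character(predicted_labels), levels = class_names)
  cm <- table(true = t_f, predicted = p_f)
  matrix(as.integer(cm), nrow = length(class_names),
         dimnames = list(true = class_names, predicted = class_names))
}

# Rank-based one-vs-rest AUC, averaged over classes present in the truth.
.macro_auc <- function(truth, scores) {
  classes <- colnames(scores)
  aucs <- c()
  for (cl in classes) {
    pos <- as.character(truth) == cl
    if (!any(pos) || all(pos)) next
    a <- suppressMessages(
      pROC::auc(pROC::roc(response = pos, predictor = scores[, cl],
                          levels = c(FALSE, TRUE), direction = "<",
                          quiet = TRUE)))
    aucs <- c(aucs, as.numeric(a))
  }
  if (length(aucs)) mean(aucs) else NA_real_
}

#' Compute the multiclass metric panel from a confusion matrix
#'
#' Macro averaging over the classes present in the truth (a class absent
#' from both truth and prediction is dropped with a warning; a
#' truth-present class that is never predicted contributes precision 0).
#' Reported fields: accuracy; macro sensitivity (recall), precision and F1;
#' `fnr = 1 - sensitivity`; Fowlkes-Mallows index
#' `sqrt(precision * sensitivity)`; multiclass Matthews correlation
#' coefficient; Cohen's kappa; micro-averaged precision/recall (equal to
#' accuracy for single-label problems, emitted for transparency); and
#' macro one-vs-rest AUC when per-class scores are supplied.
#'
#' @param cm confusion matrix from [confusion()].
#' @param scores optional `N x C` score/probability matrix with class
#'   columns, for AUC.
#' @param truth optional length-`N` truth vector matching `scores`.
#' @param elapsed_time optional seconds to record in the report.
#' @return an object of class `eval_report`.
#' @export
compute_metrics <- function(cm, scores = NULL, truth = NULL,
                            elapsed_time = NA_real_) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty", call. = FALSE)
  classes <- rownames(cm)
  row_s <- rowSums(cm)
  col_s <- colSums(cm)
  absent <- row_s == 0 & col_s == 0
  if (any(absent)) {
    warning("classes absent from truth and prediction excluded from macro ",
            "averages: ", paste(classes[absent], collapse = ", "))
  }
  in_truth <- row_s > 0
  tp <- diag(cm)
  recall <- ifelse(row_s > 0, tp / row_s, NA_real_)
  precision <- ifelse(col_s > 0, tp / col_s, 0)
  f1 <- ifelse(precision + recall > 0 & !is.na(recall),
               2 * precision * recall / (precision + recall), 0)
  macro_recall <- mean(recall[in_truth])
  macro_precision <- mean(precision[in_truth])
  macro_f1 <- mean(f1[in_truth])
  accuracy <- sum(tp) / total
  # multiclass MCC from the confusion matrix
  num <- sum(tp) * total - sum(row_s * col_s)
  den <- sqrt(max(total^2 - sum(col_s^2), 0)) *
    sqrt(max(total^2 - sum(row_s^2), 0))
  mcc <- if (den > 0) num / den else 0
  pe <- sum(row_s * col_s) / total^2
  kappa <- if (1 - pe > 0) (accuracy - pe) / (1 - pe) else 0
  auc <- if (!is.null(scores) && !is.null(truth)) {
    .macro_auc(truth, scores)
  } else {
    NA_real_
  }
  per_class <- data.frame(class = classes, support = as.integer(row_s),
                          predicted = as.integer(col_s),
                          recall = recall, precision = precision, f1 = f1,
                          row.names = NULL)
  structure(list(accuracy = accuracy,
                 sensitivity = macro_recall,
                 precision = macro_precision,
                 f1 = macro_f1,
                 fnr = 1 - macro_recall,
                 auc = auc,
                 fowlkes_mallows = sqrt(macro_precision * macro_recall),
                 mcc = mcc,
                 kappa = kappa,
                 micro_precision = accuracy,
                 micro_recall = accuracy,
                 per_class = per_class,
                 confusion = cm,
                 n = total,
                 elapsed_time = elapsed_time),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n=%d acc=%.3f sens=%.3f prec=%.3f ",
                     "f1=%.3f fm=%.3f mcc=%.3f kappa=%.3f auc=%s\n"),
              x$n, x$accuracy, x$sensitivity, x$precision, x$f1,
              x$fowlkes_mallows, x$mcc, x$kappa,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

# ---- classifier presets -------------------------------------------------
# Names follow the MATLAB Classification Learner nomenclature; internals
# are documented open-source equivalents, configurable via `opts`.

.knn_predict_prob <- function(train, test, labels, k, weighted = FALSE) {
  d2 <- outer(rowSums(test^2), rowSums(train^2), "+") -
    2 * test %*% t(train)
  d2 <- pmax(d2, 0)
  classes <- levels(labels)
  prob <- matrix(0, nrow(test), length(classes),
                 dimnames = list(NULL, classes))
  kk <- min(k, nrow(train))
  for (i in seq_len(nrow(test))) {
    ord <- order(d2[i, ])[seq_len(kk)]
    w <- if (weighted) 1 / (sqrt(d2[i, ord]) + 1e-8) else rep(1, kk)
    for (j in seq_len(kk)) {
      cl <- as.character(labels[ord[j]])
      prob[i, cl] <- prob[i, cl] + w[j]
    }
    prob[i, ] <- prob[i, ] / sum(prob[i, ])
  }
  prob
}

# Two-hidden-layer softmax perceptron trained by BFGS with analytic
# backprop gradients (cross-entropy + L2 weight decay).
.mlp2_train <- function(x, y, h1 = 10L, h2 = 10L, decay = 1e-3,
                        maxit = 150L) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  classes <- levels(y)
  n <- nrow(xs); d <- ncol(xs); C <- length(classes)
  yi <- as.integer(y)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), yi)] <- 1
  sizes <- list(W1 = c(d, h1), b1 = h1, W2 = c(h1, h2), b2 = h2,
                W3 = c(h2, C), b3 = C)
  n_par <- d * h1 + h1 + h1 * h2 + h2 + h2 * C + C
  unpack <- function(theta) {
    i <- 0
    take <- function(len) {
      out <- theta[(i + 1):(i + len)]
      i <<- i + len
      out
    }
    list(W1 = matrix(take(d * h1), d, h1), b1 = take(h1),
         W2 = matrix(take(h1 * h2), h1, h2), b2 = take(h2),
         W3 = matrix(take(h2 * C), h2, C), b3 = take(C))
  }
  forward <- function(p, xin) {
    a1 <- tanh(sweep(xin %*% p$W1, 2, p$b1, "+"))
    a2 <- tanh(sweep(a1 %*% p$W2, 2, p$b2, "+"))
    z3 <- sweep(a2 %*% p$W3, 2, p$b3, "+")
    z3 <- z3 - apply(z3, 1, max)
    ez <- exp(z3)
    list(a1 = a1, a2 = a2, prob = ez / rowSums(ez))
  }
  obj <- function(theta) {
    p <- unpack(theta)
    f <- forward(p, xs)
    -sum(Y * log(pmax(f$prob, 1e-12))) / n +
      0.5 * decay * (sum(p$W1^2) + sum(p$W2^2) + sum(p$W3^2))
  }
  grad <- function(theta) {
    p <- unpack(theta)
    f <- forward(p, xs)
    d3 <- (f$prob - Y) / n
    gW3 <- t(f$a2) %*% d3 + decay * p$W3
    gb3 <- colSums(d3)
    d2 <- (d3 %*% t(p$W3)) * (1 - f$a2^2)
    gW2 <- t(f$a1) %*% d2 + decay * p$W2
    gb2 <- colSums(d2)
    d1 <- (d2 %*% t(p$W2)) * (1 - f$a1^2)
    gW1 <- t(xs) %*% d1 + decay * p$W1
    gb1 <- colSums(d1)
    c(gW1, gb1, gW2, gb2, gW3, gb3)
  }
  theta0 <- stats::rnorm(n_par, 0, 0.3)
  fit <- stats::optim(theta0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-8))
  list(params = unpack(fit$par), center = ctr, scale = scl,
       classes = classes, forward = forward)
}

.mlp2_predict <- function(model, x) {
  xs <- scale(as.matrix(x), model$center, model$scale)
  prob <- model$forward(model$params, xs)$prob
  colnames(prob) <- model$classes
  prob
}

.reorder_prob <- function(prob, classes) {
  out <- matrix(0, nrow(prob), length(classes),
                dimnames = list(NULL, classes))
  shared <- intersect(colnames(prob), classes)
  out[, shared] <- prob[, shared]
  out
}

#' Names of the available classifier presets
#'
#' @return character vector of names accepted by [crossval_classify()].
#' @export
classifier_presets <- function() {
  c("fine_tree", "quadratic_svm", "medium_knn", "weighted_knn",
    "bagged_tree", "narrow_nn", "medium_nn", "bilayered_nn")
}

.get_classifier <- function(name, opts = list()) {
  o <- function(key, default) opts[[key]] %||% default
  switch(
    name,
    fine_tree = list(
      fit = function(x, y) {
        df <- data.frame(.y = y, x)
        rpart::rpart(.y ~ ., df, method = "class",
                     control = rpart::rpart.control(
                       cp = o("cp", 1e-4), minsplit = o("minsplit", 4),
                       xval = 0))
      },
      predict = function(m, x) predict(m, data.frame(x), type = "prob")),
    quadratic_svm = list(
      fit = function(x, y) {
        e1071::svm(x, y, kernel = "polynomial", degree = 2,
                   coef0 = o("coef0", 1), cost = o("cost", 1),
                   probability = TRUE)
      },
      predict = function(m, x) {
        attr(predict(m, x, probability = TRUE), "probabilities")
      }),
    medium_knn = list(
      fit = function(x, y) list(x = x, y = y, k = o("k", 10)),
      predict = function(m, x) .knn_predict_prob(m$x, x, m$y, m$k)),
    weighted_knn = list(
      fit = function(x, y) list(x = x, y = y, k = o("k", 10)),
      predict = function(m, x) {
        .knn_predict_prob(m$x, x, m$y, m$k, weighted = TRUE)
      }),
    bagged_tree = list(
      fit = function(x, y) {
        randomForest::randomForest(x, y, ntree = o("ntree", 100),
                                   mtry = ncol(x))
      },
      predict = function(m, x) predict(m, x, type = "prob")),
    narrow_nn = list(
      fit = function(x, y) .nnet_fit(x, y, size = o("size", 10),
                                     decay = o("decay", 1e-4)),
      predict = .nnet_predict),
    medium_nn = list(
      fit = function(x, y) .nnet_fit(x, y, size = o("size", 25),
                                     decay = o("decay", 1e-4)),
      predict = .nnet_predict),
    bilayered_nn = list(
      fit = function(x, y) .mlp2_train(x, y, h1 = o("h1", 10),
                                       h2 = o("h2", 10),
                                       decay = o("decay", 1e-3)),
      predict = .mlp2_predict),
    stop("unknown classifier preset: ", name, call. = FALSE)
  )
}

.nnet_fit <- function(x, y, size, decay) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  m <- nnet::nnet(xs, nnet::class.ind(y), size = size, decay = decay,
                  softmax = TRUE, maxit = 200, trace = FALSE,
                  MaxNWts = 50000)
  list(model = m, center = ctr, scale = scl, classes = levels(y))
}

.nnet_predict <- function(m, x) {
  xs <- scale(as.matrix(x), m$center, m$scale)
  prob <- predict(m$model, xs)
  colnames(prob) <- m$classes
  prob
}

#' Stratified cross-validated classification
#'
#' Assigns stratified folds, trains the named classifier preset on each
#' training split, pools the out-of-fold predictions and class scores, and
#' scores them once through [compute_metrics()]. Fully seeded: the same
#' data, classifier and seed reproduce the report exactly (except
#' `elapsed_time`).
#'
#' @param data a [feature_matrix()] with at least two classes.
#' @param classifier_name one of [classifier_presets()]:
#'   `fine_tree` (unpruned shallow-limit decision tree), `quadratic_svm`
#'   (degree-2 polynomial-kernel SVM), `medium_knn` (k = 10),
#'   `weighted_knn` (distance-weighted k = 10), `bagged_tree` (bagging via
#'   full-mtry random forest), `narrow_nn`/`medium_nn` (1-hidden-layer
#'   perceptrons of width 10/25), `bilayered_nn` (2-hidden-layer 10+10
#'   perceptron).
#' @param folds requested fold count. Default 10.
#' @param seed integer seed for folds and any classifier randomness.
#' @param fold_ids optional externally supplied fold assignment (length
#'   `N`), e.g. for group-aware splitting; overrides stratification.
#' @param opts named list of preset-specific overrides (e.g. `cost`, `k`,
#'   `size`).
#' @return an [compute_metrics()] `eval_report`.
#' @export
crossval_classify <- function(data, classifier_name = "quadratic_svm",
                              folds = 10L, seed = 1L, fold_ids = NULL,
                              opts = list()) {
  labels <- droplevels(data$labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  clf <- .get_classifier(classifier_name, opts)
  t0 <- proc.time()[["elapsed"]]
  res <- with_seed(derive_seed(seed, paste0("cv_", classifier_name)), {
    fold_id <- fold_ids %||% make_folds(labels, folds, seed = NULL)
    n <- nrow(data$values)
    scores <- matrix(0, n, nlevels(labels),
                     dimnames = list(NULL, levels(labels)))
    pred <- character(n)
    for (f in unique(fold_id)) {
      te <- fold_id == f
      model <- clf$fit(data$values[!te, , drop = FALSE],
                       droplevels(labels[!te]))
      prob <- .reorder_prob(
        clf$predict(model, data$values[te, , drop = FALSE]),
        levels(labels))
      scores[te, ] <- prob
      pred[te] <- levels(labels)[max.col(prob, ties.method = "first")]
    }
    list(pred = pred, scores = scores)
  })
  cm <- confusion(as.character(labels), res$pred, levels(labels))
  compute_metrics(cm, scores = res$scores, truth = labels,
                  elapsed_time = proc.time()[["elapsed"]] - t0)
}
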