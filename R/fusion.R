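# Serial correlation-based fusion: concatenate multi-extractor feature
# tables, correlate consecutive column pairs, split into positively vs
# weakly correlated sets, and keep whichever scores better under a
# 1-nearest-neighbor cross-validated fitness.

#' Serially fuse feature matrices
#'
#' Horizontal concatenation of feature tables from multiple extractors:
#' width `k1 + k2 + ...`, column order preserving input order, labels
#' unchanged. All inputs must have identical sample counts and labels.
#'
#' @param mats list of [feature_matrix()] objects.
#' @return the fused [feature_matrix()].
#' @export
serial_fuse <- function(mats) {
  if (length(mats) == 0) stop("`mats` must be non-empty", call. = FALSE)
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (nrow(m$values) != nrow(ref$values) ||
        !identical(as.character(m$labels), as.character(ref$labels))) {
      stop("all feature matrices must share sample count and labels",
           call. = FALSE)
    }
  }
  feature_matrix(do.call(cbind, lapply(mats, function(m) m$values)),
                 ref$labels,
                 make.unique(unlist(lapply(mats, function(m) m$feature_names))))
}

# Pearson correlation via the raw-sum formula; constant columns give a zero
# denominator and are assigned r = 0 by convention.
.pearson_sum <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(max(n * sum(x^2) - sum(x)^2, 0)) *
    sqrt(max(n * sum(y^2) - sum(y)^2, 0))
  if (!is.finite(den) || den <= 0) return(0)
  min(max(num / den, -1), 1)
}

#' Pairwise correlation of consecutive feature columns
#'
#' Partitions the fused columns into consecutive disjoint pairs
#' `(1,2), (3,4), ...` (an odd final column pairs with itself) and computes
#' the Pearson correlation of each pair across the `N` samples.
#'
#' @param fused a [feature_matrix()] with at least 2 samples.
#' @return list with `pair_index` (`P x 2` matrix of column indices) and
#'   `pair_r` (length-`P` vector in `[-1, 1]`).
#' @export
pairwise_correlation <- function(fused) {
  v <- fused$values
  if (nrow(v) < 2) stop("need at least 2 samples", call. = FALSE)
  k <- ncol(v)
  i1 <- seq(1L, k, by = 2L)
  i2 <- pmin(i1 + 1L, k)
  r <- vapply(seq_along(i1),
              function(p) .pearson_sum(v[, i1[p]], v[, i2[p]]),
              numeric(1))
  list(pair_index = cbind(first = i1, second = i2), pair_r = r)
}

# Stratified fold assignment; degrades to fewer folds when the smallest
# class has fewer members than requested.
make_folds <- function(labels, folds, seed = NULL) {
  labels <- factor(labels)
  folds_eff <- max(2L, min(as.integer(folds), min(table(labels))))
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds_eff), length(idx)))
    }
  })
  fold_id
}

#' Cross-validated 1-NN fitness of a feature set
#'
#' Mean stratified cross-validated accuracy of a k-nearest-neighbor
#' classifier (Euclidean; `k = 1` is the "fine" configuration used to score
#' candidate feature sets). Fold assignment and distance-tie resolution are
#' fixed by `seed`, so repeated calls are identical.
#'
#' @param mat a [feature_matrix()] with at least two classes.
#' @param k neighborhood size. Default 1.
#' @param folds requested fold count; reduced automatically when a class is
#'   smaller. Default 10.
#' @param seed integer seed for fold assignment.
#' @return pooled out-of-fold accuracy in `[0, 1]`.
#' @export
knn_fitness <- function(mat, k = 1L, folds = 10L, seed = 1L) {
  if (nlevels(droplevels(mat$labels)) < 2) {
    stop("fitness requires at least two classes", call. = FALSE)
  }
  labels <- droplevels(mat$labels)
  with_seed(derive_seed(seed, "knn_fitness"), {
    fold_id <- make_folds(labels, folds, seed = NULL)
    correct <- 0L
    for (f in unique(fold_id)) {
      te <- fold_id == f
      pred <- class::knn(mat$values[!te, , drop = FALSE],
                         mat$values[te, , drop = FALSE],
                         labels[!te], k = k)
      correct <- correct + sum(pred == labels[te])
    }
    correct / length(labels)
  })
}

#' Fuse feature sets and keep the better correlation partition
#'
#' Full serial correlation-based fusion: concatenate the inputs, correlate
#' consecutive column pairs, route both columns of a pair with
#' `r > threshold` to the positively correlated set and all remaining
#' columns to the weakly correlated set, score both sets with
#' [knn_fitness()], and declare the higher-scoring set the winner (ties go
#' to the positive set; an empty partition scores 0).
#'
#' @inheritParams knn_fitness
#' @param mats list of [feature_matrix()] objects with shared labels.
#' @param threshold correlation cut in `[-1, 1]`; pairs strictly above it
#'   count as positively correlated. Default 0.5.
#' @return an object of class `fusion_result` with elements `fused`,
#'   `pair_index`, `pair_r`, `positive_set`, `weak_set`,
#'   `fitness_positive`, `fitness_weak`, `chosen` (`"positive"`/`"weak"`),
#'   and `selected` (the winning [feature_matrix()]).
#' @export
fuse_select <- function(mats, threshold = 0.5, k = 1L, folds = 10L,
                        seed = 1L) {
  fused <- serial_fuse(mats)
  pc <- pairwise_correlation(fused)
  pos_pairs <- pc$pair_r > threshold
  pos_cols <- sort(unique(as.vector(pc$pair_index[pos_pairs, , drop = FALSE])))
  weak_cols <- setdiff(seq_len(ncol(fused$values)), pos_cols)
  positive_set <- if (length(pos_cols)) fm_select(fused, pos_cols) else NULL
  weak_set <- if (length(weak_cols)) fm_select(fused, weak_cols) else NULL
  fit_pos <- if (is.null(positive_set)) 0 else {
    knn_fitness(positive_set, k = k, folds = folds, seed = seed)
  }
  fit_weak <- if (is.null(weak_set)) 0 else {
    knn_fitness(weak_set, k = k, folds = folds, seed = seed)
  }
  chosen <- if (fit_pos >= fit_weak) "positive" else "weak"
  structure(list(fused = fused,
                 pair_index = pc$pair_index,
                 pair_r = pc$pair_r,
                 positive_set = positive_set,
                 weak_set = weak_set,
                 fitness_positive = fit_pos,
                 fitness_weak = fit_weak,
                 chosen = chosen,
                 selected = if (chosen == "positive") positive_set else weak_set),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(paste0("<fusion_result> fused %d cols | positive %d ",
                     "(fitness %.3f) | weak %d (fitness %.3f) | chosen: %s\n"),
              ncol(x$fused$values),
              if (is.null(x$positive_set)) 0L else ncol(x$positive_set$values),
              x$fitness_positive,
              if (is.null(x$weak_set)) 0L else ncol(x$weak_set$values),
              x$fitness_weak, x$chosen))
  invisible(x)
}
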