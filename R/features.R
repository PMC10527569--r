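# FeatureMatrix container (samples x features + labels) and the feature
# extraction contract. Real pipelines plug CNN embeddings in through
# read_feature_csv(); the bundled toy extractor gives a deterministic,
# weight-free stand-in so downstream stages are fully testable.

#' Construct a feature matrix
#'
#' The unit of fusion and selection: an `N x K` numeric matrix of per-sample
#' features plus a length-`N` label vector and `K` feature names carrying
#' source-extractor provenance (e.g. `"toy_a_0001"`).
#'
#' @param values numeric `N x K` matrix, all entries finite.
#' @param labels length-`N` vector of class identifiers (coerced to factor).
#' @param feature_names optional length-`K` character vector; defaults to
#'   existing column names or `f_0001 ...`.
#' @return an object of class `feature_matrix` with elements `values`,
#'   `labels`, `feature_names`.
#' @export
feature_matrix <- function(values, labels, feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("feature values must all be finite", call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("`labels` length must equal the number of rows", call. = FALSE)
  }
  feature_names <- feature_names %||% colnames(values) %||%
    sprintf("f_%04d", seq_len(ncol(values)))
  if (length(feature_names) != ncol(values)) {
    stop("`feature_names` length must equal the number of columns",
         call. = FALSE)
  }
  colnames(values) <- feature_names
  structure(list(values = values, labels = factor(labels),
                 feature_names = feature_names),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset the feature columns of a feature matrix
#'
#' Column subsetting that preserves labels and provenance names, e.g. to
#' apply a selection mask: `fm_select(fm, which(mask == 1))`.
#'
#' @param fm a [feature_matrix()].
#' @param cols integer or logical column index.
#' @return the reduced [feature_matrix()].
#' @export
fm_select <- function(fm, cols) {
  feature_matrix(fm$values[, cols, drop = FALSE], fm$labels,
                 fm$feature_names[cols])
}

#' Write / read a feature matrix as CSV
#'
#' Plain-text interchange format: first column `label`, remaining columns
#' the features with their provenance-prefixed names in the header.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV file path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` returns a [feature_matrix()].
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(label = as.character(fm$labels), fm$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) {
    stop("feature CSV must contain a `label` column", call. = FALSE)
  }
  vals <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  feature_matrix(vals, df$label, colnames(vals))
}

#' Augment images with horizontal and vertical flips
#'
#' Expands each image into four variants: the original, its left-right
#' flip, its up-down flip, and both flips combined. Labels are replicated
#' accordingly, so `N` images become `4 N`.
#'
#' @param images list of `H x W x 3` arrays.
#' @param labels vector of length `length(images)`.
#' @return list with elements `images` (length `4 N`, original-first order)
#'   and `labels`.
#' @export
augment_flips <- function(images, labels) {
  if (length(images) == 0) stop("`images` must be non-empty", call. = FALSE)
  stopifnot(length(labels) == length(images))
  out <- vector("list", 4L * length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    out[[4L * i - 3L]] <- img
    out[[4L * i - 2L]] <- flip_image(img, "lr")
    out[[4L * i - 1L]] <- flip_image(img, "ud")
    out[[4L * i]] <- flip_image(flip_image(img, "lr"), "ud")
  }
  list(images = out, labels = rep(labels, each = 4L))
}

#' Declare a feature extractor
#'
#' Names an extractor and its embedding width. The built-in `"toy"` family
#' computes deterministic per-image summary statistics (global and 4x4-grid
#' patch means/SDs, intensity histogram, per-channel moments) and maps them
#' through a fixed random projection seeded by the extractor name, so
#' differently named extractors emulate different CNN backbones. Real CNN
#' embeddings enter the pipeline via [read_feature_csv()] instead.
#'
#' @param name extractor identifier; becomes the feature-name prefix.
#' @param embed_dim output feature count `K` (>= 1).
#' @return an object of class `extractor_spec`.
#' @export
extractor_spec <- function(name = "toy", embed_dim = 64L) {
  embed_dim <- as.integer(embed_dim)
  if (embed_dim < 1L) stop("`embed_dim` must be >= 1", call. = FALSE)
  structure(list(name = name, embed_dim = embed_dim),
            class = "extractor_spec")
}

# Summary-statistic descriptor of one image: 2 global + 16 + 16 patch
# stats + 16 histogram bins + 6 per-channel moments = 56 values.
.image_descriptor <- function(img) {
  g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  h <- nrow(g); w <- ncol(g)
  rb <- cut(seq_len(h), 4, labels = FALSE)
  cb <- cut(seq_len(w), 4, labels = FALSE)
  pm <- ps <- numeric(16)
  k <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      k <- k + 1
      patch <- g[rb == i, cb == j]
      pm[k] <- mean(patch)
      ps[k] <- stats::sd(patch)
    }
  }
  hist_bins <- tabulate(pmin(floor(g * 16) + 1, 16), nbins = 16) / length(g)
  ch_mean <- apply(img, 3, mean)
  ch_sd <- apply(img, 3, stats::sd)
  c(mean(g), stats::sd(g), pm, ps, hist_bins, ch_mean, ch_sd)
}

#' Extract features from a list of images
#'
#' Applies the extractor declared by `spec` to every image, returning rows
#' in input order. Deterministic: the toy extractor's projection matrix is
#' derived from the extractor name and width alone.
#'
#' @param images non-empty list of `H x W x 3` arrays.
#' @param labels class labels, one per image.
#' @param spec an [extractor_spec()].
#' @return a [feature_matrix()] of dimension `length(images) x embed_dim`.
#' @export
extract_features <- function(images, labels, spec = extractor_spec()) {
  if (length(images) == 0) stop("`images` must be non-empty", call. = FALSE)
  stopifnot(length(labels) == length(images))
  desc <- t(vapply(images, .image_descriptor, numeric(56)))
  proj_seed <- derive_seed(sum(utf8ToInt(spec$name)), spec$embed_dim)
  proj <- with_seed(proj_seed, {
    matrix(stats::rnorm(56 * spec$embed_dim), 56, spec$embed_dim) / sqrt(56)
  })
  vals <- tanh(desc %*% proj)
  feature_matrix(vals, labels,
                 sprintf("%s_%04d", spec$name, seq_len(spec$embed_dim)))
}
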