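# Synthetic data generators: hazy low-contrast lesion-like images built
# with the same forward haze model the enhancement stage inverts, and
# labelled feature tables with known informative / noise / redundant
# structure. Every generator is a pure function of its spec and seed.

# Class palette: lesion chromaticity per class (RGB in [0,1]), distinct
# enough that a toy extractor can separate classes.
.lesion_palette <- function(n_classes) {
  hues <- seq(0, 0.9, length.out = n_classes)
  t(vapply(seq_len(n_classes), function(i) {
    grDevices::col2rgb(grDevices::hsv(hues[i], 0.75, 0.25 + 0.4 * (i %% 3) / 2)) / 255
  }, numeric(3)))
}

#' Generate hazy lesion-like fixture images
#'
#' Draws, per class, elliptical lesion blobs with class-specific color on a
#' light skin-toned background (clean image `J`), then degrades them with
#' the haze forward model `I = J*T + A*(1 - T)` where the transmission is
#' `T = exp(-haze_strength * depth)` over a smooth radial depth field, plus
#' optional Gaussian sensor noise. Returning the clean images, transmission
#' maps and atmospheric light makes dehazing quality directly measurable.
#'
#' @param n_classes number of lesion classes. Default 7.
#' @param per_class images per class. Default 30.
#' @param size `c(H, W)` in pixels. Default `c(64, 64)`.
#' @param haze_strength attenuation coefficient `beta >= 0` of the
#'   synthetic depth field; 0 disables haze. Default 1.
#' @param noise_sigma SD of additive Gaussian sensor noise (applied after
#'   the haze model, then clipped). Default 0.005.
#' @param atmospheric_light scalar or length-3 `A` in `(0, 1]`. Default 1.
#' @param seed integer seed.
#' @return list with `images` (hazy), `labels` (factor `class_1 ...`),
#'   `clean` (ground-truth `J`), `transmission` (list of `T` maps) and
#'   `atmospheric_light`.
#' @export
make_hazy_images <- function(n_classes = 7L, per_class = 30L,
                             size = c(64L, 64L), haze_strength = 1,
                             noise_sigma = 0.005, atmospheric_light = 1,
                             seed = 1L) {
  stopifnot(haze_strength >= 0, n_classes >= 1, per_class >= 1)
  a <- rep(atmospheric_light, length.out = 3)
  stopifnot(all(a > 0), all(a <= 1))
  h <- size[1]; w <- size[2]
  palette <- .lesion_palette(n_classes)
  with_seed(derive_seed(seed, "hazy_images"), {
    n <- n_classes * per_class
    images <- clean <- tmaps <- vector("list", n)
    labels <- character(n)
    idx <- 0
    for (cl in seq_len(n_classes)) {
      for (rep_i in seq_len(per_class)) {
        idx <- idx + 1
        labels[idx] <- sprintf("class_%d", cl)
        # skin-toned background with gentle intensity gradient
        base <- 0.75 + 0.05 * stats::runif(1)
        bg <- c(base, base - 0.12, base - 0.18)
        row_g <- matrix(seq(-0.03, 0.03, length.out = h), h, w)
        j <- array(0, dim = c(h, w, 3))
        for (c in 1:3) j[, , c] <- bg[c] + row_g
        # elliptical lesion blob, class-specific color, smooth edge
        cy <- h / 2 + stats::runif(1, -h / 8, h / 8)
        cx <- w / 2 + stats::runif(1, -w / 8, w / 8)
        ry <- stats::runif(1, h / 6, h / 4)
        rx <- stats::runif(1, w / 6, w / 4)
        yy <- matrix(seq_len(h), h, w)
        xx <- matrix(seq_len(w), h, w, byrow = TRUE)
        dist2 <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2
        blob <- exp(-pmax(dist2 - 1, 0) * 6) * (dist2 < 4)
        blob[dist2 <= 1] <- 1
        col <- palette[cl, ] * stats::runif(1, 0.85, 1.15)
        for (c in 1:3) {
          j[, , c] <- j[, , c] * (1 - blob) + min(col[c], 1) * blob
        }
        j <- clip01(j)
        # smooth radial depth field -> transmission
        depth <- sqrt(((yy - h / 2) / h)^2 + ((xx - w / 2) / w)^2)
        depth <- 1 - depth / max(depth)   # deepest haze at the center
        tmap <- exp(-haze_strength * depth)
        hazy <- array(0, dim = c(h, w, 3))
        for (c in 1:3) {
          hazy[, , c] <- j[, , c] * tmap + a[c] * (1 - tmap)
        }
        if (noise_sigma > 0) {
          hazy <- hazy + array(stats::rnorm(h * w * 3, 0, noise_sigma),
                               dim = dim(hazy))
        }
        images[[idx]] <- clip01(hazy)
        clean[[idx]] <- j
        tmaps[[idx]] <- tmap
      }
    }
    list(images = images, labels = factor(labels), clean = clean,
         transmission = tmaps, atmospheric_light = a)
  })
}

#' Generate a labelled feature table with known structure
#'
#' Informative features are class-conditional Gaussians whose class centers
#' are rescaled so the minimum pairwise center distance equals
#' `class_separation` (in within-class SD units; 0 collapses all centers).
#' Noise features are class-independent standard normals. Redundant
#' features are jittered copies of informative ones, laid out immediately
#' after their source column so that consecutive-pair correlation finds
#' them (`r > 0.9` at the default jitter). The ground-truth column roles
#' are returned for recovery scoring.
#'
#' @param n_samples total rows. Default 200.
#' @param n_classes number of classes (>= 2). Default 7.
#' @param n_informative class-dependent features. Default 5.
#' @param n_noise irrelevant features. Default 40.
#' @param n_redundant jittered duplicates of the first `n_redundant`
#'   informative features (must be `<= n_informative`). Default 5.
#' @param class_separation minimum pairwise class-center distance in SD
#'   units. Default 6.
#' @param jitter_sd SD of the noise added to redundant copies. Default 0.1.
#' @param seed integer seed.
#' @return list with `data` (a [feature_matrix()] of width
#'   `n_informative + n_noise + n_redundant`), `informative_idx`,
#'   `redundant_idx`, `noise_idx` and `redundant_pairs` (2-column matrix of
#'   source/copy column indices).
#' @export
make_feature_dataset <- function(n_samples = 200L, n_classes = 7L,
                                 n_informative = 5L, n_noise = 40L,
                                 n_redundant = 5L, class_separation = 6,
                                 jitter_sd = 0.1, seed = 1L) {
  stopifnot(n_classes >= 2, n_informative >= 1, n_noise >= 0,
            n_redundant >= 0, n_redundant <= n_informative,
            class_separation >= 0)
  with_seed(derive_seed(seed, "feature_dataset"), {
    labels <- factor(sprintf("class_%d",
                             rep_len(seq_len(n_classes), n_samples)))
    centers <- matrix(stats::rnorm(n_classes * n_informative),
                      n_classes, n_informative)
    if (class_separation > 0) {
      dmin <- min(stats::dist(centers))
      centers <- centers * (class_separation / dmin)
    } else {
      centers[] <- 0
    }
    inf_vals <- centers[as.integer(labels), , drop = FALSE] +
      matrix(stats::rnorm(n_samples * n_informative), n_samples)
    noise_vals <- matrix(stats::rnorm(n_samples * n_noise),
                         n_samples, n_noise)
    red_vals <- if (n_redundant > 0) {
      inf_vals[, seq_len(n_redundant), drop = FALSE] +
        matrix(stats::rnorm(n_samples * n_redundant, 0, jitter_sd),
               n_samples, n_redundant)
    } else {
      matrix(0, n_samples, 0)
    }
    # layout: [inf_1, red_1, ..., inf_r, red_r, inf_{r+1}, ..., noise]
    k_total <- n_informative + n_noise + n_redundant
    vals <- matrix(0, n_samples, k_total)
    names_out <- character(k_total)
    informative_idx <- integer(n_informative)
    redundant_idx <- integer(n_redundant)
    pos <- 0
    for (j in seq_len(n_informative)) {
      pos <- pos + 1
      vals[, pos] <- inf_vals[, j]
      names_out[pos] <- sprintf("inf_%02d", j)
      informative_idx[j] <- pos
      if (j <= n_redundant) {
        pos <- pos + 1
        vals[, pos] <- red_vals[, j]
        names_out[pos] <- sprintf("red_%02d", j)
        redundant_idx[j] <- pos
      }
    }
    if (n_noise > 0) {
      noise_idx <- pos + seq_len(n_noise)
      vals[, noise_idx] <- noise_vals
      names_out[noise_idx] <- sprintf("noise_%02d", seq_len(n_noise))
    } else {
      noise_idx <- integer(0)
    }
    list(data = feature_matrix(vals, labels, names_out),
         informative_idx = informative_idx,
         redundant_idx = redundant_idx,
         noise_idx = noise_idx,
         redundant_pairs = cbind(source = informative_idx[seq_len(n_redundant)],
                                 copy = redundant_idx))
  })
}

#' Split one feature matrix into multiple column-contiguous sources
#'
#' Inverse of [serial_fuse()]: cuts the columns into consecutive blocks of
#' the given widths (which must sum to the total width), preserving labels,
#' so `serial_fuse(split_multisource(m, w))` reconstructs `m` exactly.
#'
#' @param mat a [feature_matrix()].
#' @param widths integer vector of block widths summing to `ncol`.
#' @return list of [feature_matrix()] objects.
#' @export
split_multisource <- function(mat, widths) {
  widths <- as.integer(widths)
  if (sum(widths) != ncol(mat$values) || any(widths < 1)) {
    stop("`widths` must be positive and sum to the feature count",
         call. = FALSE)
  }
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(widths), function(i) {
    fm_select(mat, starts[i]:ends[i])
  })
}
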