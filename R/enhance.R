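# Hybrid lesion contrast enhancement: dark-channel-prior haze reduction
# followed by per-channel top-hat / bottom-hat morphological sharpening.
# All neighborhood operations use replicate (edge-clamp) padding.

# Shift a matrix by (dr, dc) with replicate padding via index clamping.
.shift_mat <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Separable square min/max filter of half-width r (window (2r+1)^2).
.window_filter_sq <- function(m, r, op) {
  if (r < 1) return(m)
  out <- m
  for (k in seq_len(r)) {
    out <- op(out, .shift_mat(m, k, 0L), .shift_mat(m, -k, 0L))
  }
  m2 <- out
  for (k in seq_len(r)) {
    out <- op(out, .shift_mat(m2, 0L, k), .shift_mat(m2, 0L, -k))
  }
  out
}

.disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Grayscale erosion (op = pmin) / dilation (op = pmax) with a flat SE.
.morph_gray <- function(m, shape, r, op) {
  if (shape == "square") return(.window_filter_sq(m, r, op))
  off <- .disk_offsets(r)
  out <- m
  for (i in seq_len(nrow(off))) {
    if (off$dr[i] == 0 && off$dc[i] == 0) next
    out <- op(out, .shift_mat(m, off$dr[i], off$dc[i]))
  }
  out
}

.opening <- function(m, shape, r) {
  .morph_gray(.morph_gray(m, shape, r, pmin), shape, r, pmax)
}

.closing <- function(m, shape, r) {
  .morph_gray(.morph_gray(m, shape, r, pmax), shape, r, pmin)
}

#' Haze-reduction parameters
#'
#' Parameters of the dark-channel-prior haze model `I = J*T + A*(1 - T)`,
#' where `I` is the observed image, `J` the scene radiance, `A` the
#' atmospheric light and `T` the per-pixel transmission.
#'
#' @param patch_size odd window size (pixels) of the dark-channel minimum
#'   filter. Default 15.
#' @param omega haze-retention weight in `(0, 1]`; the estimated haze is
#'   only removed up to this fraction so images keep a natural depth cue.
#'   Default 0.95.
#' @param t0 transmission floor in `(0, 1)` guarding the division in the
#'   radiance recovery. Default 0.1.
#' @param light_fraction fraction of the brightest dark-channel pixels used
#'   to estimate the atmospheric light. Default 0.001.
#' @param eps lower floor applied to each component of the estimated
#'   atmospheric light, avoiding division by zero. Default 1e-3.
#' @return an object of class `haze_params`.
#' @export
haze_params <- function(patch_size = 15L, omega = 0.95, t0 = 0.1,
                        light_fraction = 0.001, eps = 1e-3) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L || patch_size %% 2L == 0L) {
    stop("`patch_size` must be an odd integer >= 1", call. = FALSE)
  }
  if (omega <= 0 || omega > 1) stop("`omega` must be in (0, 1]", call. = FALSE)
  if (t0 <= 0 || t0 >= 1) stop("`t0` must be in (0, 1)", call. = FALSE)
  if (light_fraction <= 0) stop("`light_fraction` must be > 0", call. = FALSE)
  structure(list(patch_size = patch_size, omega = omega, t0 = t0,
                 light_fraction = light_fraction, eps = eps),
            class = "haze_params")
}

#' Morphological filtering parameters
#'
#' Structuring element used by [top_hat()], [bottom_hat()] and
#' [enhance_image()].
#'
#' @param se_shape structuring-element shape, `"disk"` or `"square"`.
#' @param se_radius radius in pixels (`NULL` = scale a radius-9 disk on a
#'   256-pixel image proportionally to the shorter image side, minimum 1).
#' @return an object of class `morph_params`.
#' @export
morph_params <- function(se_shape = c("disk", "square"), se_radius = NULL) {
  se_shape <- match.arg(se_shape)
  if (!is.null(se_radius)) {
    se_radius <- as.integer(se_radius)
    if (se_radius < 1L) stop("`se_radius` must be >= 1", call. = FALSE)
  }
  structure(list(se_shape = se_shape, se_radius = se_radius),
            class = "morph_params")
}

.resolve_se_radius <- function(morph, img) {
  morph$se_radius %||% max(1L, as.integer(round(9 * min(dim(img)[1:2]) / 256)))
}

#' Dark channel of an RGB image
#'
#' Per-pixel minimum over the three color channels and over a
#' `patch_size x patch_size` neighborhood (replicate-padded). In haze-free
#' dermoscopy patches at least one channel is near zero, so high dark-channel
#' values flag the additive haze veil.
#'
#' @param img an `H x W x 3` array in `[0, 1]`.
#' @param patch_size odd window size in pixels.
#' @return an `H x W` matrix with values in `[0, 1]`.
#' @export
dark_channel <- function(img, patch_size = 15L) {
  validate_image(img)
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L || patch_size %% 2L == 0L) {
    stop("`patch_size` must be an odd integer >= 1", call. = FALSE)
  }
  chan_min <- pmin(img[, , 1], img[, , 2], img[, , 3])
  .window_filter_sq(chan_min, (patch_size - 1L) %/% 2L, pmin)
}

#' Estimate the atmospheric light of a hazy image
#'
#' Mean color of the image pixels whose dark-channel value lies in the top
#' `light_fraction` quantile; these are the most haze-opaque pixels and so
#' best approximate the global additive light term `A`.
#'
#' @param img an `H x W x 3` array in `[0, 1]`.
#' @param dark the dark channel of `img` (see [dark_channel()]).
#' @param light_fraction fraction of brightest dark-channel pixels to use.
#' @param eps floor applied per component (guards later division).
#' @return a length-3 vector with components in `[eps, 1]`.
#' @export
estimate_atmospheric_light <- function(img, dark, light_fraction = 0.001,
                                       eps = 1e-3) {
  validate_image(img)
  n <- length(dark)
  n_top <- max(1L, ceiling(light_fraction * n))
  idx <- order(dark, decreasing = TRUE)[seq_len(n_top)]
  flat <- matrix(img, nrow = n, ncol = 3)
  a <- colMeans(flat[idx, , drop = FALSE])
  if (!all(is.finite(a))) a <- apply(flat, 2, max)
  pmin(pmax(a, eps), 1)
}

#' Estimate the transmission map
#'
#' `T = 1 - omega * dark_channel(I / A)`, clamped into `[t0, 1]`: the
#' dark-channel prior applied to the atmospheric-light-normalized image,
#' attenuated by `omega` and floored at `t0`.
#'
#' @param img an `H x W x 3` array in `[0, 1]`.
#' @param a length-3 atmospheric light, strictly positive.
#' @param params a [haze_params()] object.
#' @return an `H x W` transmission matrix in `[t0, 1]`.
#' @export
estimate_transmission <- function(img, a, params = haze_params()) {
  validate_image(img)
  stopifnot(length(a) == 3, all(a > 0))
  norm <- array(0, dim = dim(img))
  for (c in 1:3) norm[, , c] <- pmin(img[, , c] / a[c], 1)
  chan_min <- pmin(norm[, , 1], norm[, , 2], norm[, , 3])
  dark <- .window_filter_sq(chan_min, (params$patch_size - 1L) %/% 2L, pmin)
  pmin(pmax(1 - params$omega * dark, params$t0), 1)
}

#' Recover scene radiance from a hazy image
#'
#' Inverts the haze model: `J = (I - A) / max(T, t0) + A`, clipped to
#' `[0, 1]` per channel. With the true `A` and `T` (all above `t0`) this is
#' the exact algebraic inverse of `I = J*T + A*(1 - T)`.
#'
#' @param img an `H x W x 3` hazy image in `[0, 1]`.
#' @param a length-3 atmospheric light.
#' @param tmap `H x W` transmission map.
#' @param t0 transmission floor for the division.
#' @return an `H x W x 3` dehazed image in `[0, 1]`.
#' @export
recover_radiance <- function(img, a, tmap, t0 = 0.1) {
  validate_image(img)
  stopifnot(length(a) == 3, all(dim(tmap) == dim(img)[1:2]))
  div <- pmax(tmap, t0)
  out <- array(0, dim = dim(img))
  for (c in 1:3) out[, , c] <- (img[, , c] - a[c]) / div + a[c]
  clip01(out)
}

#' Top-hat transform (bright small-scale structures)
#'
#' `img - opening(img, s)` per channel with flat structuring element `s`:
#' extracts bright details smaller than the element. Non-negative; zero on
#' constant images.
#'
#' @param img an `H x W x 3` array in `[0, 1]`.
#' @param morph a [morph_params()] object.
#' @return an `H x W x 3` array of non-negative residuals.
#' @export
top_hat <- function(img, morph = morph_params()) {
  validate_image(img)
  r <- .resolve_se_radius(morph, img)
  out <- array(0, dim = dim(img))
  for (c in 1:3) {
    out[, , c] <- img[, , c] - .opening(img[, , c], morph$se_shape, r)
  }
  pmax(out, 0)
}

#' Bottom-hat transform (dark small-scale structures)
#'
#' `closing(img, s) - img` per channel: extracts dark details smaller than
#' the structuring element. Non-negative; zero on constant images.
#'
#' @inheritParams top_hat
#' @return an `H x W x 3` array of non-negative residuals.
#' @export
bottom_hat <- function(img, morph = morph_params()) {
  validate_image(img)
  r <- .resolve_se_radius(morph, img)
  out <- array(0, dim = dim(img))
  for (c in 1:3) {
    out[, , c] <- .closing(img[, , c], morph$se_shape, r) - img[, , c]
  }
  pmax(out, 0)
}

#' Hybrid contrast enhancement of a lesion image
#'
#' Two-stage enhancement: (1) dark-channel-prior haze reduction (estimate
#' atmospheric light and transmission, recover radiance), then (2)
#' morphological contrast boost `F = J + top_hat(J) - bottom_hat(J)`,
#' clipped to `[0, 1]`. Stage 2 brightens small bright structures and
#' darkens small dark ones, raising local and global contrast around the
#' lesion.
#'
#' @param img an `H x W x 3` array in `[0, 1]`.
#' @param haze a [haze_params()] object.
#' @param morph a [morph_params()] object.
#' @return the enhanced `H x W x 3` image in `[0, 1]`.
#' @export
enhance_image <- function(img, haze = haze_params(), morph = morph_params()) {
  validate_image(img)
  dark <- dark_channel(img, haze$patch_size)
  a <- estimate_atmospheric_light(img, dark, haze$light_fraction, haze$eps)
  tmap <- estimate_transmission(img, a, haze)
  j <- recover_radiance(img, a, tmap, haze$t0)
  clip01(j + top_hat(j, morph) - bottom_hat(j, morph))
}
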