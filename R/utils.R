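#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps every stochastic routine reproducible without clobbering the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, staying inside
# the 32-bit integer range. Distinct labels give distinct, stable streams.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak signal-to-noise ratio between two images
#'
#' PSNR in decibels for intensities on \code{[0, 1]} (peak value 1). Used to
#' quantify how closely a dehazed image restores a known clean reference.
#'
#' @param x,y numeric arrays of identical dimensions with values in `[0, 1]`.
#' @return PSNR in dB; `Inf` when the images are identical.
#' @export
psnr <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}

#' Root-mean-square contrast of an image
#'
#' Standard deviation of the grayscale intensities (channel mean for RGB
#' input), a simple global contrast measure.
#'
#' @param img an image array (`H x W` or `H x W x 3`) with values in `[0, 1]`.
#' @return non-negative scalar.
#' @export
rms_contrast <- function(img) {
  g <- if (length(dim(img)) == 3) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
  stats::sd(as.vector(g))
}
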