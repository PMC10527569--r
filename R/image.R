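# Images are plain numeric arrays H x W x 3 with intensities in [0, 1].
# 8-bit quantization happens only at the file boundary (PNG read/write).

validate_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite intensities", arg), call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 1) {
    stop(sprintf("`%s` intensities must lie in [0, 1]", arg), call. = FALSE)
  }
  invisible(img)
}

#' Read a lesion image from a PNG file
#'
#' Reads an RGB (or grayscale, expanded to RGB) PNG into the `H x W x 3`
#' array-in-`[0,1]` representation used throughout the package. Any alpha
#' channel is dropped.
#'
#' @param path path to a PNG file.
#' @return an `H x W x 3` numeric array with values in `[0, 1]`.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) {
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  } else if (dim(px)[3] == 4) {
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3] == 2) {
    px <- array(rep(px[, , 1], 3), dim = c(dim(px)[1:2], 3))
  }
  validate_image(px, "path")
}

#' Write a lesion image to a PNG file
#'
#' @param img an `H x W x 3` array with values in `[0, 1]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  validate_image(img)
  png::writePNG(img, path)
  invisible(path)
}

#' Flip an image left-right or up-down
#'
#' @param img an `H x W x 3` image array.
#' @param direction `"lr"` mirrors columns, `"ud"` mirrors rows.
#' @return the flipped image.
#' @export
flip_image <- function(img, direction = c("lr", "ud")) {
  direction <- match.arg(direction)
  if (direction == "lr") {
    img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  } else {
    img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  }
}
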