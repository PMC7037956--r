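#' Grayscale intensity image with declared bit depth
#'
#' Wraps a matrix of integer pixel intensities together with its effective
#' bit depth \eqn{n} (so all values lie in \eqn{[0, 2^n - 1]}). Medical
#' images are often stored in 16-bit containers with fewer effective bits
#' (e.g. 13-bit MRI); the declared depth, not the container, determines the
#' intensity binning used everywhere in this package.
#'
#' @param pixels Numeric matrix of integer-valued intensities.
#' @param bit_depth Integer in 1..16.
#' @return An \code{intensity_image}: the pixel matrix with class and a
#'   \code{bit_depth} attribute.
#' @examples
#' img <- intensity_image(matrix(0:15, 4, 4), bit_depth = 4)
#' @export
intensity_image <- function(pixels, bit_depth) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels != floor(pixels))) {
    stop("`pixels` must be integer-valued without NAs", call. = FALSE)
  }
  if (length(bit_depth) != 1L || bit_depth < 1 || bit_depth > 16 ||
      bit_depth != floor(bit_depth)) {
    stop("`bit_depth` must be a single integer in 1..16", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L ||
      nrow(pixels) > 4096L || ncol(pixels) > 4096L) {
    stop("image dimensions must be between 1x1 and 4096x4096", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1)) {
    stop(sprintf("pixel values must lie in [0, %d] for bit depth %d",
                 2^bit_depth - 1, bit_depth), call. = FALSE)
  }
  structure(pixels, bit_depth = as.integer(bit_depth),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d, bit depth %d, range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              min(x), max(x)))
  invisible(x)
}

# Extract the plain pixel matrix and bit depth from an intensity_image (or
# accept a bare matrix with an explicit depth).
.img_pixels <- function(image) {
  if (!inherits(image, "intensity_image")) {
    stop("expected an `intensity_image`; see intensity_image()",
         call. = FALSE)
  }
  matrix(as.numeric(image), nrow(image), ncol(image))
}

.img_depth <- function(image) {
  n <- attr(image, "bit_depth")
  if (is.null(n)) stop("image has no bit depth", call. = FALSE)
  as.integer(n)
}
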