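# Patch extraction, spatial weighting, and estimation of patch intensity
# distributions by weighted histogram or Parzen-window smoothing.

# Reflect 1-based indices into [1, n] by mirror reflection with edge
# duplication (... 2 1 | 1 2 ... n-1 n | n n-1 ...). Valid for offsets up to
# n, which bounds the usable pad at n.
.reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

# Pad a matrix by k rows/cols on each side using mirror reflection.
.mirror_pad <- function(mat, k) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  if (k == 0L) return(mat)
  if (k > nr || k > nc) {
    stop("mirror pad ", k, " exceeds image size ", nr, "x", nc,
         call. = FALSE)
  }
  ri <- .reflect_index(seq.int(1L - k, nr + k), nr)
  ci <- .reflect_index(seq.int(1L - k, nc + k), nc)
  mat[ri, ci, drop = FALSE]
}

#' Extract a square patch around a pixel
#'
#' Returns the \eqn{l \times l} neighbourhood centred at a pixel.
#' Out-of-bounds samples are filled by mirror reflection (edge-inclusive),
#' so no intensity values absent from the image are introduced.
#'
#' @param image An \code{\link{intensity_image}}.
#' @param x Centre as \code{c(row, col)}, 1-based, inside the image.
#' @param l Odd patch side length, \eqn{l \ge 1}.
#' @return An \eqn{l \times l} numeric matrix of intensities.
#' @export
extract_patch <- function(image, x, l) {
  px <- .img_pixels(image)
  .check_side_length(l)
  if (length(x) != 2L || x[1] < 1 || x[1] > nrow(px) ||
      x[2] < 1 || x[2] > ncol(px)) {
    stop("patch centre (", paste(x, collapse = ", "),
         ") outside image bounds", call. = FALSE)
  }
  k <- (l - 1L) %/% 2L
  ri <- .reflect_index(seq.int(x[1] - k, x[1] + k), nrow(px))
  ci <- .reflect_index(seq.int(x[2] - k, x[2] + k), ncol(px))
  px[ri, ci, drop = FALSE]
}

.check_side_length <- function(l) {
  if (length(l) != 1L || l < 1 || l != floor(l) || l %% 2 == 0) {
    stop("patch side length `l` must be a positive odd integer", call. = FALSE)
  }
  invisible(as.integer(l))
}

.new_weight_map <- function(w, kind) {
  k <- (nrow(w) - 1L) %/% 2L
  structure(list(w = w, centre = c(k + 1L, k + 1L), kind = kind),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<weight_map> %s, %d x %d, centre weight %.4g\n",
              x$kind, nrow(x$w), ncol(x$w), x$w[x$centre[1], x$centre[2]]))
  invisible(x)
}

#' Uniform spatial weight map
#'
#' @param l Odd patch side length.
#' @return A \code{weight_map} with every entry \eqn{1/l^2}.
#' @export
uniform_weight_map <- function(l) {
  l <- .check_side_length(l)
  .new_weight_map(matrix(1 / l^2, l, l), "uniform")
}

#' Gaussian spatial weight map
#'
#' Isotropic Gaussian weights \eqn{\omega(y) = G_\sigma(y - c)} centred on
#' the patch centre, normalized to sum 1. Point-symmetric about the centre
#' with its strict maximum there.
#'
#' @param l Odd patch side length.
#' @param sigma Gaussian spread in pixels, \eqn{\sigma > 0}.
#' @return A \code{weight_map}.
#' @examples
#' w <- gaussian_weight_map(3, 1)
#' w$w[1, 1] / w$w[2, 2]  # exp(-1): corner vs centre
#' @export
gaussian_weight_map <- function(l, sigma) {
  l <- .check_side_length(l)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  d <- seq.int(-(l - 1L) %/% 2L, (l - 1L) %/% 2L)
  w <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  .new_weight_map(w / sum(w), "gaussian")
}

#' Centre-dominant modified weight map
#'
#' A convex combination of a normalized Gaussian map and a point mass at the
#' patch centre: \eqn{(1-\alpha) G_\sigma + \alpha \delta_c}. Relative to
#' the plain Gaussian map it concentrates extra weight on the centre pixel,
#' making the weighted histogram more sensitive to where intensities sit
#' relative to the patch centre.
#'
#' @inheritParams gaussian_weight_map
#' @param alpha Centre mass fraction in \eqn{[0, 1)}; \code{alpha = 0}
#'   reduces to \code{\link{gaussian_weight_map}}. Default 0.5.
#' @return A \code{weight_map}.
#' @export
modified_weight_map <- function(l, sigma, alpha = 0.5) {
  if (length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop("`alpha` must lie in [0, 1)", call. = FALSE)
  }
  g <- gaussian_weight_map(l, sigma)
  w <- (1 - alpha) * g$w
  w[g$centre[1], g$centre[2]] <- w[g$centre[1], g$centre[2]] + alpha
  m <- .new_weight_map(w, "modified")
  m
}

.weights_matrix <- function(weights, l) {
  w <- if (inherits(weights, "weight_map")) weights$w else weights
  if (!is.matrix(w) || !is.numeric(w)) {
    stop("`weights` must be a weight_map or a numeric matrix", call. = FALSE)
  }
  if (!missing(l) && (nrow(w) != l || ncol(w) != l)) {
    stop(sprintf("weight map is %dx%d but patch is %dx%d",
                 nrow(w), ncol(w), l, l), call. = FALSE)
  }
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  w
}

# Map integer intensities to 1-based bin indices: floor(v * bins / 2^n) + 1.
.bin_index <- function(v, bins, n) {
  floor(v * bins / 2^n) + 1L
}

#' Weighted patch intensity histogram
#'
#' Bins each patch intensity \eqn{v} into bin
#' \eqn{\lfloor v \cdot bins / 2^n \rfloor}, accumulating the spatial weight
#' \eqn{\omega(y)} of each patch location into its bin, then normalizes to a
#' probability vector.
#'
#' @param patch Numeric matrix of integer intensities (an extracted patch).
#' @param weights A \code{weight_map} or numeric matrix of the same shape.
#' @param bins Number of histogram bins, \eqn{2 \le bins \le 2^n}.
#' @param n Bit depth of the source image.
#' @return Probability vector of length \code{bins} summing to 1.
#' @examples
#' weighted_histogram(matrix(c(0, 0, 1, 1), 2), matrix(c(1, 1, 1, 3), 2),
#'                    bins = 2, n = 1)  # (1/3, 2/3)
#' @export
weighted_histogram <- function(patch, weights, bins, n) {
  if (!is.matrix(patch) || !is.numeric(patch)) {
    stop("`patch` must be a numeric matrix", call. = FALSE)
  }
  w <- .weights_matrix(weights)
  if (!identical(dim(w), dim(patch))) {
    stop(sprintf("weight map is %dx%d but patch is %dx%d",
                 nrow(w), ncol(w), nrow(patch), ncol(patch)), call. = FALSE)
  }
  .check_bins(bins, n)
  if (any(patch < 0) || any(patch > 2^n - 1)) {
    stop("patch intensities outside [0, 2^n - 1]", call. = FALSE)
  }
  b <- .bin_index(as.vector(patch), bins, n)
  h <- vapply(split(as.vector(w), factor(b, levels = seq_len(bins))),
              sum, numeric(1))
  unname(h / sum(h))
}

.check_bins <- function(bins, n) {
  if (length(bins) != 1L || bins < 2 || bins != floor(bins)) {
    stop("`bins` must be an integer >= 2", call. = FALSE)
  }
  if (bins > 2^n) {
    stop(sprintf("bins (%d) exceeds the number of intensity levels 2^%d",
                 bins, n), call. = FALSE)
  }
  invisible(as.integer(bins))
}

# Parzen smoothing kernel over histogram bins: column-stochastic matrix K
# with K[a, b] = mass moved from bin b to bin a by a discrete Gaussian of
# standard deviation `bandwidth` bins, reflected at the bin edges. The
# reflection makes K doubly stochastic (symmetric heat kernel on the
# interval), so smoothing never decreases entropy.
.parzen_kernel <- function(bins, bandwidth) {
  if (length(bandwidth) != 1L || !is.finite(bandwidth) || bandwidth <= 0) {
    stop("`bandwidth` must be a positive number", call. = FALSE)
  }
  R <- max(1L, min(as.integer(ceiling(4 * bandwidth)), bins - 1L))
  g <- stats::dnorm(seq.int(-R, R), sd = bandwidth)
  g <- g / sum(g)
  K <- matrix(0, bins, bins)
  for (b in seq_len(bins)) {
    t <- .reflect_index(seq.int(b - R, b + R), bins)
    for (j in seq_along(t)) K[t[j], b] <- K[t[j], b] + g[j]
  }
  K
}

#' Parzen-window estimate of a patch intensity distribution
#'
#' The weighted histogram smoothed along the bin axis by a discrete Gaussian
#' kernel of standard deviation \code{bandwidth} bins (reflected at the bin
#' edges) and renormalized. Smoothing spreads mass to neighbouring bins so
#' the estimate is strictly positive wherever the raw histogram has mass
#' within a few bandwidths.
#'
#' @inheritParams weighted_histogram
#' @param bandwidth Kernel standard deviation in bins, \eqn{> 0}.
#' @return Probability vector of length \code{bins} summing to 1.
#' @export
parzen_estimate <- function(patch, weights, bins, n, bandwidth = 1) {
  h <- weighted_histogram(patch, weights, bins, n)
  K <- .parzen_kernel(bins, bandwidth)
  p <- as.vector(K %*% h)
  p / sum(p)
}
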