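# Per-pixel descriptor images: every pixel of the source image is replaced
# by the uncertainty of its local patch intensity distribution under one of
# the four core functions. The descriptor image is the common "third
# modality" into which images of different contrast mechanisms are mapped.

#' Patch descriptor configuration
#'
#' Bundles the parameters controlling how patch intensity distributions are
#' estimated: patch size, histogram bins, spatial weighting, and estimator.
#'
#' @param l Odd patch side length in pixels (default 7).
#' @param bins Number of histogram bins. \code{NULL} (default) resolves per
#'   image to \eqn{\min(l^2, 2^n, 256)}: the number of distinct levels a
#'   patch can realize, capped for tractability. Pass an explicit value
#'   (e.g. \code{2^n}) to override the cap.
#' @param weighting Spatial weighting of patch locations: \code{"uniform"},
#'   \code{"gaussian"}, or \code{"modified"} (centre-dominant Gaussian).
#' @param sigma Gaussian spread in pixels; \code{NULL} defaults to
#'   \eqn{l/4}, keeping \eqn{\pm 2\sigma} inside the patch.
#' @param alpha Centre mass fraction for \code{"modified"} weighting.
#' @param estimator \code{"histogram"} (raw weighted histogram) or
#'   \code{"parzen"} (histogram smoothed along the bin axis).
#' @param bandwidth Parzen kernel standard deviation in bins.
#' @return A \code{patch_spec} object.
#' @examples
#' patch_spec(l = 15, weighting = "modified", estimator = "parzen")
#' @export
patch_spec <- function(l = 7, bins = NULL,
                       weighting = c("uniform", "gaussian", "modified"),
                       sigma = NULL, alpha = 0.5,
                       estimator = c("histogram", "parzen"),
                       bandwidth = 1) {
  l <- .check_side_length(l)
  weighting <- match.arg(weighting)
  estimator <- match.arg(estimator)
  if (!is.null(bins)) {
    if (length(bins) != 1L || bins < 2 || bins != floor(bins)) {
      stop("`bins` must be an integer >= 2 or NULL", call. = FALSE)
    }
    bins <- as.integer(bins)
  }
  structure(list(l = l, bins = bins, weighting = weighting, sigma = sigma,
                 alpha = alpha, estimator = estimator, bandwidth = bandwidth),
            class = "patch_spec")
}

#' @export
print.patch_spec <- function(x, ...) {
  cat(sprintf("<patch_spec> l=%d, bins=%s, weighting=%s, estimator=%s\n",
              x$l, if (is.null(x$bins)) "auto" else x$bins,
              x$weighting, x$estimator))
  invisible(x)
}

# Fill in per-image defaults: bins = min(l^2, 2^n, 256), sigma = l / 4.
.resolve_spec <- function(spec, n) {
  if (!inherits(spec, "patch_spec")) {
    stop("`spec` must be a patch_spec", call. = FALSE)
  }
  if (is.null(spec$bins)) spec$bins <- as.integer(min(spec$l^2, 2^n, 256))
  if (is.null(spec$sigma)) spec$sigma <- spec$l / 4
  if (spec$bins > 2^n) {
    stop(sprintf("spec has %d bins but the image has only 2^%d levels",
                 spec$bins, n), call. = FALSE)
  }
  spec
}

.spec_weight_map <- function(spec) {
  switch(spec$weighting,
    uniform = uniform_weight_map(spec$l),
    gaussian = gaussian_weight_map(spec$l, spec$sigma),
    modified = modified_weight_map(spec$l, spec$sigma, spec$alpha)
  )
}

#' Variety degree of a patch
#'
#' The maximum number of distinguishable intensity levels a patch can
#' realize: \eqn{r = \min(l^2, 2^n, bins)}. It caps the uncertainty measure
#' of every patch at \code{\link{upper_bound}(kind, r)}.
#'
#' @param l Patch side length.
#' @param n Image bit depth (1..16).
#' @param bins Histogram bin count; \code{Inf} when binning is not limiting.
#' @return Integer variety degree.
#' @examples
#' variety_degree(7, 13)        # 49: small patch limits
#' variety_degree(65, 8)        # 256: bit depth limits
#' @export
variety_degree <- function(l, n, bins = Inf) {
  if (l < 1 || n < 1 || n > 16) {
    stop("need l >= 1 and bit depth n in 1..16", call. = FALSE)
  }
  as.integer(min(l^2, 2^n, bins))
}

# --- dense / sliding histogram engines --------------------------------------

# 2-D cumulative sum.
.cumsum2 <- function(m) {
  m <- apply(m, 2, cumsum)
  t(apply(m, 1, cumsum))
}

# Sums of all l x l windows of `padmat`; output is (nrow-l+1) x (ncol-l+1).
.box_sum <- function(padmat, l) {
  C <- .cumsum2(padmat)
  C <- rbind(0, cbind(0, C))
  nr <- nrow(padmat) - l + 1L
  nc <- ncol(padmat) - l + 1L
  i <- seq_len(nr)
  j <- seq_len(nc)
  C[i + l, j + l, drop = FALSE] - C[i, j + l, drop = FALSE] -
    C[i + l, j, drop = FALSE] + C[i, j, drop = FALSE]
}

# Dense per-pixel weighted histograms: npix x bins matrix (row order =
# column-major pixel order of the image).
.dense_histograms <- function(Bp, l, bins, w, nr, nc) {
  npix <- nr * nc
  uniform <- all(w == w[1])
  if (uniform && bins < l^2) {
    # per-bin box filter: O(bins * npix), exact integer counts
    H <- matrix(0, npix, bins)
    for (b in seq_len(bins)) {
      H[, b] <- as.vector(.box_sum((Bp == b) * 1, l)) * w[1]
    }
  } else {
    # offset accumulation: O(l^2 * npix), any weight map
    H <- matrix(0, npix, bins)
    pix <- seq_len(npix)
    for (i in seq_len(l)) {
      for (j in seq_len(l)) {
        sub <- Bp[i:(i + nr - 1L), j:(j + nc - 1L)]
        idx <- (as.vector(sub) - 1L) * npix + pix
        H[idx] <- H[idx] + w[i, j]
      }
    }
  }
  H
}

# Sliding-window engine for uniform weights + raw histogram with large bin
# counts: maintains the window's integer bin counts incrementally and
# updates the measure through a lookup table of f(c / l^2), so the cost is
# O(npix * l) regardless of `bins`.
.sliding_measures <- function(Bp, l, bins, kinds, nr, nc) {
  tbls <- lapply(kinds, function(kind) .core_fun(kind)((0:(l^2)) / l^2))
  names(tbls) <- kinds
  nk <- length(tbls)
  out <- lapply(tbls, function(.) matrix(0, nr, nc))
  for (i in seq_len(nr)) {
    rows <- i:(i + l - 1L)
    counts <- tabulate(Bp[rows, seq_len(l)], nbins = bins)
    occ <- which(counts > 0L)
    cur <- vapply(tbls, function(tb) sum(tb[counts[occ] + 1L]), 0)
    for (m in seq_len(nk)) out[[m]][i, 1L] <- cur[m]
    if (nc > 1L) {
      for (j in 2:nc) {
        outv <- Bp[rows, j - 1L]
        inv <- Bp[rows, j + l - 1L]
        u <- unique(c(outv, inv))
        net <- tabulate(match(inv, u), length(u)) -
          tabulate(match(outv, u), length(u))
        old <- counts[u]
        new <- old + net
        counts[u] <- new
        for (m in seq_len(nk)) {
          tb <- tbls[[m]]
          cur[m] <- cur[m] + sum(tb[new + 1L]) - sum(tb[old + 1L])
          out[[m]][i, j] <- cur[m]
        }
      }
    }
  }
  out
}

# Compute descriptor value matrices for several kinds at once, sharing the
# patch histogram work. Returns a named list of nr x nc matrices.
.compute_descriptors <- function(image, spec, kinds) {
  px <- .img_pixels(image)
  n <- .img_depth(image)
  spec <- .resolve_spec(spec, n)
  l <- spec$l
  nr <- nrow(px)
  nc <- ncol(px)
  if (l > min(nr, nc)) {
    stop(sprintf("patch side %d exceeds image size %dx%d", l, nr, nc),
         call. = FALSE)
  }
  kinds <- vapply(kinds, .match_kind, "")
  k <- (l - 1L) %/% 2L
  B <- matrix(.bin_index(px, spec$bins, n), nr, nc)
  Bp <- .mirror_pad(B, k)
  uniform_hist <- spec$weighting == "uniform" && spec$estimator == "histogram"
  npix <- nr * nc
  if (uniform_hist && (as.double(npix) * spec$bins > 2^23 ||
                       spec$bins > 1024L)) {
    return(.sliding_measures(Bp, l, spec$bins, kinds, nr, nc))
  }
  if (as.double(npix) * spec$bins > 2^24) {
    stop("image x bins combination too large for weighted/Parzen ",
         "estimation; reduce `bins` or the image size", call. = FALSE)
  }
  w <- .weights_matrix(.spec_weight_map(spec), l)
  H <- .dense_histograms(Bp, l, spec$bins, w, nr, nc)
  P <- H / rowSums(H)
  if (spec$estimator == "parzen") {
    K <- .parzen_kernel(spec$bins, spec$bandwidth)
    P <- P %*% t(K)
    P <- P / rowSums(P)
  }
  out <- lapply(kinds, function(kind) {
    matrix(rowSums(.core_fun(kind)(P)), nr, nc)
  })
  names(out) <- kinds
  out
}

#' Compute a descriptor image
#'
#' Replaces every pixel \eqn{x} of the image by the uncertainty
#' \eqn{D_{x,l} = M_{kind}(N_{x,l})} of its \eqn{l \times l} patch intensity
#' distribution, estimated per \code{spec}. Mirror padding at the borders
#' keeps the output the same size as the input. Values lie in
#' \eqn{[0, B_{kind}(r)]} with \eqn{r = \min(l^2, 2^n, bins)}.
#'
#' @param image An \code{\link{intensity_image}}.
#' @param spec A \code{\link{patch_spec}}.
#' @param kind Core function kind; see \link{core_kinds}.
#' @return A \code{descriptor_image}: list with \code{values} (numeric
#'   matrix), \code{kind}, resolved \code{spec}, variety degree \code{r},
#'   and source \code{bit_depth}.
#' @examples
#' img <- intensity_image(matrix(sample(0:255, 64, TRUE), 8, 8), 8)
#' d <- compute_descriptor_image(img, patch_spec(l = 3), "m2")
#' range(d$values)
#' @export
compute_descriptor_image <- function(image, spec = patch_spec(),
                                     kind = "m2") {
  kind <- .match_kind(kind)
  vals <- .compute_descriptors(image, spec, kind)[[kind]]
  n <- .img_depth(image)
  rspec <- .resolve_spec(spec, n)
  structure(list(values = vals, kind = kind, spec = rspec,
                 r = variety_degree(rspec$l, n, rspec$bins),
                 bit_depth = n, normalized = "none"),
            class = "descriptor_image")
}

#' @export
print.descriptor_image <- function(x, ...) {
  cat(sprintf(
    "<descriptor_image> %s, %d x %d, l=%d, bins=%d, r=%d, range [%.4g, %.4g]\n",
    x$kind, nrow(x$values), ncol(x$values), x$spec$l, x$spec$bins, x$r,
    min(x$values), max(x$values)))
  invisible(x)
}

#' Compress the effective bit depth of an image
#'
#' Integer-divides intensities by \eqn{2^{n - n_{target}}}, emulating
#' storage at a lower effective bit depth (e.g. compressing 13-bit MRI
#' intensities to 1/64 of their range gives 7 effective bits). Reduces the
#' variety degree and hence the descriptor value range.
#'
#' @param image An \code{\link{intensity_image}} of bit depth \eqn{n}.
#' @param n_target Target bit depth, \eqn{1 \le n_{target} \le n}.
#' @return An \code{intensity_image} of bit depth \code{n_target}.
#' @examples
#' img <- intensity_image(matrix(8191, 1, 1), 13)
#' compress_bit_depth(img, 7)  # pixel 8191 -> 127
#' @export
compress_bit_depth <- function(image, n_target) {
  px <- .img_pixels(image)
  n <- .img_depth(image)
  if (length(n_target) != 1L || n_target < 1 || n_target > n ||
      n_target != floor(n_target)) {
    stop(sprintf("`n_target` must be an integer in 1..%d", n), call. = FALSE)
  }
  intensity_image(floor(px / 2^(n - n_target)), n_target)
}

#' Normalize a descriptor image
#'
#' @param desc A \code{descriptor_image}.
#' @param mode \code{"none"} (identity), \code{"global_minmax"} (affine map
#'   of values onto \eqn{[0, 1]}; a constant image maps to all zeros), or
#'   \code{"local_zscore"} (per-pixel \eqn{(D - \mu_w)/(\sigma_w +
#'   10^{-8})} over a sliding window, mirror-padded).
#' @param window Odd window side for \code{"local_zscore"}, \eqn{\ge 3}.
#' @return A \code{descriptor_image} with normalized values; the
#'   \code{normalized} field records the mode applied.
#' @export
normalize_descriptor <- function(desc,
                                 mode = c("none", "global_minmax",
                                          "local_zscore"),
                                 window = 7) {
  if (!inherits(desc, "descriptor_image")) {
    stop("`desc` must be a descriptor_image", call. = FALSE)
  }
  mode <- match.arg(mode)
  v <- desc$values
  if (mode == "none") return(desc)
  if (mode == "global_minmax") {
    rng <- range(v)
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  } else {
    if (length(window) != 1L || window < 3 || window %% 2 == 0 ||
        window != floor(window)) {
      stop("`window` must be an odd integer >= 3", call. = FALSE)
    }
    if (window > min(dim(v))) {
      stop("`window` exceeds the descriptor image size", call. = FALSE)
    }
    k <- (window - 1L) %/% 2L
    vp <- .mirror_pad(v, k)
    m <- .box_sum(vp, window) / window^2
    m2 <- .box_sum(vp^2, window) / window^2
    s <- sqrt(pmax(m2 - m^2, 0))
    v <- (v - m) / (s + 1e-8)
  }
  desc$values <- v
  desc$normalized <- mode
  desc
}
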