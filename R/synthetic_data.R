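# Synthetic multimodal phantoms: shared anatomy rendered through
# modality-specific intensity look-up tables with Gaussian noise and a
# smooth multiplicative intensity-nonuniformity (INU) field, emulating the
# statistics of simulated brain MRI (3% noise, 20% INU, three contrast
# mappings of one anatomy) without downloading any data.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (length(seed) != 1L || !is.finite(seed) || abs(seed) >= 2^31) {
    stop("`seed` must be a single integer below 2^31", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Separable Gaussian blur with mirror-padded borders.
.gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- min(k, nrow(mat), ncol(mat))
  g <- stats::dnorm(seq.int(-k, k), sd = sigma)
  g <- g / sum(g)
  band <- function(n) {
    A <- matrix(0, n, n + 2L * k)
    for (i in seq_len(n)) A[i, i:(i + 2L * k)] <- g
    A
  }
  p <- .mirror_pad(mat, k)
  band(nrow(mat)) %*% p %*% t(band(ncol(mat)))
}

#' Generate a synthetic tissue label volume
#'
#' Builds a stack of 2-D tissue label maps emulating simulated brain
#' anatomy: an elliptical "head" whose interior is divided into
#' \code{n_tissues - 1} nested, noise-perturbed bands of equal area (label 1
#' is background). The perturbation noise is correlated across slices and
#' the ellipse axes drift slowly, so adjacent slices are similar but never
#' identical. Deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param n_slices Number of slices, \eqn{\ge 1}.
#' @param rows,cols Slice dimensions, \eqn{\ge 16}.
#' @param n_tissues Number of labels including background, \eqn{\ge 3}.
#' @return Integer array of dimension \code{c(n_slices, rows, cols)} with
#'   values in \code{1:n_tissues}.
#' @examples
#' lab <- make_label_volume(1, 3, 32, 32)
#' table(lab[1, , ])
#' @export
make_label_volume <- function(seed, n_slices = 1, rows = 128, cols = 128,
                              n_tissues = 5) {
  if (n_slices < 1 || rows < 16 || cols < 16) {
    stop("need n_slices >= 1 and rows, cols >= 16", call. = FALSE)
  }
  if (n_tissues < 3) stop("need at least 3 tissues", call. = FALSE)
  .with_seed(seed, {
    out <- array(1L, dim = c(n_slices, rows, cols))
    rc <- (rows + 1) / 2
    cc <- (cols + 1) / 2
    rowg <- matrix(seq_len(rows), rows, cols)
    colg <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    rho <- 0.85  # slice-to-slice noise correlation
    f <- NULL
    for (s in seq_len(n_slices)) {
      e <- .gauss_smooth(matrix(stats::rnorm(rows * cols), rows, cols),
                         sigma = max(2, rows / 16))
      e <- e / stats::sd(e)
      f <- if (is.null(f)) e else rho * f + sqrt(1 - rho^2) * e
      t <- if (n_slices > 1) (s - 1) / (n_slices - 1) else 0
      ax <- 0.42 * cols * (1 + 0.08 * sin(2 * pi * t))
      ay <- 0.45 * rows * (1 + 0.08 * cos(2 * pi * t))
      u <- sqrt(((colg - cc) / ax)^2 + ((rowg - rc) / ay)^2)
      inside <- u <= 1
      field <- u + 0.22 * f
      q <- stats::quantile(field[inside],
                           probs = seq(0, 1, length.out = n_tissues))
      q[1] <- -Inf
      q[n_tissues] <- Inf
      lab <- matrix(1L, rows, cols)
      lab[inside] <- 1L + findInterval(field[inside], q,
                                       rightmost.closed = TRUE)
      out[s, , ] <- pmin(lab, n_tissues)
    }
    attr(out, "seed") <- seed
    out
  })
}

#' Render a modality from tissue labels
#'
#' Maps each tissue label to a mean intensity, multiplies by a smooth
#' intensity-nonuniformity bias field of amplitude \code{inu_pct} percent,
#' adds zero-mean Gaussian noise with standard deviation \code{noise_pct}
#' percent of the intensity range, and clips/rounds to the declared bit
#' depth: \eqn{v = \mathrm{clip}(\mathrm{round}(lut[label] \cdot bias(x) +
#' \epsilon), 0, 2^n - 1)}. Deterministic for a fixed seed.
#'
#' @param labels Label matrix or array from \code{\link{make_label_volume}}.
#' @param lut Numeric vector mapping label \eqn{k} to mean intensity
#'   \code{lut[k]} (intensity units of the target bit depth); must cover all
#'   labels present.
#' @param noise_pct Noise standard deviation as percent of \eqn{2^n - 1}.
#' @param inu_pct Bias field amplitude in percent (the field spans
#'   \eqn{1 \pm inu\_pct/100}).
#' @param n Bit depth of the rendered image.
#' @param seed Integer RNG seed.
#' @return An \code{\link{intensity_image}} for a label matrix, or a list of
#'   them (one per slice) for a label array.
#' @export
render_modality <- function(labels, lut, noise_pct = 3, inu_pct = 20,
                            n = 13, seed = 0) {
  if (noise_pct < 0 || noise_pct > 100 || inu_pct < 0 || inu_pct > 100) {
    stop("`noise_pct` and `inu_pct` must lie in [0, 100]", call. = FALSE)
  }
  slices <- if (is.matrix(labels)) list(labels) else {
    lapply(seq_len(dim(labels)[1]), function(s) {
      matrix(labels[s, , ], dim(labels)[2], dim(labels)[3])
    })
  }
  mx <- max(vapply(slices, max, 0))
  if (length(lut) < mx || anyNA(lut[seq_len(mx)])) {
    stop("`lut` must cover all labels 1..", mx, call. = FALSE)
  }
  if (any(lut < 0) || any(lut > 2^n - 1)) {
    stop("`lut` means must lie in [0, 2^n - 1]", call. = FALSE)
  }
  out <- .with_seed(seed, {
    rows <- nrow(slices[[1]])
    cols <- ncol(slices[[1]])
    # one smooth bias field for the whole volume: within-slice Gaussian
    # smoothness plus strong slice-to-slice correlation, emulating a single
    # 3-D nonuniformity field over the stack
    biases <- NULL
    if (inu_pct > 0) {
      rho <- 0.97
      b <- NULL
      biases <- lapply(slices, function(.) {
        e <- .gauss_smooth(matrix(stats::rnorm(rows * cols), rows, cols),
                           sigma = rows / 4)
        b <<- if (is.null(b)) e else rho * b + sqrt(1 - rho^2) * e
        b
      })
      bmax <- max(vapply(biases, function(b) max(abs(b)), 0))
      biases <- lapply(biases, function(b) 1 + (inu_pct / 100) * b / bmax)
    }
    lapply(seq_along(slices), function(s) {
      lab <- slices[[s]]
      bias <- if (is.null(biases)) 1 else biases[[s]]
      eps <- if (noise_pct > 0) {
        matrix(stats::rnorm(rows * cols, sd = noise_pct / 100 * (2^n - 1)),
               rows, cols)
      } else 0
      v <- matrix(lut[lab], rows, cols) * bias + eps
      intensity_image(pmin(pmax(round(v), 0), 2^n - 1), n)
    })
  })
  if (is.matrix(labels)) out[[1]] else out
}

#' Standard aligned multimodal pair
#'
#' The canonical fixture for the similarity-curve experiments: one anatomy
#' slice rendered through two intensity look-up tables with reversed tissue
#' ordering ("T1-like" vs "T2-like"), 13 effective bits, 3% noise, and 20%
#' intensity nonuniformity. The reversed ordering makes the raw intensity
#' correlation between the pair negative, while the shared anatomy keeps
#' their descriptor images close.
#'
#' @param seed Integer RNG seed (keep below \eqn{2^{31} - 1000}; slice
#'   renderers derive their seeds by small offsets).
#' @param size Square image side in pixels (default 128; use 512 for
#'   full-fidelity runs).
#' @param n Bit depth (default 13).
#' @return List with intensity images \code{a} and \code{b}, the
#'   \code{labels} matrix, the two LUTs, and the \code{seed}.
#' @export
standard_pair <- function(seed, size = 128, n = 13) {
  lab3 <- make_label_volume(seed, 1, size, size, n_tissues = 5)
  labels <- matrix(lab3[1, , ], size, size)
  frac <- c(0.08, 0.30, 0.50, 0.70, 0.88)
  lut_a <- round(frac * (2^n - 1))
  lut_b <- rev(lut_a)
  list(a = render_modality(labels, lut_a, 3, 20, n, seed + 101),
       b = render_modality(labels, lut_b, 3, 20, n, seed + 202),
       labels = labels, lut_a = lut_a, lut_b = lut_b, seed = seed)
}

#' Standard aligned multimodal slice stack
#'
#' A stack of corresponding slices in two modalities with reversed-contrast
#' LUTs, for slice-matching experiments. Ground-truth correspondence is
#' index identity; anatomy evolves gradually along the stack.
#'
#' @inheritParams standard_pair
#' @param n_slices Number of slices (default 30).
#' @param size Square slice side in pixels (default 64).
#' @return List with slice lists \code{a} and \code{b}, the label volume,
#'   and the \code{seed}.
#' @export
standard_stack <- function(seed, n_slices = 30, size = 64, n = 13) {
  labels <- make_label_volume(seed, n_slices, size, size, n_tissues = 5)
  frac <- c(0.08, 0.30, 0.50, 0.70, 0.88)
  lut_a <- round(frac * (2^n - 1))
  lut_b <- rev(lut_a)
  list(a = render_modality(labels, lut_a, 3, 20, n, seed + 101),
       b = render_modality(labels, lut_b, 3, 20, n, seed + 202),
       labels = labels, seed = seed)
}

#' Random smooth deformation field
#'
#' Band-limited random displacements: independent Gaussian noise fields for
#' the row and column components, smoothed with a Gaussian of standard
#' deviation \code{scale / 2} pixels and rescaled so the maximum
#' displacement norm equals \code{amplitude}. For amplitudes well below the
#' correlation scale the warp is invertible (positive Jacobian determinant).
#'
#' @param seed Integer RNG seed.
#' @param rows,cols Field dimensions.
#' @param amplitude Maximum displacement norm in pixels (\eqn{\ge 0}; 0
#'   gives the zero field).
#' @param scale Spatial correlation length in pixels.
#' @return A \code{\link{deformation_field}}.
#' @export
random_smooth_deformation <- function(seed, rows, cols, amplitude = 3,
                                      scale = 32) {
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  .with_seed(seed, {
    if (amplitude == 0) {
      return(deformation_field(matrix(0, rows, cols), matrix(0, rows, cols)))
    }
    dr <- .gauss_smooth(matrix(stats::rnorm(rows * cols), rows, cols),
                        sigma = scale / 2)
    dc <- .gauss_smooth(matrix(stats::rnorm(rows * cols), rows, cols),
                        sigma = scale / 2)
    m <- max(sqrt(dr^2 + dc^2))
    deformation_field(dr * amplitude / m, dc * amplitude / m)
  })
}
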