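# Similarity measures on descriptor and intensity images, rigid transform
# search producing similarity curves, slice matching with deflection
# statistics, and discrete deformation selection.

.values_of <- function(x) {
  if (inherits(x, "descriptor_image")) return(x$values)
  if (inherits(x, "intensity_image")) return(.img_pixels(x))
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a descriptor_image, intensity_image, or numeric matrix",
       call. = FALSE)
}

#' Mean absolute difference similarity
#'
#' The registration objective: the mean over (masked) pixels of
#' \eqn{|a - b|} (L1). Lower is more similar; 0 iff the images agree on the
#' mask. An RMS (L2) variant is available via \code{norm = "l2"}.
#'
#' @param a,b Descriptor images, intensity images, or numeric matrices of
#'   equal shape.
#' @param mask Optional logical matrix restricting the evaluation region.
#' @param norm \code{"l1"} (mean absolute difference, default) or
#'   \code{"l2"} (root mean square difference).
#' @return Non-negative scalar in the units of the inputs.
#' @examples
#' mad_similarity(matrix(c(0, 2, 1, 3), 2), matrix(c(1, 2, 1, 1), 2))
#' @export
mad_similarity <- function(a, b, mask = NULL, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  va <- .values_of(a)
  vb <- .values_of(b)
  if (!identical(dim(va), dim(vb))) {
    stop("images have different shapes", call. = FALSE)
  }
  d <- va - vb
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(va))) {
      stop("mask shape does not match the images", call. = FALSE)
    }
    d <- d[mask]
    if (length(d) == 0L) stop("mask selects no pixels", call. = FALSE)
  }
  if (norm == "l1") mean(abs(d)) else sqrt(mean(d^2))
}

#' Mutual information between two images
#'
#' Shannon mutual information \eqn{I(A, B) = H(A) + H(B) - H(A, B)} from the
#' joint \code{bins x bins} intensity histogram, in nats. Higher is more
#' similar; \eqn{I(A, A) = H(A)}.
#'
#' @param a,b Intensity images of equal shape (each binned by its own bit
#'   depth).
#' @param bins Marginal histogram bins (default 64).
#' @param mask Optional logical matrix restricting the evaluation region.
#' @return Mutual information in nats (non-negative up to rounding).
#' @export
mutual_information <- function(a, b, bins = 64, mask = NULL) {
  pa <- .img_pixels(a)
  pb <- .img_pixels(b)
  if (!identical(dim(pa), dim(pb))) {
    stop("images have different shapes", call. = FALSE)
  }
  .check_bins(bins, min(.img_depth(a), .img_depth(b)))
  ba <- .bin_index(as.vector(pa), bins, .img_depth(a))
  bb <- .bin_index(as.vector(pb), bins, .img_depth(b))
  if (!is.null(mask)) {
    keep <- as.vector(mask)
    if (!any(keep)) stop("mask selects no pixels", call. = FALSE)
    ba <- ba[keep]
    bb <- bb[keep]
  }
  joint <- tabulate((ba - 1L) * bins + bb, nbins = bins * bins)
  pj <- joint / sum(joint)
  pma <- tabulate(ba, nbins = bins) / length(ba)
  pmb <- tabulate(bb, nbins = bins) / length(bb)
  h <- function(p) -sum(.xlogx(p))
  h(pma) + h(pmb) - h(pj)
}

#' Rigid transform of an image with validity mask
#'
#' Rotates the image about its centre and translates it, resampling by
#' bilinear interpolation. The returned mask marks output pixels whose
#' pre-image lies inside the source; pixels outside are set to 0 and masked
#' invalid. Angle 0 with zero shift is the identity.
#'
#' @param image An \code{\link{intensity_image}}.
#' @param angle Rotation in degrees about the image centre,
#'   \eqn{|angle| \le 180}.
#' @param shift Translation \code{c(dx, dy)} in pixels (column, row),
#'   applied after the rotation.
#' @return List with \code{image} (an \code{intensity_image}, values
#'   rounded) and \code{mask} (logical matrix of valid pixels).
#' @export
rigid_transform <- function(image, angle = 0, shift = c(0, 0)) {
  px <- .img_pixels(image)
  n <- .img_depth(image)
  if (abs(angle) > 180) stop("|angle| must be <= 180 degrees", call. = FALSE)
  nr <- nrow(px)
  nc <- ncol(px)
  a <- -angle * pi / 180  # inverse mapping
  cc <- (nc + 1) / 2
  rc <- (nr + 1) / 2
  # destination grid (column-major)
  cx <- rep(seq_len(nc), each = nr) - cc - shift[1]
  cy <- rep(seq_len(nr), times = nc) - rc - shift[2]
  xs <- cos(a) * cx - sin(a) * cy + cc
  ys <- sin(a) * cx + cos(a) * cy + rc
  # small tolerance so lattice-exact cases (e.g. 90 degrees) keep their
  # border pixels despite ~1e-15 trigonometric rounding
  eps <- 1e-9
  valid <- xs >= 1 - eps & xs <= nc + eps & ys >= 1 - eps & ys <= nr + eps
  out <- .bilinear_sample(px, ys, xs)
  out[!valid] <- 0
  out <- pmin(pmax(round(out), 0), 2^n - 1)
  list(image = intensity_image(matrix(out, nr, nc), n),
       mask = matrix(valid, nr, nc))
}

# Bilinear sampling of `px` at fractional (row, col) coordinates; the
# coordinates are clamped to the image domain first.
.bilinear_sample <- function(px, ys, xs) {
  nr <- nrow(px)
  nc <- ncol(px)
  ys <- pmin(pmax(ys, 1), nr)
  xs <- pmin(pmax(xs, 1), nc)
  y0 <- pmin(floor(ys), nr - 1L)
  x0 <- pmin(floor(xs), nc - 1L)
  if (nr == 1L) y0 <- rep(1, length(ys))
  if (nc == 1L) x0 <- rep(1, length(xs))
  fy <- ys - y0
  fx <- xs - x0
  y1 <- pmin(y0 + 1, nr)
  x1 <- pmin(x0 + 1, nc)
  idx <- function(r, c) px[(c - 1) * nr + r]
  (1 - fy) * (1 - fx) * idx(y0, x0) + (1 - fy) * fx * idx(y0, x1) +
    fy * (1 - fx) * idx(y1, x0) + fy * fx * idx(y1, x1)
}

# Erode a logical mask so that only pixels whose full (2k+1)^2 neighbourhood
# is valid survive. Zero padding: out-of-frame is invalid.
.erode_mask <- function(mask, k) {
  if (k == 0L) return(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(0, nr + 2L * k, nc + 2L * k)
  pad[(k + 1):(k + nr), (k + 1):(k + nc)] <- mask * 1
  .box_sum(pad, 2L * k + 1L) == (2L * k + 1L)^2
}

.method_kinds <- function(methods) {
  methods[methods %in% core_kinds]
}

.check_method <- function(method) {
  ok <- c(core_kinds, "mi", "mad_raw")
  if (length(method) != 1L || !method %in% ok) {
    stop("`method` must be one of ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  method
}

#' Similarity curves over a rigid transform sweep
#'
#' For each parameter value, transforms the moving image (rotation about the
#' centre or translation along one axis), recomputes its descriptor on the
#' transformed image, and evaluates each method's similarity to the fixed
#' image over the valid-overlap region. Descriptor methods (\code{"m1"} ..
#' \code{"m4"}) and \code{"mad_raw"} report dissimilarity (lower = better);
#' \code{"mi"} reports similarity (higher = better). Descriptor methods are
#' evaluated on the valid mask eroded by the patch radius, so no patch
#' touches out-of-frame fill values.
#'
#' @param fixed,moving Intensity images of equal shape.
#' @param methods Character vector of methods; descriptor kinds share the
#'   patch histogram computation.
#' @param spec A \code{\link{patch_spec}} for descriptor methods.
#' @param parameters Strictly increasing numeric vector of angles (degrees)
#'   or shifts (pixels).
#' @param mode \code{"rotate"}, \code{"translate_x"}, or
#'   \code{"translate_y"}.
#' @param norm L1/L2 flag passed to \code{\link{mad_similarity}}.
#' @param mi_bins Bins for the \code{"mi"} method.
#' @return For \code{similarity_curves}, a named list of
#'   \code{similarity_curve} objects (data frames with columns
#'   \code{parameter}, \code{similarity}, \code{overlap}, plus attributes
#'   \code{method}, \code{mode}, \code{lower_is_better}).
#' @examples
#' pair <- standard_pair(1, size = 48)
#' cv <- similarity_curve(pair$a, pair$b, "m2", patch_spec(l = 3),
#'                        parameters = seq(-10, 10, by = 5))
#' cv$parameter[which.min(cv$similarity)]
#' @export
similarity_curves <- function(fixed, moving, methods = c("m1", "m2"),
                              spec = patch_spec(),
                              parameters = seq(-25, 25, by = 1),
                              mode = c("rotate", "translate_x",
                                       "translate_y"),
                              norm = c("l1", "l2"), mi_bins = 64) {
  mode <- match.arg(mode)
  norm <- match.arg(norm)
  methods <- vapply(methods, .check_method, "")
  if (length(parameters) < 1L) {
    stop("`parameters` must be non-empty", call. = FALSE)
  }
  if (is.unsorted(parameters, strictly = TRUE)) {
    stop("`parameters` must be strictly increasing", call. = FALSE)
  }
  pf <- .img_pixels(fixed)
  if (!identical(dim(pf), dim(.img_pixels(moving)))) {
    stop("fixed and moving images have different shapes", call. = FALSE)
  }
  kinds <- .method_kinds(methods)
  d_fixed <- if (length(kinds)) .compute_descriptors(fixed, spec, kinds)
  k <- if (length(kinds)) (spec$l - 1L) %/% 2L else 0L
  sims <- matrix(NA_real_, length(parameters), length(methods),
                 dimnames = list(NULL, methods))
  overlap <- numeric(length(parameters))
  for (i in seq_along(parameters)) {
    p <- parameters[i]
    tr <- switch(mode,
      rotate = rigid_transform(moving, angle = p),
      translate_x = rigid_transform(moving, shift = c(p, 0)),
      translate_y = rigid_transform(moving, shift = c(0, p))
    )
    overlap[i] <- mean(tr$mask)
    emask <- if (length(kinds)) .erode_mask(tr$mask, k)
    d_mov <- if (length(kinds)) .compute_descriptors(tr$image, spec, kinds)
    for (m in methods) {
      sims[i, m] <- if (m %in% core_kinds) {
        mad_similarity(d_fixed[[m]], d_mov[[m]], mask = emask, norm = norm)
      } else if (m == "mad_raw") {
        mad_similarity(pf, .img_pixels(tr$image), mask = tr$mask,
                       norm = norm)
      } else {
        mutual_information(fixed, tr$image, bins = mi_bins, mask = tr$mask)
      }
    }
  }
  out <- lapply(methods, function(m) {
    structure(data.frame(parameter = parameters, similarity = sims[, m],
                         overlap = overlap),
              method = m, mode = mode,
              lower_is_better = !identical(m, "mi"),
              class = c("similarity_curve", "data.frame"))
  })
  names(out) <- methods
  out
}

#' @rdname similarity_curves
#' @param method A single method for \code{similarity_curve}.
#' @export
similarity_curve <- function(fixed, moving, method = "m2",
                             spec = patch_spec(),
                             parameters = seq(-25, 25, by = 1),
                             mode = c("rotate", "translate_x",
                                      "translate_y"),
                             norm = c("l1", "l2"), mi_bins = 64) {
  similarity_curves(fixed, moving, methods = method, spec = spec,
                    parameters = parameters, mode = mode, norm = norm,
                    mi_bins = mi_bins)[[1]]
}

#' Normalized convergence rate of a similarity curve
#'
#' Quantifies how steeply a similarity curve climbs away from its optimum:
#' after min-max normalizing the curve to \eqn{[0, 1]} (dissimilarity
#' orientation), returns the mean normalized value at the two points
#' \code{radius} away from the optimum parameter (linearly interpolated).
#' Higher means steeper convergence to the extremum. A flat curve returns 0.
#'
#' @param curve A \code{similarity_curve}.
#' @param radius Parameter distance from the optimum at which to read the
#'   curve; both endpoints must lie within the sampled range.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
normalized_convergence_rate <- function(curve, radius) {
  if (!inherits(curve, "similarity_curve")) {
    stop("`curve` must be a similarity_curve", call. = FALSE)
  }
  v <- curve$similarity
  if (!isTRUE(attr(curve, "lower_is_better"))) v <- -v
  rng <- range(v)
  if (rng[2] <= rng[1]) return(0)
  vn <- (v - rng[1]) / (rng[2] - rng[1])
  p0 <- curve$parameter[which.min(v)]
  lo <- p0 - radius
  hi <- p0 + radius
  pr <- range(curve$parameter)
  if (lo < pr[1] || hi > pr[2]) {
    stop(sprintf("radius %g not covered around the optimum at %g", radius,
                 p0), call. = FALSE)
  }
  ends <- stats::approx(curve$parameter, vn, xout = c(lo, hi))$y
  mean(ends)
}

#' Match slices across two image stacks
#'
#' For each reference slice, finds the search slice optimizing the method's
#' similarity and classifies the signed index difference (search minus
#' reference, ground truth being index identity): zero deflection (exact
#' match), right deflection (+1), left deflection (-1), or failure
#' (|difference| > 1). Ties at the optimum break toward the lowest index.
#'
#' @param reference,search Non-empty lists of intensity images (equal
#'   shapes).
#' @param method Similarity method; see \code{\link{similarity_curves}}.
#' @param spec A \code{\link{patch_spec}} for descriptor methods.
#' @param norm,mi_bins As in \code{\link{similarity_curves}}.
#' @return A \code{deflection_summary}: list with counts \code{RDN},
#'   \code{LDN}, \code{ZDN}, \code{SUM}, \code{failures}, \code{total}, and
#'   percentages \code{ZDP} and \code{SUM_probability}.
#' @export
match_slices <- function(reference, search, method = "m2",
                         spec = patch_spec(), norm = c("l1", "l2"),
                         mi_bins = 64) {
  method <- .check_method(method)
  norm <- match.arg(norm)
  if (!length(reference) || !length(search)) {
    stop("stacks must be non-empty", call. = FALSE)
  }
  descr <- method %in% core_kinds
  dref <- if (descr) {
    lapply(reference, function(im) .compute_descriptors(im, spec, method)[[1]])
  } else reference
  dsea <- if (descr) {
    lapply(search, function(im) .compute_descriptors(im, spec, method)[[1]])
  } else search
  found <- integer(length(reference))
  for (i in seq_along(reference)) {
    s <- vapply(seq_along(search), function(j) {
      if (descr) {
        mad_similarity(dref[[i]], dsea[[j]], norm = norm)
      } else if (method == "mad_raw") {
        mad_similarity(reference[[i]], search[[j]], norm = norm)
      } else {
        mutual_information(reference[[i]], search[[j]], bins = mi_bins)
      }
    }, 0)
    found[i] <- if (method == "mi") which.max(s) else which.min(s)
  }
  diff <- found - seq_along(reference)
  total <- length(reference)
  rdn <- sum(diff == 1L)
  ldn <- sum(diff == -1L)
  zdn <- sum(diff == 0L)
  structure(list(RDN = rdn, LDN = ldn, ZDN = zdn, SUM = rdn + ldn + zdn,
                 failures = sum(abs(diff) > 1L), total = total,
                 ZDP = 100 * zdn / total,
                 SUM_probability = 100 * (rdn + ldn + zdn) / total,
                 method = method, found = found),
            class = "deflection_summary")
}

#' @export
print.deflection_summary <- function(x, ...) {
  cat(sprintf(
    "<deflection_summary> %s: RDN=%d LDN=%d ZDN=%d SUM=%d (of %d)\n",
    x$method, x$RDN, x$LDN, x$ZDN, x$SUM, x$total))
  cat(sprintf("  ZDP=%.2f%%  SUM probability=%.2f%%  failures=%d\n",
              x$ZDP, x$SUM_probability, x$failures))
  invisible(x)
}

#' @export
as.data.frame.deflection_summary <- function(x, ...) {
  data.frame(method = x$method, RDN = x$RDN, LDN = x$LDN, ZDN = x$ZDN,
             SUM = x$SUM, ZDP = x$ZDP, SUM_probability = x$SUM_probability,
             failures = x$failures, total = x$total)
}

#' Dense deformation field
#'
#' Per-pixel 2-vector displacements in pixel units: \code{dr} (row) and
#' \code{dc} (column) components as matrices of the image shape.
#'
#' @param dr,dc Numeric matrices of equal shape with finite entries.
#' @return A \code{deformation_field}.
#' @export
deformation_field <- function(dr, dc) {
  if (!is.matrix(dr) || !is.matrix(dc) || !identical(dim(dr), dim(dc))) {
    stop("`dr` and `dc` must be matrices of equal shape", call. = FALSE)
  }
  if (!all(is.finite(dr)) || !all(is.finite(dc))) {
    stop("deformation field entries must be finite", call. = FALSE)
  }
  structure(list(dr = dr, dc = dc), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dr^2 + x$dc^2)
  cat(sprintf("<deformation_field> %d x %d, max |d| = %.3f px\n",
              nrow(x$dr), ncol(x$dr), max(mag)))
  invisible(x)
}

#' Residual between two deformation fields
#'
#' The mean per-pixel Euclidean norm of the difference between an estimated
#' and a ground-truth deformation field over the domain \eqn{\Omega}:
#' \eqn{\tau = \frac{1}{|\Omega|}\sum_{x \in \Omega}
#' \lVert d_c(x) - d_g(x) \rVert}.
#'
#' @param d_c,d_g Deformation fields over the same domain.
#' @param mask Optional logical matrix defining \eqn{\Omega} (default: all
#'   pixels).
#' @return Scalar residual in the fields' length units.
#' @export
deformation_residual <- function(d_c, d_g, mask = NULL) {
  if (!inherits(d_c, "deformation_field") ||
      !inherits(d_g, "deformation_field")) {
    stop("expected deformation_field objects", call. = FALSE)
  }
  if (!identical(dim(d_c$dr), dim(d_g$dr))) {
    stop("deformation fields have different domains", call. = FALSE)
  }
  nr <- sqrt((d_c$dr - d_g$dr)^2 + (d_c$dc - d_g$dc)^2)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(nr))) {
      stop("mask shape does not match the fields", call. = FALSE)
    }
    nr <- nr[mask]
    if (!length(nr)) stop("mask selects no pixels", call. = FALSE)
  }
  mean(nr)
}

#' Warp an image by a deformation field
#'
#' Pull-back warping: the output at pixel \eqn{x} samples the input at
#' \eqn{x + d(x)} by bilinear interpolation (coordinates clamped to the
#' image domain), rounded back to integer intensities.
#'
#' @param image An \code{\link{intensity_image}}.
#' @param field A \code{\link{deformation_field}} of the image shape.
#' @return A warped \code{intensity_image}.
#' @export
warp_image <- function(image, field) {
  px <- .img_pixels(image)
  n <- .img_depth(image)
  if (!identical(dim(px), dim(field$dr))) {
    stop("field shape does not match the image", call. = FALSE)
  }
  nr <- nrow(px)
  nc <- ncol(px)
  ys <- rep(seq_len(nr), times = nc) + as.vector(field$dr)
  xs <- rep(seq_len(nc), each = nr) + as.vector(field$dc)
  out <- .bilinear_sample(px, ys, xs)
  out <- pmin(pmax(round(out), 0), 2^n - 1)
  intensity_image(matrix(out, nr, nc), n)
}

#' Select the best deformation from a discrete candidate set
#'
#' Given a fixed image and candidate (warped image, deformation field)
#' pairs, picks the candidate whose warped image optimizes the method's
#' similarity to the fixed image (minimum for descriptor/MAD methods,
#' maximum for MI; ties toward the lowest index), and scores the selected
#' field against the ground-truth field by the \eqn{\tau} residual.
#'
#' @param fixed An \code{\link{intensity_image}}.
#' @param candidates Non-empty list of \code{list(image =, field =)} pairs.
#' @param ground_truth The ground-truth \code{\link{deformation_field}}.
#' @param method,spec,norm,mi_bins As in \code{\link{match_slices}}.
#' @return List with \code{index} of the selected candidate, its residual
#'   \code{tau}, and the vector of \code{similarities}.
#' @export
select_best_deformation <- function(fixed, candidates, ground_truth,
                                    method = "m2", spec = patch_spec(),
                                    norm = c("l1", "l2"), mi_bins = 64) {
  method <- .check_method(method)
  norm <- match.arg(norm)
  if (!length(candidates)) {
    stop("`candidates` must be non-empty", call. = FALSE)
  }
  descr <- method %in% core_kinds
  dfix <- if (descr) .compute_descriptors(fixed, spec, method)[[1]]
  s <- vapply(candidates, function(cand) {
    if (descr) {
      dc <- .compute_descriptors(cand$image, spec, method)[[1]]
      mad_similarity(dfix, dc, norm = norm)
    } else if (method == "mad_raw") {
      mad_similarity(fixed, cand$image, norm = norm)
    } else {
      mutual_information(fixed, cand$image, bins = mi_bins)
    }
  }, 0)
  idx <- if (method == "mi") which.max(s) else which.min(s)
  list(index = idx,
       tau = deformation_residual(candidates[[idx]]$field, ground_truth),
       similarities = s)
}
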