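#' @keywords internal
"_PACKAGE"

#' Core function kinds
#'
#' The four strictly concave core functions used to quantify the uncertainty
#' of a patch intensity distribution:
#' \describe{
#'   \item{\code{"m1"}}{Shannon entropy term, \eqn{f(p) = -p \log p}.}
#'   \item{\code{"m2"}}{Logarithmic fuzzy entropy,
#'     \eqn{f(p) = -[p \log p + (1-p)\log(1-p)]}.}
#'   \item{\code{"m3"}}{Exponential fuzzy entropy,
#'     \eqn{f(p) = p e^{1-p} + (1-p) e^{p} - 1}.}
#'   \item{\code{"m4"}}{Rational concave function,
#'     \eqn{f(p) = p/(1+p) - p/2}.}
#' }
#' All logarithms are natural, so uncertainty values are in nats.
#'
#' @format Character vector of the four kind tags.
#' @export
core_kinds <- c("m1", "m2", "m3", "m4")

# x * log(x) with the convention 0 * log 0 := 0, applied element-wise
.xlogx <- function(x) {
  y <- x * log(x)
  y[x <= 0] <- 0
  y
}

.match_kind <- function(kind) {
  kind <- tolower(as.character(kind))
  if (length(kind) != 1L || !kind %in% core_kinds) {
    stop("`kind` must be one of ", paste(core_kinds, collapse = ", "),
         ", got: ", paste(kind, collapse = ", "), call. = FALSE)
  }
  kind
}

# Vectorized core function f_kind on [0, 1]; no domain checks (internal).
.core_fun <- function(kind) {
  switch(kind,
    m1 = function(p) -.xlogx(p),
    m2 = function(p) -(.xlogx(p) + .xlogx(1 - p)),
    m3 = function(p) p * exp(1 - p) + (1 - p) * exp(p) - 1,
    m4 = function(p) p / (1 + p) - p / 2
  )
}

#' Evaluate a single core-function term
#'
#' Computes \eqn{f_{kind}(p)} for probabilities \code{p}, using natural
#' logarithms and the conventions \eqn{0 \log 0 := 0} and
#' \eqn{(1-p)\log(1-p) := 0} at \eqn{p = 1}.
#'
#' @param kind One of \code{"m1"}, \code{"m2"}, \code{"m3"}, \code{"m4"};
#'   see \link{core_kinds}.
#' @param p Numeric vector of probabilities in \eqn{[0, 1]}.
#' @return Numeric vector of uncertainty contributions (nats).
#' @examples
#' core_term("m2", 0.5)  # ln 2
#' core_term("m2", 1)    # 0 by the 0 log 0 convention
#' @export
core_term <- function(kind, p) {
  kind <- .match_kind(kind)
  if (!is.numeric(p) || anyNA(p)) {
    stop("`p` must be numeric without NAs", call. = FALSE)
  }
  bad <- p < 0 | p > 1
  if (any(bad)) {
    stop("probability outside [0, 1]: ", paste(p[bad], collapse = ", "),
         call. = FALSE)
  }
  .core_fun(kind)(p)
}

# Validate a probability vector: entries in [0,1], sum 1 within tol.
# Renormalization is deliberately refused: a histogram that does not sum to
# one indicates an upstream bug, not a rounding problem.
.check_probability_vector <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    stop("probability vector must be non-empty numeric without NAs",
         call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    stop("probability vector has entries outside [0, 1]", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop(sprintf("probabilities sum to %.12f, not 1 (tolerance %g)", s, tol),
         call. = FALSE)
  }
  invisible(p)
}

#' Uncertainty measure of a distribution
#'
#' Sums the core-function terms over all bins of a probability vector:
#' \eqn{M_{kind}(p) = \sum_i f_{kind}(p_i)}. For a distribution over
#' \eqn{r} bins the value lies in \eqn{[0, B_{kind}(r)]}, attaining 0 at a
#' point mass and the upper bound at the uniform distribution.
#'
#' @inheritParams core_term
#' @param p Probability vector: non-negative entries summing to 1 within
#'   \code{1e-9}. Its length is the variety degree \eqn{r}.
#' @return Uncertainty value in nats.
#' @examples
#' uncertainty_measure("m1", rep(1 / 4, 4))  # ln 4
#' uncertainty_measure("m2", c(1, 0, 0))     # 0
#' @seealso \code{\link{upper_bound}}
#' @export
uncertainty_measure <- function(kind, p) {
  kind <- .match_kind(kind)
  .check_probability_vector(p)
  sum(.core_fun(kind)(p))
}

#' Upper bound of an uncertainty measure
#'
#' Closed-form maximum of \code{\link{uncertainty_measure}} over
#' distributions with \code{r} bins (attained at the uniform distribution):
#' \deqn{B_1(r) = \log r}
#' \deqn{B_2(r) = \log r + (r-1)\log\frac{r}{r-1}}
#' \deqn{B_3(r) = e^{(r-1)/r} + (r-1)e^{1/r} - r}
#' \deqn{B_4(r) = \frac{r}{r+1} - \frac12}
#' \eqn{B_1} and \eqn{B_2} grow without bound; \eqn{B_3} and \eqn{B_4}
#' saturate below \eqn{e} and \eqn{1/2} (about 2.705 and 0.496 already at
#' \eqn{r = 256}).
#'
#' @inheritParams core_term
#' @param r Integer variety degree(s), \eqn{r \ge 1}.
#' @return Bound value(s) in nats; 0 for \eqn{r = 1} under every kind.
#' @examples
#' upper_bound("m2", 4)    # ln 4 + 3 ln(4/3)
#' upper_bound("m4", 256)  # about 0.496
#' @export
upper_bound <- function(kind, r) {
  kind <- .match_kind(kind)
  .check_r(r, min = 1)
  switch(kind,
    m1 = log(r),
    m2 = log(r) + ifelse(r == 1, 0, (r - 1) * log(r / (r - 1))),
    m3 = exp((r - 1) / r) + (r - 1) * exp(1 / r) - r,
    m4 = r / (r + 1) - 0.5
  )
}

.check_r <- function(r, min) {
  if (!is.numeric(r) || length(r) < 1L || anyNA(r) ||
      any(r < min) || any(r != floor(r))) {
    stop("`r` must be integer-valued and >= ", min, call. = FALSE)
  }
  invisible(r)
}

#' Bound gap between logarithmic fuzzy entropy and Shannon entropy
#'
#' The extra quantification range \eqn{\Delta(r) = B_2(r) - B_1(r)
#' = (r-1)\log\frac{r}{r-1}} gained by the logarithmic fuzzy entropy over
#' Shannon entropy. Strictly increasing in \eqn{r}, below 1 for every finite
#' \eqn{r}, and converging to 1 nat as \eqn{r \to \infty}.
#'
#' @param r Integer variety degree(s), \eqn{r \ge 2}.
#' @return Gap value(s) in nats.
#' @examples
#' bound_gap(2)     # ln 2
#' bound_gap(8192)  # close to 1
#' @export
bound_gap <- function(r) {
  .check_r(r, min = 2)
  (r - 1) * log(r / (r - 1))
}

#' Check the strict Jensen inequality for a core function
#'
#' Tests whether \eqn{f(\lambda x_1 + (1-\lambda) x_2) >
#' \lambda f(x_1) + (1-\lambda) f(x_2)} holds for the given triple, i.e.
#' whether the core function behaves strictly concavely there.
#'
#' @inheritParams core_term
#' @param x1,x2 Distinct points in \eqn{(0, 1]}.
#' @param lam Mixing weight in the open interval \eqn{(0, 1)}.
#' @return \code{TRUE} if the strict inequality holds, \code{FALSE}
#'   otherwise.
#' @export
check_strict_concavity <- function(kind, x1, x2, lam) {
  kind <- .match_kind(kind)
  stopifnot(length(x1) == 1L, length(x2) == 1L, length(lam) == 1L)
  if (x1 == x2) stop("`x1` and `x2` must be distinct", call. = FALSE)
  if (lam <= 0 || lam >= 1) stop("`lam` must lie in (0, 1)", call. = FALSE)
  f <- .core_fun(kind)
  unname(f(lam * x1 + (1 - lam) * x2) > lam * f(x1) + (1 - lam) * f(x2))
}

#' Table of upper bounds and the bound gap
#'
#' Evaluates all four upper bounds \eqn{B_1 \ldots B_4} and the gap
#' \eqn{\Delta(r) = B_2(r) - B_1(r)} over a range of variety degrees.
#'
#' @param r_min,r_max Integer range of variety degrees, \code{r_min >= 1}.
#' @param r Optional explicit vector of degrees overriding the range.
#' @return A data frame with columns \code{r}, \code{b1} .. \code{b4},
#'   \code{gap} (all in nats; \code{gap} is \code{NA} at \eqn{r = 1}).
#' @examples
#' bounds_table(2, 8)
#' @export
bounds_table <- function(r_min = 2, r_max = 256, r = NULL) {
  if (is.null(r)) {
    .check_r(c(r_min, r_max), min = 1)
    if (r_max < r_min) stop("`r_max` must be >= `r_min`", call. = FALSE)
    r <- seq(r_min, r_max)
  } else {
    .check_r(r, min = 1)
  }
  data.frame(
    r = r,
    b1 = upper_bound("m1", r),
    b2 = upper_bound("m2", r),
    b3 = upper_bound("m3", r),
    b4 = upper_bound("m4", r),
    gap = ifelse(r >= 2, upper_bound("m2", r) - upper_bound("m1", r), NA_real_)
  )
}
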