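#' @title Fixed-bandwidth multivariate kernel density estimation
#' @description The kernel estimator \eqn{\hat f(x) = (n h^d)^{-1} \sum_i
#'   K((x - x_i)/h)} with the standard multivariate normal kernel
#'   \eqn{K(u) = (2\pi)^{-d/2} \exp(-\|u\|^2/2)} and a single scalar
#'   bandwidth h shared across dimensions (features are standardized
#'   upstream). Evaluation runs in log space so queries far from the data
#'   underflow gracefully to exact zeros rather than NaN.
#' @name density_estimation
NULL

#' Construct a fixed-bandwidth KDE model
#'
#' @param points training observations: an n x d numeric matrix (a vector is
#'   treated as n x 1).
#' @param h bandwidth (window width), a single positive scalar.
#' @return an object of class `kde_model` with fields `points`, `h`, `n`, `d`.
#' @export
kde_model <- function(points, h) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 1) stop_invalid("KDE needs at least one training point")
  if (!all(is.finite(points))) stop_invalid("training points must be finite")
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop_invalid("bandwidth h must be a single positive number")
  structure(list(points = points, h = as.numeric(h),
                 n = nrow(points), d = ncol(points)),
            class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  cat(sprintf("Gaussian KDE: n = %d, d = %d, h = %g\n", x$n, x$d, x$h))
  invisible(x)
}

#' Standard multivariate normal kernel
#'
#' \eqn{K(u) = (2\pi)^{-d/2} \exp(-\|u\|^2 / 2)}: strictly positive and
#' radially symmetric.
#'
#' @param u a numeric vector of length d, or an m x d matrix of row vectors.
#' @return kernel density value(s).
#' @export
gaussian_kernel <- function(u) {
  if (is.matrix(u)) {
    d <- ncol(u)
    q <- rowSums(u^2)
  } else {
    d <- length(u)
    q <- sum(u^2)
  }
  (2 * pi)^(-d / 2) * exp(-q / 2)
}

# Log-density of the KDE at each row of X (m x d). The core evaluation
# routine: everything else delegates here.
kde_logdensity <- function(points, h, X) {
  d <- ncol(points)
  L <- -sqdist(X, points) / (2 * h^2)
  row_logsumexp(L) - log(nrow(points)) - d * log(h) - (d / 2) * log(2 * pi)
}

#' Evaluate a KDE at a single query point
#'
#' @param model a [kde_model()].
#' @param x numeric query vector of length `model$d`.
#' @return the density estimate (nonnegative scalar).
#' @export
kde_evaluate <- function(model, x) {
  stopifnot(inherits(model, "kde_model"))
  x <- as.numeric(x)
  if (length(x) != model$d)
    stop_invalid("query has length %d but model dimension is %d",
                 length(x), model$d)
  exp(kde_logdensity(model$points, model$h, matrix(x, nrow = 1)))
}

#' Evaluate a KDE over a grid of query points
#'
#' Elementwise identical to [kde_evaluate()]; vectorized over rows.
#'
#' @param model a [kde_model()].
#' @param grid an m x d matrix (or list of length-d vectors, or a plain
#'   vector when d = 1).
#' @return numeric vector of m density values.
#' @export
kde_evaluate_grid <- function(model, grid) {
  stopifnot(inherits(model, "kde_model"))
  if (is.list(grid)) grid <- do.call(rbind, grid)
  if (is.vector(grid)) grid <- matrix(grid, ncol = model$d)
  grid <- as.matrix(grid)
  if (ncol(grid) != model$d)
    stop_invalid("grid has %d columns but model dimension is %d",
                 ncol(grid), model$d)
  exp(kde_logdensity(model$points, model$h, grid))
}

#' Normal-reference bandwidth rule
#'
#' The bandwidth minimizing asymptotic MISE when the data are normal:
#' \eqn{h = (4/(3n))^{1/5} \sigma}, with \eqn{\sigma} the sample standard
#' deviation.
#'
#' @param values univariate numeric sample, n >= 2.
#' @return bandwidth h > 0.
#' @export
bandwidth_normal_reference <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop_invalid("need at least 2 values for a bandwidth")
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0)
    stop_invalid("degenerate sample: standard deviation is zero")
  (4 / (3 * n))^(1 / 5) * s
}

#' MAD-robust bandwidth rule
#'
#' Replaces the sample s.d. in the normal-reference rule by the robust
#' estimate MAD/0.6745, where MAD is the median absolute deviation from the
#' median and 0.6745 = qnorm(3/4) makes it consistent for \eqn{\sigma}
#' under normality. Preferred for long-tailed data such as wear rates.
#'
#' @param values univariate numeric sample, n >= 2.
#' @return bandwidth h > 0.
#' @export
bandwidth_robust <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop_invalid("need at least 2 values for a bandwidth")
  mad_raw <- stats::median(abs(values - stats::median(values)))
  if (!is.finite(mad_raw) || mad_raw <= 0)
    stop_invalid("degenerate sample: median absolute deviation is zero")
  (4 / (3 * n))^(1 / 5) * mad_raw / 0.6745
}
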