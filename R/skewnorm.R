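#' Skew-normal density, sampling, and moments
#'
#' The skew-normal distribution with location `mu`, scale `sigma` and shape
#' `alpha` has density
#' \deqn{f(x) = \frac{2}{\sigma}\,\phi\!\left(\frac{x-\mu}{\sigma}\right)
#'   \Phi\!\left(\alpha\,\frac{x-\mu}{\sigma}\right),}
#' where \eqn{\phi} and \eqn{\Phi} are the standard normal density and
#' cumulative distribution function. At `alpha = 0` it reduces to
#' `dnorm(x, mu, sigma)`. It is the per-nucleus likelihood used throughout
#' this package for ensembles of predicted chemical shifts, which are often
#' visibly skewed.
#'
#' @param x numeric vector of quantiles (ppm).
#' @param mu location parameter (ppm).
#' @param sigma scale parameter (ppm), strictly positive.
#' @param alpha shape (skewness) parameter, dimensionless.
#' @param log logical; return the log-density?
#' @return `dskewnorm` returns the (log-)density; `rskewnorm` returns `n`
#'   random deviates; `skewnorm_mean` and `skewnorm_var` return the analytic
#'   distribution mean and variance.
#' @examples
#' dskewnorm(0, 0, 1, 0)            # standard normal density at 0
#' skewnorm_mean(0, 1, 1)           # 1/sqrt(pi)
#' skewnorm_var(0, 1, 1)            # 1 - 1/pi
#' @export
dskewnorm <- function(x, mu, sigma, alpha, log = FALSE) {
  if (any(sigma <= 0)) stop("`sigma` must be strictly positive", call. = FALSE)
  stopifnot(length(mu) == 1L, length(sigma) == 1L, length(alpha) == 1L)
  dskewnorm_cpp(as.numeric(x), mu, sigma, alpha, isTRUE(log))
}

#' @rdname dskewnorm
#' @param n number of deviates.
#' @export
rskewnorm <- function(n, mu, sigma, alpha) {
  if (any(sigma <= 0)) stop("`sigma` must be strictly positive", call. = FALSE)
  # Azzalini's stochastic representation: X = delta|Z0| + sqrt(1-delta^2) Z1
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  mu + sigma * (delta * z0 + sqrt(1 - delta^2) * z1)
}

#' @rdname dskewnorm
#' @export
skewnorm_mean <- function(mu, sigma, alpha) {
  mu + sigma * sqrt(2 / pi) * alpha / sqrt(1 + alpha^2)
}

#' @rdname dskewnorm
#' @export
skewnorm_var <- function(mu, sigma, alpha) {
  sigma^2 * (1 - (2 / pi) * alpha^2 / (1 + alpha^2))
}

#' Credible interval of a sample of posterior draws
#'
#' Computes the interval containing a given posterior mass. The default is the
#' highest-density interval (HDI): the shortest contiguous interval holding
#' `mass` of the draws, found by scanning all windows of the sorted sample.
#' The equal-tailed interval is available via `method = "eti"`. The reported
#' `center` is the midpoint of the interval, matching the convention of
#' quoting an interval as its center plus or minus the distance to the bounds.
#'
#' @param draws numeric vector of posterior draws (length >= 2, or a single
#'   repeated value).
#' @param mass probability mass in (0, 1); default 0.94.
#' @param method `"hdi"` (default) or `"eti"`.
#' @return A list of class `credint` with elements `lower`, `upper`, `center`
#'   and `mass`.
#' @export
credible_interval <- function(draws, mass = 0.94, method = c("hdi", "eti")) {
  method <- match.arg(method)
  draws <- as.numeric(draws)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 1L) stop("no finite draws", call. = FALSE)
  if (!(mass > 0 && mass < 1)) stop("`mass` must be in (0, 1)", call. = FALSE)
  if (n == 1L || max(draws) == min(draws)) {
    lo <- hi <- draws[1L]
  } else if (method == "hdi") {
    s <- sort(draws)
    k <- max(1L, ceiling(mass * n))
    if (k >= n) {
      lo <- s[1L]; hi <- s[n]
    } else {
      widths <- s[(k + 1L):n] - s[1L:(n - k)]
      i <- which.min(widths)
      lo <- s[i]; hi <- s[i + k]
    }
  } else {
    q <- stats::quantile(draws, c((1 - mass) / 2, 1 - (1 - mass) / 2),
                         names = FALSE, type = 7)
    lo <- q[1L]; hi <- q[2L]
  }
  structure(list(lower = lo, upper = hi, center = (lo + hi) / 2, mass = mass),
            class = "credint")
}

#' @export
print.credint <- function(x, digits = 4, ...) {
  half <- (x$upper - x$lower) / 2
  cat(sprintf("%.0f%% credible interval: %s +/- %s  [%s, %s]\n",
              100 * x$mass, format(x$center, digits = digits),
              format(half, digits = digits),
              format(x$lower, digits = digits),
              format(x$upper, digits = digits)))
  invisible(x)
}
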