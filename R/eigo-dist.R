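#' The extended inverse-Gompertz (EIGo) distribution
#'
#' Density, distribution function, quantile function, random generation,
#' hazard and cumulative hazard for the three-parameter extended
#' inverse-Gompertz distribution with shape parameters `alpha`, `beta` and
#' scale parameter `theta`.
#'
#' The distribution function is
#' \deqn{F(x) = 1 - \{1 - \exp(-\zeta(x))\}^{\alpha}, \quad x > 0,}
#' where \eqn{\zeta(x) = (\beta/\theta)\,(e^{\theta/x} - 1)}.  The density is
#' \deqn{f(x) = \alpha\beta x^{-2} \exp(\theta/x - \zeta(x))
#'   \{1 - e^{-\zeta(x)}\}^{\alpha - 1}.}
#' Setting \eqn{\alpha = 1} recovers the inverse-Gompertz distribution;
#' letting \eqn{\theta \to 0} recovers the generalized inverted-exponential
#' distribution, and both together the inverse-exponential distribution.
#' The hazard is unimodal (upside-down bathtub) and the right tail decays
#' like \eqn{x^{-(\alpha + 1)}}, so moments of order `r` exist only for
#' `r < alpha`.
#'
#' The support is the positive half-line: density and hazard evaluations
#' reject non-positive `x`; `peigo` maps `x <= 0` to probability 0.
#'
#' @param x vector of positive times.
#' @param q vector of quantiles; values at or below 0 have probability 0.
#' @param p vector of probabilities, strictly inside (0, 1).
#' @param n number of draws.
#' @param alpha,beta positive shape parameters.
#' @param theta positive scale parameter.
#' @param log,log.p logical; if TRUE, probabilities/densities are on the
#'   log scale.
#' @param lower.tail logical; if TRUE (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @return `deigo` the density, `peigo` the distribution function, `qeigo`
#'   the quantile function, `reigo` random deviates, `heigo` the hazard rate
#'   and `Heigo` the cumulative hazard.
#' @examples
#' deigo(1, 2, 1, 1)              # ~ 0.8003
#' peigo(1, 2, 1, 1)              # ~ 0.3266
#' qeigo(0.5, 1, 1, 1)            # median ~ 1.8988
#' set.seed(1); reigo(3, 1, 0.5, 0.5)
#' @name eigo
NULL

#' Auxiliary function of the EIGo distribution
#'
#' Computes \eqn{\zeta(x; \beta, \theta) = (\beta/\theta)(e^{\theta/x} - 1)},
#' the exponent appearing throughout the EIGo distribution, likelihood and
#' posterior.  It is strictly decreasing in `x`, diverges as `x` approaches 0
#' and vanishes as `x` grows.
#'
#' @param x vector of positive times.
#' @param beta,theta positive shape and scale parameters.
#' @return numeric vector of non-negative values.
#' @export
eigo_zeta <- function(x, beta, theta) {
  stop_if_not_positive(x, "x")
  stop_if_not_positive(beta, "beta")
  stop_if_not_positive(theta, "theta")
  beta / theta * expm1(theta / x)
}

#' @rdname eigo
#' @export
deigo <- function(x, alpha, beta, theta, log = FALSE) {
  stop_if_not_positive(alpha, "alpha")
  stop_if_not_positive(beta, "beta")
  stop_if_not_positive(theta, "theta")
  stop_if_not_positive(x, "x")
  z <- beta / theta * expm1(theta / x)
  logf <- log(alpha) + log(beta) - 2 * log(x) + theta / x - z +
    (alpha - 1) * log1mexp(z)
  if (log) logf else exp(logf)
}

#' @rdname eigo
#' @export
peigo <- function(q, alpha, beta, theta, lower.tail = TRUE, log.p = FALSE) {
  stop_if_not_positive(alpha, "alpha")
  stop_if_not_positive(beta, "beta")
  stop_if_not_positive(theta, "theta")
  logsf <- rep(0, length(q))      # support is (0, Inf): F(x <= 0) = 0
  pos <- !is.na(q) & q > 0
  z <- beta / theta * expm1(theta / q[pos])
  logsf[pos] <- alpha * log1mexp(z)
  logsf[is.na(q)] <- NA_real_
  if (lower.tail) {
    p <- -expm1(logsf)
    if (log.p) log(p) else p
  } else {
    if (log.p) logsf else exp(logsf)
  }
}

#' @rdname eigo
#' @export
qeigo <- function(p, alpha, beta, theta, lower.tail = TRUE, log.p = FALSE) {
  stop_if_not_positive(alpha, "alpha")
  stop_if_not_positive(beta, "beta")
  stop_if_not_positive(theta, "theta")
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  # invert F: S = (1 - q)  =>  zeta = -log(1 - (1-q)^(1/alpha))
  w <- log1p(-p) / alpha             # log (1-q)^(1/alpha), < 0
  zeta <- -log1mexp(-w)              # -log(1 - e^w) > 0
  theta / log1p(theta * zeta / beta)
}

#' @rdname eigo
#' @export
reigo <- function(n, alpha, beta, theta) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("'n' must be a non-negative count")
  if (n == 0) return(numeric(0))
  qeigo(stats::runif(n), alpha, beta, theta)
}

#' @rdname eigo
#' @export
heigo <- function(x, alpha, beta, theta, log = FALSE) {
  logh <- deigo(x, alpha, beta, theta, log = TRUE) -
    peigo(x, alpha, beta, theta, lower.tail = FALSE, log.p = TRUE)
  if (log) logh else exp(logh)
}

#' @rdname eigo
#' @export
Heigo <- function(x, alpha, beta, theta) {
  -peigo(x, alpha, beta, theta, lower.tail = FALSE, log.p = TRUE)
}

#' Survival, hazard and related reliability functions of the EIGo model
#'
#' Evaluates in one pass the survival function, hazard rate, cumulative
#' hazard, reversed hazard (f/F) and odds function (F/S) at the supplied
#' times.  If the survival probability underflows to zero the hazard is
#' reported as `Inf` with a warning.
#'
#' @inheritParams eigo
#' @return a data.frame with columns `x`, `survival`, `hazard`, `cum_hazard`,
#'   `reversed_hazard`, `odds`.
#' @export
eigo_hazards <- function(x, alpha, beta, theta) {
  f <- deigo(x, alpha, beta, theta)
  s <- peigo(x, alpha, beta, theta, lower.tail = FALSE)
  F_ <- 1 - s
  if (any(s == 0 & f > 0)) {
    warning("survival underflowed to 0; hazard reported as Inf")
  }
  data.frame(
    x = x,
    survival = s,
    hazard = f / s,
    cum_hazard = Heigo(x, alpha, beta, theta),
    reversed_hazard = f / F_,
    odds = F_ / s
  )
}

#' Mode of the EIGo density
#'
#' The mode has no closed form; it is located by bounded maximization of the
#' log-density, bracketed by a coarse geometric grid search.  Stationarity of
#' the log-density at the returned point is checked and non-convergence
#' raises an error.
#'
#' @inheritParams eigo
#' @param tol relative convergence tolerance passed to [stats::optimize()].
#' @return the positive time at which the density attains its maximum.
#' @export
eigo_mode <- function(alpha, beta, theta, tol = 1e-10) {
  stop_if_not_positive(alpha, "alpha")
  stop_if_not_positive(beta, "beta")
  stop_if_not_positive(theta, "theta")
  logf <- function(x) deigo(x, alpha, beta, theta, log = TRUE)
  # geometric bracket around the scale of the distribution
  grid <- exp(seq(log(theta * 1e-4), log(theta * 1e6), length.out = 400L))
  vals <- logf(grid)
  i <- which.max(vals)
  if (i == 1L || i == length(grid)) {
    stop("mode search failed: maximum on the bracket boundary (grid [",
         min(grid), ", ", max(grid), "])")
  }
  opt <- stats::optimize(logf, lower = grid[i - 1L], upper = grid[i + 1L],
                         maximum = TRUE, tol = tol)
  m <- opt$maximum
  eps <- m * 1e-4
  if (logf(m) < logf(m - eps) || logf(m) < logf(m + eps)) {
    stop("mode search did not converge to a local maximum at x = ", m)
  }
  m
}
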