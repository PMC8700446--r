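# Moments, reliability measures, entropies and order statistics of the EIGo
# distribution.  The formal series expansions of these quantities do not
# converge for arbitrary positive shape parameters, so everything here is
# computed from the defining integral by adaptive quadrature (rel/abs
# tolerance 1e-9 with the infinite-limit transform of stats::integrate).

# Tail index: f(x) ~ alpha * beta^alpha * x^-(alpha+1) as x -> Inf, so
# E[X^r] is finite iff r < alpha.
moment_exists <- function(r, alpha) r < alpha

nonfinite_with_reason <- function(reason) {
  warning(reason, call. = FALSE)
  structure(Inf, reason = reason)
}

#' Raw moments of the EIGo distribution
#'
#' Computes \eqn{E[X^r]} by adaptive quadrature of \eqn{x^r f(x)} over the
#' positive half-line.  Because the density has a power tail of index
#' \eqn{\alpha + 1}, the moment exists only for `r < alpha`; otherwise `Inf`
#' is returned (with a warning and a `reason` attribute), never a silently
#' truncated number.
#'
#' @param r non-negative moment order.
#' @inheritParams eigo
#' @return the moment, or `Inf` when it does not exist.
#' @export
eigo_moment <- function(r, alpha, beta, theta) {
  if (length(r) != 1L || is.na(r) || r < 0) stop("'r' must be a non-negative order")
  stop_if_not_positive(alpha, "alpha")
  if (r == 0) return(1)
  if (!moment_exists(r, alpha)) {
    return(nonfinite_with_reason(sprintf(
      "E[X^%g] does not exist: tail index alpha + 1 requires r < alpha = %g", r, alpha)))
  }
  eigo_quad(function(x) x^r * deigo(x, alpha, beta, theta), 0, Inf)
}

#' Mean residual life of the EIGo distribution
#'
#' The expected remaining lifetime \eqn{E[X - t \mid X > t]}, computed as
#' \eqn{S(t)^{-1} \int_t^\infty S(x)\,dx}.  At `t = 0` this equals the mean.
#' A finite mean requires `alpha > 1`; otherwise `Inf` is returned with a
#' warning.
#'
#' @param t non-negative age.
#' @inheritParams eigo
#' @export
eigo_mrl <- function(t, alpha, beta, theta) {
  if (length(t) != 1L || is.na(t) || t < 0) stop("'t' must be non-negative")
  stop_if_not_positive(alpha, "alpha")
  if (alpha <= 1) {
    return(nonfinite_with_reason(sprintf(
      "mean residual life is non-finite: requires alpha > 1 (alpha = %g)", alpha)))
  }
  s <- function(x) peigo(x, alpha, beta, theta, lower.tail = FALSE)
  st <- if (t == 0) 1 else s(t)
  eigo_quad(s, t, Inf) / st
}

#' Mean inactivity time and strong mean inactivity time
#'
#' For a unit known to have failed by time `t`, the mean inactivity time is
#' \eqn{E[t - X \mid X \le t] = F(t)^{-1}\int_0^t F(x)\,dx}, and the strong
#' version is \eqn{E[t^2 - X^2 \mid X \le t] = F(t)^{-1}\int_0^t 2xF(x)\,dx}.
#' Both are computed by quadrature and lie in \eqn{(0, t)} and
#' \eqn{(0, t^2)} respectively.
#'
#' @param t positive time with `peigo(t, ...) > 0`.
#' @inheritParams eigo
#' @return list with elements `mit` and `smit`.
#' @export
eigo_inactivity <- function(t, alpha, beta, theta) {
  stop_if_not_positive(t, "t")
  Ft <- peigo(t, alpha, beta, theta)
  if (Ft <= 0) stop("cdf at 't' is numerically zero; inactivity time undefined")
  Ffun <- function(x) peigo(x, alpha, beta, theta)
  list(
    mit = eigo_quad(Ffun, 0, t) / Ft,
    smit = eigo_quad(function(x) 2 * x * Ffun(x), 0, t) / Ft
  )
}

#' Stress-strength reliability of two EIGo variables
#'
#' Computes \eqn{R = P(X > Z)} for independent strength
#' \eqn{X \sim EIGo(\alpha, \beta_1, \theta_1)} and stress
#' \eqn{Z \sim EIGo(\alpha, \beta_2, \theta_2)} as
#' \eqn{\int_0^\infty f_1(x) F_2(x)\,dx}.  The construction assumes a common
#' shape `alpha`; with `strict = TRUE` (default) differing `alpha` values are
#' an error, with `strict = FALSE` they are allowed with a warning (the
#' quadrature itself is generic).
#'
#' @param strength,stress parameter triples (see [eigo_params()]).
#' @param strict logical; enforce the common-`alpha` assumption.
#' @return a probability in [0, 1].
#' @export
eigo_stress_strength <- function(strength, stress, strict = TRUE) {
  p1 <- as_eigo_params(strength)
  p2 <- as_eigo_params(stress)
  if (p1[["alpha"]] != p2[["alpha"]]) {
    msg <- "stress and strength have different 'alpha' shape parameters"
    if (strict) stop(msg, " (set strict = FALSE to integrate anyway)", call. = FALSE)
    warning(msg, call. = FALSE)
  }
  eigo_quad(function(x) {
    deigo(x, p1[["alpha"]], p1[["beta"]], p1[["theta"]]) *
      peigo(x, p2[["alpha"]], p2[["beta"]], p2[["theta"]])
  }, 0, Inf)
}

#' Probability-weighted moments of the EIGo distribution
#'
#' Computes \eqn{\rho_{r,k} = E[X^r F(X)^k]} by quadrature of
#' \eqn{x^r F(x)^k f(x)}.  Finite only for `r < alpha` (same tail argument as
#' [eigo_moment()]); `k = 0` reduces to the raw moment and `r = 0` gives
#' \eqn{1/(k+1)} by the probability-integral transform.
#'
#' @param r,k non-negative orders.
#' @inheritParams eigo
#' @export
eigo_pwm <- function(r, k, alpha, beta, theta) {
  if (length(r) != 1L || is.na(r) || r < 0) stop("'r' must be a non-negative order")
  if (length(k) != 1L || is.na(k) || k < 0) stop("'k' must be a non-negative order")
  stop_if_not_positive(alpha, "alpha")
  if (!moment_exists(r, alpha)) {
    return(nonfinite_with_reason(sprintf(
      "E[X^%g F^%g] does not exist: requires r < alpha = %g", r, k, alpha)))
  }
  eigo_quad(function(x) {
    x^r * peigo(x, alpha, beta, theta)^k * deigo(x, alpha, beta, theta)
  }, 0, Inf)
}

#' Renyi and delta entropies of the EIGo distribution
#'
#' Both entropies are transforms of the same integral
#' \eqn{I_\delta = \int_0^\infty f(x)^\delta\,dx}, evaluated once by
#' quadrature: the Renyi entropy of order `delta` is
#' \eqn{\log(I_\delta)/(1-\delta)} and the delta-entropy is
#' \eqn{\log(1 - I_\delta)/(\delta - 1)}.  The integral is finite only when
#' the tail exponent \eqn{\delta(\alpha + 1)} exceeds 1; divergence is
#' reported as a non-finite result.  The delta-entropy is `NaN` when
#' \eqn{I_\delta > 1} (its defining logarithm is undefined there).
#'
#' @param delta positive order, different from 1.
#' @inheritParams eigo
#' @return list with elements `renyi`, `delta_entropy` and `integral`.
#' @export
eigo_entropy <- function(delta, alpha, beta, theta) {
  stop_if_not_positive(delta, "delta")
  if (delta == 1) stop("'delta' must differ from 1 (use a nearby value for the Shannon limit)")
  stop_if_not_positive(alpha, "alpha")
  if (delta * (alpha + 1) <= 1) {
    warning(sprintf(
      "integral of f^delta diverges: tail exponent delta*(alpha+1) = %g <= 1",
      delta * (alpha + 1)), call. = FALSE)
    return(list(renyi = if (delta < 1) Inf else -Inf, delta_entropy = NaN,
                integral = Inf))
  }
  I <- eigo_quad(function(x) deigo(x, alpha, beta, theta)^delta, 0, Inf)
  de <- if (I < 1) log1p(-I) / (delta - 1) else NaN
  if (is.nan(de)) warning("delta-entropy undefined: integral of f^delta exceeds 1")
  list(renyi = log(I) / (1 - delta), delta_entropy = de, integral = I)
}

#' Order-statistic density and distribution for EIGo samples
#'
#' For the r-th smallest of `n` iid EIGo lifetimes, the density is
#' \eqn{f_{(r)}(x) = B(r, n-r+1)^{-1} f(x) F(x)^{r-1} S(x)^{n-r}} and the
#' distribution function is the upper binomial tail
#' \eqn{\sum_{d=r}^n \binom{n}{d} F(x)^d S(x)^{n-d}}, both evaluated
#' directly.
#'
#' @param x vector of positive times.
#' @param r rank, an integer in 1..n.
#' @param n sample size.
#' @inheritParams eigo
#' @return list with numeric vectors `pdf` and `cdf`.
#' @export
eigo_order_statistic <- function(x, r, n, alpha, beta, theta) {
  if (length(r) != 1L || length(n) != 1L || is.na(r) || is.na(n) ||
      r < 1 || r > n || r != round(r) || n != round(n)) {
    stop("'r' must be an integer rank in 1..n")
  }
  Fx <- peigo(x, alpha, beta, theta)
  fx <- deigo(x, alpha, beta, theta)
  list(
    pdf = fx * stats::dbeta(Fx, r, n - r + 1),
    cdf = stats::pbinom(r - 1, n, Fx, lower.tail = FALSE)
  )
}
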