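#' Type-II censored sample
#'
#' Container for a Type-II censored life test: `n` units go on test and the
#' test stops at the `m`-th failure, so only the `m` smallest lifetimes are
#' observed.  `m = n` is a complete sample.  Input times are sorted
#' internally, so likelihood values do not depend on input order.
#'
#' @param times positive failure times (the observed `m` smallest).
#' @param n total number of units on test; defaults to `length(times)`
#'   (complete sample).
#' @return an object of class `"eigo_type2"` with elements `times` (sorted
#'   ascending), `n` and `m`.
#' @examples
#' eigo_type2(c(3, 1, 2), n = 5)
#' @export
eigo_type2 <- function(times, n = length(times)) {
  stop_if_not_positive(times, "times")
  m <- length(times)
  if (length(n) != 1L || is.na(n) || n != round(n) || n < m) {
    stop("'n' must be an integer >= length(times)")
  }
  structure(list(times = sort(as.numeric(times)), n = as.integer(n), m = m),
            class = "eigo_type2")
}

#' @export
print.eigo_type2 <- function(x, ...) {
  cat(sprintf("Type-II censored sample: m = %d failures out of n = %d units%s\n",
              x$m, x$n, if (x$m == x$n) " (complete)" else ""))
  cat("times:", paste(utils::head(signif(x$times, 5), 10), collapse = ", "),
      if (x$m > 10) "...\n" else "\n")
  invisible(x)
}

as_type2 <- function(sample) {
  if (inherits(sample, "eigo_type2")) sample else eigo_type2(sample)
}

# Parameter validation for the likelihood surface.  Unlike the distribution
# functions, the inference code also admits theta < 0: the same closed-form
# expressions then describe the defective variant of the model
# ((beta/theta)(e^{theta/x} - 1) at theta = -t equals (beta/t)(1 - e^{-t/x})),
# which places mass F(0+) > 0 at zero -- the inverse analogue of the
# negative-shape Gompertz.  See `defective` in [eigo_mle()].
check_fit_params <- function(params) {
  if (!is.numeric(params) || length(params) != 3L || anyNA(params)) {
    stop("'params' must be a numeric vector (alpha, beta, theta)", call. = FALSE)
  }
  if (!is.null(names(params)) && all(c("alpha", "beta", "theta") %in% names(params))) {
    params <- params[c("alpha", "beta", "theta")]
  }
  if (params[[1L]] <= 0 || params[[2L]] <= 0 || params[[3L]] == 0) {
    stop("'alpha' and 'beta' must be positive and 'theta' non-zero", call. = FALSE)
  }
  stats::setNames(as.numeric(params), c("alpha", "beta", "theta"))
}

#' Type-II censored EIGo log-likelihood
#'
#' Log-likelihood of an EIGo parameter triple for the first `m` of `n`
#' lifetimes:
#' \deqn{\ell = m\log(\alpha\beta) + \theta\sum x_{(i)}^{-1}
#'   - 2\sum\log x_{(i)} - \sum\zeta_i
#'   + (\alpha-1)\sum\log(1 - e^{-\zeta_i})
#'   + \alpha(n-m)\log(1 - e^{-\zeta_m}),}
#' with \eqn{\zeta_i = \zeta(x_{(i)}; \beta, \theta)}.  The combinatorial
#' constant \eqn{\log\{n!/(n-m)!\}} is omitted: for a complete sample the
#' value is exactly \eqn{\sum \log f(x_i)}, the convention under which
#' information criteria are computed.  Non-finite intermediates yield `-Inf`
#' (optimizer-safe).
#'
#' The likelihood also admits `theta < 0`, where the same expressions define
#' the defective branch of the model (positive mass at zero); see
#' [eigo_mle()].
#'
#' @param sample an [eigo_type2()] object (or a numeric vector, treated as a
#'   complete sample).
#' @param params parameter triple (alpha, beta, theta); `theta` may be
#'   negative (defective branch) but not zero.
#' @return the log-likelihood kernel value.
#' @export
eigo_loglik <- function(sample, params) {
  sample <- as_type2(sample)
  p <- check_fit_params(params)
  alpha <- p[["alpha"]]; beta <- p[["beta"]]; theta <- p[["theta"]]
  x <- sample$times; n <- sample$n; m <- sample$m
  z <- beta / theta * expm1(theta / x)
  L <- log1mexp(z)
  ll <- m * log(alpha * beta) + theta * sum(1 / x) - 2 * sum(log(x)) -
    sum(z) + (alpha - 1) * sum(L) + alpha * (n - m) * L[m]
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' Analytic score of the Type-II censored EIGo log-likelihood
#'
#' Gradient of [eigo_loglik()] with respect to (alpha, beta, theta), using
#' \eqn{\zeta'_\beta = \zeta/\beta} and
#' \eqn{\zeta'_\theta = (\beta/\theta^2)\{e^{\theta/x}(\theta/x - 1) + 1\}}.
#'
#' @inheritParams eigo_loglik
#' @return numeric vector of length 3 named (alpha, beta, theta).
#' @export
eigo_score <- function(sample, params) {
  sample <- as_type2(sample)
  p <- check_fit_params(params)
  alpha <- p[["alpha"]]; beta <- p[["beta"]]; theta <- p[["theta"]]
  x <- sample$times; n <- sample$n; m <- sample$m
  tx <- theta / x
  z <- beta / theta * expm1(tx)
  L <- log1mexp(z)
  g <- 1 / expm1(z)                      # e^{-z} / (1 - e^{-z})
  dzb <- z / beta
  dzt <- beta / theta^2 * (exp(tx) * (tx - 1) + 1)
  s_alpha <- m / alpha + sum(L) + (n - m) * L[m]
  s_beta <- m / beta - sum(dzb) + (alpha - 1) * sum(dzb * g) +
    alpha * (n - m) * dzb[m] * g[m]
  s_theta <- sum(1 / x) - sum(dzt) + (alpha - 1) * sum(dzt * g) +
    alpha * (n - m) * dzt[m] * g[m]
  c(alpha = s_alpha, beta = s_beta, theta = s_theta)
}

# Moment/quantile-matched starting values plus a scrambled coarse grid.
# `sign` = -1 generates starting points on the defective branch; the
# median-matching formula for beta works unchanged with signed theta.
mle_starts <- function(sample, n_starts, sign = 1) {
  x <- sample$times
  med <- stats::median(x)
  starts <- list()
  for (a0 in c(0.5, 1, 2, 5)) {
    for (t0 in sign * med * c(0.25, 1)) {
      zm <- -log1p(-0.5^(1 / a0))       # zeta at the median
      b0 <- t0 * zm / expm1(t0 / med)
      starts[[length(starts) + 1L]] <- c(a0, max(abs(b0), 1e-8), t0)
    }
  }
  # deterministic jitter for the remaining starts
  i <- 0L
  while (length(starts) < n_starts) {
    i <- i + 1L
    base <- starts[[(i - 1L) %% 8L + 1L]]
    starts[[length(starts) + 1L]] <- base * exp(0.7 * sin(i * c(1, 2, 3)))
  }
  starts[seq_len(n_starts)]
}

#' Maximum-likelihood fit of the EIGo distribution
#'
#' Maximizes the Type-II censored log-likelihood by quasi-Newton (BFGS with
#' the analytic score) on log-parameters, which enforces positivity without
#' constraints.  Several starting points (quantile-matched initials plus a
#' scrambled grid) are tried and the best local optimum is kept.  The
#' variance-covariance matrix is the inverse observed information
#' ([eigo_observed_info()]) at the optimum.
#'
#' When `defective = TRUE` the scale parameter is optimized over the whole
#' real line: on the negative branch the same likelihood expressions describe
#' a defective lifetime model with positive mass at zero, the inverse
#' analogue of the Gompertz distribution with negative shape.  This is the
#' convention under which Gompertz-type models are conventionally compared to
#' other families when the data favour the defective branch; the default
#' keeps the proper (positive-scale) model.
#'
#' @inheritParams eigo_loglik
#' @param n_starts number of optimizer starts (per branch).
#' @param defective logical; also search the negative-scale (defective)
#'   branch and return the better optimum.
#' @param control passed to [stats::optim()] (maxit defaults to 1000,
#'   reltol 1e-12).
#' @return an object of class `"eigo_mle"`: a list with `params` (named
#'   estimate vector; `theta < 0` flags the defective branch), `loglik`,
#'   `ncl` (negative log-likelihood), `vcov`, `se`, `converged`, `n_starts`,
#'   `defective`, `score` at the optimum and the `sample`.
#' @examples
#' fit <- eigo_mle(eigo_data("yarn"))
#' coef(fit)
#' @export
eigo_mle <- function(sample, n_starts = 12L, defective = FALSE,
                     control = list()) {
  sample <- as_type2(sample)
  if (sample$m < 3L) {
    warning("fewer than 3 observed failures: 3-parameter fit is under-identified")
  }
  control <- utils::modifyList(list(maxit = 1000L, reltol = 1e-12), control)
  best <- NULL
  ok <- 0L
  for (sgn in if (defective) c(1, -1) else 1) {
    # log-parameterization per branch: theta = sgn * exp(lp[3])
    nll <- function(lp) -eigo_loglik(sample, exp(lp) * c(1, 1, sgn))
    gr <- function(lp) -eigo_score(sample, exp(lp) * c(1, 1, sgn)) * exp(lp) * c(1, 1, sgn)
    for (s in mle_starts(sample, n_starts, sign = sgn)) {
      res <- tryCatch(
        stats::optim(log(abs(s)), nll, gr, method = "BFGS", control = control),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$value)) next
      ok <- ok + 1L
      res$sgn <- sgn
      if (is.null(best) || res$value < best$value) best <- res
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  params <- stats::setNames(exp(best$par) * c(1, 1, best$sgn),
                            c("alpha", "beta", "theta"))
  info <- eigo_observed_info(sample, params)
  vc <- attr(info, "inverse")
  sc <- eigo_score(sample, params)
  scale <- pmax(1, abs(params))
  structure(list(
    params = params,
    loglik = -best$value,
    ncl = best$value,
    vcov = vc,
    se = sqrt(pmax(diag(vc), 0)),
    converged = best$convergence == 0 && max(abs(sc * scale)) < 1e-2,
    n_starts = ok,
    defective = params[["theta"]] < 0,
    score = sc,
    sample = sample
  ), class = "eigo_mle")
}

#' @export
print.eigo_mle <- function(x, ...) {
  cat("EIGo maximum-likelihood fit (Type-II censored likelihood)\n")
  cat(sprintf("  m = %d of n = %d; log-likelihood = %.4f (NCL = %.4f)\n",
              x$sample$m, x$sample$n, x$loglik, x$ncl))
  tab <- cbind(estimate = x$params, se = x$se)
  print(signif(tab, 6))
  if (isTRUE(x$defective)) {
    cat("  note: negative-scale (defective) branch; mass at zero =",
        signif(1 - (1 - exp(x$params[["beta"]] / x$params[["theta"]]))^x$params[["alpha"]], 3), "\n")
  }
  if (!x$converged) cat("  warning: optimizer did not report clean convergence\n")
  invisible(x)
}

#' @export
coef.eigo_mle <- function(object, ...) object$params

#' @export
vcov.eigo_mle <- function(object, ...) object$vcov

#' @export
logLik.eigo_mle <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$sample$m, class = "logLik")
}

#' Observed information matrix of the Type-II censored EIGo likelihood
#'
#' Negative Hessian of the log-likelihood, obtained by central differences of
#' the analytic score (one analytic differentiation layer keeps the numerical
#' noise down); step `1e-5 * max(1, |param|)` per coordinate.  The result is
#' symmetrized.  Its inverse (attribute `"inverse"`) is the asymptotic
#' variance-covariance estimate of the MLEs; if the matrix is singular a
#' pseudo-inverse is used with a warning.
#'
#' @inheritParams eigo_loglik
#' @return 3x3 matrix with attribute `"inverse"`.
#' @export
eigo_observed_info <- function(sample, params) {
  sample <- as_type2(sample)
  p <- as.numeric(check_fit_params(params))
  H <- matrix(0, 3, 3)
  for (i in 1:3) {
    h <- 1e-5 * max(1, abs(p[i]))
    up <- dn <- p
    up[i] <- p[i] + h
    dn[i] <- p[i] - h
    H[i, ] <- (eigo_score(sample, up) - eigo_score(sample, dn)) / (2 * h)
  }
  info <- -(H + t(H)) / 2
  dimnames(info) <- list(c("alpha", "beta", "theta"), c("alpha", "beta", "theta"))
  inv <- tryCatch(solve(info), error = function(e) {
    warning("observed information is singular; using pseudo-inverse")
    MASS::ginv(info)
  })
  dimnames(inv) <- dimnames(info)
  attr(info, "inverse") <- inv
  info
}

#' Wald confidence intervals for an EIGo fit
#'
#' Normal-theory intervals `estimate -/+ z * se` per parameter.  Lower
#' bounds below 0 are clipped to 0 (the parameters are positive) and flagged
#' in the `clipped` column.
#'
#' @param fit an [eigo_mle()] object.
#' @param level confidence level in (0, 1).
#' @return matrix with columns `lower`, `upper`, `clipped`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  if (!inherits(fit, "eigo_mle")) stop("'fit' must be an eigo_mle object")
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- fit$params - z * fit$se
  upper <- fit$params + z * fit$se
  clipped <- lower < 0 & fit$params > 0   # positive parameters only
  lower[clipped] <- 0
  cbind(lower = lower, upper = upper, clipped = as.numeric(clipped))
}

#' @export
confint.eigo_mle <- function(object, parm, level = 0.95, ...) {
  ci <- wald_ci(object, level)[, c("lower", "upper"), drop = FALSE]
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
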