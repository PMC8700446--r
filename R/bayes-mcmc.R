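#' Independent gamma priors for the EIGo parameters
#'
#' The three parameters get independent Gamma(a_i, b_i) priors (shape/rate).
#' Zero hyper-parameters are accepted as the documented improper limit:
#' the prior kernel is always \eqn{p^{a-1} e^{-bp}}, so `a = 0, b = 0` means
#' \eqn{\pi(p) \propto 1/p} and `a = 1, b -> 0` approaches a flat prior.
#'
#' @param a,b numeric vectors of length 3 (shapes and rates for alpha, beta,
#'   theta), all entries non-negative.
#' @return an object of class `"eigo_prior"`.
#' @examples
#' eigo_prior(a = c(1.0, 0.2, 0.2), b = c(2, 2, 2))
#' @export
eigo_prior <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 3L || length(b) != 3L ||
      anyNA(a) || anyNA(b) || any(a < 0) || any(b < 0)) {
    stop("'a' and 'b' must be non-negative numeric vectors of length 3")
  }
  improper <- any(a == 0 | b == 0)
  if (improper) warning("zero hyper-parameters: improper prior limit in use")
  structure(list(a = stats::setNames(as.numeric(a), c("alpha", "beta", "theta")),
                 b = stats::setNames(as.numeric(b), c("alpha", "beta", "theta")),
                 improper = improper),
            class = "eigo_prior")
}

#' Elicit gamma hyper-parameters from a prior mean and variance
#'
#' Maps a desired prior mean \eqn{\mu} and variance \eqn{v} to the
#' shape/rate pair \eqn{(a, b) = (\mu^2/v, \mu/v)}.
#'
#' @param mean,var positive prior mean(s) and variance(s), recycled.
#' @return list with components `a` and `b`.
#' @examples
#' elicit_gamma_prior(0.5, 0.25)   # a = 1, b = 2
#' @export
elicit_gamma_prior <- function(mean, var) {
  stop_if_not_positive(mean, "mean")
  stop_if_not_positive(var, "var")
  list(a = mean^2 / var, b = mean / var)
}

#' Exact gamma full conditional of the shape parameter alpha
#'
#' Given (beta, theta), alpha's full conditional under its gamma prior is
#' Gamma with shape `m + a1` and rate
#' \deqn{b_1^* = b_1 - (n-m)\log(1 - e^{-\zeta_m})
#'   - \sum_i \log(1 - e^{-\zeta_i}),}
#' which always exceeds `b1` since each log term is negative.
#'
#' @inheritParams eigo_loglik
#' @param beta,theta current values of the other two parameters.
#' @param prior an [eigo_prior()] object.
#' @return list with elements `shape` and `rate`.
#' @export
eigo_alpha_conditional <- function(sample, beta, theta, prior) {
  sample <- as_type2(sample)
  stopifnot(inherits(prior, "eigo_prior"))
  stop_if_not_positive(beta, "beta")
  stop_if_not_positive(theta, "theta")
  x <- sample$times
  L <- log1mexp(beta / theta * expm1(theta / x))
  list(shape = sample$m + prior$a[["alpha"]],
       rate = prior$b[["alpha"]] - (sample$n - sample$m) * L[sample$m] - sum(L))
}

#' Joint log-posterior kernel of the EIGo parameters
#'
#' [eigo_loglik()] plus the log gamma-prior kernel
#' \eqn{\sum_i (a_i - 1)\log p_i - b_i p_i}, normalizing constants dropped.
#' Non-finite values map to `-Inf`.
#'
#' @inheritParams eigo_loglik
#' @param prior an [eigo_prior()] object.
#' @export
eigo_log_posterior <- function(sample, params, prior) {
  stopifnot(inherits(prior, "eigo_prior"))
  p <- as_eigo_params(params)
  lp <- eigo_loglik(sample, p) +
    sum((prior$a - 1) * log(p) - prior$b * p)
  if (!is.finite(lp)) -Inf else lp
}

#' Gibbs-within-Metropolis-Hastings sampler for the EIGo posterior
#'
#' Per sweep: alpha is drawn exactly from its gamma full conditional
#' ([eigo_alpha_conditional()]); beta and then theta are updated by
#' Metropolis-Hastings with normal random-walk proposals centred at the
#' current value, acceptance computed in log space from the joint posterior
#' kernel, and non-positive proposals rejected outright (the target density
#' is zero there).
#'
#' Proposal standard deviations default to adaptive scaling during burn-in:
#' every 50 sweeps the SD is rescaled by `exp(1.5 * (rate - 0.234))` (capped
#' at a factor 2 per window), targeting the classical 23.4\% random-walk
#' acceptance rate, then frozen at the end of burn-in so the retained chain
#' is a genuine Markov chain.  Fixed SDs can be supplied instead.
#'
#' @inheritParams eigo_log_posterior
#' @param iter total sweeps `M` (default 12000).
#' @param burnin sweeps discarded `M0 < M` (default 2000).
#' @param proposal_sd `NULL` for adaptive tuning, or positive numeric of
#'   length 2 (SDs for beta and theta).
#' @param inits starting values; default the MLE of the sample.
#' @param seed optional integer seed set before sampling.
#' @return an object of class `"eigo_chain"`: list with `draws` (an `iter` x 3
#'   matrix), `burnin`, `accept_rate` (post-burn-in, for beta and theta),
#'   `proposal_sd` (final), `prior` and `inits`.
#' @export
eigo_gibbs <- function(sample, prior, iter = 12000L, burnin = 2000L,
                       proposal_sd = NULL, inits = NULL, seed = NULL) {
  sample <- as_type2(sample)
  stopifnot(inherits(prior, "eigo_prior"))
  if (!is.null(seed)) set.seed(seed)
  if (iter <= burnin || burnin < 0) stop("need 0 <= burnin < iter")
  if (is.null(inits)) {
    inits <- eigo_mle(sample)$params
    if (inits[["theta"]] < 0) inits[["theta"]] <- abs(inits[["theta"]])
  }
  inits <- as_eigo_params(inits)
  adaptive <- is.null(proposal_sd)
  sd_bt <- if (adaptive) pmax(0.25 * abs(inits[c("beta", "theta")]), 1e-3)
           else {
             stop_if_not_positive(proposal_sd, "proposal_sd")
             if (length(proposal_sd) != 2L) stop("'proposal_sd' must have length 2")
             proposal_sd
           }

  x <- sample$times; n <- sample$n; m <- sample$m
  sxi <- sum(1 / x); slx <- sum(log(x))
  a <- prior$a; b <- prior$b

  # log-likelihood pieces as functions of the cached zeta vector
  zfun <- function(beta, theta) beta / theta * expm1(theta / x)
  # full log posterior kernel given cached sums
  lp_kernel <- function(alpha, beta, theta, z, L) {
    m * log(alpha * beta) + theta * sxi - 2 * slx - sum(z) +
      (alpha - 1) * sum(L) + alpha * (n - m) * L[m] +
      sum((a - 1) * log(c(alpha, beta, theta)) - b * c(alpha, beta, theta))
  }

  draws <- matrix(NA_real_, iter, 3L,
                  dimnames = list(NULL, c("alpha", "beta", "theta")))
  beta <- inits[["beta"]]; theta <- inits[["theta"]]
  z <- zfun(beta, theta); L <- log1mexp(z)
  acc <- c(beta = 0L, theta = 0L)          # post-burn-in acceptance counts
  acc_win <- c(beta = 0L, theta = 0L)      # adaptation window counts

  for (j in seq_len(iter)) {
    # Gibbs step: exact gamma conditional of alpha
    rate <- b[["alpha"]] - (n - m) * L[m] - sum(L)
    alpha <- stats::rgamma(1L, shape = m + a[["alpha"]], rate = rate)
    lp_cur <- lp_kernel(alpha, beta, theta, z, L)

    # M-H step for beta: zeta is linear in beta, no new exp needed
    bstar <- beta + stats::rnorm(1L, 0, sd_bt[1L])
    if (bstar > 0) {
      zs <- z * (bstar / beta); Ls <- log1mexp(zs)
      lp_new <- lp_kernel(alpha, bstar, theta, zs, Ls)
      if (log(stats::runif(1L)) <= lp_new - lp_cur) {
        beta <- bstar; z <- zs; L <- Ls; lp_cur <- lp_new
        if (j > burnin) acc[1L] <- acc[1L] + 1L else acc_win[1L] <- acc_win[1L] + 1L
      }
    }

    # M-H step for theta
    tstar <- theta + stats::rnorm(1L, 0, sd_bt[2L])
    if (tstar > 0) {
      zs <- zfun(beta, tstar); Ls <- log1mexp(zs)
      lp_new <- lp_kernel(alpha, beta, tstar, zs, Ls)
      if (log(stats::runif(1L)) <= lp_new - lp_cur) {
        theta <- tstar; z <- zs; L <- Ls
        if (j > burnin) acc[2L] <- acc[2L] + 1L else acc_win[2L] <- acc_win[2L] + 1L
      }
    }

    draws[j, ] <- c(alpha, beta, theta)

    if (adaptive && j <= burnin && j %% 50L == 0L) {
      sd_bt <- sd_bt * pmin(2, pmax(0.5, exp(1.5 * (acc_win / 50 - 0.234))))
      acc_win[] <- 0L
    }
  }

  rate_post <- acc / (iter - burnin)
  if (any(rate_post == 0)) {
    warning("zero post-burn-in acceptance for ",
            paste(names(rate_post)[rate_post == 0], collapse = ", "),
            ": chain is not moving")
  }
  structure(list(draws = draws, burnin = as.integer(burnin),
                 accept_rate = rate_post, proposal_sd = sd_bt,
                 prior = prior, inits = inits),
            class = "eigo_chain")
}

#' @export
print.eigo_chain <- function(x, ...) {
  cat(sprintf("EIGo posterior chain: %d sweeps (%d burn-in)\n",
              nrow(x$draws), x$burnin))
  cat(sprintf("  M-H acceptance: beta %.3f, theta %.3f (proposal SDs %.4g, %.4g)\n",
              x$accept_rate[["beta"]], x$accept_rate[["theta"]],
              x$proposal_sd[1L], x$proposal_sd[2L]))
  print(signif(bayes_estimates(x)$estimate, 5))
  invisible(x)
}

#' @export
summary.eigo_chain <- function(object, credible_level = 0.95, ...) {
  bayes_estimates(object, credible_level)
}

#' Posterior point estimates and credible intervals from a chain
#'
#' The squared-error-loss Bayes estimate is the mean of the post-burn-in
#' draws per coordinate.  The `100(1-gamma)%` credible interval takes the
#' empirical `gamma/2` and `1-gamma/2` order statistics of the sorted
#' retained draws, so the endpoints are elements of the chain.
#'
#' @param chain an [eigo_gibbs()] chain.
#' @param credible_level interval coverage (default 0.95).
#' @return list with `estimate` (named vector), `ci` (3 x 2 matrix) and
#'   `retained` (number of draws used).
#' @export
bayes_estimates <- function(chain, credible_level = 0.95) {
  stopifnot(inherits(chain, "eigo_chain"))
  if (credible_level <= 0 || credible_level >= 1) stop("'credible_level' must be in (0,1)")
  keep <- chain$draws[(chain$burnin + 1L):nrow(chain$draws), , drop = FALSE]
  k <- nrow(keep)
  if (k < 1L) stop("no post-burn-in draws")
  gam <- 1 - credible_level
  ilo <- max(1L, round(k * gam / 2))
  ihi <- min(k, round(k * (1 - gam / 2)))
  ci <- t(apply(keep, 2L, function(v) sort(v)[c(ilo, ihi)]))
  colnames(ci) <- c("lower", "upper")
  list(estimate = colMeans(keep), ci = ci, retained = k)
}
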