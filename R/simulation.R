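# Monte-Carlo evaluation of the Type-II censored estimators: generate
# censored EIGo samples, apply the maximum-likelihood and/or Bayes
# estimators, and summarize by average estimate, RMSE, relative absolute
# bias, and average interval length.

#' Simulate a Type-II censored EIGo sample
#'
#' Draws `n` iid EIGo lifetimes by inverse transform, sorts them, and retains
#' the `m` smallest (the life test stops at the m-th failure).
#'
#' @param truth parameter triple (alpha, beta, theta).
#' @param n total units on test.
#' @param m failures observed, `1 <= m <= n`.
#' @param seed optional integer seed.
#' @return an [eigo_type2()] sample.
#' @export
simulate_type2 <- function(truth, n, m = n, seed = NULL) {
  p <- as_eigo_params(truth)
  if (m < 1 || m > n) stop("need 1 <= m <= n")
  if (!is.null(seed)) set.seed(seed)
  x <- reigo(n, p[["alpha"]], p[["beta"]], p[["theta"]])
  eigo_type2(sort(x)[seq_len(m)], n = n)
}

#' Summarize a matrix of estimates against the truth
#'
#' For each parameter: average \eqn{\bar\phi = S^{-1}\sum\hat\phi_i}, root
#' mean squared error \eqn{\sqrt{S^{-1}\sum(\hat\phi_i - \phi)^2}} and
#' relative absolute bias \eqn{S^{-1}\sum|\hat\phi_i - \phi|/\phi}.
#'
#' @param estimates an S x 3 matrix of parameter estimates (columns alpha,
#'   beta, theta).
#' @param truth the true parameter triple.
#' @return data.frame with columns `parameter`, `truth`, `average`, `rmse`,
#'   `rab`.
#' @export
estimate_metrics <- function(estimates, truth) {
  p <- as_eigo_params(truth)
  estimates <- as.matrix(estimates)
  if (ncol(estimates) != 3L || nrow(estimates) < 1L) {
    stop("'estimates' must be an S x 3 matrix")
  }
  data.frame(
    parameter = c("alpha", "beta", "theta"),
    truth = as.numeric(p),
    average = colMeans(estimates),
    rmse = sqrt(colMeans(sweep(estimates, 2L, p)^2)),
    rab = colMeans(abs(sweep(estimates, 2L, p))) / as.numeric(p),
    row.names = NULL
  )
}

#' Average confidence length
#'
#' Mean width of a collection of intervals; errors on crossed bounds.
#'
#' @param lower,upper numeric vectors of interval endpoints.
#' @return the mean of `upper - lower`.
#' @export
interval_length <- function(lower, upper) {
  if (length(lower) != length(upper)) stop("bound vectors differ in length")
  if (any(upper < lower)) stop("crossed interval bounds")
  mean(upper - lower)
}

# Counter-based per-replicate seed: independent, individually replayable,
# and kept below 2^31 - 1.
replicate_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * as.double(i)) %% 2147483647)
}

#' Monte-Carlo study of the EIGo estimators for one scenario
#'
#' Runs `reps` independent replicates of: simulate a Type-II censored sample
#' of `m` failures out of `n` from `truth`, fit by maximum likelihood (Wald
#' intervals), and optionally by the Gibbs-within-M-H Bayes sampler (credible
#' intervals).  Replicates use counter-derived seeds so any single replicate
#' can be replayed.  Failed replicates are dropped and counted; if more than
#' 20\% fail the summary is flagged unreliable.
#'
#' @param truth true parameter triple.
#' @param n,m sample size and observed failures per replicate.
#' @param reps number of MLE replicates.
#' @param methods subset of `c("mle", "bayes")`.
#' @param prior an [eigo_prior()]; required for the Bayes method.
#' @param mcmc list of [eigo_gibbs()] settings (`iter`, `burnin`).
#' @param bayes_reps number of Bayes replicates (defaults to `reps`; the
#'   Bayes arm is far more expensive, so smaller values are common and the
#'   scale-down is recorded in the summary).
#' @param level confidence/credible level for interval-length summaries.
#' @param seed scenario seed, an integer.
#' @return an object of class `"eigo_sim"`: list with `metrics` (one
#'   data.frame per method), `acl` (average interval lengths), `failed`
#'   (failure counts), `unreliable` flag and the scenario settings.
#' @export
run_scenario <- function(truth, n, m = n, reps = 1000L,
                         methods = "mle", prior = NULL, mcmc = list(),
                         bayes_reps = reps, level = 0.95, seed = 1L) {
  p <- as_eigo_params(truth)
  methods <- match.arg(methods, c("mle", "bayes"), several.ok = TRUE)
  if ("bayes" %in% methods && is.null(prior)) {
    stop("the Bayes method needs a 'prior'")
  }
  mcmc <- utils::modifyList(list(iter = 12000L, burnin = 2000L), mcmc)

  metrics <- list(); acl <- list(); failed <- c()

  if ("mle" %in% methods) {
    est <- matrix(NA_real_, reps, 3L)
    wid <- matrix(NA_real_, reps, 3L)
    for (i in seq_len(reps)) {
      s <- simulate_type2(p, n, m, seed = replicate_seed(seed, i))
      fit <- tryCatch(eigo_mle(s, n_starts = 6L), error = function(e) NULL)
      if (is.null(fit)) next
      est[i, ] <- fit$params
      ci <- wald_ci(fit, level)
      wid[i, ] <- ci[, "upper"] - ci[, "lower"]
    }
    ok <- stats::complete.cases(est)
    failed["mle"] <- sum(!ok)
    metrics$mle <- estimate_metrics(est[ok, , drop = FALSE], p)
    acl$mle <- colMeans(wid[ok, , drop = FALSE])
  }

  if ("bayes" %in% methods) {
    est <- matrix(NA_real_, bayes_reps, 3L)
    wid <- matrix(NA_real_, bayes_reps, 3L)
    for (i in seq_len(bayes_reps)) {
      s <- simulate_type2(p, n, m, seed = replicate_seed(seed, i))
      res <- tryCatch({
        ch <- eigo_gibbs(s, prior, iter = mcmc$iter, burnin = mcmc$burnin)
        bayes_estimates(ch, level)
      }, error = function(e) NULL)
      if (is.null(res)) next
      est[i, ] <- res$estimate
      wid[i, ] <- res$ci[, "upper"] - res$ci[, "lower"]
    }
    ok <- stats::complete.cases(est)
    failed["bayes"] <- sum(!ok)
    metrics$bayes <- estimate_metrics(est[ok, , drop = FALSE], p)
    acl$bayes <- colMeans(wid[ok, , drop = FALSE])
  }

  total <- c(mle = reps, bayes = bayes_reps)[names(failed)]
  structure(list(
    metrics = metrics, acl = acl, failed = failed,
    unreliable = any(failed / total > 0.2),
    truth = p, n = n, m = m, reps = reps, bayes_reps = bayes_reps,
    level = level, seed = seed, methods = methods
  ), class = "eigo_sim")
}

#' @export
print.eigo_sim <- function(x, ...) {
  cat(sprintf("EIGo Monte-Carlo scenario: truth (%g, %g, %g), n = %d, m = %d\n",
              x$truth[1L], x$truth[2L], x$truth[3L], x$n, x$m))
  for (meth in names(x$metrics)) {
    reps <- if (meth == "bayes") x$bayes_reps else x$reps
    cat(sprintf("-- %s (%d replicates, %d failed)\n", toupper(meth), reps,
                x$failed[[meth]]))
    print(cbind(signif(x$metrics[[meth]][-1L], 4),
                acl = signif(x$acl[[meth]], 4)))
  }
  if (x$unreliable) cat("WARNING: > 20% replicate failures; summary unreliable\n")
  invisible(x)
}
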