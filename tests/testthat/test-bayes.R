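# Gamma priors, posterior kernel, Gibbs-within-M-H sampler, Bayes summaries.

prior1 <- eigo_prior(a = c(1.0, 0.2, 0.2), b = c(2, 2, 2))

test_that("prior constructor validates and flags improper limits", {
  expect_s3_class(prior1, "eigo_prior")
  expect_false(prior1$improper)
  expect_warning(pr0 <- eigo_prior(c(0, 1, 1), c(0, 1, 1)), "improper")
  expect_true(pr0$improper)
  expect_error(eigo_prior(c(-1, 1, 1), c(1, 1, 1)), "non-negative")
  # elicitation helper: mean 0.5, variance 0.25 -> Gamma(1, 2)
  h <- elicit_gamma_prior(0.5, 0.25)
  expect_equal(h$a, 1); expect_equal(h$b, 2)
})

test_that("alpha full conditional matches its closed form", {
  s <- eigo_type2(c(1, 2, 3))
  pr <- eigo_prior(a = c(1.5, 1, 1), b = c(2, 1, 1))
  cond <- eigo_alpha_conditional(s, beta = 1, theta = 1, prior = pr)
  expect_equal(cond$shape, 3 + 1.5)
  z <- (exp(1 / c(1, 2, 3)) - 1)            # beta = theta = 1
  expect_equal(cond$rate, 2 - sum(log(1 - exp(-z))), tolerance = 1e-12)
  expect_gte(cond$rate, 2)                  # rate >= b1 always
  # censored case: the censoring term enters through the largest time
  sc <- eigo_type2(c(1, 2, 3), n = 5)
  cond2 <- eigo_alpha_conditional(sc, 1, 1, pr)
  expect_equal(cond2$rate, cond$rate - 2 * log(1 - exp(-z[3])),
               tolerance = 1e-12)
})

test_that("log-posterior is likelihood plus gamma prior kernel", {
  s <- eigo_type2(c(0.5, 1.2, 2.0, 3.1))
  pr <- eigo_prior(a = c(2, 1, 1), b = c(2, 2, 2))
  p1 <- c(1.2, 0.8, 0.6); p2 <- c(0.9, 1.1, 0.4)
  lp_ref <- function(p) {
    eigo_loglik(s, p) + sum((pr$a - 1) * log(p) - pr$b * p)
  }
  expect_equal(eigo_log_posterior(s, p1, pr) - eigo_log_posterior(s, p2, pr),
               lp_ref(p1) - lp_ref(p2), tolerance = 1e-12)
  # flat-prior limit: posterior kernel equals the likelihood kernel
  flat <- suppressWarnings(eigo_prior(a = c(1, 1, 1), b = rep(1e-12, 3)))
  expect_equal(eigo_log_posterior(s, p1, flat), eigo_loglik(s, p1),
               tolerance = 1e-8)
  expect_true(is.finite(eigo_log_posterior(eigo_type2(yarn),
                                           c(5.89, 418.7, 70.4), pr)))
})

test_that("chains are reproducible and mix at sensible acceptance rates", {
  set.seed(31)
  s <- simulate_type2(c(0.5, 0.1, 0.1), 40, 40)
  ch1 <- eigo_gibbs(s, prior1, iter = 3000, burnin = 1000, seed = 7)
  ch2 <- eigo_gibbs(s, prior1, iter = 3000, burnin = 1000, seed = 7)
  expect_identical(ch1$draws, ch2$draws)
  expect_true(all(ch1$draws > 0))
  ch <- eigo_gibbs(s, prior1, iter = 12000, burnin = 2000, seed = 8)
  expect_gt(ch$accept_rate[["beta"]], 0.15)
  expect_lt(ch$accept_rate[["beta"]], 0.40)
  expect_gt(ch$accept_rate[["theta"]], 0.15)
  expect_lt(ch$accept_rate[["theta"]], 0.40)
})

test_that("with beta and theta frozen, alpha draws follow the gamma conditional", {
  set.seed(32)
  s <- simulate_type2(c(1, 0.5, 0.5), 30, 30)
  inits <- c(1, 0.5, 0.5)
  # vanishingly small proposal SDs freeze beta and theta at their initials
  ch <- suppressWarnings(eigo_gibbs(s, prior1, iter = 10000, burnin = 0,
                                    proposal_sd = c(1e-14, 1e-14),
                                    inits = inits, seed = 9))
  cond <- eigo_alpha_conditional(s, inits[2], inits[3], prior1)
  ks <- suppressWarnings(ks.test(ch$draws[, "alpha"], "pgamma",
                                 shape = cond$shape, rate = cond$rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior mean matches an independent quadrature oracle", {
  # tiny sample: alpha integrates out analytically, leaving a 2-D integral
  x <- c(0.3, 0.5, 0.8); m <- 3
  a <- prior1$a; b <- prior1$b
  logker <- function(bb, tt) {
    z <- bb / tt * (exp(tt / x) - 1); L <- log(1 - exp(-z))
    -(m + a[1]) * log(b[1] - sum(L)) + (m + a[2] - 1) * log(bb) - b[2] * bb +
      (a[3] - 1) * log(tt) - tt * (b[3] - sum(1 / x)) - sum(z) - sum(L)
  }
  Ea_cond <- function(bb, tt) {
    z <- bb / tt * (exp(tt / x) - 1)
    (m + a[1]) / (b[1] - sum(log(1 - exp(-z))))
  }
  lb <- seq(log(1e-4), log(60), length.out = 220)
  lt <- seq(log(1e-6), log(40), length.out = 220)
  W <- exp(outer(lb, lt, Vectorize(function(u, v) logker(exp(u), exp(v)) + u + v)))
  EA <- outer(lb, lt, Vectorize(function(u, v) Ea_cond(exp(u), exp(v))))
  oracle <- sum(W * EA) / sum(W)
  ch <- eigo_gibbs(eigo_type2(x), prior1, iter = 120000, burnin = 10000,
                   seed = 10, inits = c(1, 1, 0.5))
  est <- bayes_estimates(ch)$estimate
  expect_equal(est[["alpha"]], oracle, tolerance = 0.02)
})

test_that("a near-degenerate prior dominates a tiny sample", {
  mu <- c(2, 1, 1)
  strong <- eigo_prior(a = rep(1e4, 3), b = 1e4 / mu)  # mean mu, sd mu/100
  set.seed(33)
  s <- simulate_type2(c(1, 1, 1), 5, 5)
  ch <- eigo_gibbs(s, strong, iter = 8000, burnin = 2000, seed = 11,
                   inits = mu)
  est <- bayes_estimates(ch)$estimate
  expect_equal(unname(est), mu, tolerance = 0.02)
})

test_that("bayes_estimates: means, order-statistic intervals, degenerate chains", {
  const <- structure(list(
    draws = matrix(rep(c(2, 1, 0.5), each = 100), 100, 3,
                   dimnames = list(NULL, c("alpha", "beta", "theta"))),
    burnin = 10L), class = "eigo_chain")
  est <- bayes_estimates(const)
  expect_equal(unname(est$estimate), c(2, 1, 0.5))
  expect_equal(unname(est$ci[, "lower"]), c(2, 1, 0.5))
  expect_equal(unname(est$ci[, "upper"]), c(2, 1, 0.5))
  # endpoints are elements of the retained draws
  set.seed(34)
  s <- simulate_type2(c(1, 0.5, 0.5), 20, 20)
  ch <- eigo_gibbs(s, prior1, iter = 2000, burnin = 500, seed = 12)
  est <- bayes_estimates(ch, 0.9)
  kept <- ch$draws[501:2000, ]
  for (j in 1:3) {
    expect_true(est$ci[j, "lower"] %in% kept[, j])
    expect_true(est$ci[j, "upper"] %in% kept[, j])
  }
  expect_error(bayes_estimates(ch, 1.5), "credible_level")
})

test_that("credible intervals narrow as the sample grows", {
  width <- function(n, seed) {
    s <- simulate_type2(c(0.5, 0.1, 0.1), n, n, seed = seed)
    ch <- eigo_gibbs(s, prior1, iter = 6000, burnin = 1500, seed = seed)
    ci <- bayes_estimates(ch)$ci
    ci[, "upper"] - ci[, "lower"]
  }
  w40 <- rowMeans(vapply(1:4, function(k) width(40, 400 + k), numeric(3)))
  w80 <- rowMeans(vapply(1:4, function(k) width(80, 800 + k), numeric(3)))
  expect_true(all(w80 < w40))
})

test_that("posterior means recover the truth at n = 80 under its matched prior", {
  prA <- eigo_prior(a = c(2, 1, 1), b = c(2, 2, 2))   # means (1, 0.5, 0.5)
  set.seed(35)
  ests <- vapply(1:8, function(k) {
    s <- simulate_type2(c(1, 0.5, 0.5), 80, 80, seed = 5000 + k)
    bayes_estimates(eigo_gibbs(s, prA, iter = 6000, burnin = 1500,
                               seed = 6000 + k))$estimate
  }, numeric(3))
  expect_equal(mean(ests["alpha", ]), 1.0, tolerance = 0.2)
  expect_equal(mean(ests["beta", ]), 0.5, tolerance = 0.25)
  expect_equal(mean(ests["theta", ]), 0.5, tolerance = 0.25)
})
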