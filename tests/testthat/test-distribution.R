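# Density, distribution, quantile, random generation, hazards and mode.

test_that("zeta matches its closed form and limits", {
  expect_equal(eigo_zeta(1, 1, 1), exp(1) - 1, tolerance = 1e-12)
  expect_lt(eigo_zeta(1e12, 2, 3), 1e-10)                 # -> 0 as x -> Inf
  expect_gt(eigo_zeta(1e-3, 1, 1), 1e100)                 # -> Inf as x -> 0+
  x <- exp(seq(-2, 4, length.out = 30))
  expect_true(all(diff(eigo_zeta(x, 2, 0.5)) < 0))        # strictly decreasing
  # theta -> 0 limit is beta / x (the generalized inverted-exponential rate)
  expect_equal(eigo_zeta(2.5, 3, 1e-10), 3 / 2.5, tolerance = 1e-8)
  expect_error(eigo_zeta(0, 1, 1), "positive")
  expect_error(eigo_zeta(-1, 1, 1), "positive")
})

test_that("density and distribution match direct substitution", {
  # x = 1, (2, 1, 1): written out by hand from the closed form
  z <- exp(1) - 1
  expect_equal(deigo(1, 2, 1, 1), 2 * exp(1 - z) * (1 - exp(-z)),
               tolerance = 1e-12)
  expect_equal(peigo(1, 2, 1, 1), 1 - (1 - exp(-z))^2, tolerance = 1e-12)
  # independent reference implementation across the parameter grid
  x <- c(0.05, 0.3, 1, 4, 20)
  for (i in seq_len(nrow(param_grid))) {
    p <- param_grid[i, ]
    expect_equal(deigo(x, p$alpha, p$beta, p$theta),
                 ref_pdf(x, p$alpha, p$beta, p$theta), tolerance = 1e-9)
    # the naive reference loses a digit to cancellation when F is ~1e-8
    expect_equal(peigo(x, p$alpha, p$beta, p$theta),
                 ref_cdf(x, p$alpha, p$beta, p$theta), tolerance = 1e-7)
  }
  expect_error(deigo(-1, 1, 1, 1), "positive")
  expect_error(deigo(1, -1, 1, 1), "positive")
})

test_that("density integrates to one across the parameter grid", {
  for (i in seq_len(nrow(param_grid))) {
    p <- param_grid[i, ]
    total <- integrate(function(x) deigo(x, p$alpha, p$beta, p$theta),
                       0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("distribution function has correct limits and conventions", {
  expect_equal(peigo(c(-1, 0), 2, 1, 1), c(0, 0))
  expect_equal(peigo(Inf, 2, 1, 1), 1)
  expect_lt(peigo(1e-4, 2, 1, 1), 1e-12)
  x <- exp(seq(-3, 5, length.out = 60))
  expect_true(all(diff(peigo(x, 0.7, 2, 0.3)) >= 0))
  # survival complements the cdf
  expect_equal(peigo(x, 2, 1, 1, lower.tail = FALSE), 1 - peigo(x, 2, 1, 1),
               tolerance = 1e-12)
})

test_that("sub-models are recovered", {
  x <- c(0.2, 0.7, 1.5, 4, 12)
  # alpha = 1: inverse-Gompertz, whose cdf is exp(-zeta)
  expect_equal(peigo(x, 1, 2, 0.5), exp(-eigo_zeta(x, 2, 0.5)),
               tolerance = 1e-12)
  # theta -> 0: generalized inverted-exponential F = 1 - (1 - e^(-b/x))^a
  expect_equal(peigo(x, 2.5, 1.5, 1e-8), 1 - (1 - exp(-1.5 / x))^2.5,
               tolerance = 1e-6)
  # both: inverse-exponential F = e^(-b/x)
  expect_equal(peigo(x, 1, 1.5, 1e-8), exp(-1.5 / x), tolerance = 1e-6)
})

test_that("quantile function inverts the cdf", {
  # median of (1,1,1): invert S = 0.5 by hand: zeta = log 2, x = 1/log(1+log 2)
  expect_equal(qeigo(0.5, 1, 1, 1), 1 / log(1 + log(2)), tolerance = 1e-12)
  expect_equal(peigo(qeigo(0.5, 1, 1, 1), 1, 1, 1), 0.5, tolerance = 1e-12)
  qs <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  for (i in seq_len(nrow(param_grid))) {
    p <- param_grid[i, ]
    expect_equal(peigo(qeigo(qs, p$alpha, p$beta, p$theta),
                       p$alpha, p$beta, p$theta), qs, tolerance = 1e-10)
  }
  # boundary behaviour (the lower tail closes only logarithmically slowly)
  expect_lt(qeigo(1e-300, 2, 1, 1), qeigo(1e-12, 2, 1, 1))
  expect_lt(qeigo(1e-12, 2, 1, 1), qeigo(0.5, 2, 1, 1))
  expect_gt(qeigo(1 - 1e-12, 2, 1, 1), 1e5)
  expect_error(qeigo(0, 1, 1, 1), "inside")
  expect_error(qeigo(1, 1, 1, 1), "inside")
  expect_error(qeigo(1.2, 1, 1, 1), "inside")
})

test_that("random generation is reproducible and distributed as the cdf", {
  expect_identical(reigo(0, 1, 1, 1), numeric(0))
  set.seed(42); a <- reigo(50, 1, 0.5, 0.5)
  set.seed(42); b <- reigo(50, 1, 0.5, 0.5)
  expect_identical(a, b)
  expect_true(all(a > 0))
  set.seed(7)
  x <- reigo(5000, 1.0, 0.5, 0.5)
  ks <- suppressWarnings(ks.test(x, function(q) peigo(q, 1.0, 0.5, 0.5)))
  expect_gt(ks$p.value, 0.01)
  expect_error(reigo(-1, 1, 1, 1), "count")
})

test_that("mode maximizes the density", {
  m <- eigo_mode(2, 1, 1)
  # brute-force grid oracle
  grid <- exp(seq(log(1e-3), log(50), length.out = 20000))
  oracle <- grid[which.max(deigo(grid, 2, 1, 1))]
  expect_equal(m, oracle, tolerance = 5e-4)
  for (i in c(1, 14, 27)) {
    p <- param_grid[i, ]
    mm <- eigo_mode(p$alpha, p$beta, p$theta)
    eps <- mm * 1e-3
    expect_lt(deigo(mm - eps, p$alpha, p$beta, p$theta),
              deigo(mm, p$alpha, p$beta, p$theta))
    expect_lt(deigo(mm + eps, p$alpha, p$beta, p$theta),
              deigo(mm, p$alpha, p$beta, p$theta))
    # stationarity of the log-density (central difference)
    h <- mm * 1e-5
    dlog <- (deigo(mm + h, p$alpha, p$beta, p$theta, log = TRUE) -
             deigo(mm - h, p$alpha, p$beta, p$theta, log = TRUE)) / (2 * h)
    expect_lt(abs(dlog * mm), 1e-4)
  }
})

test_that("hazard identities hold and the hazard is unimodal", {
  x <- exp(seq(log(0.05), log(40), length.out = 50))
  h <- eigo_hazards(x, 2, 1, 1)
  expect_equal(h$survival, 1 - peigo(x, 2, 1, 1), tolerance = 1e-12)
  expect_equal(h$cum_hazard, -log(h$survival), tolerance = 1e-12)
  expect_equal(max(abs(h$cum_hazard + log(h$survival))), 0, tolerance = 1e-12)
  expect_equal(h$hazard, deigo(x, 2, 1, 1) / h$survival, tolerance = 1e-12)
  expect_equal(h$odds, (1 - h$survival) / h$survival, tolerance = 1e-10)
  # x = 1, (2,1,1): hand-computed hazard and cumulative hazard
  z <- exp(1) - 1
  s1 <- (1 - exp(-z))^2
  expect_equal(eigo_hazards(1, 2, 1, 1)$hazard,
               2 * exp(1 - z) * (1 - exp(-z)) / s1, tolerance = 1e-10)
  # upside-down bathtub: hazard rises then falls, one sign change
  for (i in seq_len(nrow(param_grid))) {
    p <- param_grid[i, ]
    xg <- exp(seq(log(p$theta * 1e-2), log(p$theta * 1e3), length.out = 200))
    hz <- eigo_hazards(xg, p$alpha, p$beta, p$theta)$hazard
    slope <- sign(diff(hz))
    slope <- slope[slope != 0]            # ignore underflow-flat stretches
    expect_lte(sum(diff(slope) != 0), 1)
    expect_true(which.max(hz) > 1 && which.max(hz) < length(hz))
  }
})

test_that("likelihood-ratio ordering in alpha holds", {
  x <- exp(seq(-2, 4, length.out = 80))
  for (pars in list(c(3, 1, 1, 1), c(2, 0.5, 0.5, 3), c(1.2, 1.1, 2, 0.3))) {
    l1 <- deigo(x, pars[1], pars[3], pars[4], log = TRUE)
    l2 <- deigo(x, pars[2], pars[3], pars[4], log = TRUE)
    keep <- l1 > -300 & l2 > -300   # representable region: subtraction is exact
    lr <- (l1 - l2)[keep]
    expect_true(all(diff(lr) <= 1e-12))
  }
})

test_that("parameter constructor rejects invalid triples", {
  p <- eigo_params(2, 1, 1)
  expect_s3_class(p, "eigo_params")
  expect_named(p, c("alpha", "beta", "theta"))
  expect_error(eigo_params(0, 1, 1), "positive")
  expect_error(eigo_params(1, -2, 1), "positive")
  expect_error(eigo_params(1, 1, 0), "positive")
  expect_error(eigo_params(NA, 1, 1), "positive")
})
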