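# Shared fixtures and small oracles for the test suite.

yarn <- eigo_data("yarn")
equipment <- eigo_data("equipment")

# parameter grid used by normalization / property sweeps
param_grid <- expand.grid(alpha = c(0.5, 1, 3), beta = c(0.1, 1, 3),
                          theta = c(0.1, 1, 3))

# independent reference implementation of the density, written directly from
# the closed form (no shared helpers with the package internals)
ref_pdf <- function(x, a, b, t) {
  z <- (b / t) * (exp(t / x) - 1)
  a * b * x^-2 * exp(t / x - z) * (1 - exp(-z))^(a - 1)
}
ref_cdf <- function(x, a, b, t) {
  z <- (b / t) * (exp(t / x) - 1)
  1 - (1 - exp(-z))^a
}

# Monte-Carlo mean with its standard error
mc_mean <- function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))

expect_within_3se <- function(value, mc) {
  expect_lt(abs(value - mc[["mean"]]), 3 * mc[["se"]] + 1e-12)
}
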