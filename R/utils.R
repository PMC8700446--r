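# Internal numerical helpers shared across the package.

# log(1 - exp(-a)) for a > 0, stable for both small and large a.
log1mexp <- function(a) {
  out <- numeric(length(a))
  small <- a <= log(2)
  out[small] <- log(-expm1(-a[small]))
  out[!small] <- log1p(-exp(-a[!small]))
  out[a <= 0] <- -Inf
  out
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x <= 0)) {
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

#' Validated EIGo parameter triple
#'
#' Builds the named parameter vector (alpha, beta, theta) of the extended
#' inverse-Gompertz distribution.  `alpha` and `beta` are shape parameters,
#' `theta` is the scale parameter (same units as the time variable).  All
#' three must be strictly positive; construction fails otherwise.
#'
#' @param alpha,beta,theta positive scalars.
#' @return a named numeric vector of length 3 with class `"eigo_params"`.
#' @examples
#' eigo_params(2, 1, 1)
#' @export
eigo_params <- function(alpha, beta, theta) {
  stop_if_not_positive(alpha, "alpha")
  stop_if_not_positive(beta, "beta")
  stop_if_not_positive(theta, "theta")
  if (length(alpha) != 1L || length(beta) != 1L || length(theta) != 1L) {
    stop("parameters must be scalars", call. = FALSE)
  }
  structure(c(alpha = alpha, beta = beta, theta = theta),
            class = c("eigo_params", "numeric"))
}

# Coerce a length-3 numeric (named or not) to a validated parameter triple.
as_eigo_params <- function(params) {
  if (inherits(params, "eigo_params")) return(params)
  if (!is.numeric(params) || length(params) != 3L) {
    stop("'params' must be a numeric vector (alpha, beta, theta)", call. = FALSE)
  }
  if (!is.null(names(params)) && all(c("alpha", "beta", "theta") %in% names(params))) {
    params <- params[c("alpha", "beta", "theta")]
  }
  eigo_params(params[[1L]], params[[2L]], params[[3L]])
}

# Adaptive quadrature with the package-wide default tolerances.
eigo_quad <- function(f, lower, upper, rel.tol = 1e-9, abs.tol = 1e-9,
                      subdivisions = 500L) {
  stats::integrate(f, lower, upper, rel.tol = rel.tol, abs.tol = abs.tol,
                   subdivisions = subdivisions)$value
}
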