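Package: eigompertz
Title: The Extended Inverse-Gompertz Lifetime Distribution with Classical
    and Bayesian Inference under Type-II Censoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Density, distribution, quantile, random generation, hazard and
    reliability functions for the three-parameter extended inverse-Gompertz
    (EIGo) lifetime distribution, together with maximum-likelihood and
    Bayesian (Metropolis-Hastings-within-Gibbs) estimation of its parameters
    from complete or Type-II censored samples.  Includes moments, mean
    residual life, mean inactivity time, stress-strength reliability,
    probability-weighted moments, entropies and order statistics computed by
    adaptive quadrature; a Monte-Carlo harness summarising estimator bias,
    RMSE, relative absolute bias and interval length; and a suite of eleven
    competing inverted lifetime models with information-criterion and
    EDF goodness-of-fit model comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
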