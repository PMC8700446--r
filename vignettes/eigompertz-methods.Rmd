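---
title: "The extended inverse-Gompertz model: methods and design notes"
author: "eigompertz package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extended inverse-Gompertz model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigompertz)
```

## The model

The extended inverse-Gompertz (EIGo) distribution is a three-parameter
lifetime model on the positive half-line with distribution function

$$F(x) = 1 - \left\{1 - e^{-\zeta(x)}\right\}^{\alpha}, \qquad
\zeta(x) = \frac{\beta}{\theta}\left(e^{\theta/x} - 1\right),
\qquad x > 0,$$

where $\alpha, \beta > 0$ are shape parameters and $\theta > 0$ is a scale
with the units of the time variable.  It arises by applying the
exponentiation device $F = 1 - (1 - R)^\alpha$ to the inverse-Gompertz
distribution function $R(x) = e^{-\zeta(x)}$, i.e. to the law of $1/T$ for a
Gompertz-distributed $T$.  Three familiar sub-models sit inside it:
$\alpha = 1$ gives back the inverse-Gompertz; $\theta \to 0$ gives the
generalized inverted-exponential law $1 - (1 - e^{-\beta/x})^{\alpha}$; both
together give the inverse-exponential law $e^{-\beta/x}$.

Two structural facts drive most of the numerical design:

* the hazard is unimodal ("upside-down bathtub"): it rises from 0, peaks,
  and decays like $\alpha/x$;
* the right tail is heavy, $f(x) \sim \alpha\beta^{\alpha} x^{-(\alpha+1)}$,
  so $E[X^r]$ exists **only for $r < \alpha$**.  Every moment-like routine in
  the package checks this index first and returns `Inf` with an explanatory
  warning instead of a silently truncated number.

## Closed forms versus quadrature

The distribution function, density, quantile function
($x_q = \theta / \log\{1 + \theta\zeta_q/\beta\}$ with
$\zeta_q = -\log\{1 - (1-q)^{1/\alpha}\}$), hazard and cumulative hazard are
closed-form.  Everything else — moments, mean residual life, mean
inactivity times, stress–strength reliability $P(X > Z)$,
probability-weighted moments, Rényi and $\delta$-entropies, order-statistic
quantities — is computed by adaptive quadrature of its defining integral
(`stats::integrate`, relative and absolute tolerance $10^{-9}$, with the
built-in infinite-limit transform).  Formal binomial-series expansions of
these quantities exist but are not convergence-guaranteed for non-integer
$\alpha$, so they are deliberately not used.

Numerical safety: $\zeta$ is evaluated through `expm1`, and
$\log(1 - e^{-\zeta})$ through the standard `log1mexp` split, so the cdf and
log-likelihood are accurate both deep in the left tail (where $\zeta$ is
astronomically large) and far in the right tail (where $\zeta \to 0$ and the
naive expression cancels catastrophically).  The mode has no closed form and
is found by golden-section maximization of the log-density inside a bracket
located by a geometric grid; stationarity is verified and failure raises an
error rather than returning the bracket edge.

## Type-II censoring and maximum likelihood

A Type-II censored life test observes the $m$ smallest of $n$ lifetimes.
The log-likelihood kernel implemented (and reported as NCL, the negative
log-likelihood criterion) is

$$\ell = m\log(\alpha\beta) + \theta\sum x_{(i)}^{-1} - 2\sum\log x_{(i)}
 - \sum\zeta_i + (\alpha - 1)\sum\log(1 - e^{-\zeta_i})
 + \alpha(n - m)\log(1 - e^{-\zeta_m}),$$

omitting only the parameter-free combinatorial constant $\log\{n!/(n-m)!\}$,
so that for a complete sample $\ell = \sum_i \log f(x_i)$ and the usual
information-criterion identities (AIC $= 2k + 2\,$NCL and so on) hold
exactly.  The analytic score uses $\zeta'_\beta = \zeta/\beta$ and
$\zeta'_\theta = (\beta/\theta^2)\{e^{\theta/x}(\theta/x - 1) + 1\}$ and is
verified against central finite differences in the test suite.

`eigo_mle()` maximizes over log-parameters (positivity without constraints)
with BFGS and the analytic gradient, from 12 starting points: eight
quantile-matched initials (a small $\alpha$–$\theta$ grid with $\beta$
solved so the model median matches the sample median) plus deterministic
jitters.  The reported variance–covariance matrix inverts the observed
information, computed by central differences **of the analytic score**
(step $10^{-5}\max(1, |\hat\vartheta_i|)$); differentiating an analytic
gradient once is much less noisy than differentiating the likelihood twice.
Wald intervals are plain $\hat\vartheta \mp z_{\varepsilon/2}\,\mathrm{se}$;
lower bounds below zero are clipped to zero and flagged, since the
parameters are positive but the intervals are untransformed.

### The negative-scale (defective) branch

The likelihood expressions above are analytic in $\theta$ and remain valid
for $\theta < 0$, where

$$\zeta(x;\beta,-t) = \frac{\beta}{t}\left(1 - e^{-t/x}\right)$$

stays positive but **bounded** as $x \to 0$, so $F(0^+) > 0$: the model
becomes a *defective* lifetime distribution with an atom of failure mass at
zero.  This is the exact inverse-domain analogue of the Gompertz
distribution with negative shape (which is defective at $+\infty$ and is
routinely fitted in survival software, e.g. `flexsurv`).  On real data the
unrestricted-sign likelihood often prefers this branch decisively: on the
packaged equipment data the proper-model optimum is NCL $44.97$ while the
defective branch reaches $40.77$.  `eigo_mle(defective = TRUE)` searches
both branches (12 starts each) and returns the better optimum, flagging the
branch; the model-comparison battery fits the two Gompertz-type families
(IGo, EIGo) this way, which is also what makes its output line up with
published analyses of these datasets.  The default for a standalone fit
remains the proper model.

## Bayesian estimation

The three parameters carry independent Gamma$(a_i, b_i)$ (shape/rate)
priors.  The posterior kernel is the censored log-likelihood plus
$\sum_i (a_i - 1)\log\vartheta_i - b_i\vartheta_i$; hyper-parameters of zero
are accepted as the documented improper limit of that same kernel.  A
helper maps a prior mean/variance pair to $(a, b) = (\mu^2/v, \mu/v)$.

Conditional on $(\beta, \theta)$, $\alpha$ is exactly Gamma with shape
$m + a_1$ and rate
$b_1 - (n-m)\log(1 - e^{-\zeta_m}) - \sum_i \log(1 - e^{-\zeta_i})$ — every
subtracted term is negative, so the rate always exceeds $b_1$.  The sampler
(`eigo_gibbs`) therefore alternates one exact Gibbs draw for $\alpha$ with
Metropolis–Hastings random-walk updates for $\beta$ and then $\theta$
(normal proposals centred at the current value, acceptance computed in log
space from the full joint kernel, non-positive proposals rejected outright
because the target is zero there).  Defaults follow common practice for
this sampler: 12,000 sweeps with the first 2,000 discarded, and initial
values at the MLE.

The proposal standard deviations are the one genuinely free tuning choice.
The default adapts them only during burn-in — every 50 sweeps the SD is
rescaled by $\exp\{1.5(\text{rate} - 0.234)\}$, capped at a factor of 2 per
window, targeting the classical 23.4% random-walk acceptance rate — and
freezes them at the end of burn-in, so the retained draws come from a
genuine Markov chain.  Fixed SDs can be supplied instead.  Point estimates
under squared-error loss are posterior means of the retained draws;
credible intervals take the empirical $\gamma/2$ and $1 - \gamma/2$ order
statistics of the sorted retained draws, so the endpoints are elements of
the chain.

The sampler is validated two independent ways in the test suite: (i) with
$\beta, \theta$ frozen, the $\alpha$ draws pass a Kolmogorov–Smirnov test
against the closed-form gamma conditional; (ii) on a tiny complete sample,
$\alpha$ integrates out of the posterior analytically, leaving a 2-D
integral that a dense log-grid quadrature can evaluate — the chain's
posterior mean matches that oracle to under 2%.

## The Monte-Carlo harness

`run_scenario()` repeats: draw $n$ lifetimes by inverse transform, keep the
smallest $m$, estimate by maximum likelihood and/or the Bayes sampler, and
summarize with the average estimate, RMSE
$\sqrt{S^{-1}\sum(\hat\varphi - \varphi)^2}$, relative absolute bias
$S^{-1}\sum|\hat\varphi - \varphi|/\varphi$, and the average width of the
Wald or credible interval.  Per-replicate seeds are derived from the
scenario seed by a counter ($\text{seed} + 1000003\,i \bmod 2^{31}-1$) so
any replicate can be replayed on its own.  Replicates whose optimizer fails
are dropped and counted; a failure fraction above 20% flags the summary
unreliable.  The Bayes arm accepts its own (usually smaller) replicate
count, recorded in the summary: at roughly half a second per chain, 200
Bayesian replicates cost a few minutes, which is the scale used by the
shipped acceptance script, while the frequentist arm runs its full 1000
replicates in seconds.

Simulations in this package emulate iid sampling from the proper
($\theta > 0$) EIGo model under Type-II censoring — nothing more.  They do
not emulate covariates, group structure, rounding or detection limits of
real reliability data, so a passing recovery test demonstrates correctness
of the estimators under the model, not robustness to model violation.

## The competing-model battery

Eleven standard inverted families (inverse-exponential, inverse-Weibull,
generalized inverted-exponential, inverse-gamma, generalized and
exponentiated inverse-Weibull, generalized inverted half-logistic,
inverted-Kumaraswamy, inverted Nadarajah–Haghighi, alpha-power
inverse-Weibull, inverse-Gompertz) are implemented with numerically
stabilized log-densities and closed-form distribution functions, fitted by
the same multi-start log-parameter BFGS.  Three quirks deserve note:

* the exponentiated inverse-Weibull is the inverse-Weibull under a
  parameter relabelling ($[e^{-x^{-\beta}}]^{\theta} = e^{-\theta
  x^{-\beta}}$); their fitted likelihoods must tie exactly, and the test
  suite asserts it on both packaged datasets;
* the generalized inverse-Weibull as usually written,
  $\alpha\beta\theta^\beta x^{-\beta-1}e^{-\alpha(\theta/x)^\beta}$,
  confounds $\alpha$ with $\theta^\beta$; the fit profiles $\theta$ out
  (fixes it at 1), reports it without a standard error, and only the
  attained likelihood is meaningful;
* the inverse-exponential has the closed form
  $\hat\theta = n/\sum x_i^{-1}$ with $\mathrm{se} = \hat\theta/\sqrt{n}$,
  used directly.

`gof_report()` assembles NCL, AIC, corrected AIC
($\mathrm{AIC} + 2k(k+1)/(n-k-1)$), BIC and HQIC, the two-sided
Kolmogorov–Smirnov statistic with `stats::ks.test`'s p-value (exact
small-sample where available; the p-value convention of other software is
not asserted tightly anywhere), and Anderson–Darling / Cramér–von Mises
statistics in the Chen–Balakrishnan standardized form with small-sample
adjustment ($A^* = A^2(1 + 0.75/n + 2.25/n^2)$,
$W^* = W^2(1 + 0.5/n)$) — the convention of the widely used
goodness-of-fit tooling for fitted parametric models, and the one under
which published analyses of these two datasets reproduce to all printed
digits.

## Degenerate inputs, ties, tolerances

* Fewer than three observed failures leaves the three-parameter curvature
  under-identified: the fit warns and the information matrix may need the
  pseudo-inverse fallback (itself warned about).
* Tied failure times are accepted as-is; no continuity correction is
  applied, and `ks.test`'s ties warning is suppressed in the report.
* Probability-integral transforms that reach exactly 0 or 1 are clipped to
  machine margins with a warning before the EDF statistics.
* Quadrature tolerances ($10^{-9}$), the score finite-difference check
  ($10^{-5}$ relative), the quantile round-trip ($10^{-10}$) and the
  information-criterion identities ($10^{-9}$) are all asserted in the test
  suite at those levels.

## Known limitations

* The defective branch is provided for fitting and model comparison; the
  d/p/q/r functions deliberately reject $\theta \le 0$, so defective fits
  are summarized through their likelihood, information criteria and EDF
  statistics rather than through quantiles or random generation.
* Convergence diagnostics for the sampler are limited to acceptance rates
  and the exported chain; no potential-scale-reduction machinery is
  included.
* Wald intervals are untransformed and can clip at zero for small samples;
  profile-likelihood or bootstrap intervals are not implemented.
* The Bayes estimator is posterior-mean-only (squared-error loss);
  alternative losses are out of scope.
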