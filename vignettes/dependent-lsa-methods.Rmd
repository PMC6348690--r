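---
title: "Local similarity analysis for dependent time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local similarity analysis for dependent time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deplsa)
```

## The problem

Longitudinal microbiome studies produce abundance series for hundreds of
OTUs sampled at the same time points. Two OTUs may interact only during part
of the study (a bloom, a seasonal window) and one may lead the other by a
few sampling intervals, so whole-series correlations (Pearson, Spearman)
miss exactly the signals of interest. Local similarity analysis (LSA)
addresses this: it aligns equal-length subintervals of the two series,
allowing the start positions to differ by at most a delay $D$, and takes as
its statistic the maximal absolute sum of pointwise products.

The catch is significance. The classical tail approximation for the LS
score and the permutation test both assume the observations within each
series are independent. Abundance series are almost always autocorrelated
— a day's community composition predicts the next day's — and under
autocorrelation those p-values can be wrong by a factor of three or more
(an AR(1) coefficient of 0.5 in both series roughly triples the false
positive rate at the 5% level). This package implements two tests whose
type I error stays controlled for dependent, weakly stationary series,
together with the classical baselines and the simulation machinery to
verify all of the above.

## The LS score

For mean-zero series $X_t, Y_t$, $t = 1, \dots, n$, the local similarity
score with maximum delay $D$ is

$$ s_D = \max_{\substack{i, j, \ell \\ |i - j| \le D}}
   \left| \sum_{k=0}^{\ell-1} X_{i+k} Y_{j+k} \right|. $$

`ls_score()` computes this with the classical dynamic programme: positive
and negative accumulators per diagonal,
$P(i,j) = \max(0, P(i-1,j-1) + X_i Y_j)$ and
$N(i,j) = \max(0, N(i-1,j-1) - X_i Y_j)$, restricted to $|i - j| \le D$
(a Smith–Waterman-style local alignment of the product series,
$O(n(2D+1))$ in C++). `ls_score_bruteforce()` is the exhaustive
$O(n^2)$ reference used to verify the programme; the test suite checks
equality on hundreds of random instances.

Conventions worth stating: the score is the *unnormalized* partial sum (the
tests divide by $\hat\omega\sqrt n$ later); positions are 1-based; the
delay is `start_y - start_x`, so a positive delay means the first series
leads; among tied alignments the lexicographically smallest
`(delay, start_x, length)` is reported, which makes results deterministic.
Ties that arise from sub-intervals whose products sum to exactly zero are
resolved by the accumulator-reset rule of the recurrence itself (the reset
at zero means a maximal run never extends through a zero-sum prefix), so
the brute-force and DP representatives can differ there while the score —
the quantity every downstream test uses — is always identical.

## Significance for dependent series

Under the null that $X$ and $Y$ are unassociated, the normalized score
$s_D / (\omega \sqrt n)$ has the asymptotic upper-tail function

$$ \mathcal L_D(x) = 1 - 8^{2D+1}\left[\sum_{k\ge1}
   \left(\frac{1}{x^2} + \frac{1}{(2k-1)^2\pi^2}\right)
   \exp\!\left(-\frac{(2k-1)^2\pi^2}{2x^2}\right)\right]^{2D+1}, $$

implemented in `ld_tail()`. The series is truncated when a term falls below
$10^{-16}$ (the terms decay like $e^{-ck^2}$, so this happens after a
handful of terms for any statistic one meets in practice), with a hard cap
of 1000 terms; for enormous arguments where the cap binds, the analytic
tail of the $\sum 1/((2k-1)^2\pi^2) = 1/8$ series is folded in so the
function reaches 0 exactly in the $x \to \infty$ limit. Results are clamped
to $[0, 1]$ and nonpositive arguments return 1 (a zero score is never
evidence of association).

The scale $\omega^2$ is where dependence enters.

* **TLSA** (`tlsa_test()`) uses the i.i.d. scale
  $\hat\sigma^2 = \widehat{\mathrm{var}}(X_t Y_t)$, the sample variance of
  the product series (1/n convention). Valid for independent observations
  only, and conservative even there.
* **DDLSA** (`ddlsa_test()`) replaces it with the *long-run variance* of
  the product series $Z_t = X_t Y_t$,
  $\omega^2 = \lim_n \mathrm{var}(\sum Z_i)/n$, which absorbs the
  autocovariance mass that the marginal variance misses. Under the null the
  autocovariance of $Z$ factorizes, $\gamma_z(k) \approx
  \gamma_x(k)\gamma_y(k)$, giving the Bartlett-kernel estimate

  $$ \hat\omega_n^2 = \hat\gamma_x(0)\hat\gamma_y(0)
     + 2\sum_{k=1}^{b_w}\Bigl(1 - \frac{k}{b_w}\Bigr)
     \hat\gamma_x(k)\hat\gamma_y(k), $$

  with Andrews' AR(1) plug-in bandwidth: fit $\hat\phi$ to the demeaned
  products by lag-1 least squares,
  $\hat\tau = 4\hat\phi^2/(1-\hat\phi^2)^2$, and
  $b_w = \lfloor 1.1447(\hat\tau n)^{1/3}\rfloor$.
* **LSAres** (`lsares_test()`) takes the opposite route: whiten each series
  with an AIC-selected AR($p$) or ARMA($p,q$) maximum likelihood fit and
  apply TLSA to the residual pair, which is approximately independent when
  the model is adequate.

`permutation_test()`, `pcc_test()` and `srcc_test()` complete the set of
baselines studied by the simulation harness.

### Numerical choices

* **Autocovariances** use the $1/n$ divisor (not $1/(n-k)$), which keeps
  the Bartlett estimate positive semi-definite; the same convention is used
  by `standardize()` so all second moments in the package agree.
* **Bandwidth safeguards.** $\hat\phi$ is clamped to $[-0.97, 0.97]$
  because $\hat\tau$ explodes as $|\hat\phi| \to 1$; $b_w$ is clamped to
  $[0, n-1]$. With $b_w = 0$ (e.g. when the products are empirically
  uncorrelated at lag 1) the kernel sum is empty and
  $\hat\omega^2_n = \hat\gamma_x(0)\hat\gamma_y(0)$, which is also the
  asymptotic TLSA scale under the null — so DDLSA gracefully degrades to
  TLSA for genuinely independent data.
* **Positivity floor.** The truncated kernel sum can go nonpositive in
  pathological samples; $\hat\omega^2_n$ is floored at
  $10^{-3}\,\hat\gamma_x(0)\hat\gamma_y(0)$ and the result is flagged
  (`floored` in the variance object, a note on the test). The same floor
  protects the i.i.d. scale when the product series is constant.
* **Bartlett weight at the boundary.** The weight $(1 - k/b_w)$ is used
  verbatim, so the $k = b_w$ term receives weight zero. The common
  $(1 - k/(b_w+1))$ variant differs only in this boundary term; we keep the
  former because it is the form the long-run estimator here is defined
  with, and the difference is far below Monte-Carlo resolution in every
  experiment in the test suite.
* **Perfect correlations** in the PCC/SRCC baselines ($|r|$ within
  $10^{-12}$ of 1) return $p = 0$ with an explicit flag rather than an
  infinite t statistic propagating NaNs.
* **Permutation p-values** are the plain fraction of permuted scores at
  least as large as the observed one, with an optional
  $(b+1)/(N+1)$ mode (`add_one`) that can never return exactly zero.

### Residual whitening choices

The AR grid is $p \in 0..5$, the ARMA grid $p, q \in 0..3$: wide enough to
cover low-order generative models with margin while keeping an all-pairs
analysis affordable. Every candidate is fitted by maximum likelihood via
`stats::arima()` (CSS-initialized full ML) with an intercept, because real
abundance series are not mean-zero. Candidates that fail to converge or
whose fitted polynomials are non-stationary/non-invertible (unit-circle
root check) are skipped and logged in the returned object; AIC picks among
the survivors. Each series of a pair is fitted independently — the selected
orders are allowed to differ — and the full-length conditional residual
vectors keep the two residual series aligned in time.

## The simulation study

`simulate_null()` provides three null families (all with standard normal
innovations, started from an $N(0,1)$ draw, first 100 samples discarded):
AR(1) with coefficients $(\rho_1, \rho_2)$; ARMA(1,1) adding
$0.5\,\varepsilon_{t-1}$ (with $\rho = -0.5$ the AR and MA polynomials
cancel and the series is white noise — a useful sanity case); and a
threshold AR(1) for $Y$ whose coefficient switches between $\rho_2$
(when $Y_{t-1} \le -1$) and $0.5$.

Two alternatives generate *locally* associated pairs in a symmetric middle
window of $m = \lfloor np \rfloor$ points starting at
$\lfloor (n-m)/2 \rfloor + 1$ (the published construction specifies the
middle placement with floors; the exact off-by-one is fixed here and
documented):

* **local AR** (`simulate_local_ar()`): $X$ is a stationary AR(1) with
  unit marginal variance; inside the window
  $Y_t = (X_t + \xi_t)/\sqrt{1+\sigma^2}$ with
  $\sigma^2 = (1-\rho^2)/\rho^2$, so $\mathrm{cor}(X_t, Y_t) = \rho$;
  outside, $Y$ is an independent AR(1) with coefficient
  $\rho_1/(1+\sigma^2)$, which keeps $Y$ approximately stationary with
  unit variance throughout.
* **bivariate AR** (`simulate_bivariate_ar()`): both series are AR(1);
  the innovation pairs are jointly normal with the correlation chosen so
  the stationary series correlation is exactly $\rho$ inside the window
  and 0 outside. Infeasible parameter combinations (implied innovation
  correlation outside $[-1,1]$) are rejected with the offending value.

The alternatives start from their stationary initial draws and use no
burn-in, exactly as defined. All generators are deterministic given a seed,
and the Monte-Carlo harness (`empirical_size()`, `empirical_power()`)
derives one sub-seed per replicate from its master seed, so results are
independent of evaluation order and different methods can be run on
identical simulated data streams — the natural way to compare them.

What the simulators deliberately do *not* emulate: compositionality and
zero inflation of real OTU counts, seasonality/periodicity, unequal
sampling intervals, and measurement error. Passing the size and power
checks therefore demonstrates correctness of the statistics under weak
stationarity, not robustness to every failure mode of real abundance data;
the pipeline's Ljung–Box screen and the residual diagnostics are the
user-facing tools for judging adequacy on a given dataset.

### Problem sizes used in the checks

The published study ran 10,000 replicates per table cell. The package's
own test suite re-runs representative cells at 10,000 replicates for the
cheap vectorized methods (PCC, TLSA, DDLSA at $n \le 1000$) and 2,000
replicates for the fit-heavy (LSAres) and permutation cells, comparing
within three combined Monte-Carlo standard errors — the resolution at
which those replication counts are informative. The power claim (DDLSA
under the local AR alternative with $\rho_1 = 0.5$, $\rho = 0.5$,
$p = 0.6$, $n = 100$) sits almost exactly on its published 0.9 boundary,
so it is checked one-sidedly with the same 3-SE allowance.

## The abundance-table pipeline

`read_abundance()` parses a factors-by-time TSV with explicit, line-numbered
format errors. The analysis defaults mirror common practice for such
tables: `prevalence_filter()` keeps factors observed (nonmissing *and*
nonzero, since zeros encode absence) in at least a given fraction of time
points, inclusive at the boundary; `interpolate_missing()` fills interior
gaps linearly against the time index and extends the ends with the nearest
observed value; `pairwise_analyze()` runs the chosen test on every
unordered pair with `max_delay = 3` by default (simulations use 0) and
standardizes each series first — the LSA p-values are scale-invariant
anyway, so this costs nothing statistically and makes scores comparable
across pairs; environment factors and OTUs are treated identically.

Multiple testing uses Storey q-values: $\hat\pi_0(\lambda) =
\#\{p > \lambda\}/(m(1-\lambda))$ on the grid $\lambda = 0.05, \dots,
0.95$, smoothed with a df-3 cubic spline and read off at
$\lambda = 0.95$, then the monotone step-up transform
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. Because
$\hat\pi_0$ is unstable when only a handful of pairs are tested,
`fdr_method = "bh"` fixes $\pi_0 = 1$ (Benjamini–Hochberg) as a documented
fallback. `significant_pairs()`, `sorensen_index()` and `method_overlap()`
support the downstream comparisons one typically reports: which
associations replicate across datasets and how the methods' significant
sets intersect.

## Known limitations

* The tail function is asymptotic in $n$; all methods (DDLSA included) are
  somewhat conservative at $n \lesssim 100$, and the long-run variance
  estimate is noisy for very short series.
* DDLSA assumes weak stationarity. Strong seasonality (periodic
  autocovariance) violates it; for such data the residual route with an
  adequate model, or detrending, is more appropriate.
* LSAres inherits the risk of model mis-specification; in the simulations
  size stays controlled under the mis-specified families studied, but a
  grossly wrong model can discard real signal along with the
  autocorrelation.
* The permutation test is implemented as a baseline; it is *not* valid for
  autocorrelated series, which is precisely the point the size experiments
  make.
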