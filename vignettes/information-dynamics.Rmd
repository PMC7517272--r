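---
title: "Gaussian information dynamics from state-space VAR models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian information dynamics from state-space VAR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodyn)
```

## The model and the measures

`infodyn` quantifies directed information flow in networks of jointly
Gaussian stochastic processes observed as multichannel stationary time
series. The generative model is a vector autoregression (VAR) of order $p$
over $M$ channels, written in row-vector form

$$Y_n = \sum_{k=1}^{p} Y_{n-k} A_k + U_n, \qquad
  \Sigma = \mathrm{E}[U_n^{\mathsf T} U_n],$$

so that entry $(i, j)$ of $A_k$ is the influence of channel $i$ at lag $k$
on channel $j$ — **row = source, column = target** everywhere in the
package, including all files it reads and writes. This convention is stated
in every serialized artifact because transposed coefficient matrices are
the single most common usage error with VAR tooling.

For Gaussian processes every information measure used here reduces to a log
ratio of *partial variances* $\lambda_{j|a}$: the steady-state error
variance of the best linear prediction of channel $j$'s present from the
past of the channel set $a$. With $s$ the complement of $\{i, j\}$:

* transfer entropy $T_{i \to j} = \tfrac12 \ln(\lambda_{j|j} / \lambda_{j|ij})$,
* joint transfer entropy $T_{ik \to j} = \tfrac12 \ln(\lambda_{j|j} / \lambda_{j|ijk})$,
* conditional transfer entropy $T_{i \to j|s} = \tfrac12 \ln(\lambda_{j|js} / \lambda_{j|ijs})$,

all in nats. The joint transfer from two sources is decomposed into
unique, redundant and synergistic parts with the minimum-mutual-information
rule: $R_{ik\to j} = \min(T_{i\to j}, T_{k\to j})$, $U_{i\to j} = T_{i\to j}
- R$, $U_{k\to j} = T_{k\to j} - R$, $S_{ik\to j} = T_{ik\to j} - T_{i\to j}
- T_{k\to j} + R$. The four bookkeeping identities hold exactly by
construction; `pid_decompose()` returns raw floating-point values and leaves
the clamping of $-10^{-16}$-type dust to reporting code.

## Partial variances via the state-space form

Computing $\lambda_{j|a}$ for a *subset* $a$ of channels from the full VAR
parameters is the technical core. The VAR is first rewritten as an
innovations-form state-space (ISS) model

$$Y_n = C Z_n + E_n, \qquad Z_{n+1} = A Z_n + K E_n,$$

with the state stacking the last $p$ observation vectors
(`var_to_iss()`); the innovations coincide with the VAR innovations, and
the equivalence is exact — driving both representations with the same
innovation sequence reproduces identical outputs, which is the contract the
tests enforce rather than any particular matrix layout. Restricting the
observation equation to the rows in $a$ leaves a state-space model that is
no longer in innovations form; the stabilizing solution $P$ of the
filtering discrete algebraic Riccati equation (DARE)

$$P = A P A^{\mathsf T} + Q -
  (A P C_a^{\mathsf T} + S)(C_a P C_a^{\mathsf T} + R)^{-1}
  (A P C_a^{\mathsf T} + S)^{\mathsf T}$$

returns it to innovations form, and the reduced innovation covariance
$\Phi(a) = C_a P C_a^{\mathsf T} + R$ carries $\lambda_{j|a}$ on its
diagonal. When $a$ is the full channel set the model is already in
innovations form and $\lambda_{j|a} = \Sigma_{jj}$ exactly; the package
special-cases this instead of iterating.

**Numerical choices.** The DARE is solved by the fixed-point Kalman
iteration $P_{t+1} = f(P_t)$ started at $P_0 = Q$, with symmetrization each
step, convergence tolerance $10^{-12}$ on the relative change, and a cap of
$10^4$ iterations. For stable state matrices and positive-definite
innovation covariances the iteration converges linearly to the stabilizing
solution. Non-convergence, a singular reduced covariance, or a non-positive
reduced variance raise a first-class `dare_error` carrying the iteration
count: this failure mode is *informative*, since least-squares
identification at sample sizes near the coefficient count routinely
produces models whose submodel DARE does not converge — exactly the regime
where the sparse identifier below is the appropriate tool. `cte_matrix()`
records per-entry failures as `NA` with a warning instead of aborting,
because one pathological source should not void an entire network scan. One
Riccati solve per *excluded source* yields a full column set of the matrix
at once ($M$ solves for the $M \times M$ matrix, not $M^2$).

## Identification: least squares and the sparse path

`identify_ols()` is the closed-form minimizer with residual covariance
under the unbiased divisor $N - p - Mp$; it refuses numerically singular
Gram matrices (reciprocal condition below $10^{-12}$) with a
`singular_regression` error rather than returning garbage coefficients.

`identify_lasso()` solves the $\ell_1$-penalized problem over a descending
grid of 300 penalties, log-spaced from $\lambda_{\max}$ (the smallest value
zeroing every coefficient, computed from the largest absolute
regressor–response correlation on standardized data) down to
$10^{-4}\lambda_{\max}$. The penalty applies element-wise to the whole
coefficient matrix with a single global $\lambda$; because the Gaussian
objective separates over target channels, this is fitted exactly as $M$
per-target coordinate-descent problems (glmnet) sharing one penalty
sequence. Series are standardized per column to zero mean and unit
variance, and coefficients are rescaled to original units afterwards;
rescaled magnitudes below $10^{-12}$ are snapped to exact zero so that
support queries are deterministic. No intercept is fitted: the processes
are zero-mean by construction and real data are z-scored upstream. The
innovation covariance of the sparse fit is the residual covariance of the
final model on all rows (divisor $N - p$); a bias-corrected divisor is not
meaningful once shrinkage is involved, so the plain maximum-likelihood form
is used and documented.

**Penalty selection.** Each of 10 hold-out repetitions draws 10% of the
regression rows (uniformly, without replacement, seeded) as a test set,
fits the full path on the remaining rows, and records test RSS and support
size per penalty. The default selector is the classical one-standard-error
rule: the largest penalty whose mean test RSS is within one standard error
of the minimum. This choice was a genuinely open design point. Selecting
the raw RSS minimizer (`selection = "min"`) over-fits under data paucity,
and the superficially attractive ratio of mean RSS to mean support size
(`selection = "ratio"`, also available) is dominated by its denominator and
drifts to dense solutions — in network terms, a false-positive rate near 1
when samples are scarce. The one-standard-error rule makes the selected
penalty grow as data shrink, which is what produces the behavior expected
of a sparse network identifier: near-zero spurious transfer on absent
links at every sample size, at the price of missing the weakest true links.
Grid values whose path the solver abandons at the dense end (expected when
rows are fewer than coefficients) are excluded from comparison per repeat
rather than silently counted as zero-error.

`select_order_bic()` fixes the candidate comparison window to the last
$N - p_{\max}$ rows so criteria for different orders are computed on the
same observations, and uses the standard multivariate form
$N'\ln\det\hat\Sigma_p + \ln(N')\,p M^2$; the criterion's exact variant was
unspecified upstream, so the standard one is used and stated here.

## Significance of network links

Two significance rules, matched to the two identifiers:

* **Surrogate thresholding (for OLS).** Each channel is independently
  randomized by the iterative amplitude-adjusted Fourier transform (IAAFT):
  alternate imposing the original Fourier amplitudes and remapping values
  onto the original amplitude multiset by rank, until the rank permutation
  reaches a fixed point or 100 iterations pass. Surrogates keep every
  channel's spectrum (hence autocorrelation) while destroying all
  cross-channel coupling, which is precisely the null of "no transfer".
  The observed conditional TE of a directed link is declared significant
  when it *strictly* exceeds the 95th percentile of its value across 100
  surrogate datasets (ties conservative); surrogates on which the refit or
  a Riccati solve fails are dropped with a warning, requiring at least half
  to survive. The iteration count and stall rule are implementation
  choices, stated here because upstream sources leave them open.
* **Support detection (for LASSO).** For a sparse model, the conditional
  TE along a direction is exactly zero iff every lag coefficient on that
  direction is zero, so the mask is simply the lag-collapsed coefficient
  support — deterministic in the model, with the same $10^{-12}$ zero
  threshold as the identifier.

No multiple-testing correction is applied across links; the per-link level
is the object of interest in the calibration tests.

## The two simulation benchmarks

The package ships two generators that double as study designs; their
defaults *are* the benchmark conditions and are not meant to be tuned.

**Oscillator network** (`build_simulation1_model()`): four channels,
VAR(2). Channels 1–3 carry autonomous oscillations from complex-conjugate
pole pairs (modulus 0.95 each; frequencies 0.1, 0.025, 0.025
cycles/sample); channel 1 drives channels 2 and 3 with unit weight; 2 and 3
drive channel 4 with weight 0.5 each; channel 4 has no self-dynamics; unit
innovation covariance. The pole frequencies deserve a note: with the
slow-oscillation value 0.025 for channels 2 and 3 the theoretical
decomposition towards channel 4 gives $T_{2\to4} = T_{3\to4} = R_{23\to4} =
0.63$ and $S_{23\to4} = 0.56$ nats (unique transfers zero — the sources are
exactly symmetric), and every measure towards channel 1 is identically
zero. These values are verified in the tests both against the Riccati
machinery and against brute-force nested regressions on a $10^6$-sample
realization.

**Random sparse networks** (`build_simulation2_model()`): ten channels,
VAR(10), exactly 45 of the 90 ordered pairs linked (density 0.5), each
selected link receiving *one* non-zero coefficient at a uniformly drawn lag
with value uniform in $[-0.6, 0.6]$, diagonal-free, innovations of variance
0.1, redrawn up to 100 times until stable. Two readings were open here and
are exposed as arguments rather than hidden: whether a link may occupy
several lags (default: one, the minimal reading that keeps the link count
exact) and whether channels have self-dynamics (default: none). Note that a
uniform coefficient draw makes a sizeable fraction of true links very weak
(about one in six has magnitude below 0.1); at 100 samples those links are
undetectable in principle, which caps achievable reconstruction accuracy in
the hardest benchmark cell around 0.75 regardless of identifier — a ceiling
worth remembering when reading the benchmark output.

`run_simulation1()` sweeps the data-paucity ratio $K = N/(Mp)$ over
realizations, identifying each by OLS and/or LASSO and scoring PID bias and
variance against theory; least-squares failures at $K = 1$ are counted, not
fatal, because they are part of the phenomenon. `run_simulation2()` draws a
fresh network per realization, scores estimated conditional-TE matrices via
absolute error on null links (`BIAS`) and normalized error on true links
(`BIASN`), and scores reconstruction via FPR/FNR/ACC with each method's
significance rule. One upstream ambiguity is resolved deliberately: the
error-metric definitions (absolute on null, normalized on non-null) are
taken as authoritative over a contradictory prose sentence about which set
each average runs over, and "accuracy" is the fraction of *correct*
classifications. Per-realization seeds derive deterministically from the
base seed, so parallel or reordered execution cannot change results.
Identification order is fixed at the true $p = 10$; no order selection is
performed inside the benchmark.

## Problem sizes used in the shipped tests

The test suite exercises the benchmarks at reduced but honest sizes, chosen
as the package's own trade-off between statistical resolution and suite
turnaround: 20 realizations for distributional claims (orderings, trend
monotonicity, mean accuracy), 8 runs of 100 surrogates for the calibration
of the significance test's nominal level, $5\times10^5$–$10^6$ samples for
the brute-force regression oracles (1% agreement band), and 50 random
stable models for the partial-variance monotonicity and PID-identity
properties. Distributional assertions at these sizes are stochastic but
seeded; the tolerances quoted in the tests are three-or-more-sigma bands
under the corresponding binomial or Monte-Carlo error.

## What the generators do and do not emulate

Both generators produce exactly the linear-Gaussian world in which the
partial-variance identities are exact: stationary, zero-mean, fixed
topology, Gaussian innovations. Passing benchmarks therefore demonstrates
correctness of the estimation machinery, not robustness to what real
physiological series add on top — nonstationarity, non-Gaussian margins,
measurement noise, slow trends, or time-varying coupling. The intended
workflow for real data (z-score channels, select $p$ by BIC, identify by
both methods, compare surrogate- and sparsity-based networks, summarize
with `in_strength()`, including its grouped super-node form for
sub-network-to-sub-network flow) is supported, but the inference rests on
the adequacy of the stationary VAR description, which must be argued
separately for each dataset.

## Known limitations

* The minimum-mutual-information redundancy is one of several PID
  completions; quantities beyond the four identities (e.g. separate source
  asymmetries) are not identified by it.
* The DARE fixed-point iteration converges linearly; for state matrices
  with spectral radius very near 1 it can need thousands of iterations
  (the cap surfaces as `dare_error` rather than a silent wrong answer).
* Frequency-domain decompositions, elastic-net/adaptive-lasso penalties,
  and time-varying or multiscale extensions are out of scope.
* The sparse identifier shrinks large coefficients; its transfer-entropy
  estimates on strong links are biased low at small samples. The benchmark
  reports make this visible rather than correcting it.
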