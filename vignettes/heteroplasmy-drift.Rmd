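---
title: "Modelling mtDNA heteroplasmy segregation by random genetic drift"
author: "mtdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mtDNA heteroplasmy segregation by random genetic drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdrift)
```

## The model and its assumptions

Heteroplasmy — the fraction of mtDNA molecules in a cell or individual
carrying a mutation — is transmitted maternally through a germline
bottleneck: per germ-cell generation only an effective number $N$ of mtDNA
segregating units is resampled, so the mutant fraction performs a neutral
Wright–Fisher random walk. In the diffusion limit the frequency $x$ of the
mutant after cumulative drift is described by the Kimura distribution with
two parameters: the founder fraction $p \in (0,1)$ and a bottleneck
parameter $b \in (0,1)$,

$$\phi(x) = \sum_{i \ge 1} i(i+1)(2i+1)\,p\,q\,
  F(1-i,\,i+2;\,2;\,p)\,F(1-i,\,i+2;\,2;\,x)\; b^{i(i+1)/2},$$

a continuous density on $(0,1)$ plus point masses at the absorbing
boundaries,

$$f_0 = q - \sum_{i\ge1} (2i+1)\,p\,q\,F(1-i,i+2;2;p)\,b^{i(i+1)/2},
\qquad
f_1 = p + \sum_{i\ge1} (-1)^i (2i+1)\,p\,q\,F(1-i,i+2;2;p)\,b^{i(i+1)/2},$$

where $q = 1-p$ and $F$ is the terminating Gauss hypergeometric
polynomial. $b$ compounds all drift: $b = (1-1/N)^g$ after $g$ generations
of a constant bottleneck of $N$ units, $b \to 1$ means no drift and
$b \to 0$ complete fixation. The model assumes strict neutrality (no
selection on mutant load), no de-novo mutation, and exchangeable offspring;
everything the cohort statistics can identify about the bottleneck's
biology is compressed into the single compound parameter $b$.

Two identities anchor the whole package: $E[x] = p$ (drift is unbiased) and
$\mathrm{Var}[x] = p(1-p)(1-b)$. Both are verified against numerical
quadrature of $\phi$ over a $19\times19$ grid of $(p, b)$ in the test
suite, together with exact normalization
$f_0 + f_1 + \int_0^1\phi = 1$ and the relabelling symmetry
$f_0(p,b) = f_1(1-p,b)$.

## Estimation

`fit_kimura()` is a method-of-moments estimator: $\hat p_0$ is the sample
mean, $\hat V$ the sample variance ($n-1$ denominator — the conventional
choice, which matters only in the third digit at $n = 35$), the
*normalized variance* $\hat V/(\hat p_0(1-\hat p_0))$ estimates $1-b$, and
the fixation and tail probabilities are evaluated from the Kimura
distribution at $(\hat p_0, \hat b)$. The estimator fails loudly in two
degenerate regimes: all-identical measurements ($\hat V = 0$, the $b = 1$
boundary) and normalized variance $\ge 1$ (more dispersed than complete
fixation — no drift distribution fits). `fit_kimura_summary()` applies the
same estimator to a published $(p_0, V, n)$ summary when raw values are
unavailable.

Measurements reported as exactly 0 (below the assay detection threshold)
enter the fit by default: under drift they are genuine candidate fixations
on wild-type, and dropping them would bias both moments upward.
`exclude_zeros = TRUE` provides the sensitivity analysis.

### Monte-Carlo confidence intervals

Sample-size uncertainty is quantified by parametric resampling
(`mc_confidence_intervals()`): draw replicate cohorts of size $n$ from the
fitted distribution, refit each, and take 2.5th/97.5th percentiles of every
statistic across replicates (10,000 by default). Replicates whose refit
fails are excluded and counted. The coverage of the interval for $p_0$ is
itself validated in the test suite: over 500 cohorts simulated at known
$(p, b, n) = (0.3, 0.8, 35)$, the interval covers the truth $95\% \pm 2\%$
of the time.

A reporting subtlety worth knowing: the package reports fixation and tail
probabilities *at the point estimates*, with intervals from the
Monte-Carlo refits. The alternative convention — reporting the *mean* of
each statistic across the replicates — gives visibly different numbers for
the deep-tail quantities, because they are convex in $(p_0, b)$ near the
boundary and Jensen's inequality inflates replicate means (at
$p_0 = 0.337$, $b = 0.72$, $n = 35$ the point value of $f_1$ is 0.0028
while the mean over 10,000 refits is 0.0041). Deep tails are also
hypersensitive to rounding of the inputs: moving $b$ from 0.87 to 0.88
changes $f_1$ by a factor of four at $p_0 = 0.126$. Comparisons of such
quantities across reports should always check which convention — and which
input precision — was used.

### Goodness of fit

`ks_test_mc()` tests the drift null hypothesis with a Kolmogorov–Smirnov
statistic adapted to the mixed distribution: the sup distance honours the
atoms at 0 and 1, and — because atoms produce *tied* observations — it is
computed from the signed one-sided maxima ($D^+$ at the end of each tie
block, $D^-$ against the left limit at its start). Taking absolute
differences at every sorted index would manufacture spurious distance
inside tie blocks; the error is large (it roughly doubles $D$ for cohorts
with a substantial zero class) and is exactly the kind of defect the
type-I calibration test exists to catch.

Because the null parameters are estimated from the same data, the p-value
comes from a parametric bootstrap *with re-estimation*: each replicate
draws $n$ values from the fitted null and is refitted before its $D^*$ is
computed, and $p = (1 + \#\{D^* \ge D\})/(\text{valid reps} + 1)$. The
suite verifies calibration directly: over 500 null cohorts ($n = 200$) the
rejection rate at $\alpha = 0.05$ is within $0.05 \pm 0.02$ (measured
slightly conservative, as expected for a moment-based rather than
maximum-likelihood refit), and the test retains high power against a
coarse lattice alternative (binomial with 5 trials).

## The synthetic-data generator

`simulate_offspring()` is both the package's synthetic-data source and the
independent oracle for the Kimura implementation: offspring heteroplasmy
is resampled through $g$ explicit binomial Wright–Fisher steps of $N$
units — no shared code with the series evaluation — and the measurement
layer adds Gaussian assay noise (replicate SD 1.7% by default), truncates
to $[0,1]$ and censors below the 2% detection threshold, mirroring a
semiquantitative fluorescent-PCR assay. `simulate_single_cells()` models
within-pool single-cell loads as binomial sampling of the cell's mtDNA
copies (around 150 for lymphocytes; $10^4$–$10^6$ for blastomeres and
oocytes, at which the binomial spread vanishes).
`simulate_blastomere_replicates()` adds within-embryo replicate noise; its
default SD of 0.015 is a deliberate calibration such that a cohort with
between-embryo SD near 0.23–0.25 yields a one-way ICC near 0.994 — the
published agreement regime for replicate blastomeres. The default seed
3243 is recorded in every cohort.

The shipped demonstration cohort
(`inst/extdata/synthetic_embryo_cohort.tsv`, the file name marks it as
synthetic) uses founder $p = 0.3$, $N = 300$, $g = 98$
($b = 0.721$), $n = 35$ embryos with $k = 2$ blastomere replicates —
scaled to emulate a carrier's embryo cohort: mean load ~30%, high
inter-embryo variance, a couple of mutation-free embryos, near-perfect
intra-embryo agreement.

What the generator does *not* emulate: mechanistic copy-number dynamics in
primordial germ cells (only the compound $b$), selection against high-load
cells, tissue-specific segregation, PCR chemistry. Passing tests therefore
validate the statistical machinery under the stated model, not the model's
biological completeness.

### The diffusion approximation and its lattice limits

The Kimura distribution is the $N\to\infty$ diffusion limit of the
Wright–Fisher chain. At small $N$ the chain lives on a lattice of $N+1$
frequencies, and a two-sample KS comparison against the continuous limit
*must* reject at large sample sizes: at $N = 10$ the sup distance to the
diffusion limit is about 0.07, far above the $n = 10^4$ two-sample KS
resolution of 0.023. The cross-validation tests therefore assert the
convergence picture — the distance falls monotonically from $N = 10$
through $N = 200$ — and statistical indistinguishability in the diffusion
regime ($N = 200$, $g = 66$, $b \approx 0.72$, the regime matching fitted
human germline bottlenecks), plus a 20-bin interior histogram agreement
(chi-square at $n = 10^5$). Exact finite-$N$ Markov-chain computations
(binomial transition matrices) were used during development to confirm the
series: fixation probabilities converge to the series values with the
expected $O(1/N)$ boundary bias.

## Numerical choices

* **Hypergeometric evaluation.** $F(1-i, i+2; 2; x)$ is evaluated through
  the Jacobi-polynomial identity
  $F(1-i,i+2;2;x) = P^{(1,1)}_{i-1}(1-2x)/i$ and the stable three-term
  recurrence for $P^{(1,1)}_n$ on $[-1,1]$; the naive alternating power
  series cancels catastrophically for large $i$.
* **CDF.** The antiderivative of each density term reduces to Legendre
  polynomials via $\frac{d}{dz}P_i = \frac{i+1}{2}P^{(1,1)}_{i-1}$, giving
  $\int_0^x F_i(t)\,dt = (1 - P_i(1-2x))/(i(i+1))$ — so the CDF is exact
  term-by-term, not quadrature, and closes normalization identically.
* **Truncation.** Terms are summed until every running series has seen 50
  consecutive increments below $10^{-12}$, hard cap 500 terms. The factor
  $b^{i(i+1)/2}$ guarantees super-geometric decay for $b \lesssim 0.999$;
  beyond that the series is declared non-convergent with an explicit error
  (near $b = 1$ the distribution is a near-delta at $p$ and fixation
  masses are astronomically small anyway).
* **Negative clipping.** Truncation can leave the density a hair below
  zero; magnitudes under $10^{-10}$ are clipped, anything larger raises an
  error — separating round-off from genuine evaluation bugs.
* **Sampling.** Inverse-CDF interpolation on a 4097-point grid of the
  continuous part, with the atoms handled exactly. Sampler fidelity was
  checked directly: sup distance to the true CDF at $2\times10^5$ draws is
  at the empirical noise floor ($\approx 0.002$).
* **Units.** Heteroplasmy is a fraction in $[0,1]$ everywhere inside the
  package; percentages exist only at I/O boundaries (`read_measurements()`
  converts on ingest, reports carry both representations).

## Single-cell and cohort descriptive statistics

`summarize_pools()` gives per-pool means, SDs, ranges and the
cell-weighted grand mean (for the pool-vs-whole-sample representativeness
check). `mean_sd_regression()` regresses per-pool SD on per-pool mean —
unweighted OLS by default, the simplest reading of how such slopes are
conventionally reported, with a weighted option. `icc_oneway()` implements
the one-way random-effects ICC with the unbalanced correction
$k_0 = (\sum k_i - \sum k_i^2/\sum k_i)/(g-1)$; one-way is the natural
model for replicate blastomeres within embryos, and the implementation is
cross-checked against `stats::aov` mean squares in the tests.
`transmission_rate()` counts offspring at or above the detection threshold
(a load exactly at the threshold is detected — the threshold is the
smallest *detectable* proportion) and attaches an exact binomial CI.

## Problem sizes

The test suite's simulation sizes are chosen so the whole suite runs in
about a minute on one CPU: $10^5$ draws for moment checks, $10^4$ per
sample for the two-sample oracle comparisons, 500 trials for the type-I
and coverage experiments (at 199 bootstrap replicates and 2,000 CI
replicates respectively), and $19\times19$ parameter grids for the
analytic identities. The method defaults (10,000 CI replicates, 2,000
bootstrap replicates) are what analyses of real cohorts should use.

## Known limitations

* The moment estimator is not maximum likelihood; it is the estimator
  matching the normalized-variance definition of $b$, and its sampling
  behaviour is quantified by the Monte-Carlo machinery rather than
  asymptotic theory.
* Series evaluation is limited to $b \lesssim 0.999$ (see above).
* The KS test conditions on a successful fit; cohorts failing the fit
  (complete fixation, over-dispersion) have no defined p-value.
* No selection, mutation, or multi-tissue joint modelling; the package
  deliberately stays within the single-cohort neutral-drift scope.
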