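# mtdrift

Statistical analysis of mitochondrial DNA (mtDNA) heteroplasmy segregation
under random genetic drift.

## The problem

A woman carrying a pathogenic heteroplasmic mtDNA mutation (such as
m.3243A>G, the common MELAS mutation) transmits it to her offspring at
wildly variable mutant loads: siblings conceived from the same carrier can
range from mutation-free to a load high enough to cause disease. The
standard explanation is the **germline bottleneck**: during oogenesis only
a small effective number of mtDNA segregating units is transmitted per cell
generation, so allele frequencies drift. Quantifying that drift — and
testing whether drift alone explains an observed offspring cohort — is the
core task in genetic counselling and in prenatal/preimplantation diagnosis
(PND/PGD) for mtDNA disease.

`mtdrift` is aimed at researchers analysing cohorts of heteroplasmy
measurements (embryos, oocytes, fetal tissues, single cells) who want to:

* fit the neutral-drift (Kimura) distribution to a cohort and estimate the
  bottleneck parameter,
* attach Monte-Carlo confidence intervals reflecting sample-size
  uncertainty,
* test goodness of fit of the drift hypothesis,
* quantify single-cell dispersion, intra-embryo agreement (ICC) and
  transmission rates under an assay detection threshold,
* and simulate realistic synthetic cohorts (Wright–Fisher bottleneck +
  assay noise) for power studies and validation.

## The model

Under pure random genetic drift from founder heteroplasmy *p*, allele
frequency *x* follows the **Kimura distribution**: point masses *f0* at 0
(mutant lost) and *f1* at 1 (mutant fixed) plus a continuous density on
(0, 1),

    phi(x) = sum_{i>=1} i(i+1)(2i+1) p q F(1-i, i+2; 2; p) F(1-i, i+2; 2; x) b^{i(i+1)/2},

with *q* = 1 − *p*, *F* the (terminating) Gauss hypergeometric polynomial,
and *b* in (0, 1) the **bottleneck parameter** compounding all accumulated
drift (under a Wright–Fisher bottleneck of *N* segregating units for *g*
generations, *b* = (1 − 1/*N*)^*g*). Mean and variance are closed-form:

    E[x] = p,     Var[x] = p (1 - p) (1 - b),

so the **normalized variance** *V*/(*p*(1 − *p*)) of a cohort estimates
1 − *b*. That moment identity is the estimator behind `fit_kimura()`:
sample mean → *p0*, sample variance → *V*, *b* = 1 − *V*/(*p0*(1 − *p0*)),
with fixation probabilities and the clinically relevant tail
P(*x* > 60%) evaluated from the fitted distribution.

## Worked example

The package ships a small synthetic demonstration cohort
(`inst/extdata/synthetic_embryo_cohort.tsv`, generated by the package's own
Wright–Fisher simulator with seed 3243): 35 embryos from a simulated
carrier plus two blastomere replicates per embryo.

```r
library(mtdrift)

demo <- system.file("extdata", "synthetic_embryo_cohort.tsv", package = "mtdrift")
tab  <- read_measurements(demo)            # loads percent -> fraction
embryos <- tab[tab$sample_type == "embryo", ]

fit <- fit_kimura(embryos$load)
fit <- mc_confidence_intervals(fit, reps = 10000, seed = 3243)
fit
#> Kimura drift-distribution fit
#>   Sample size (n)                 35
#>   Mean mutation level (p0)        0.3456  (0.2626-0.4341)
#>   Mutation level variance (V)     0.06753  (0.04267-0.09481)
#>   Normalized variance V/(p0(1-p0)) 0.2986  (0.1983-0.4127)
#>   Bottleneck parameter (b)        0.7014  (0.5873-0.8017)
#>   P(fixing on wild-type) f0       0.09332  (0.02014-0.2215)
#>   P(fixing on the mutant) f1      0.004667  (0.0001325-0.03126)
#>   P(load > 60%)                  0.1881  (0.08906-0.3002)
#>   95% CIs from 10000 Monte-Carlo refits (seed 3243)
```

The cohort's mean mutant load is 34.6% with a bottleneck parameter of 0.70:
about 30% of the founder's heteroplasmy variance capacity has been
converted into inter-offspring variance by drift. Roughly 9% of conceptions
are expected mutation-free, and 19% above the 60% load associated with
clinical expression.

```r
ks_test_mc(embryos$load, reps = 1999, seed = 3243)
#> Monte-Carlo KS test against the fitted Kimura distribution
#>   D = 0.1269, p-value = 0.094 (1999 bootstrap replicates)
```

The parametric-bootstrap KS test does not reject the drift hypothesis for
this cohort.

```r
blast <- tab[tab$sample_type == "blastomere", ]
icc_oneway(blast$load, blast$sample_id)
#> One-way random-effects ICC = 0.9976 (35 groups, 2 replicates each)

transmission_rate(embryos$load)
#> Transmission rate: 33 of 35 offspring carry the mutation (94%; exact 95% CI 81-99%)
#>   at detection threshold 2%
```

Replicate blastomeres agree almost perfectly within embryos (ICC ≈ 0.998)
while embryos differ strongly from one another — the signature of drift
having acted before the first cleavage divisions, not after.

See the methods vignette (`vignettes/heteroplasmy-drift.Rmd`) for the
model, estimators, simulator and numerical choices in detail.

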