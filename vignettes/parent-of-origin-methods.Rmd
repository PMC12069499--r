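---
title: "Models and methods for parent-of-origin analysis in trio cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for parent-of-origin analysis in trio cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triopoe)
```

## The scientific problem

A quantitative trait shows a *parent-of-origin effect* (POE) when the
offspring phenotype depends on which parent an influence - a phenotypic
association or a transmitted allele - came from. In parent-offspring trio
cohorts with serial offspring measurements this can be interrogated at
three levels, and `triopoe` implements all three:

1. **Cross-sectional phenotypic contrasts.** At each offspring visit the
   trait is regressed separately on the mother's and on the father's
   trait; a significantly stronger maternal slope indicates maternal
   bias, and vice versa.
2. **Longitudinal contrasts.** Visits are pooled in a mixed-effect model
   so the *overall* maternal and paternal influences across the life
   course can be compared within one fit.
3. **Genetic allele-origin contrasts.** With trio genotypes, the parental
   origin of each offspring allele can usually be determined without
   statistical phasing; comparing reciprocal heterozygotes (maternal
   minor allele vs paternal minor allele) isolates imprinting-like
   genetic POE.

Because the motivating cohort data are controlled-access, the package
carries a forward simulator that generates trio cohorts with *known*
maternal, paternal and allele-origin effects. Every downstream stage is
validated against that ground truth in the test suite.

## Trait preprocessing

Skewed traits are handled by either a natural-log transform or the
rank-based inverse normal transform
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ (Blom offset; ties receive
average ranks, missing values propagate). The Blom constant was chosen
because it is the common default in quantitative-trait GWAS
preprocessing; the transform is invariant under any strictly monotone
change of the input, which is tested as a property. Per-trait choices
live in a named registry (`default_transforms()`): lipids and the
insulin axis are log-transformed, skinfolds inverse-normal, and
everything else is left untouched. The registry is an argument of every
fitting function, so the mapping is configurable per analysis.

Derived indices use the field's standard formulas: BMI $= w/h^2$
(kg/m$^2$), WHR $=$ waist/hip, and Friedewald LDL
$= \mathrm{TC} - \mathrm{HDL} - \mathrm{TG}/2.2$ in mmol/l (the divisor
is configurable to 5 for mg/dl). The Friedewald formula is invalid at
high triglycerides; above 4.5 mmol/l the value is returned missing with
a warning rather than extrapolated.

## Cross-sectional models and the Wald Z contrast

For trait $y$ at visit $v$ and parent $P \in \{m, p\}$, the package fits

$$ y_i = \alpha + b_P\, z(x_{P,i}) + \gamma' c_i + \varepsilon_i $$

by OLS after listwise deletion, where $z(\cdot)$ is the z-score of the
(transformed) parental trait and $c_i$ the covariates - offspring age
and sex for anthropometric traits, plus offspring and parental BMI for
cardiometabolic traits. By default the outcome is z-scored too, giving
standardised coefficients; `standardize = "predictor"` leaves the
outcome on its own scale, which is the parameterisation under which the
simulator's slopes are defined and recovered. When the outcome is BMI
itself, BMI is dropped from the covariates to avoid tautology. The
maternal and paternal models each use their own complete cases, so
their sample sizes differ when parental missingness differs - as in
real cohorts.

The POE test is the Wald statistic on the coefficient difference:

$$ Z = \frac{b_1 - b_2}{\sqrt{SE_1^2 + SE_2^2 - \mathrm{cov}(b_1, b_2)}},
\qquad p = 2\,[1 - \Phi(|Z|)], $$

with $b_1$ maternal by convention, so $Z > 0$ means maternal bias.
Because the two coefficients come from separately fitted models, their
covariance is not identified by those fits alone; `poe_scan()` therefore
offers three covariance policies:

* `"zero"` (default): omit the term. This matches the arithmetic that
  reproduces published two-model analyses and is conservative when the
  true covariance is positive.
* `"joint"`: put both parents in one model and take
  $2\,V_{12}$ from the coefficient covariance matrix; the resulting
  statistic equals the textbook Wald test of the linear contrast
  $b_m - b_p$, which the test suite verifies against an independent
  implementation to $10^{-8}$.
* `"bootstrap"`: paired resampling of trios.

Significance is flagged at the conventional $p < 0.05$ and, separately,
at a fixed multiplicity-adjusted threshold $p \le 0.001$; the threshold
is a constant rather than a recomputed Bonferroni level because the
reference analyses report the threshold, not the test count.

The mid-parent regression (`fit_midparent_model()`) regresses the
offspring trait on the mean of the two z-scored parental traits - the
classical heritability regression. With independent parents of equal
scale, a configuration with $\beta_m = \beta_p = 0.25$ has expected
mid-parent slope $0.5$, an analytic identity the tests check by
simulation.

## Longitudinal mixed models

`fit_longitudinal_model()` stacks the offspring trait over visits,
z-scoring within visit so that visit-level location/scale differences do
not masquerade as parental effects, and fits

$$ y_{iv} = \alpha + b_m z(x_{m,i}) + b_p z(x_{p,i}) + \gamma' c_{iv}
  + u^{fam}_i + u^{ind}_i + \varepsilon_{iv} $$

with random intercepts for family and for the repeated observations of
each offspring (`lme4`). Both parents enter one joint model: the pooled
"overall effect" comparison needs a within-model contrast, and the joint
fit supplies $\mathrm{cov}(b_m, b_p)$ exactly. A separate-models variant
is exposed for sensitivity analysis. With one offspring per family the
two random intercepts partition one family-level variance between them;
their *sum* is the identified quantity, which is what the intraclass
correlation recovery test asserts.

Estimation uses REML by default rather than ML. This is a deliberate
choice: REML's fixed-effect covariance divides by residual degrees of
freedom, so in the degenerate limit (single visit, zero random
variances) the longitudinal contrast collapses *exactly* (to $10^{-6}$
and better) onto the joint cross-sectional Wald Z, a reduction the test
suite enforces. Under ML the two would differ by the $n/(n-p)$ variance
factor. `method = "ML"` is available. Non-convergence is flagged on the
result, never raised, and singular variance components sit at the zero
boundary.

Parental traits are simulated (and modelled) as single baseline
measurements; with parental measurements at multiple waves the predictor
would be the wave closest to each offspring visit, and the baseline-only
behaviour is the degenerate case of that rule.

## Trio genetics

**QC.** SNPs are excluded when call missingness exceeds 5%, founder
minor-allele frequency falls below 1%, or the founder Hardy-Weinberg
exact p value is below 0.05 (all thresholds configurable). Allele
frequency and HWE use founders only, so Mendelian transmission cannot
imitate disequilibrium. The HWE test is the exact conditional test:
summing probabilities of heterozygote counts no more probable than the
observed one, given the allele counts, using a log-space recurrence; the
suite checks it against a direct log-factorial enumeration for *every*
genotype table with up to 200 individuals, to $10^{-12}$.

**Origin assignment.** `assign_parental_origin()` is a deterministic
case analysis of the 27 trio dosage combinations: homozygous offspring
force both origins; a heterozygous offspring is resolved whenever at
least one parent is homozygous; the double-heterozygote trio (mother,
father and offspring all heterozygous) is `AMBIGUOUS`; impossible
combinations are `MENDELIAN_ERROR`; any missing genotype gives
`MISSING`. The implementation is verified against brute-force
enumeration of all parental transmissions. `AMBIGUOUS` trios are
*excluded* from origin-based models - population-reference phasing could
rescue some of them, but that is outside the package's scope, and
exclusion is conservative. Trios with Mendelian errors contribute no
origin information for that SNP; the SNP itself is kept unless it fails
QC.

**Association models.** With A the major and B the minor allele and m/p
the transmitting parent, the three contrasts are: maternal
(ApBm vs AA), paternal (AmBp vs AA) and POE (ApBm vs AmBp - the
reciprocal-heterozygote contrast). The trait is log-transformed and
z-scored (configurable), and the group indicator fitted by an
estimating-equation model with independence working correlation
clustered on family and robust sandwich standard errors. With
independence working correlation the point estimates are OLS and the
covariance is the cluster-robust sandwich, which with one offspring per
family equals heteroskedasticity-robust OLS exactly - the suite asserts
this equivalence to $10^{-8}$. Groups smaller than 10 offspring yield an
explicit skip record with counts, not a silent omission. Swapping the
stored maternal/paternal labels negates the POE estimate exactly
(tested).

## The simulator and what it does (not) emulate

`pmns_like_config()` encodes the default study conditions: 700 trios,
offspring visits at birth/6/12/24 years, parental effect sizes in the
0.05-0.45 range that shift between visits (including a maternal-biased
glucose trajectory and a sign-changing insulin effect), lognormally
skewed insulin/triglyceride traits, 5% missing parental phenotype
values, and an imprinted SNP (maternal-allele effect 0.3 SD, MAF 0.3).
Choices the underlying studies do not pin down were fixed once on
field-typical values and documented rather than tuned: parental traits
are independent normals (no assortative mating; a `spousal_cor` knob
exists because the literature is silent), one offspring per family,
visit ages jittered by ±0.5 y so age covariates are non-degenerate, and
founder genotypes drawn in HWE with strictly Mendelian transmission.

The generator is deliberately phenomenological. It does not model
gestational physiology, puberty, epigenetic mechanisms, linkage between
SNPs, or trait-trait covariance; passing tests therefore demonstrate
statistical correctness of the pipeline (calibration, coverage, power,
invariances under relabelling), not biological realism of any particular
dataset.

## Numerical and validation choices

* All randomness flows from a single integer seed; identical
  configurations are byte-identical, which the suite asserts via
  serialisation.
* Type-I calibration runs 1000 null replicates of 500 trios
  ($\beta_m = \beta_p$, no imprinting) and requires both the phenotypic
  and the genetic POE tests to reject at a rate inside the binomial 95%
  interval around 0.05. Parameter recovery runs 100 replicates of 700
  trios with $\beta_m = 0.3$, $\beta_p = 0.1$ and a 0.3 SD
  maternal-allele effect, requiring $\ge 93\%$ coverage of truth within
  ±2 SE and $\ge 80\%$ power for maternal-bias detection. These problem
  sizes mirror the cohort scale the package targets.
* Published Wald Z values are reconstructed from the printed coefficient
  table with `cov = 0`. 105 of the 108 table cells agree within ±0.05
  (printed inputs are rounded to 3 decimals); the remaining three cells
  differ by up to 0.75, which no input rounding can explain and which is
  consistent with a nonzero coefficient covariance in the original
  analysis whose value was not published. The reconstruction test
  reports this honestly rather than widening its tolerance.
* Ties in the exact HWE p value are compared with a relative guard of
  $10^{-9}$ so "equally probable" configurations are included as the
  definition requires.

## Known limitations

* No statistical phasing: double-heterozygote trios stay ambiguous.
* No imputation or dosage genotypes; hard calls only.
* One offspring per family; larger sibships are out of scope.
* The longitudinal layer models intercept-only random structure; random
  slopes over age are not implemented.
* Estimating-equation machinery covers the independence working
  correlation (the relevant case for one offspring per family), not
  exchangeable or AR structures.
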