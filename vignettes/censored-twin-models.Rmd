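---
title: "Censored twin models for gene-by-SES analysis of educational achievement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored twin models for gene-by-SES analysis of educational achievement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Children from higher-socioeconomic-status (SES) families score higher, on
average, on standardized educational-achievement (EA) tests. Two
complementary designs quantify how genes and SES interact in producing
that gradient:

* the **classical twin design**, which uses the difference in resemblance
  between monozygotic (MZ) and dizygotic (DZ) twin pairs to split the
  phenotypic variance of EA into additive-genetic (A), common-environment
  (C) and unique-environment (E) components — and asks whether the means
  and the variance components themselves differ across SES strata
  (group-wise gene-by-environment moderation); and
* the **polygenic-score (PGS) design**, which uses a per-child score built
  from genome-wide association results for educational attainment, both
  between families (does the PGS predict EA, and does the slope depend on
  SES?) and within families (does the DZ co-twin with the higher PGS
  outscore the other?). The within-family contrast is immune to
  family-level confounding, because both co-twins share the household's
  SES.

`twincens` implements this entire inference chain for a national test
scored on a 501–550 scale with a **hard ceiling at 550**: a non-trivial
fraction of children — increasingly many at higher SES — obtain the
maximum score, so every likelihood in the package is built on the
**censored bivariate normal distribution** with a fixed right-censoring
threshold.

## The censored pair likelihood

A twin pair with model-implied means $(\mu_1,\mu_2)$, variances
$(v_1,v_2)$ and covariance $c$ contributes according to its observation
pattern:

| pattern | contribution |
|---|---|
| both observed | bivariate normal density $\phi_2(y_1,y_2)$ |
| one observed, one at the ceiling | $\phi(y_o)\,P(Y_c > t \mid y_o)$ via the conditional normal |
| both at the ceiling | $P(Y_1 > t,\ Y_2 > t)$, a bivariate rectangle probability |
| singleton observed | univariate density |
| singleton at the ceiling | univariate survival $\bar\Phi\!\big((t-\mu)/\sigma\big)$ |

Incomplete pairs (one twin's score missing) are retained with their
univariate contribution — raw-data full-information maximum likelihood
(FIML). A stored score equal to the threshold is *always* treated as
censored; the flag is derived from the data, never trusted from input,
because the ceiling is a property of the instrument.

The rectangle probability is the numerical crux. `bvn_upper_rect()`
reduces $P(Z_1>h, Z_2>k)$ to the one-dimensional integral
$\int_h^\infty \phi(z)\,\bar\Phi\!\big((k-\rho z)/\sqrt{1-\rho^2}\big)\,dz$
evaluated by adaptive quadrature to absolute accuracy near $10^{-12}$;
degenerate correlations ($\rho = \pm 1$) use closed forms. Inside the
optimizer a vectorized fixed-order Gauss–Legendre evaluation of the
equivalent correlation-integral form handles thousands of pairs at once
(it agrees with the adaptive kernel to $10^{-10}$ and falls back to it for
$|\rho| > 0.92$). Both routes are tested against the arcsine orthant
closed form and a $10^7$-draw Monte-Carlo oracle.

## The twin model and its ladder

The ACE covariance structure uses the identity-by-descent logic: the
implied within-pair covariance is $a^2 + c^2$ for MZ and
$\tfrac12 a^2 + c^2$ for DZ pairs; the DZ additive-genetic correlation is
fixed at 0.5 (no dominance, no sex-limitation models — the design tests
sex differences in *means* only). Means carry a per-twin sex covariate
(boys' increment), optionally per SES group, and optionally a per-group
PGS slope. Twins in a pair share the intercept; per-twin sex covariates
handle opposite-sex DZ pairs naturally.

Model specifications (`twin_spec()`) declare which blocks are stratified
by SES versus equated, so the free-parameter count — and therefore every
likelihood-ratio degree of freedom — follows mechanically from the spec.
The canonical analysis ladder run by `run_pipeline()` is:

1. total-sample ACE;
2. 1-df test of C;
3. SES-stratified means (+ per-group sex tests, C-after-SES test);
4. SES-stratified variance components (9-df moderation test);
5. PGS means/variances by SES (3-df equality tests);
6. EA-on-PGS inside the twin model (3-df slope and intercept equality);
7. DZ within-pair PGS correlation;
8. within-family higher-versus-lower-PGS contrast (1-df).

### Numerical choices

* **Variance parameterization.** Components are optimized on the SD scale
  and squared in the model. Non-negativity holds by construction and the
  $c^2 \to 0$ boundary is an interior stationary point of the profile, so
  boundary estimates are exactly 0 rather than clipped.
* **Optimization.** Quasi-Newton (`nlminb`) with moment-based starts
  (group means by sex; ACE split from the observed twin correlations,
  $a^2_0 = 2(r_{MZ}-r_{DZ})V$) and a deterministic table of perturbed
  restarts (variances scaled by fixed factors, intercepts shifted by fixed
  offsets). No random jitter: fits are bit-reproducible for a fixed
  dataset. Convergence requires a clean optimizer exit and agreement of
  the two best starts in $-2\log L$ within $10^{-4}$.
* **Confidence intervals** are profile-likelihood: bounds where the
  profile deviance rises by the $\chi^2_1$ quantile, with re-optimization
  of all other parameters. Variance components profile on the SD scale;
  when the profile at zero stays under the cutoff the lower bound is
  reported as exactly 0.0. (Whether published twin-model intervals of this
  kind are profile or Wald is usually unstated; profile is implemented
  here because it reproduces the characteristic 0.0 lower bounds, and at
  large $n$ it agrees with Wald intervals — a tested property.)
* **Degenerate inputs.** Pairs with both scores missing are rejected;
  separating A from C requires both zygosities (an MZ-only sample leaves
  $a^2$ and $c^2$ unidentified); a stratified model with an empty SES cell
  fails loudly; non-positive-definite moment sets are treated as
  infeasible points by the optimizer and as errors at the user interface.
* **Significance convention.** p-values are always reported; the
  pipeline's default decision threshold is $\alpha = 0.01$, a deliberate
  choice so that mid-range p-values (a few percent) on multi-df variance
  tests are read as "retainable" rather than decisive. It is configurable.

## The synthetic cohort generator

Because individual-level twin-register data cannot be redistributed, the
package carries a first-class generator (`sim_config()`,
`simulate_cohort()`) whose defaults encode the study conditions the
estimators are meant to face:

* four SES strata with MZ/DZ cell counts (320/571, 1030/1859, 766/1378,
  363/642 pairs), girls' mean scores 533.2, 535.8, 538.9, 542.0 and boys'
  increments 1.3, 1.2, 1.2, 0.3;
* ACE variances decreasing with SES: A = 65.9, 60.8, 52.3, 47.8;
  C = 2.7, 1.8, 0, 0; E = 17.9, 16.5, 14.7, 11.2 (score points squared);
* ceiling censoring at 550 (the censored fraction rises from ~4% to ~14%
  across strata), floor clipping at 501 *without* a censoring flag — the
  floor's mass is negligible and is deliberately not modeled in the
  likelihood;
* 14% incomplete pairs (one twin's score missing at random);
* standardized PGS with SES-increasing group means (−0.30, −0.10, 0.10,
  0.30 — calibration constants chosen to put the 3-df mean-equality
  chi-square in the empirically observed range at ~2300 genotyped
  children, not estimates), unit within-group variance, within-pair
  correlation 1 (MZ) / 0.5 (DZ, configurable upward for assortative
  mating), and an EA effect of 2.7 points per SD so the PGS accounts for
  roughly 10% of within-group variance.

**Where the PGS sits in the generating model.** The PGS is a measured slice
of the additive-genetic component, not an extra variance source: the
generator draws $A_i = \beta\,(PGS_i - \mu_g) + R_i$ with
$\mathrm{var}(R) = a^2 - \beta^2\sigma^2_{PGS}$ and $R$ correlated 1 (MZ)
/ 0.5 (DZ) across co-twins. With the default DZ PGS correlation of 0.5
the total additive component has exactly variance $a^2$ and twin
correlations 1 / 0.5, so the configured ACE values are the *true*
generating decomposition whether or not an analysis uses the PGS, and the
group means are exact because the PGS is centered within group. Raising
the DZ PGS correlation above 0.5 (assortative mating) perturbs the DZ
genetic correlation by at most $\beta^2\sigma^2 \Delta r / a^2$ — under
the defaults, below 0.01 in correlation units.

Randomness is drawn from named substreams (sexes, PGS, ACE components,
missingness), so switching one feature off does not perturb the others,
and generation is byte-reproducible given the seed.

**What the generator does *not* emulate:** genotypes and LD structure
(the PGS arrives as a score), the item-level test and its IRT equating
(scores are drawn normal before censoring, whereas real standardized
scores are slightly negatively skewed even below the ceiling),
non-response correlated with SES, age and cohort effects, and parental
genotypes (no non-transmitted-allele designs). Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to these departures.

**A calibration honesty note.** The generator's marginal latent score
distribution has mean ≈ 537.9 and SD ≈ 9.0. The published marginal of the
national test is mean 535, SD 9 — but that describes the full national
test-taking population, while the group means and cell counts above
describe a twin cohort that over-represents high-SES families (a
documented property of the register). The two cannot both be matched by
any one configuration; the package keeps the group-level truth exact and
lets the marginal mean fall where the SES mix puts it.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle: the
rectangle kernel against closed forms and Monte Carlo; the dataset
deviance against a directly-coded bivariate density; uncensored saturated
correlations against the product-moment estimate; profile intervals
against Wald intervals at scale. Parameter recovery runs on cohorts of
6,000 pairs per experiment (SE of a recovered mean ≈ 0.14 points; of
$a^2$ ≈ 1.6; of $c^2$ ≈ 1.8 — which is why the C component is checked
against an absolute ±3 SE band while A, E and the total use relative
bands). Censoring-correction efficacy is a paired 50-replicate simulation
on the heaviest-ceiling cell, where the naive (uncensored-likelihood)
mean is biased low by ≈ 0.6 points and the corrected fit is unbiased.
Likelihood-ratio calibration uses 1,000 replicates for the 3-df PGS
mean-equality and 1-df within-family nulls and 500 replicates for the
3-df slope-equality null, at 500 pairs (300 DZ pairs for the
within-family null) per replicate — sizes chosen so the whole suite runs
in minutes on one CPU while keeping the binomial check on the 5%
rejection rate sharp to about ±1.4 (±1.9) percentage points.

## Worked example

```{r, eval = FALSE}
library(twincens)

cfg <- sim_config()                  # the documented default cohort
d   <- simulate_cohort(cfg, seed = 1)
rep <- run_pipeline(d)               # the eight-stage ladder
print(rep)
report_json(rep, "report.json")
```

Individual pieces are exported for focused analyses:
`fit_twin_model(data, twin_spec(...))`, `twin_correlation()`,
`pgs_by_ses_tests()`, `ea_on_pgs_fit()`, `dz_pgs_correlation()`,
`within_family_test()`, and `profile_ci()`.

## Known limitations

* Group-wise moderation only: SES enters as four strata, not as a
  continuous moderator; no ADE or sex-limitation variance models; no
  multivariate or extended-pedigree models.
* The floor at 501 is clipped in the generator but not modeled in the
  likelihood; with realistic parameters fewer than one score in ten
  thousand is affected.
* The within-family contrast is implemented as a mean-difference
  parameter on PGS-ordered pairs with a 1-df test (with an OLS
  difference-regression sensitivity estimator alongside); other
  parameterizations of the same contrast exist and are not all
  equivalent at small $n$.
* Profile intervals assume a unimodal profile; severely under-identified
  fits report non-bracketed bounds as missing rather than guessing.
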