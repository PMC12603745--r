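---
title: "Methods: regional vulnerability indices and the brain-body battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional vulnerability indices and the brain-body battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainbody)
```

## The model

A Regional Vulnerability Index asks a simple question: how much does one
person's pattern of regional cortical thickness resemble the *average*
structural signature of a disorder, as established by large case-control
meta-analyses? The signature — the expected pattern (EP) — is a vector of 34
standardized effect sizes, one per Desikan-Killiany cortical region. The
subject's profile is made comparable to it in four fixed steps:

1. **Hemisphere averaging.** `thickness = (lh + rh) / 2` per region.
2. **Residualization.** Per region, OLS on an intercept plus age, sex,
   intracranial volume, comorbidity flags (ADHD, type-2 diabetes) and an
   ordinal image-quality rating, fitted on the *pooled* sample. Pooling is
   deliberate: the later z-normalization also uses the full sample, and
   mixing a controls-only regression with full-sample scaling would make the
   two stages inconsistent. A controls-only fit is available
   (`normalize_profiles(pooled = FALSE)`) as a sensitivity variant and is
   flagged in the run report.
3. **Rank-based inverse normal transform (INT).** Residuals are mapped to
   normal quantiles via their ranks, `qnorm((r - c)/(n - 2c + 1))`. We use
   the Blom offset `c = 3/8` — the convention of the rank-normalization
   ecosystem this pipeline is modeled on — with `c = 1/2` available for
   sensitivity runs. Ties get average ranks, so tied inputs map to one
   output value. The INT makes the final correlation robust to marginal
   non-normality at the cost of discarding the residuals' scale.
4. **Z-normalization** per region with the mean and sample (n−1) standard
   deviation of the full sample.

The RVI for subject *s* and disorder *d* is then the Pearson correlation
over the 34 regions between the normalized profile and the EP. Because both
vectors enter a correlation, the RVI is invariant to affine rescaling of
either — which is why the EP's units (Cohen's d, log-OR, etc.) never matter,
only its *shape*. EPs are stored in case-minus-control orientation, so
patients are expected to score higher; group tests report Cohen's d in
HC-minus-SZ order, making the expected sign negative.

Nine disease classes are carried by the default registry (SSD, BD, MDD, AD,
PD, hypertension, metabolic syndrome, T2D, ADHD). EP values themselves are
*data*, supplied by the user or generated synthetically — published
meta-analytic effect sizes are not redistributed with the package.

## Group inference

Every two-group comparison runs through one gate: Shapiro-Wilk within each
group at α = 0.05; if both groups look normal, an independent two-sample
t-test, otherwise a two-sided Mann-Whitney U (normal approximation with
continuity correction when either group exceeds 8 observations, exact
otherwise). We default to Welch's t rather than the pooled-variance form —
with unequal group variances the pooled test is anticonservative, and with
equal variances Welch loses almost nothing; the pooled form sits behind
`var_equal = TRUE` and the run report records which was used. RVI tests
always take the t branch (the scores are correlations of rank-normalized
profiles and close to normal by construction), as do component-score tests.

Three FDR families are kept separate, mirroring how such results are
conventionally reported: the nine RVI tests, the retained-component tests,
and the fitness/psychopathology battery (unadjusted by default;
`adjust_battery = TRUE` opts in). Post-hoc power uses the noncentral t
distribution with `ncp = d*sqrt(n1*n2/(n1+n2))` and is reported at the
observed d and at the 0.2 / 0.5 / 0.8 benchmarks; at `d = 0` the formula
returns α exactly, a useful self-check.

## Latent structure

The combined battery (computed RVIs plus psychopathology and fitness
variables) is screened with the Kaiser-Meyer-Olkin measure: per-variable MSA
is `Σr² / (Σr² + Σa²)` over off-diagonal pairs, with anti-image partial
correlations `a` taken from the inverse correlation matrix. Screening is a
*single pass*: variables with MSA below 0.5 are dropped unless they appear
on a theory-driven retain list (by default the SSD and BD indices, the core
psychosis-spectrum constructs), and the overall MSA is recomputed once on
the survivors. We do not iterate the rule because iterated exclusion couples
the decision to estimation noise in small samples and makes the retained set
order-dependent.

Component count comes from Horn's parallel analysis in its classical form:
eigenvalues of the observed correlation matrix against the 95th percentile
of eigenvalues from 1000 standard-normal datasets of the same shape,
retaining the leading run of exceedances. Defaults (1000 replicates, 95th
percentile) are our documented choices; the retention rule is deterministic
given the seed.

PCA is computed on the correlation matrix, the retained loadings varimax-
rotated with Kaiser normalization (convergence tolerance 1e-10, tight enough
that a planar grid search cannot beat the criterion). Orthogonal rotation
preserves per-variable communalities — asserted to 1e-8 in the tests.
Components are re-ordered by rotated explained variance and sign-fixed so
each component's dominant loading is positive. Subject scores use the
regression method (`Z R⁻¹ L`) and are standardized before group testing;
regression scores of an orthogonal rotation are only approximately
uncorrelated in-sample, so the tests assert `|r| < 0.1` rather than exact
orthogonality. Component *labels* ("Psychosis-spectrum Vulnerability",
etc.) are reporting metadata keyed by dominant loadings, never used in
computation.

## Anthropometrics and fitness

Body density uses the four-site Durnin–Womersley log-linear model
`density = c − m·log10(sum4)` with the age/sex-banded coefficients of the
original calibration study shipped as a code-defined table
(`durnin_womersley_coefficients()`, ages 17–72); percent fat follows Siri,
`(4.95/density − 4.5)·100`. Skinfold site values pool all repeats and sides
equally. WHR, WHtR and BMI are plain ratios.

The Chester step test records heart rate per completed 2-minute level
(cadence rising 60→140 bpm, i.e. 15→35 steps/min on a 30 cm step) and stops
at 80% of the age-predicted maximum (`0.8·(220 − age)`). With at least three
completed levels, VO₂max is the least-squares line of per-level aerobic cost
on heart rate evaluated at the *full* predicted maximum `220 − age` — the
analytic counterpart of the protocol's graphical extrapolation to the
maximum-heart-rate crossing, not to the 80% stopping cap. With fewer levels
the estimate is undefined with a structured reason. The per-level aerobic
costs (16, 21, 26, 31, 36 ml O₂/kg/min) are protocol-standard defaults for
the 30 cm step and are configurable, since sites read them off printed
datasheets that vary in vintage. Grip strength averages the per-side means
of two trials per side; jump width takes the best trial.

## The synthetic cohort generator

The generator exists so that every stage is testable end to end without
clinical data; its defaults are the study conditions the package targets: 43
controls and 42 patients, 34 regions, nine disorders with pairwise EP
correlation 0.3 (disorder signatures overlap — the premise of any
transdiagnostic analysis), and a 17-variable battery driven by three latent
factors (general-risk indices; fitness/anthropometry; psychosis-spectrum
plus psychopathology, with the Parkinson index cross-loading) with group
shifts of 0.7 and 1.36 sd on the fitness and psychosis factors only —
matching which latent dimensions separate groups in this design. Baseline
thickness is 2.5 mm with 0.1 mm residual region noise and 0.02 mm
per-hemisphere measurement noise; covariate effects (age slope −0.005
mm/year, sex offset 0.02 mm, a small ICV slope, a QC-rating effect) are
built in so residualization has real work to do. Age is uniform on 18–60,
sex ~ Bernoulli(0.68) (the cohort shape this emulates is two-thirds male),
ICV ~ N(1.5·10⁶, 1.5·10⁵) mm³.

Disorder patterns are drawn per region from a multivariate normal with the
target cross-disorder correlation matrix; at 34 regions the *realized*
correlation between two nominally uncorrelated patterns wanders within
roughly ±0.35, which is why specificity properties are asserted on averages
over cohorts with freshly drawn patterns. Patient thickness receives an
EP-aligned mean shift `scale · noise_sd · pattern` (injection defaults to
zero — a null cohort); `calibrate_effect_scale()` finds by bisection on a
20,000-subject pilot (common random numbers across evaluations, tolerance
0.02) the scale whose expected RVI Cohen's d matches a target such as 1.1.
All randomness flows from one master seed through fixed stream offsets
(patterns, covariates, thickness, battery, fitness records), so identical
configs give byte-identical cohorts.

Two honest simplifications. First, region noise is independent Gaussian
after pattern injection — the simplest model under which the RVI's
correlation statistic behaves as assumed; real cortical thickness has
spatially correlated noise, so passing tests say nothing about spatial
autocorrelation. Second, the raw fitness records (skinfold repeats, step
heart rates, trials) are generated as plausible measurements to exercise the
anthropometric derivations, but are not numerically consistent with the
factor-model battery columns; inverting Durnin–Womersley and Chester to
impose a latent structure on raw measurements would add complexity without
testing anything additional. In the pipeline, the computed RVIs replace the
generator's RVI-named battery columns for the PCA stage.

## Numerical choices and degenerate inputs

- INT requires ≥ 2 values and errors when all values are tied; a
  zero-variance region errors in `znormalize()` naming the region.
- Zero-variance profiles or patterns make the RVI undefined: an error by
  default, `NA` with a warning under `lenient = TRUE`.
- A rank-deficient design errors naming the collinear columns; constant
  covariates are absorbed by the intercept with a message.
- BH adjustment computes `m/i · p` in that order so that `adjusted ≥ raw`
  holds in floating point as well as on paper.
- KMO on an (effectively) identity correlation matrix is 0/0 and is
  reported as `NA` with a warning; a singular correlation matrix errors
  naming the most collinear pair.
- Bisection in the calibrator aborts with the attained maximum when a
  target d is unreachable at the configured noise level.

## Problem sizes used in the checks

The bundled tests and the acceptance script run at sizes chosen to make
Monte-Carlo error small relative to the asserted tolerances on a single
CPU: 2000 null cohorts for type-I calibration (the ±3·SE band around 0.05
is [0.035, 0.065]), 500 cohorts for effect recovery against the calibrated
d = 1.1, 50,000 replicates for the Monte-Carlo power cross-check (SE ≈
0.002 against a 0.01 tolerance), 1000 random vectors for the INT and BH
oracle comparisons, and 100 re-runs of the stochastic null simulation for
the parallel-analysis stability check.

## Known limitations

Only cortical thickness is modeled — no subcortical, white-matter or
surface-area variants of the index. No site harmonization (single-site
design assumed). The full maximum-likelihood factor-analysis sensitivity
check is out of scope; the PCA path is the implemented analysis. EP
heterogeneity (patterns estimated from populations unlike the analysis
cohort) is a real-world caveat the synthetic generator does not emulate.
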