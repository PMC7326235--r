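---
title: "Methods: a fuzzy-set reproductive ageing score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a fuzzy-set reproductive ageing score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rascore)
```

## The problem and the model

The menopausal transition takes years, yet the conventional description —
pre-, peri-, postmenopausal — is categorical, with thresholds that lump
women at quite different stages together. `rascore` computes a continuous
reproductive ageing score (RAS) in [0.00, 1.00] from three questionnaire
items: age, the number of menstrual periods in the last twelve months, and
the three-level regularity answer ("regular" / "irregular for a few
months" / "stopped").

Fuzzy set theory supplies the machinery. A membership function μ assigns
each woman a degree of belonging to the set "advanced reproductive age",
rather than a hard class. Two memberships are combined:

**μ_A — menstrual pattern.** From a cohort cross-tabulation, the
proportion of regularly menstruating women among those reporting a given
period count is P(period) = x/(x+y+z), with x, y, z the counts of the
three regularity answers. The development data (3107 women aged 38–66,
RHINE multicentre study; shipped as `rhine_period_crosstab()`) show P near
0 at zero periods, near 1 at twelve, and falling again above twelve —
cycles both lengthen and shorten early in the transition. The smooth
approximation is an exponential of a quartic,

$$\hat P(\text{period}) = \exp(c_4 u^4 + c_3 u^3 + c_2 u^2 + c_1 u + c_0),
\qquad u = \text{period} - \text{shift},$$

and μ_A = 1 − P̂, clamped into [0, 1]. The published coefficients
(`default_mu_a()`) use shift = 0.7.

**μ_B — age.** The proportion of women whose menses have stopped at each
year of age, P(age) = z/(x+y+z) (`rhine_age_crosstab()`), is sigmoidal in
age and approximated by a logistic with quadratic linear predictor,

$$\mu_B(\text{age}) = \mathrm{plogis}(b_2\,\text{age}^2 + b_1\,\text{age} + b_0).$$

Before evaluating μ_B, age is modified for two factors associated with
earlier menopause: +2 years for current smoking, +1 year for unilateral
oophorectomy (so a smoker with one ovary gets +3). The offsets are model
parameters (`ras_model()`), can be disabled with `use_modifiers = FALSE`
when smoking or oophorectomy are analysed in their own right, and apply to
*current* smoking only — former smokers are not modified.

**Aggregation.** The score is the algebraic (probabilistic-sum) fuzzy
union, RAS = μ_A + μ_B − μ_A·μ_B. It is commutative, has 0 as neutral and
1 as absorbing element, never falls below either membership, and stays in
[0, 1] whenever its inputs do.

The model assumes a natural transition: women currently using exogenous
sex hormones, pregnant or breastfeeding women, women whose irregularity
has a cause other than menopause, and women with bilateral oophorectomy
are excluded up front (`apply_eligibility_filters()`). Bilateral
oophorectomy in particular is an exclusion rather than an automatic score
of 1.00: the modifiers only cover the loss of one ovary, and scoring
surgical menopause with a natural-transition model would be invented
biology.

## Numerical choices

*Clamping μ_A.* The published coefficients make the fitted proportion
exceed 1 slightly around 12–13 periods, so the raw 1 − P̂ dips just below
zero there (about −0.06 at twelve periods). μ_A is therefore clamped into
[0, 1] *after* evaluation; the clamp is part of the model contract (it is
what keeps RAS inside [0.00, 1.00]) and is stated in the CLI help.
Clamping lives in the membership evaluators only — `fuzzy_union()` rejects
inputs outside [0, 1] rather than silently repairing them.

*Support of μ_A.* The development data end at 15 periods and the quartic
exponent is unconstrained beyond that, so period counts above 15 are
clamped to 15 with a warning.

*The 0.7 shift.* A shifted quartic is itself a quartic, so the shift is a
redundant parameterisation. Refits fix shift = 0; the packaged default
model keeps shift = 0.7 so the published curve is evaluated exactly as
printed.

*Fitting.* Both curves are fitted by **unweighted** least squares in
probability space over the observed grid points: grid rows with zero
totals are dropped (the fit sees only observed points, matching the
discrete series the curves approximate), and each point counts equally
regardless of its cell count. Whether the original development fit was
count-weighted is not documented; unweighted refits reproduce — indeed
improve on — the published approximation errors (mean squared error
0.0022 vs 0.011 for μ_A on 16 points, 0.0011 vs 0.002 for μ_B on 29
points), so unweighted is the package's choice. Optimisation is
Levenberg–Marquardt (`minpack.lm::nls.lm`) started from a closed-form
linear fit — ordinary least squares of the quartic on log P (points with
P strictly inside (0, 1)) for μ_A, of the quadratic on logit P (clipped
to [10⁻⁴, 1 − 10⁻⁴]) for μ_B. Start and refinement are deterministic; no
random restarts. Non-convergence is reported in the `converged` flag,
never silently.

*Degenerate inputs.* Fits require at least 6 (μ_A) / 4 (μ_B) grid points —
one more than the free parameters. Validation issues are returned as data,
not raised, so batch processing can proceed; a record reporting stopped
menses with 1–12 recent periods is accepted (recently stopped), while
stopped with more than 12 is flagged as contradictory. Hormone values are
used only as complete FSH/estradiol pairs; half-pairs draw an advisory and
are ignored, never imputed or coerced to zero. Ages are whole years
(fractional ages truncate toward zero with a warning), because the
development cross-tabulation is by year of age.

## Validation against hormones

`classify_menopausal_status()` applies the established combined serum
cut-offs: nonmenopausal = FSH ≤ 20 IU/L and 17β-estradiol ≥ 147 pmol/L;
postmenopausal = FSH ≥ 80 IU/L and estradiol ≤ 73 pmol/L; every other
combination is perimenopausal. Two ROC contrasts are run with the RAS as
discriminator: nonmenopausal vs the rest, and postmenopausal vs the rest.
The AUC equals the Mann–Whitney pair statistic (ties count ½); the test
suite checks this against brute-force pair counting on small inputs. The
95% interval uses the DeLong method — the conventional nonparametric
choice; the method name is carried in the result so downstream reports
are explicit about it. `quartile_summary()` tabulates age, menstrual
pattern and hormone levels within the conventional score bins 0.00–0.25,
0.26–0.50, 0.51–0.75, 0.76–1.00, binning the score after rounding to two
decimals (matching the two-decimal bin labels) with right-closed bounds.
Score rounding anywhere else is presentation-only.

## The synthetic cohort generator

No per-woman development or validation records are distributable, so
`generate_cohort()` simulates the statistical structure the method
assumes. Each woman receives a latent transition stage

$$u = \mathrm{plogis}\!\left(\frac{\text{age} - 51 + \varepsilon}{3}\right),
\qquad \varepsilon \sim N(0, 2^2)\ \text{years},$$

which drives everything else: menses stop with probability u (making the
stopped-by-age series sigmoidal, midpoint near 51 — the observed
transition midpoint in the development data); menstruating women become
irregular and lose periods as u grows, with occasional counts of 13–15
most likely mid-transition (shortening cycles); FSH rises and estradiol
falls log-linearly in u between the anchor medians 11 → 124 IU/L and
264 → 12 pmol/L with lognormal noise (σ = 0.5 on the log scale — hormone
spreads are strongly right-skewed). A latent *continuous* stage, rather
than a three-class simulator, is deliberate: the score's central claim is
about intermediate values, and the generator must exercise them.
Exclusion flags default to small nonzero prevalences (hormone use 5%,
pregnancy 1%, breastfeeding 1%, unrelated irregularity 2%, bilateral
oophorectomy 1%) so the eligibility filter is always exercised; smoking is
20% and unilateral oophorectomy 3%. Same seed, same configuration →
byte-identical cohort, and the caller's RNG stream is left untouched.

What the generator does *not* emulate: survey non-response, centre
effects, assay error structure, exogenous-hormone use correlated with
symptoms, or any demographic realism beyond what the score consumes.
Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers the structure it assumes — not field performance on a
real population; the published validation AUCs (0.91 and 0.85 against
hormone cut-offs) come from a real cohort whose records are not
deposited. On the default synthetic cohort the two contrasts reach AUC
≈ 0.92 and 0.91, which the test suite checks only against the weaker
bound 0.8.

## Problem sizes and runtime

The package's standard checks use cohorts of 200–5000 synthetic women
(5000 for the hormone-validation and coupling properties, 3000 for refits
on synthetic cross-tabulations, 2000 for the null-AUC check), the full
16- and 29-point development series for all curve refits, and 20–25
randomised small inputs (n ≤ 50) for the brute-force AUC oracle. The
whole suite runs in a few seconds on one CPU.

## Known limitations

- The score covers the natural transition in the development age range
  38–66; μ_B extrapolates outside (a warning is logged outside 35–70) and
  μ_A is clamped above 15 periods.
- Factors such as chronic disease, gynaecological disorders and past
  hormone use are not modelled — a limitation shared with categorical
  staging consensus schemes.
- The development population is Northern/Western European; transition
  timing differs between populations, so the printed coefficients may need
  refitting elsewhere (`fit_mu_a()`/`fit_mu_b()` on a local
  cross-tabulation is exactly that).
- The RAS stages progress toward menopause; it is not a climacteric
  symptom score and does not measure post-menopausal health.
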