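---
title: "Methods: points-based prediction of early pregnancy loss after IVF-ET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: points-based prediction of early pregnancy loss after IVF-ET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eplscore)
```

## The model

After in vitro fertilization with embryo transfer (IVF-ET), the first
routine transvaginal scan on days 27–29 after transfer yields a handful of
measurements — gestational sac diameter (GSD, mm), yolk sac diameter (YSD,
mm), embryonic length (EL, mm) and embryonic heart rate (EHR, bpm) — that,
together with maternal age (MA, years) and endometrial thickness on
transfer day (EM, mm), predict whether the pregnancy will be lost by 12
weeks (early pregnancy loss, EPL). `eplscore` implements the standard
two-stage construction of a clinical points system from such data:

1. **Logistic stage.** A binary logistic regression of the EPL outcome on
   the candidate predictors, with backward stepwise screening by Wald
   p-value, gives per-unit log-odds coefficients $\beta_i$.
2. **Points stage** (the Sullivan/Framingham convention). Each factor $i$
   is discretized into intervals $j$ with representative values $W_{ij}$;
   one interval is the base with reference value $W_{i\mathrm{REF}}$. The
   integer points for interval $j$ are
   $$\mathrm{points}_{ij} = \operatorname{round}\!\left(\frac{\beta_i\,(W_{ij} - W_{i\mathrm{REF}})}{B}\right),$$
   where $B$ is the base constant fixing how much log-odds one point is
   worth. The published system takes $B = 5\,\beta_{\mathrm{MA}} = 0.46$,
   i.e. one point equals the risk increase of five years of maternal age.
   A patient's total is the sum of their per-factor points, and a lookup
   table attaches an estimated miscarriage risk to each achievable total
   (−8 … 14 for the published system, with risks 0.18% … 95.42%).

The published six-factor system ships as a JSON fixture. Only the
coefficients, intervals, representative values, $B$ and the risk table are
stored; the integer points are re-derived on every load, so the fixture can
never drift from the stated formula.

### Interval conventions

The printed category labels leave formal gaps ("<29" followed by "30–39")
and one overlap-free but boundary-ambiguous pair per factor. We resolve
them with half-open $[\ell, u)$ intervals and these boundary choices: MA
30/40; GSD 9/13/27 with 27.0 belonging to the middle interval (its label
"13.0–27.0" names the boundary, and ">27.0" is explicitly exclusive); EL
2.0/6.3 with 6.3 in the middle interval; EHR 100/130 with 130 in the top
interval (its "≥130" label is explicit); YSD 3.00/5.00; EM 10.0/15.0. The
printed gaps are empty at the resolution the quantities are measured
(integer years, 0.1 mm, integer bpm), so these choices change no
achievable measurement's category; explicit "≥"/">" labels win at their
own boundary.

### Rounding

Points use commercial rounding — halves away from zero — because the MA
"≥40" interval has a scaled contribution of exactly 1.5 and carries 2
points. `round_half_away()` implements this with a $10^{-9}$ guard against
binary representation error: the product $0.0920 \times 7.5 / 0.46$
evaluates a hair below 1.5 in double precision, and without the guard the
tie would be lost to 1.

### The U-shaped yolk sac

For YSD the printed contribution of the large-sac interval is positive
(+0.32 for $W = 6.00$) although $\beta\,(W - W_\mathrm{REF})$ is negative:
both small and large yolk sacs are abnormal findings that raise risk. The
factor therefore carries an `"absolute"` deviation mode,
$|\beta_i||W_{ij} - W_{i\mathrm{REF}}|/B$, so deviation in either
direction scores positive points. All other factors are `"signed"`.

### Degenerate measurements

Absent cardiac activity is encoded as EHR = 0 bpm (falling in "<100", 5
points) and an absent embryo as EL = 0 mm ("<2.0", 2 points). Both are
legitimate measurements, not missing data: the EPL group's heart-rate
summary (mean 42.4, SD 53.5 bpm) is only attainable if scans without
cardiac activity entered the average as zeros.

## The synthetic cohort generator

The original patient-level data are not public, so the generator creates
cohorts with the statistical structure the analysis assumes; every
downstream stage is exercised against them.

**Group-conditional mode** draws the outcome from
Bernoulli(prevalence = 1926/13977 ≈ 0.1378) and then each variable from
its outcome group's normal distribution truncated below at 0, using the
published group means and SDs (e.g. GSD 18.5 ± 3.6 mm ongoing vs
13.2 ± 4.8 mm EPL; intrauterine hematoma Bernoulli 0.160 vs 0.1885).

The EPL-group heart rate cannot be a truncated normal: no such
distribution on $[0,\infty)$ has mean 42.4 with SD 53.5. The biology
suggests the right shape — a mixture of scans with no cardiac activity
(EHR = 0) and beating hearts. We fix the beating component's SD at
12.2 bpm (the viable-pregnancy spread) and solve the two moment equations
for the zero weight $w_0$ and the beating mean $\mu$ at configuration
time; writing $q = 1 - w_0$ they reduce to
$q^2\sigma^2 - q\,(m^2+s^2) + m^2 = 0$, whose admissible root gives
$w_0 \approx 0.61$ and $\mu \approx 108.5$ bpm — about 61% of losses
without cardiac activity and survivors beating near-normally, which is
clinically plausible.

```{r mixture}
solve_ehr_mixture(mean = 42.4, sd = 53.5, positive_sd = 12.2)
```

**Logistic-generative mode** draws covariates from the pooled population
(the prevalence-weighted mixture of the two groups) and the outcome from
$\mathrm{Bernoulli}(\mathrm{expit}(c + \sum_i \beta_i x_i))$ with the
published coefficients as defaults. When no intercept is supplied, $c$ is
calibrated by root-finding so the expected event rate over the realized
covariates equals the configured prevalence. Because the outcome truly
follows a logistic model here, this mode supports parameter-recovery
experiments: at $n = 5\times10^4$ a refit recovers each coefficient within
three standard errors and re-derives at least 17 of the 19 published point
values in most replicates.

**Simplifications.** Variables are independent within outcome group — the
published tables report no covariance structure — with an optional
Gaussian-copula hook (`copula =` a correlation matrix) for sensitivity
analyses. The generator does not model gestational-age progression, twins,
loss to follow-up, measurement rounding, or the infertility-type /
insemination-method categories (which do not enter the final model).
Passing tests on these cohorts therefore demonstrate that the *pipeline*
is correct — that the derivation machinery recovers a known truth — not
that the published system's real-data performance (e.g. its AUC of ~0.88)
is reproduced; real-data operating characteristics are unknowable without
the cohort. On group-conditional cohorts the published system's AUC
exceeds 0.9 because independent group-conditional draws separate the
classes more cleanly than real, correlated biometry does; we deliberately
keep that as a soft sanity bound (> 0.8), not a reproduction target.

## Model fitting and screening

`fit_logistic()` obtains maximum-likelihood estimates by iteratively
reweighted least squares (via `stats::glm`, relative log-likelihood
tolerance $10^{-10}$, 100-iteration cap) with standard errors from the
observed information matrix; `wald_summary()` converts a coefficient to
the odds-ratio scale ($OR = e^\beta$, 95% CI $e^{\beta \pm 1.96\,se}$,
two-sided normal p). Quasi-separation is diagnosed — a diverging
standardized coefficient alongside boundary fitted probabilities — and
reported with the offending variable's name rather than returned as an
absurd odds ratio. Rows with missing predictors are dropped and counted.

Stepwise screening defaults to **backward elimination with
`alpha_stay = 0.10`** on Wald p-values. The direction and threshold are
genuinely open choices; we default to 0.10 because the published final
model retains the yolk-sac term at p = 0.060, which a 0.05 rule would have
eliminated, and we use Wald (not likelihood-ratio) statistics to match the
per-variable p-value style of the published factor table. Both are
configurable, and forward selection is provided.

The default candidate pool is every variable measurable at scan time (MA,
BMI, infertility duration, day-14 hCG, EM, GSD, YSD, EL, EHR, IUH). On
group-conditional cohorts the screening typically also retains hCG, BMI
and duration — they genuinely differ between groups — whereas the
published final model contains only six factors. Since only variables with
category definitions can become score factors, the pipeline's derive stage
refits on the scorable subset before converting to points and logs the
dropped covariates; this mirrors the published outcome without claiming to
explain the original selection path, which is not stated.

## Risk attached to totals

The published 23-row risk table is canonical and is **not** re-derived:
no constant-slope logistic in the total reproduces it (the implied
intercept drifts from about −2.6 at total −8 to −3.4 at total 14, so the
published risks were evidently not computed as $\mathrm{expit}(c + Bt)$
with fixed $c$). Two explicitly labelled alternatives are provided:

* `estimate_risk_curve()` — the analytic approximation
  $\mathrm{expit}(c + Bt)$, with $c$ calibrated by least squares on the
  logit scale against a reference table (held-slope least squares reduces
  to the mean logit residual; against the published table
  $c \approx -3.0$).
* `empirical_risk_table()` — a logistic fit of outcome on total score,
  used by the pipeline to attach monotone, smoothed risks to freshly
  derived systems.

## Evaluation conventions

A patient is classified as predicted-EPL when their total is **greater
than or equal to** the cutoff; that convention (not ">") reproduces the
published performance table's extreme rows (sensitivity 100%/specificity
0% at the minimum total, specificity 100% at the maximum).
Sensitivity, specificity, PPV, NPV and accuracy are computed at full
precision, with a metric whose denominator is zero reported as undefined
(`NA`, rendered "−"), never as 0; rounding to two decimals (halves away
from zero) happens only at presentation. AUC uses the midrank
Mann–Whitney statistic, which equals the proportion of event/non-event
pairs ranked correctly with ties counting one half; the test suite checks
it against an $O(n^2)$ pairwise oracle.

One published figure is knowingly not reproduced: the verification-set
NPV is printed as 93.62%, but the verification classification counts give
5686/(5686+339) = 94.37%. We report the count-derived value. (The
verification AUC is likewise printed as 0.890 in one place and 0.878 in
another; neither is reproducible without the data.) Similarly, the
printed odds ratios for GSD and EHR (0.892, 0.966) differ from the
exponentials of the printed coefficients (0.8914, 0.9666) by ~$10^{-3}$ —
one extra rounding step in the original report — and the package treats
the coefficients as primary.

## The pipeline

`run_pipeline()` chains simulate → temporal split → stepwise fit → point
derivation → evaluation. The split assigns the first 7261/13977 of the
cohort a year-1 label (training) and the rest year-2 (verification),
mirroring the original temporal design proportionally; since synthetic
records are exchangeable, a deterministic assignment is equivalent to a
random one and keeps runs byte-reproducible. Every bundle written to disk
carries provenance (seed, full config echo, package and R versions), and
two runs with the same config and seed produce byte-identical artifacts.

## Problem sizes and seeds

Simulation-based checks in the test suite use cohorts of 2,000–100,000
records and 15–300 replicates, sized so each check's Monte-Carlo error is
small against its tolerance (tolerances are 3 standard errors of the
quantity under test, binomial or normal as appropriate) while the whole
suite stays interactive. All stochastic operations take an explicit seed;
the package-level default (20160601) is recorded in every configuration
and output.

## Known limitations

* The generator's independence assumption overstates class separation;
  derived-system operating characteristics on synthetic cohorts are not
  estimates of real-data performance.
* The published risk table's construction is not documented and is
  treated as an opaque fixture; only its monotonicity and range are
  validated.
* No confidence intervals for AUC and no calibration assessment are
  provided.
* The system was derived in an IVF population scanned at a fixed
  post-transfer day; the package makes no claim about natural
  conceptions or other gestational windows.
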