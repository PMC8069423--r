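---
title: "Net survival and statistical cure in AML registry cohorts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net survival and statistical cure in AML registry cohorts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Setting

Population-based cancer registries record diagnosis, vital status and
follow-up but not cause of death, so survival attributable to the cancer
must be estimated *net* of background mortality. For a patient with
covariates $x$ (here: sex, handled by stratified fits, and age at
diagnosis), the observed hazard decomposes as

$$
h(t \mid x) = h^*(t \mid x) + \lambda_E(t \mid x),
$$

where $h^*$ is the expected (general-population) hazard read from a life
table matched on sex, attained age and calendar year, and $\lambda_E$ is
the excess mortality rate (EMR) attributable to the disease. Net survival
is $NS(t) = \exp\{-\Lambda_E(t)\}$ with
$\Lambda_E(t) = \int_0^t \lambda_E(s)\,ds$. In acute myeloid leukaemia
(AML) the EMR is very high immediately after diagnosis and falls steeply;
for some subtype/sex/age combinations it approaches zero within the
10-year follow-up window, which motivates the statistical-cure summary:
the fraction $\pi(x)$ of patients who will never die of their disease,
the time until a survivor is almost surely cured, and the median survival
of those who are not.

`amlcure` implements this analysis end to end: life-table machinery, the
flexible parametric excess-hazard model, the cure-constrained variant and
its three indicators, the model-free Pohar Perme and step-EMR benchmarks,
a registry-cohort simulator with closed-form truth, and a study pipeline
(subtype recoding, death-count model tiers, report tables).

## Expected mortality

A life table is a grid of hazards $h^*(\text{sex}, a, y)$ over integer
ages $a$ and calendar years $y$. During follow-up both the attained age
and the calendar year advance with $t$, so
$\Lambda^*(t) = \int_0^t h^*(\text{sex}, \lfloor a_0+s \rfloor,
\lfloor y_0+s \rfloor)\,ds$ is integrated exactly by splitting follow-up
at every integer age and calendar-year crossing. Three conventions:

* ages above the table maximum and years outside the table range use the
  nearest boundary row (standard registry practice; keeps hazards defined
  for long follow-up of old patients);
* fractional age at diagnosis is kept, and the rate cell is indexed by
  the floor of the attained age;
* dates are converted to decimal years with a 365.25-day year, so
  calendar-year boundaries are located to within a day in leap years —
  negligible at annual life-table resolution.

## The flexible excess-hazard model

The baseline estimator models the *log cumulative* excess hazard as a
restricted cubic spline (RCS) of log time, with age effects:

$$
\eta(t, x) \;=\; s(\ln t;\gamma) \;+\; A(\text{age})\,\beta
\;+\; \sum_j A_j(\text{age})\, s_j(\ln t;\delta_j),
\qquad \Lambda_E = e^{\eta},
\qquad \lambda_E = e^{\eta}\,\frac{\partial \eta}{\partial \ln t}\,
\frac{1}{t}.
$$

Each subject contributes
$\ell_i = d_i \log\{h^*_i(t_i) + \lambda_E(t_i, x_i)\} -
\Lambda_E(t_i, x_i)$ to the log likelihood, with $h^*_i$ evaluated
exactly at the subject's exit (no age/year banding). The model is the
standard flexible parametric (Royston–Parmar-type) relative-survival
formulation; `flexsurv` fits the proportional-hazards special case of the
same likelihood and is used as an independent cross-check in the test
suite (agreement to about six digits of log likelihood).

Choices that matter:

* **Knots.** Boundary knots at the minimum and maximum uncensored log
  event times, interior knots at equally spaced centiles. The baseline
  uses `baseline_df` + 1 knots.
* **Model tiers.** Mirroring registry practice of adapting parameter
  counts to the number of deaths: the *full* tier (used above 500 cases
  or above 130 deaths within 10 years) has a 4-df baseline, a 3-df RCS in
  age and a 2-df time-dependent interaction per age basis column; the
  *reduced* tier (70–130 deaths) has a 3-df baseline and a linear
  proportional age effect; below 70 deaths the stratum is excluded. The
  case criterion acts as a logical OR with the death criterion. These
  counts are the package's defaults and are configurable.
* **Age scaling.** Age enters as $(\text{age}-70)/10$ before basis
  construction, purely for conditioning; predictions undo it.
* **No orthogonalization.** Basis columns are used as constructed. With
  very early event times (registry data start at one day) the truncated
  cubes span several orders of magnitude and the coefficient covariance
  becomes strongly correlated; functions of the fit (survival, EMR,
  indicators) remain well determined, but single-coefficient standard
  errors should not be interpreted in isolation, and any simulation of
  coefficient uncertainty must use the full covariance.
* **Deterministic starts.** Initial coefficients are least squares of a
  crude target — $\log(r t)$ at event times, with $r$ the crude excess
  rate (deaths − expected)/person-time — and models with time-dependent
  terms warm-start from the nested proportional fit. No random restarts,
  so a refit reproduces the same result bit for bit.
* **Negative excess hazard.** $\lambda_E < 0$ is admissible pointwise
  (the total hazard must stay positive); the likelihood replaces the log
  of a non-positive total hazard by a continuous linear penalty below a
  floor of $10^{-8}$, so the optimizer never sees a non-finite value.
  Fits with a non-monotone cumulative excess hazard at event times are
  reported with a warning, and EMR predictions flag negative regions
  rather than clipping them.
* **Intervals.** 95% pointwise intervals for $NS$ are delta-method on the
  $\eta$ (log cumulative hazard) scale and back-transformed, hence always
  inside $(0,1)$; EMR intervals are delta-method on $\log \lambda_E$.
  The all-ages ("marginal") curve averages individual predictions over
  the estimation cohort's age distribution, with the delta method applied
  to the average.

## The cure model

Statistical cure means $\Lambda_E$ stops growing: beyond some time the
excess hazard is zero and survivors die at population rates only. The
cure-constrained model encodes this *structurally*. The time bases are
built backward — the RCS non-linear terms evaluated on the reversed axis,
with the linear term excluded — so every basis function and its
derivative vanish identically at and beyond the last knot $t_K$. Then for
any coefficients

$$
\pi(x) = \exp\{-\Lambda_E(t_K \mid x)\}
       = \exp\{-e^{\gamma_0 + A(\text{age})\beta}\},
$$

a smooth function of the coefficients (linear on the
complementary-log-log scale, which gives its delta-method interval).
The cure point defaults to the largest uncensored log event time; with a
10-year follow-up cap this places the plateau at about 10 years.

Derived indicators, for a fitted model or for the exact simulation truth:

* **Conditional probability of cure**
  $P(t \mid x) = \pi(x) / NS(t \mid x)$ — the probability that a patient
  alive (in the net sense) at $t$ belongs to the cured group; $P(0)=\pi$
  and $P(t_K)=1$.
* **Time to cure (TTC)**: the first $t$ with $P(t)$ at or above 0.95
  (threshold configurable), solved by bracketed root search to $10^{-6}$
  years on $[0, t_K]$; zero when $\pi$ already meets the threshold.
* **Median survival of the uncured (MedS)**: the root of
  $S_u(t) = \{NS(t)-\pi\}/(1-\pi) = 1/2$, reported in months. By
  construction $S_u(t_K) = 0$, so the root always exists.

TTC and MedS are not smooth explicit functions of the coefficients, so
their intervals use parametric simulation: 2000 multivariate-normal
coefficient draws (full covariance; eigenvalue square root for
robustness), percentile intervals, truncated below at zero. This respects
the zero bound and reproduces the wide asymmetric intervals typical of
sparse strata. The draws consume the R random stream; the pipeline seeds
it from its configuration so reruns are identical.

### The cure-assumption decision rule

Cure summaries are only reported where the assumption is tenable. The
published practice is a graphical check — the net survival curve reaches
a plateau and the EMR approaches zero (below 0.05 deaths per person-year)
within 10 years. The package operationalises it numerically: find the
first time the EMR falls strictly below the threshold; require it to stay
below through the horizon; and require the net survival drop from that
time to the horizon to be smaller than 0.02. The 0.02 plateau margin is
the package's own quantification of "reached a plateau" (the graphical
rule has none); an EMR exactly at the threshold rejects. The pipeline
scans a 1-year age grid and reports the accepted age range, filling
rejected cells with the literal token `"no cure"`.

The plateau margin is often the binding part of the rule. If the EMR
hovers just under the threshold after crossing it, net survival keeps
eroding; for a mixture-cure process with exponential clearance the drop
after the crossing is approximately $\varepsilon \lambda \pi$, so with
$\varepsilon = 0.05$ a clearance scale much beyond half a year pushes
middling cure fractions over the 0.02 margin even when the generating
process is a true cure model. This is intentional: "cure" is only
declared when the excess hazard is genuinely exhausted within follow-up,
not merely small.

## The synthetic-registry generator

Real registry data of this kind are not redistributable, so the package
ships a generator whose defaults emulate the study conditions of a French
AML registry cohort: diagnoses uniform over 1995–2015, ages
truncated-normal (mean 70, SD 13, support 15–95), a 53% male fraction,
vital status followed to the earlier of 10 years and an administrative
cutoff of 2018-06-30, and loss to follow-up below 1% (uniform censoring
over the follow-up window for a configurable 0.5% of subjects). Excess
mortality follows a mixture-cure process — cure with probability
$\pi(x)$, inverse-complementary-log-log in age and sex, otherwise a
Weibull excess death time — on top of background mortality drawn from the
life table by inverse-transform sampling along the attained-age
trajectory. Excess and background processes are independent given
covariates (the standard relative-survival assumption). Observed times
are rounded to day resolution with a one-day minimum, as registry date
arithmetic produces. Truth (cure status, latent times, cause of exit) is
written to a separate table so estimators can never read it accidentally.

The bundled `synthetic_life_table()` is a Gompertz surface
($5\times10^{-5} e^{0.095\,\text{age}}$, female rates scaled by 0.55, a
slow secular decline, capped at 0.7/year). It reproduces the broad shape
of adult background mortality, not any particular country's table; it is
labelled synthetic and real analyses should read a real table with
`read_life_table()`.

What the generator deliberately does not emulate: the 16-subtype AML case
mix and subtype-specific incidence; dependence between excess and
background mortality; informative censoring; period effects in treatment.
Passing recovery tests therefore shows that the estimators are correct
under the stated model, not that the model captures every feature of real
registry data.

The generator also supplies closed-form oracles. Under mixture truth,
$NS(t) = \pi + (1-\pi)\exp\{-(t/\lambda)^k\}$, TTC solves
$S_u(t) = 0.05\,\pi / \{0.95 (1-\pi)\}$, and MedS is the Weibull median
$\lambda (\ln 2)^{1/k}$. The indicator solvers accept these truth objects
directly, so the root-search machinery is validated against exact closed
forms independently of any fit.

## Validation design and problem sizes

The test suite validates each layer against an independent reference:
exact trajectory integration against a segment-sum oracle; spline
derivatives against central differences (to $10^{-6}$); the likelihood
gradient against central differences (to $10^{-5}$); the fitted model
against `flexsurv` on the shared special case; the Pohar Perme estimator
against a hand-computed three-record example and, with a zero life table,
against the empirical survival (the product-limit form of the event jumps
makes this exact); and the full chain against the generator's closed
forms. Replicated-recovery checks use 50 cohorts of 2000–4000 subjects
and a 5000-subject cohort for the parametric-vs-non-parametric
cross-validation — sizes chosen to keep Monte Carlo error well inside the
asserted bands while the whole suite runs in minutes.

Two quantitative behaviours are worth knowing. First, the
parametric-vs-Pohar-Perme discrepancy on well-specified simulated cohorts
stays below 0.01 in net survival; the suite asserts 0.02. Second, the TTC
point estimate carries a small upward bias (a few tenths of a year at
$\pi = 0.4$ with exponential excess times) because the spline plateau is
reached smoothly at the cure point rather than asymptotically; the
recovery tests bound it, and it is insensitive to the baseline df (4, 5
and 6 df behave alike, so the full-tier default of 4 is kept for cure
fits).

## Known limitations

* The Pohar Perme variance uses the standard weighted counting-process
  formula; no bootstrap.
* The step-EMR benchmark attributes exposure exactly (no actuarial
  half-interval), so its integral matches the Pohar Perme cumulative
  excess hazard only up to interval-width discretisation.
* Non-parametric net survival may exceed 1 or rise locally; this is a
  property of the estimator and is not clipped.
* The cure point is tied to the last event time; with follow-up much
  shorter than the true cure horizon, $\pi$ is an extrapolation and the
  decision rule (which would reject such strata) is the intended guard.
* Age ranges for cure acceptance are scanned at 1-year steps; finer
  structure inside a year is not resolved.
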