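---
title: "Statin-naive landmark models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statin-naive landmark models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(statinnaive)
```

## The problem

A 10-year cardiovascular risk score is used to decide whether to start a
statin, so the quantity of clinical interest is the risk *in the absence
of future statin initiation*. Deriving such a score from routine records
is circular: a sizeable fraction of the derivation cohort initiates
statins during follow-up, their post-initiation hazard is reduced, and a
model that ignores this learns a mixture of treated and untreated event
rates. The bias concentrates in the coefficients of the factors that
drive prescribing — total cholesterol above all — and in the baseline
risk of the ages where initiation is common.

`statinnaive` addresses this by *constraining* the treatment effect to
external trial evidence instead of estimating it: follow-up is split at
the initiation date and the post-initiation hazard is multiplied by a
fixed 0.75 through a log-hazard offset. Nothing about the treatment
effect is learned from the observational data; what the data do provide —
risk-factor associations and baseline hazards — is then estimated free of
the drop-in distortion.

## The two-stage landmark model

**Risk sets.** For each landmark age $a \in \{40,\dots,85\}$ and sex, the
risk set contains everyone under observation at age $a$ with no prior
cardiovascular event and no prior statin prescription. "Prior" is strict:
an event or prescription exactly at $a$ counts as after it, so follow-up
lives on $(a, a + 10]$. Follow-up is capped at the 10-year horizon, and a
minimum positive follow-up of $1/365.25$ years (one day) keeps the
likelihood defined for same-day events. With both sexes this yields the
92 age- and sex-specific models.

**Stage 1.** Measurements of SBP (mm Hg), total cholesterol (mmol/L),
HDL cholesterol (mmol/L) and current smoking (0/1) from the 10 years
before the landmark age are first cleaned (values outside 60–250 mm Hg,
1.75–20 mmol/L and 0.3–3.1 mmol/L respectively are set to missing,
value-wise), standardized with sex-specific constants frozen from the
derivation data, and then modelled jointly:
$$ y_{ikj} = \mu_k + \gamma_k (t_{ikj} - a) + u_{ik} + e_{ikj}, \qquad
   u_i \sim N_4(0, \Sigma_u), \quad e_{ikj} \sim N(0, \sigma_k^2), $$
with person $i$, factor $k$, measurement age $t_{ikj}$. The random
intercepts are correlated across factors (unstructured $4\times4$
covariance) and residual variances are factor-specific. The fit uses
`nlme::lme` (REML, `pdSymm` random structure, `varIdent` residuals,
relative tolerance $10^{-8}$, 500 iterations). The "error-free" value of
each factor at the landmark age is the BLUP
$\hat\mu_k + \hat u_{ik}$ with
$\hat u_i = \Sigma_u Z_i' V_i^{-1} (y_i - m_i)$ — the generalized least
squares conditional expectation given whatever subset of measurements the
person has. A person with no measurements receives the population trend;
a person observed for one factor has the others shifted along the fitted
covariance. Smoking is treated as a linear outcome of its 0/1 values and
carried forward as a continuous propensity, clipped to $[0,1]$ (clipping
is counted and reported, not silent).

**Stage 2.** With follow-up split into episodes at the initiation time
$t_s$, each episode $(t_0, t_1]$ with event indicator $d$ contributes
$$ \ell = d\,[\ln\nu + (\nu - 1)\ln t_1 + \eta] -
   e^{\eta} (t_1^{\nu} - t_0^{\nu}), \qquad
   \eta = \alpha + x\beta + \ln(0.75)\,\mathbb{1}[\text{on statin}]. $$
The offset coefficient is never estimated. The statin-naive 10-year risk
is $1 - \exp(-e^{\alpha + x\beta} 10^{\nu})$ — the offset is excluded, so
the prediction assumes no future initiation. The *standard* model drops
the split and the offset. A third mode frees the statin coefficient; it
exists to verify that the constrained value is recoverable, and is what
the acceptance script exercises.

**Counterfactual times.** Under the fitted model, a treated trajectory
reaching time $t$ accumulates the same hazard as an untreated one
reaching
$$ t^* = \left[t_s^{\nu} + 0.75\,(t^{\nu} - t_s^{\nu})\right]^{1/\nu}
   \le t, $$
so statin-naive predictions are validated against outcomes at the
transformed times (applied to censored and event times alike; event
indicators unchanged). The shape $\nu$ is taken from the constrained
model of the same landmark age and sex fitted on the derivation portion —
it is the model whose predictions are being validated.

Note the multiplier is the hazard ratio $0.75$ itself, not
$\exp(0.75)$: an exponentiated factor would be dimensionally inconsistent
with a 25% hazard reduction and would *lengthen* treated follow-up,
contradicting the direction of the validation comparison (statin-naive
risks are higher, so counterfactual untreated times must be shorter).
Equating cumulative hazards under the Weibull model forces $0.75$; the
multiplier is an argument (`hr`) so alternative values can be run.

## The synthetic cohort generator

The motivating records are access-restricted, so the generator emulates
their statistical structure and doubles as the oracle source for the test
suite. Under `generator_config()` defaults:

* **Population.** 45% men; entry ages uniform on 40–85 with a 20% point
  mass at 40 (people reaching the eligibility age during the study
  window — without it the landmark-40 risk set would be empty).
  Administrative follow-up uniform on 1–13.7 years (a staggered-entry
  study window), capped at age 95.
* **Trajectories.** Latent factor values are population mean + linear age
  trend + person random intercept, $\Sigma_u$ with SDs 12 mm Hg,
  0.9 mmol/L, 0.33 mmol/L and 0.25 (smoking probability) and modest
  cross-correlations (TC–HDL $-0.2$, others $\pm 0.1$ or less).
  Measurements arrive as a Poisson process (0.8/year) over a window from
  10 years before entry (mimicking pre-entry history) to exit, with
  residual SDs 10 mm Hg, 0.5 mmol/L, 0.15 mmol/L; smoking observations
  are Bernoulli draws of the latent probability clipped to $[0,1]$.
* **Events.** Weibull hazard with shape 1.15, clock starting at entry,
  covariates and baseline rate frozen at entry. The log baseline rate is
  $-4.9$ (men) / $-5.35$ (women) at age 60 plus $0.065$ per year of entry
  age; coefficients per SD are 0.25 (SBP), 0.20 (TC), $-0.20$ (HDL),
  plus 0.55 (smoking propensity), 0.60 (diabetes), 0.30 (hypertension
  treatment). These choices make true 10-year risks run from roughly 1%
  at entry age 40 (women) to about 40% at 85, the range a 40–85
  primary-care population spans. Event times are drawn by inverse
  transform on the closed-form piecewise cumulative hazard, and the same
  exponential variate also defines the latent *untreated* event time, so
  treated and untreated outcomes are exactly coupled.
* **Statin initiation.** A Bernoulli draw per person-year while
  event-free, with log-odds $-3.9 + 0.05(\text{age}-60) + 0.5 z_{TC}$ —
  about 1.5%/year at 60 rising with age and cholesterol, accumulating to
  roughly one initiator in six, matching the scale of drop-in seen in UK
  primary care. The post-initiation hazard is multiplied by 0.75.
* **Comorbidity.** Diabetes (0.25%/year) and antihypertensive treatment
  (1.7%/year) onset on a yearly grid from 10 years before entry; status
  is carried forward for life once present.

What the generator deliberately does **not** emulate: practice-level
clustering, informative visit processes (sicker people measured more
often), random slopes in the trajectories, treatment non-adherence, and
registration-date entry rules. Passing tests therefore demonstrate
correctness of the machinery under the stated data-generating process,
not robustness to those real-data features.

One qualitative feature of the real data is *not* reproducible within
this initiation structure and is worth stating plainly: crude incidence
stratified by future initiation status. Because a person only counts as
an initiator by surviving event-free to the initiation date, the
initiator group is immortal-time selected towards low rates, and the
cholesterol-mediated confounding the generator encodes (initiators do
have markedly higher underlying statin-naive risk and cholesterol) is too
weak to overcome it at any plausible loading. Real prescribing conditions
on globally assessed risk in ways a logistic model in age and cholesterol
cannot express. The tests assert the orderings the generator does
emulate.

## Evaluation and impact measures

All measures take an evaluation set of (prediction, time, event) —
observed times for the standard model, counterfactual times for the
statin-naive model — so there is no special-cased code path for the
counterfactual evaluation.

* **Calibration**: tenths of predicted risk against product-limit
  observed risk at the horizon; the slope is the coefficient of
  $\log(-\log(1-p))$ in a refitted one-covariate Weibull model (1 is
  perfect, 0.5 means the log-hazard spread is twice too wide).
* **Brier score**: unscaled mean squared error restricted to persons
  whose 10-year status is known (event within, or followed beyond, the
  horizon); no censoring weights. Between-model differences, the actual
  comparison target, are unaffected by this choice of scale.
* **Harrell's C**: `survival::concordance` (ties in predictions count
  one half), person bootstrap (200 resamples, percentile intervals,
  mandatory seed); in stacked data all landmark rows of a person resample
  together.
* **Royston's D / $R^2_D$**: rankits of the prognostic index scaled by
  $\sqrt{8/\pi}$, refitted as a single covariate;
  $R^2_D = (D^2/\sigma^2)/(D^2/\sigma^2 + \pi^2/6)$, $\sigma^2 = 8/\pi$.
* **Categorical NRI** at the 10% threshold (high risk is $p \ge 0.10$,
  closed at the threshold, consistently with the reclassification
  tables), on the restricted subset; asymptotic normal intervals.
* **Continuous NRI** in the prospective form: movers up/down by the new
  model, event probabilities within mover groups by the product-limit
  method, so censored persons contribute; intervals by person bootstrap —
  no standard closed form exists for this version, which is the one
  deviation from the asymptotic-interval convention used elsewhere.
* **IDI**: difference in discrimination slopes on the restricted subset,
  two-sample asymptotic standard error.
* **NNS/NNT**: treat everyone at $p \ge$ 10%, assume a 25% relative risk
  reduction on the product-limit observed risk of the treated group; NNS
  divides the whole risk set, NNT the treated group. Degenerate cases
  (nobody treated, zero observed risk) report `Inf` rather than failing.
  The NNS denominator is the risk-set count of the landmark age at hand.
* **Threshold proportions**: per-age exceedance proportions combined
  with external age–sex weights. The bundled weight table is synthetic
  (uniform over 40–85) and clearly labelled as such; supply a real
  standard population via `standard_population(path)`.

## Numerical choices

* Stage-2 optimization runs on $(\ln\nu, \alpha, \beta)$ — the log keeps
  the shape positive without constraints — by BFGS with the analytic
  gradient, followed by damped Newton steps until the gradient max-norm
  is below $10^{-6}$; the covariance matrix is the inverse observed
  information. A shape drifting outside $[10^{-3}, 10^{3}]$ aborts with
  an error (degenerate time scale). Non-convergence is flagged on the
  returned object, never silent.
* Episode boundary conventions: initiation at the event time is treated
  as not initiated (no post-initiation exposure, logged); initiation tied
  with a censoring date keeps a one-day treated episode.
* Stage-1 fallbacks: if the joint `lme` fit fails, independent
  univariate random-intercept fits (diagonal covariance) are used and the
  fit is flagged; a factor with no observations in the window receives
  the population trend with a diffuse variance (1 on the standardized
  scale, $0.25^2$ for smoking) and a flag.
* The derivation/validation split is by person, 2:1, seeded from the
  configuration (a registry study would split by practice; no practice
  structure exists in the generator).
* Every stochastic quantity — generator, split, bootstraps — derives
  from explicit seeds; rerunning a pipeline with the same configuration
  is byte-identical.

## Problem sizes used by the shipped checks

The test suite exercises parameter recovery at $n = 20{,}000$ (treatment
effect, stage-2 coefficients) and $n = 2{,}000$ (stage-1 variance
components, within 15% of truth), and runs the full 92-model pipeline at
$n = 4{,}000$, where sparse cells at the extreme ages occasionally carry
flagged placeholder fits — the bookkeeping keeps them visible rather than
dropping them. The statin-effect recovery check accepts the estimate
within three standard errors; at $n = 20{,}000$ under the default
initiation and event rates that standard error is about 5 percentage
points, an honest reflection of how much information ~200–600
post-initiation events carry.

## Known limitations

The constrained-offset design rests on strong assumptions:
a homogeneous 25% reduction for everyone regardless of dose, duration
and adherence; no uncertainty in the constrained effect (standard errors
of the other coefficients are accordingly slightly optimistic); and the
Weibull form for the baseline hazard, which buys the closed-form
counterfactual transformation at the price of parametric rigidity. The
stage-1 model uses random intercepts only; real trajectories with
person-specific slopes would shrink differently. The Brier score is
reported unscaled; a rescaled variant would change its level but not
between-model differences.
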