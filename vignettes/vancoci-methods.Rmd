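---
title: "Population pharmacokinetics of continuous-infusion vancomycin on extracorporeal support: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of continuous-infusion vancomycin on extracorporeal support: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancoci)
```

## The problem

Critically ill patients on extracorporeal membrane oxygenation (ECMO)
frequently receive vancomycin, often while also on continuous renal
replacement therapy (CRRT). Whether the extracorporeal circuit itself
changes vancomycin disposition — and what loading and maintenance doses
attain the 20–30 mg/L window targeted by continuous-infusion protocols —
are population-pharmacokinetic questions. `vancoci` implements the full
analysis pipeline for a matched-cohort design (ECMO cases paired 1:1 with
non-ECMO ICU controls on renal function, weight, SOFA score and age):
nonlinear mixed-effects estimation, covariate screening, bootstrap
uncertainty, Monte Carlo dose simulations, and the bedside dosing
calculators of the protocol, together with a seeded synthetic-cohort
generator so that every stage is testable without patient data.

## Structural and statistical model

Disposition follows a two-compartment linear model with zero-order
(infusion) input into the central compartment:

$$
\frac{dA_1}{dt} = R(t) - \frac{CL + Q}{V_c}A_1 + \frac{Q}{V_p}A_2,
\qquad
\frac{dA_2}{dt} = \frac{Q}{V_c}A_1 - \frac{Q}{V_p}A_2,
$$

with concentration $C(t) = A_1(t)/V_c$, clearance $CL$ (L/h), central and
peripheral volumes $V_c, V_p$ (L), intercompartmental clearance $Q$ (L/h)
and total $V_d = V_c + V_p$. `concentration_profile()` evaluates the
closed-form solution: within each infusion window the 2×2 rate matrix has
two real eigenvalues, and because the system is linear and time-invariant
the response to a regimen is the superposition of single-event responses.
The same system integrated numerically (`method = "ode"`, via deSolve) is
kept as an independent cross-check; the two routes agree to a relative
$10^{-6}$ in the test suite, and the closed form is what the Monte Carlo
simulations use, for speed.

Between-subject variability (BSV) is exponential on $CL$, $V_c$ and $V_p$
(none on $Q$): the individual value is the typical value times
$e^{\eta}$, $\eta \sim N(0, \omega^2)$, diagonal across parameters.
Residual error is exponential, handled exactly on the log scale:
$\log y_{ij} = \log f_{ij}(\theta, \eta_i) + \varepsilon_{ij}$,
$\varepsilon \sim N(0, \sigma^2)$. Additive and combined
(additive-plus-proportional variance) residual models are available for
model evaluation. Variabilities are reported as
$\%CV = 100\sqrt{\omega^2}$ on the log scale, the dominant convention for
exponential models.

The covariate model on clearance is a dichotomous CRRT multiplier,

$$\mathrm{TVCL} = CL \cdot CL_{CRRT} \cdot CL_{NOCRRT},$$

where each factor is 1 whenever its condition does not apply. We treat
the non-CRRT state as the reference category ($CL_{NOCRRT} \equiv 1$) and
estimate only the CRRT multiplier; a subject on CRRT therefore has
typical clearance $CL \times \beta_{CRRT}$. This is the only
self-consistent reading of the dichotomous descriptor, and it makes the
multiplier directly interpretable as the fractional clearance on CRRT.

## Estimation

`fit_population()` maximizes an approximate marginal likelihood. The
objective is the standard OFV, $-2\log L$ including all $n\log 2\pi$
constants, so that differences between nested models are convention-free.
The random-effects integral is approximated per subject at its
conditional mode (Laplace):

$$
-2\log L_i \approx g_i(\hat\eta_i) - q\log 2\pi +
\log\left|\tfrac{1}{2}\nabla^2 g_i(\hat\eta_i)\right|,
$$

where $g_i$ is the joint $-2\log$ density of the subject's data and
random effects and $q$ the number of random effects. A
FOCE-with-interaction variant (`method = "foce_i"`) linearizes the model
prediction around the conditional mode and evaluates the resulting
Gaussian marginal; for the log-scale exponential error model the
interaction term is constant, so FOCE-I and FOCE coincide. The Laplace
route is the primary one: the acceptance surface is parameter recovery
and agreement with an adaptive Gauss–Hermite quadrature oracle (to within
0.1 OFV units on single-random-effect problems), not bit-level agreement
with any particular estimator implementation.

Numerical choices, all visible in `fit_control()`:

* Inner search (conditional modes): damped Newton iterations with
  finite-difference derivatives, gradient tolerance $10^{-8}$, run in
  compiled code. During the outer search the modes are warm-started
  across iterations because they move smoothly with the parameters; the
  OFV of a finished fit is always re-evaluated with prior-mode starts so
  that OFVs are comparable across fits.
* Outer search: quasi-Newton (`nlminb`) on log-transformed parameters
  (positivity by construction), relative tolerance $10^{-6}$, at most 500
  iterations, followed by polish restarts from the optimum. Sparse
  designs leave a flat $V_p$–$Q$ ridge on which `nlminb` can stop early;
  a fit is declared converged when the optimizer certifies success or
  the OFV moves by less than 0.01 units under a restart.
* Optional seeded multistart (`multistart`, `jitter_sd`) for rough
  small-cohort surfaces; off by default, so a fit is deterministic given
  data and initial values.
* Degenerate cases are exact: with all $\omega^2 = 0$ the OFV reduces to
  the fixed-effect $-2\log L$; with noise-free data the generating
  parameters are recovered to optimizer precision.

Nested models are compared by the drop in OFV against the $\chi^2$
quantile; for one degree of freedom at $\alpha = 0.05$ the critical value
rounds to 3.84 and the comparison is inclusive.

## Covariate screening

`screen_forward()` adds candidates (nine covariates: age, weight, CrCl,
SOFA, APACHE II, sex, shock, CRRT, ECMO; dichotomous multipliers for
flags, median-normalized power functions for continuous covariates) one
at a time, keeping per round the candidate with the largest OFV drop if
it reaches 3.84. Auxiliary protocol criteria — shrinkage of BSV and of
residual variability — are reported in the trace for human review but do
not drive inclusion, because they are qualitative judgement calls.

Two implementation details matter for the honesty of the likelihood-ratio
test on small cohorts. First, candidate fits start from the current
optimum with an effect-sized coefficient on either side of the null value;
a start exactly at the null leaves the new coordinate with a vanishing
finite-difference gradient relative to optimization noise, and the effect
is then never picked up. Second, before the inclusion decision the
comparator and the winning candidate are alternately re-polished (the
candidate's fit with the effect stripped seeds a refit of the nested
model, and vice versa) until the OFV drop is stable: an apparent drop
that evaporates under this mutual polish was an optimizer artefact, not
evidence for the covariate. In the acceptance simulations the null
screen additionally uses one jittered multistart, because the comparator
side is the one vulnerable to under-optimization; the true-effect screen
is insensitive to the budget (its drops are an order of magnitude above
the threshold).

## Bootstrap

`bootstrap_fit()` resamples subjects (each with their full record) with
replacement to the original cohort size, refits, and summarizes each
parameter by its mean and 2.5/97.5 percentiles with linear interpolation
between order statistics. Replicates that fail the convergence criterion
are excluded and counted, with a warning beyond 20 %. The protocol
default is 1,000 replicates; the tests and the acceptance script run
100–200, which is ample for the interval locations checked there.

## Dosing simulations

`simulate_pta()` draws subjects from $N(0, \Omega)$ around the fitted
typical values and scores each regimen (loading dose over 4 h, then a
continuous infusion) against the $\geq 20$ mg/L target on a 0.5-h grid
over 48 h, for CRRT-on and CRRT-off arms of the reference subject (50
years, 70 kg, CrCl 100 mL/min — the CrCl enters dosing only through the
protocol's banded calculator, since no CrCl effect survives screening).
Attainment is judged on model-predicted, residual-error-free
concentrations, the usual convention for pharmacodynamic targets;
`include_ruv = TRUE` adds residual error first if the observed-scale
quantity is wanted. With $\Omega = 0$ the simulated fraction collapses
exactly to the 0/1 indicator of the typical profile, which the tests
exploit: the protocol regimen for the reference subject (35 mg/kg loading
plus the 35 mg/kg/day band dose, steady state $2450/24/3.7 \approx 27.6$
mg/L) attains the target with probability one at late times, whereas a
15 mg/kg/day maintenance dose (steady state 11.8 mg/L) has fallen below
it by 48 h.

## Clinical calculators

`crcl_urine()`, `crrt_intensity()`, `daily_dose_per_kg()`,
`classify_concentration()`, `adjust_dose()` and `match_controls()`
implement the protocol arithmetic. Choices where the protocol table is
ambiguous: CrCl bands are lower-inclusive half-open intervals
([25,50) → 14, [50,80) → 25, [80,120) → 35, [120,150] → 40, >150 → 45
mg/kg/day, <25 or oliguria → 7, CRRT overrides at 14); the 20–30 mg/L
"appropriate" band is inclusive at both edges; dose-adjustment magnitudes
default to the midpoints of the published ranges (750 mg, 6 h pause).
Matching requires the same renal-support modality (CrCl within ±10
mL/min, or CRRT intensity within a tolerance whose published unit is
ambiguous and is therefore an argument, default 5 on the mL/kg/h scale)
and age within ±5 years; weight and SOFA carry no published tolerance and
enter as a normalized distance to minimize rather than as hard gates.

## The synthetic-cohort generator

`generate_cohort()` emulates the study design: 11 ECMO + 11 control
subjects, CRRT prevalence 7/11 per arm, 35 mg/kg loading over 4 h
followed by the banded continuous infusion, serum samples at 4, 12 and
24 h, concentrations from the two-compartment model with exponential BSV
and residual error at the final-model estimates (CL 3.7 L/h, CRRT
multiplier 0.6, Vc 31.8 L, Vp 57.1 L, Q 3.6 L/h; BSV %CV 16.4/47/101;
RUV 8.5 %CV). Covariates come from simple parametric families anchored
to the reported medians and ranges — log-normal weight (median 70 kg),
uniform age, log-normal CrCl (median 62 mL/min) for subjects off CRRT,
log-normal CRRT intensity (median 40 mL/kg/h) — because only medians and
ranges, not distributions, are reported. Everything is reproducible from
the mandatory design seed, and generated cohorts round-trip through the
NONMEM-style event-record reader/writer.

What the generator does *not* emulate: time-varying renal function or
CRRT settings, dose adjustments after 24 h, assay censoring at the 0.8
mg/L quantification limit, correlated random effects, and model
misspecification of any kind. Passing recovery tests on these cohorts
therefore demonstrates that the estimation machinery inverts its own
generating model at the study's scale — not that the published model is
correct for real patients.

## Problem sizes in the tests and acceptance surface

The parameter-recovery checks use 100 subjects with six samples each at
1, 4, 8, 12, 24 and 48 h (horizon 72 h). The study's own three-sample
4/12/24-h schedule cannot identify the peripheral compartment well — the
terminal half-life at the generating values is about 25 h, so all
sampling would end within one half-life — and sampling into the second
day is the minimal enrichment that makes $V_p$ and $Q$ estimable. The
screening operating characteristics (20 true-effect and 20 null
replicates at the study's n = 22) use the same six-sample design for the
same reason: at 4/12/24 h the likelihood-ratio statistic for the CRRT
effect is information-limited (power ≈ 65 % even under exhaustive
optimization), which is consistent with the modest drop the original
analysis reported on its own data. The external-validation check scores
population predictions on a fresh five-subject synthetic ECMO cohort.

## Known limitations

* Diagonal $\Omega$ only; no covariance between random effects.
* No SAEM or importance-sampling estimator; no asymptotic
  (covariance-step) standard errors — uncertainty comes from the
  bootstrap, as in the source analysis.
* The FOCE-I variant shares the Laplace conditional modes; it is a
  reporting alternative, not an independent estimator.
* Percentile bootstrap only (no BCa), and no stratified resampling by
  arm.
* The dose-adjustment rules are calculators, not a closed-loop
  simulation of multi-day therapy.

## A minimal session

```{r example, eval = FALSE}
set.seed(1)
coh <- generate_cohort(cohort_design(seed = 1))
init <- population_model(theta = pk_parameters(3, 40, 40, 3),
                         omega2 = c(CL = 0.1, Vc = 0.2, Vp = 0.5),
                         sigma2 = 0.02)
scr <- screen_forward(coh, init,
                      candidates = default_candidates()["crrt"])
fit <- scr$final_model
bt <- bootstrap_fit(coh, fit$model, n_replicates = 100, seed = 2)
pta <- simulate_pta(fit$model,
                    scenario_spec(loading_doses = c(15, 25, 35),
                                  maintenance_doses = 15, seed = 3))
```
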