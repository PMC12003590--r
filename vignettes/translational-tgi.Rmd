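---
title: "From PDX tumor growth inhibition to virtual clinical trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From PDX tumor growth inhibition to virtual clinical trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoscale)
```

## The problem

Early in oncology development the only efficacy data available are tumor
growth inhibition (TGI) experiments in patient-derived xenograft (PDX)
mice: a control arm and a treated arm, each reported as an arm-mean tumor
burden over a few weeks. The clinical question, however, is posed in terms
of tumor *diameter* dynamics and time-to-progression (TTP) in patients on
a standard dosing schedule. `xenoscale` implements a translational
pipeline that connects the two:

1. **Population TGI modeling in mice** — the Simeoni model is fitted to
   every PDX study, and the per-study estimates are summarised into a
   multivariate lognormal population distribution.
2. **Allometric translation** — the exponential growth rate and the drug
   potency are scaled from mouse to human; the inter-PDX variability is
   propagated untouched.
3. **Virtual clinical trials** — cohorts of virtual patients are sampled
   from the scaled distribution, their diameter dynamics simulated under
   the clinical regimen, progression events derived with a simplified
   RECIST rule, and Kaplan–Meier TTP curves aggregated over Monte Carlo
   replicates into medians and 90% prediction intervals.

## Models

### Mouse: the Simeoni TGI model

Unperturbed tumors grow exponentially at rate $\lambda_0$ [1/day] and
switch to linear growth at rate $\lambda_1$ [cm³/day] once the burden
exceeds $\lambda_1/\lambda_0$. Drug-hit cells stop proliferating and die
through a three-stage transit chain with rate $k_1$ [1/day]; the hit rate
is $k_2\,c(t)$ with potency $k_2$ [L/mg·day] and plasma concentration
$c(t)$ [mg/L]:

$$
\begin{aligned}
\dot x_1 &= \frac{\lambda_0 x_1}{\left[1+(\tfrac{\lambda_0}{\lambda_1}w)^\psi\right]^{1/\psi}} - k_2\,c(t)\,x_1, \qquad
\dot x_2 = k_2\,c(t)\,x_1 - k_1 x_2,\\
\dot x_3 &= k_1(x_2-x_3), \qquad
\dot x_4 = k_1(x_3-x_4), \qquad w = x_1+x_2+x_3+x_4 .
\end{aligned}
$$

$\psi$ controls the sharpness of the growth switch; we fix $\psi = 20$,
the standard value in the TGI literature, which makes the switch
essentially abrupt while keeping the right-hand side smooth
(configurable via `simeoni_params()`). Tumor weight [g] and volume [cm³]
are treated as numerically identical (unit density), the universal
xenograft convention.

The system is integrated with `deSolve` (lsoda, rtol $10^{-8}$ / atol
$10^{-10}$ by default) using a compiled right-hand side with the
concentration supplied as a linearly interpolated forcing function. The
growth denominator is evaluated in a factored form that cannot overflow
for large $(\lambda_0 w/\lambda_1)^\psi$. An R-coded right-hand side is
retained and the test suite cross-checks the two routes with different
integrators at tightened tolerances. Dose discontinuities are handled by
a dense, event-refined concentration grid rather than by restarting the
integrator; the cross-integrator checks bound the residual error below
0.1%.

### Human: exponential growth with a first-order kill

Following the translated model, human tumor volume obeys
$\dot{TV} = (\lambda_{0,h} - k_{2,h}\,c(t))\,TV$, which integrates in
closed form:

$$
\ln TV(t) = \ln TV_0 + \lambda_{0,h}\,t - k_{2,h}\,\mathrm{CAUC}(t),
$$

where CAUC is the running integral of concentration. We evaluate this
closed form (exact up to the quadrature of CAUC) instead of stepping an
ODE — with 200 patients × 1000 replicates the trial stage performs
hundreds of millions of trajectory evaluations, and the closed form makes
them a matrix product. The ODE route survives as an oracle in the tests.
Diameters come from the single-spherical-mass convention
$TD = 2\,(3\,TV/4\pi)^{1/3}$, so a 20% diameter increase is exactly a
1.728× volume increase.

There is deliberately no linear growth phase, no transit chain and no
resistance term in the human model: only $\lambda_0$ and $k_2$ cross
species, which is why $\lambda_1$ and $k_1$ are never scaled.

### PK: linear compartmental models

All exposures come from literature-style linear compartmental models
(`pk_model()`): 1- or 2-compartment disposition with i.v. input,
first-order absorption (i.p. dosing in mice), or a transit-compartment
chain (delayed oral absorption, e.g. sorafenib). Profiles are computed by
piecewise matrix-exponential propagation between dose events (cached per
step size), which is exact for linear systems; the numerical-ODE route is
the test oracle. Cumulative exposure uses trapezoids on a grid with
log-spaced refinement after every dose event, keeping the quadrature
error of CAUC below 0.1% even for drugs whose half-life is minutes on a
day-scale grid.

Two unit conventions are fixed package-wide: PK, regimens and mouse TGI
run in **days**; the human TGI model runs in **months**, with
`profile_to_months()` performing the single conversion by the factor 30 —
the same factor used in the allometric rules. Concentrations are always
mg/L and potencies L/mg (the months-scale potency unit is L/mg·month);
a published variant of the potency-scaling rule prints a unit of L/g
without a corresponding factor of 1000, which we treat as typographical —
the package never mixes mg and g.

The package ships illustrative PK configurations (`inst/extdata/*.yaml`)
whose magnitudes match published population analyses of gemcitabine
(2-compartment i.v., very high clearance) and sorafenib (transit-chain
oral). They are synthetic defaults, clearly labelled, and meant to be
replaced by study-specific values. The enterohepatic-recirculation
component of published sorafenib models is not reproduced; an externally
supplied profile CSV (`read_concentration_csv()`) can carry such
secondary peaks, since the human model consumes only $c(t)$.

### Standard regimens

`build_regimen()` expands two named clinical protocols: gemcitabine
1000 mg/m² as 30-minute i.v. infusions, weekly ×7, one rest week, then 3
weeks on / 1 off (body surface area defaults to 1.8 m², the reference
adult, and is configurable); and sorafenib 400 mg orally every 12 h.
Custom event tables cover everything else, including mouse schedules.

## Population estimation: two-stage with bootstrap

Arm means — one curve per arm — are what PDX vendors report, so each
study contributes a single control and a single treated series. On such
data a two-stage approach is well-posed and transparent:

1. **Individual ML fits** (`fit_individual()`): joint Gaussian likelihood
   over both arms under a proportional or combined residual error model
   ($\mathrm{SD} = b\,\hat y$ or $\sqrt{a^2 + (b\hat y)^2}$). The control
   arm informs $(\lambda_0, \lambda_1, w_0)$; the treated arm adds
   $(k_1, k_2)$. Optimization is L-BFGS-B on log-parameters, staged: a
   control-arm prefit, a multi-start lattice over $(k_1, k_2)$ spanning
   about a decade around data-driven slopes, and a joint polish. The
   likelihood has a known flat degenerate mode ($k_1 \to 0$ with inflated
   $k_2$: damaged cells never die, mimicking slower growth); when the
   polish lands there the fit is restarted from the best non-collapsing
   lattice optimum and kept if its likelihood is within 2 units.
   $w_0$ is estimated per study, not fixed to the first observation.
2. **Log-domain summary** (`fit_population()`): all parameters are
   lognormal across PDX models, so typical values are geometric means and
   $\Omega$ is the sample covariance of the logs — with every
   off-diagonal forced to zero except $(\lambda_0, k_2)$, the only
   correlation the population model admits. The single free covariance is
   clipped so $\Omega$ stays positive semidefinite.
3. **Nonparametric bootstrap** (`bootstrap_population()`): studies are
   resampled with replacement and re-summarised (the per-study fits are
   cached, so this is instant). The replicates feed the virtual-trial
   stage as parameter-uncertainty draws.

This replaces a full nonlinear mixed-effects (SAEM) estimation: with one
averaged curve per arm there is no within-arm replication for shrinkage
to exploit, the two-stage estimator is essentially unbiased for the
typical values at panel sizes of ~27 (verified by the seeded recovery
suite), and the interface — $(\theta, \Omega,$ error$)$ — is exactly what
the translation step needs, so an NLME backend could drop in without
touching anything downstream. The known cost is that the log-variances of
weakly identified parameters ($\lambda_1$, $k_1$) are inflated by
estimation noise; the translated submatrix involves only $\lambda_0$ and
$k_2$, whose variances are estimated well.

Population estimates serialise to JSON (`write_popest_json()` /
`read_popest_json()`), so externally obtained parameters — e.g.
transcribed from a published population analysis — can drive the scaling
and trial stages directly.

## Allometric translation

$$
\lambda_{0,h} = 30\,\lambda_0\,(BW_h/BW_m)^{-\alpha}, \qquad
k_{2,h} = 30\,k_2\,(BW_h/BW_m)^{-\alpha}\,\frac{f_{u,h}}{f_{u,m}}
$$

with defaults $BW_h = 70$ kg, $BW_m = 0.025$ kg, $\alpha = 1/3$, and
unbound-fraction ratio 1 (appropriate for both gemcitabine and
sorafenib, whose protein binding is comparable across species; per-drug
override available). Only the typical values are scaled; the 2×2
log-scale covariance of $(\lambda_0, k_2)$ is copied verbatim from the
mouse $\Omega$, so geometric CVs and the correlation are preserved
exactly — an assertable invariant, not an approximation. At the defaults
the factor is $30 \cdot 2800^{-1/3}$, e.g. $\lambda_0 = 0.1$/day maps to
0.213/month.

## Virtual trials and progression

`sample_patients()` draws $(\lambda_{0,i}, k_{2,i})$ from the scaled
multivariate lognormal and a baseline volume: fixed 1 cm³ by default, or
lognormal (e.g. `baseline_spec("lognormal", 115.3, 0.16)`, an
advanced-disease baseline-SLD mix converted to volume) for diameter
trajectories comparable with clinical models. Because the human model is
log-linear, progression times are provably independent of the baseline —
changing $TV_0$ leaves every event time bit-identical, a property the
suite asserts.

A progression event is a 20% increase of the diameter over a reference.
The clinical convention this simplifies (RECIST) measures from the
smallest sum on study, so the default reference is the **nadir**
(running minimum); measuring from **baseline** is available as a switch
and both are reported by the acceptance script. The 5 mm absolute
increase floor and non-target/new-lesion progression are excluded by
design from the primary rule — the information translatable from PDX
studies does not support them — but an optional absolute floor exists for
sensitivity analysis. Patients without an event by the horizon (default
14 months) are censored there; adherence to the nominal protocol is
assumed strict.

Numerically, each patient's log-volume gain
$g(t) = \lambda_0 t - k_2\,\mathrm{CAUC}(t)$ is evaluated on a grid that
contains every node of the concentration profile plus a uniform
0.01-month mesh. Between nodes $g$ is exactly piecewise linear, so the
running minimum and the threshold crossing (at
$g - g_\mathrm{ref} = 3\ln 1.2$) are located exactly by linear inversion
— the grid is a representation, not an approximation, which the
dense-scan oracle test confirms to $10^{-3}$ months.

`km_estimate()` is an own product-limit implementation (cross-checked
against `survival::survfit` to $10^{-12}$); medians use the
first-attainment convention ($\min\{t: S(t) \le 0.5\}$).
`run_virtual_trials()` repeats cohort → TTP → KM over replicates, cycling
through the bootstrap population draws so estimation uncertainty widens
the bands, and aggregates empirical 5th/50th/95th percentiles (type-7)
of the TTP curves, of the within-cohort diameter percentile trajectories,
and of the replicate medians. A replicate whose KM never reaches 0.5
contributes its median as censored at the horizon and the summary carries
an explicit flag. Reproducibility: one master seed; per-replicate seeds
are drawn once up front, so replicate $r$ is identical whether you run
100 or 1000 replicates.

When only progression-free and overall survival are published,
`reconstruct_ttp()` recovers a TTP curve under an explicit independence
assumption between progression and death:
$S_\mathrm{TTP} = S_\mathrm{PFS}/S_\mathrm{OS}$ on the union of step
times, clipped to $[0,1]$, forced non-increasing, with pointwise
consistency violations up to 2% (digitization noise) clipped and larger
ones rejected. The assumption is a simplification and reconstructed
curves should be read as approximate references.

## The synthetic panel generator

No PDX panel data are redistributable, so `generate_pdx_panel()` creates
panels with the same structure: per-study parameters drawn from a
multivariate lognormal with only the $\lambda_0$–$k_2$ correlation,
both arms simulated with the Simeoni model, and residual noise added per
the error model (truncation to positive burdens is done by resampling,
not clipping, to avoid biasing small tumors; a truncation rate above 5%
warns).

The default truth was chosen once, on mechanistic grounds, to mirror a
gemcitabine-like pancreatic panel: 27 studies; nine arm-mean
observations over 28 days; i.p. dosing 100 mg/kg on days 0, 3, 6, 9 in a
25 g mouse; $\theta = (\lambda_0 = 0.10/\mathrm{d},\ \lambda_1 =
0.15\ \mathrm{cm^3/d},\ k_1 = 0.6/\mathrm{d},\ k_2 = 0.3$ L/mg·d$)$;
geometric CVs of roughly 30% ($\lambda_0$, $\lambda_1$), 20% ($k_1$) and
50% ($k_2$); correlation 0.4; 10% proportional noise. Two design
constraints fixed the growth numbers: control arms must traverse *both*
growth phases within the design window (otherwise $\lambda_1$ is
structurally unidentifiable — with $w_0 = 0.15$ cm³ the switch at
$\lambda_1/\lambda_0 = 1.5$ cm³ is reached around day 23), and the
treated arms must show clear but incomplete inhibition so that $k_2$ is
informative. What the generator does *not* emulate: within-arm animal
variability (vendors report arm means), measurement dropout, regimen
heterogeneity across studies, and any resistance mechanism — so passing
recovery tests demonstrates correctness of the estimator under the
model's own assumptions, not robustness to real-world misspecification.

A note on testing recovery: at $n = 27$ with a k₂ geometric CV of 50%,
the *panel itself* deviates from the population typical value with a
standard error of ~10% in log scale. A single-seed comparison of
$\hat\theta$ to $\theta$ therefore conflates estimator bias with panel
sampling noise; the recovery test in the suite averages the relative
bias over a small fixed-seed suite of independent panels, which is the
estimand the two-stage procedure can actually be held to.

## Problem sizes and numerical choices

- Individual fits take ~2 s per study (compiled RHS, thinned forcing
  polyline with interpolation error below 0.05% of the peak
  concentration); a 27-study panel fits in about a minute.
- The acceptance script runs the full documented pipeline — panel,
  fits, 200 bootstrap replicates, scaling, and 1000 replicates × 200
  patients under both progression references — in five to ten minutes on
  one core. The test suite uses 200-replicate trials for its end-to-end
  comparison; prediction-interval endpoints stabilise long before that.
- Optimizer: L-BFGS-B, log-scale, bounds about two decades beyond any
  plausible estimate; stopping `factr` matched to the ODE tolerance so
  the line search does not chase integration noise. Convergence code 52
  (line-search failure at a finite-difference optimum) is accepted as
  converged; true non-convergence flags the study and excludes it with a
  warning.
- Degenerate inputs: control-only studies return growth parameters with
  the kill chain reported absent; potency at its lower bound flags a
  non-responder, excluded from the potency summary with a warning;
  panels in which every study is identical yield $\Omega = 0$ with a
  warning rather than an error.

## Known limitations

- No resistance or time-decaying drug effect in either species; treated
  arms that regrow are fitted as-is, and human predictions inherit the
  assumption that potency is constant over the horizon.
- Validation against published TTP rests on digitized curves and, where
  TTP was not reported, on the PFS/OS independence reconstruction.
- The single-spherical-lesion SLD convention ignores multi-lesion
  bookkeeping and irregular geometry.
- PK is simulated once per regimen from typical parameters and shared by
  all virtual patients — no PK inter-individual variability, matching
  the translation framework's own convention.
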