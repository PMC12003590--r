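# xenoscale

Predicts tumor size dynamics and time-to-progression (TTP) in treated
cancer patients starting only from tumor-growth-inhibition (TGI) studies
in patient-derived-xenograft (PDX) mice.

The pipeline has three stages, each usable on its own:

1. **Population TGI modeling in mice.** Every PDX study (a control and a
   treated arm of arm-mean tumor burdens) is fitted with the Simeoni TGI
   model — exponential-to-linear growth at rates λ₀ [1/day] and
   λ₁ [cm³/day], a drug-kill term k₂·c(t) [potency k₂, L/mg·day] feeding a
   three-stage death chain with rate k₁ [1/day]. Per-study maximum
   likelihood estimates are summarised into a multivariate lognormal
   population: typical values θ, log-scale covariance Ω with correlation
   allowed only between λ₀ and k₂, plus a nonparametric bootstrap for
   estimation uncertainty.
2. **Allometric translation.** λ₀,human = 30·λ₀·(BW_h/BW_m)^(−α) (months,
   α = 1/3, 70 kg vs 25 g) and the same factor times the unbound-fraction
   ratio for k₂. The (λ₀, k₂) submatrix of Ω crosses species verbatim —
   variability is propagated, never rescaled.
3. **Virtual clinical trials.** Cohorts of virtual patients are drawn from
   the scaled distribution; each tumor follows
   dTV/dt = (λ₀,h − k₂,h·c(t))·TV, evaluated in closed form via cumulative
   drug exposure; diameters come from the spherical-mass convention
   TD = 2·(3TV/4π)^(1/3). Progression is a 20% diameter increase over the
   nadir (or baseline); Kaplan–Meier TTP curves over 1000 Monte Carlo
   replicates × 200 patients yield medians and 90% prediction intervals.

Linear compartmental PK (1/2-compartment, i.v. / first-order /
transit-chain absorption) and the standard gemcitabine (1000 mg/m² weekly
infusion cycles) and sorafenib (400 mg b.i.d. oral) regimens are built in;
a synthetic PDX panel generator makes the whole pipeline testable without
proprietary data.

## Worked example

```r
library(xenoscale)

# 1. a gemcitabine-like panel of 27 PDX studies (synthetic, seeded)
panel <- generate_pdx_panel(panel_truth(), seed = 11)

# 2. two-stage population fit
fits  <- fit_pdx_panel(panel, error = "proportional")
pop   <- fit_population(fits)
pop
#> <xeno_popest> 27 studies
#>   lambda0  theta = 0.1091     omega^2 = 0.05896  (CV 25%)
#>   lambda1  theta = 0.1596     omega^2 = 0.2864   (CV 58%)
#>   k1       theta = 0.5665     omega^2 = 0.09929  (CV 32%)
#>   k2       theta = 0.3456     omega^2 = 0.1548   (CV 41%)
#>   corr(log lambda0, log k2) = 0.159

# 3. translate to a human population (fu ratio = 1)
hp <- build_human_distribution(pop)
hp
#> <xeno_humanpop>
#>   lambda0 = 0.2322 /month (geometric CV 24.6%)
#>   k2      = 0.7356 L/mg·month (geometric CV 40.9%)
#>   corr(log lambda0, log k2) = 0.159

# 4. virtual trials under the standard gemcitabine schedule
pk   <- read_pk_yaml(system.file("extdata", "pk_gemcitabine_human.yaml",
                                 package = "xenoscale"))
reg  <- build_regimen("gemcitabine_standard", horizon = 14 * 30, bsa = 1.8)
conc <- profile_to_months(simulate_pk(pk, reg))
trial <- run_virtual_trials(hp, conc, n_patients = 200,
                            n_replicates = 50, seed = 5)
glance(trial)
#> # A tibble: 1 × 7
#>   median pi_lo pi_hi any_censored n_patients n_replicates reference
#>    <dbl> <dbl> <dbl> <lgl>             <dbl>        <dbl> <chr>
#> 1   3.14  3.02  3.35 FALSE               200           50 nadir
```

The printed numbers mean: the fitted mouse population grows ~11%/day
typically with a potency of ~0.35 L/mg·day; scaled to humans the typical
tumor doubles in ~3 months untreated; and under the standard gemcitabine
schedule half of the simulated cohorts progress (20% diameter increase
over nadir) by about 3.1 months, with the 90% prediction interval across
trial replicates spanning 3.0–3.4 months. `autoplot(trial)` draws the
KM-VPC band; `plot_td_bands(trial)` the diameter trajectories;
`clinical_ttp_table("gemcitabine")` loads published medians for overlay.

Population estimates obtained elsewhere (e.g. a published NLME analysis)
can be dropped in as JSON via `read_popest_json()` and pushed through
stages 2–3 unchanged. A thin CLI covering the same steps lives at
`inst/cli/xenoscale.R`.

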