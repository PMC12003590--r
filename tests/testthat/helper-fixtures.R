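# Shared lightweight fixtures, built in code at test time.

# Small panel truth with a design long enough that the linear growth phase
# is informative for every study.
tiny_truth <- function(n = 5) {
  panel_truth(n_studies = n)
}

# A single noise-free study from known parameters, with observations that
# straddle the exponential-to-linear switch.
noisefree_study <- function(lambda0 = 0.12, lambda1 = 0.15, k1 = 0.5,
                            k2 = 0.3, w0 = 0.2,
                            days = seq(0, 35, by = 3.5),
                            pk = default_mouse_pk()) {
  reg <- build_regimen("custom", horizon = max(days),
                       events = data.frame(time = c(0, 3, 6, 9), amount = 2.5),
                       route = "ip")
  attr(reg, "horizon") <- max(days)
  conc <- simulate_pk(pk, reg, dt = 0.1)
  grid <- sort(unique(c(0, days)))
  ctrl <- simulate_simeoni(simeoni_params(lambda0, lambda1, k1, 0, w0),
                           NULL, grid)
  trt <- simulate_simeoni(simeoni_params(lambda0, lambda1, k1, k2, w0),
                          conc, grid)
  sel <- match(days, grid)
  list(
    study = tgi_study(
      "S1",
      control = data.frame(time_day = days, tumor_cm3 = ctrl$tv_cm3[sel]),
      treated = data.frame(time_day = days, tumor_cm3 = trt$tv_cm3[sel]),
      regimen = reg),
    pk = pk,
    truth = c(lambda0 = lambda0, lambda1 = lambda1, k1 = k1, k2 = k2, w0 = w0)
  )
}

# Month-scale profile for the standard gemcitabine regimen over a horizon.
gem_month_profile <- function(horizon_months = 14, bsa = 1.8) {
  pk <- read_pk_yaml(system.file("extdata", "pk_gemcitabine_human.yaml",
                                 package = "xenoscale"))
  reg <- build_regimen("gemcitabine_standard", horizon = horizon_months * 30,
                       bsa = bsa)
  profile_to_months(simulate_pk(pk, reg))
}

# Hand-rolled random step survival data for KM cross-checks.
random_surv_data <- function(n = 30) {
  tibble::tibble(time = round(stats::rexp(n, 0.2), 2) + 0.01,
                 event = stats::runif(n) < 0.7)
}
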