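fixed_pop <- function(lambda0 = 0.2, k2 = 0, v_l0 = 0, v_k2 = 0, rho = 0) {
  om <- matrix(c(v_l0, rho * sqrt(v_l0 * v_k2),
                 rho * sqrt(v_l0 * v_k2), v_k2), 2, 2,
               dimnames = list(c("lambda0", "k2"), c("lambda0", "k2")))
  structure(list(lambda0_pop = lambda0, k2_pop = k2, omega = om,
                 scaling = scaling_config()),
            class = "xeno_humanpop")
}

test_that("untreated progression matches the closed form and ignores TV0", {
  # 20% diameter increase = 1.728x volume; t* = 3 ln(1.2) / lambda0
  pats <- tibble::tibble(patient_id = 1:3, lambda0 = 0.2, k2 = 0,
                         tv0 = c(0.5, 1, 115.3))
  rule <- progression_rule(reference = "baseline")
  res <- time_to_progression(pats, NULL, rule)
  expect_true(all(res$event))
  expect_equal(res$time, rep(3 * log(1.2) / 0.2, 3), tolerance = 1e-9)
  # nadir reference agrees when the tumor never shrinks
  resn <- time_to_progression(pats, NULL, progression_rule(reference = "nadir"))
  expect_equal(resn$time, res$time, tolerance = 1e-12)
})

test_that("event times are invariant to baseline volume under treatment", {
  conc <- gem_month_profile(horizon_months = 14)
  set.seed(5)
  base <- sample_patients(fixed_pop(0.25, 0.5, 0.09, 0.25, 0.4), 50,
                          seed = 31)
  for (ref in c("baseline", "nadir")) {
    rule <- progression_rule(reference = ref)
    a <- time_to_progression(base, conc, rule)
    b <- time_to_progression(dplyr::mutate(base, tv0 = tv0 * 37), conc, rule)
    expect_equal(a$time, b$time, tolerance = 1e-12)
    expect_equal(a$event, b$event)
  }
})

test_that("sustained shrinkage censors at the horizon", {
  conc <- constant_profile(5, seq(0, 14, 0.1), time_unit = "month")
  pats <- tibble::tibble(patient_id = 1, lambda0 = 0.2, k2 = 0.1, tv0 = 1)
  res <- time_to_progression(pats, conc, progression_rule())
  expect_false(res$event)
  expect_equal(res$time, 14)
})

test_that("nadir-referenced crossings match a dense-grid scan", {
  conc <- gem_month_profile(horizon_months = 14)
  pats <- tibble::tibble(patient_id = 1:4,
                         lambda0 = c(0.18, 0.3, 0.25, 0.4),
                         k2 = c(1.2, 0.8, 1.5, 0.6), tv0 = 1)
  rule <- progression_rule(reference = "nadir")
  res <- time_to_progression(pats, conc, rule)
  dense <- seq(0, 14, by = 1e-4)
  cauc <- approx(conc$time, conc$cauc, xout = dense, rule = 2)$y
  delta <- 3 * log(1.2)
  for (i in seq_len(nrow(pats))) {
    gi <- pats$lambda0[i] * dense - pats$k2[i] * cauc
    exc <- gi - cummin(gi)
    hit <- which(exc >= delta)
    t_star <- if (length(hit) > 0) dense[hit[1]] else 14
    expect_equal(res$time[i], t_star, tolerance = 1e-3)
  }
})

test_that("product-limit estimates match hand computations", {
  km <- km_estimate(tibble::tibble(time = c(1, 2, 3), event = TRUE))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))
  km2 <- km_estimate(tibble::tibble(time = c(1, 2, 3),
                                    event = c(TRUE, FALSE, TRUE)))
  expect_equal(km2$survival, c(1, 2 / 3, 2 / 3, 0))
  km3 <- km_estimate(tibble::tibble(time = c(2, 4), event = FALSE))
  expect_equal(km3$survival, c(1, 1, 1))
  expect_error(km_estimate(tibble::tibble(time = numeric(), event = logical())),
               "empty")
})

test_that("product-limit agrees with the survival package to 1e-12", {
  skip_if_not_installed("survival")
  set.seed(8)
  for (i in 1:100) {
    d <- random_surv_data(sample(5:60, 1))
    km <- km_estimate(d)
    sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
    ours <- km_eval_step(km, sf$time)
    expect_equal(ours, sf$surv, tolerance = 1e-12)
  }
})

test_that("curve medians follow the first-attainment convention", {
  cv <- tibble::tibble(time = c(0, 2, 5), survival = c(1, 0.6, 0.4))
  expect_equal(as.numeric(curve_median(cv)), 5)
  plateau <- tibble::tibble(time = c(0, 4, 6), survival = c(1, 0.5, 0.2))
  expect_equal(as.numeric(curve_median(plateau)), 4)
  never <- tibble::tibble(time = c(0, 10), survival = c(1, 0.7))
  m <- curve_median(never)
  expect_true(is.na(m))
  expect_false(attr(m, "reached"))
})

test_that("TTP reconstruction from PFS and OS obeys its limits", {
  pfs <- tibble::tibble(time = c(0, 1, 2, 3), survival = c(1, 0.8, 0.5, 0.3))
  os_flat <- tibble::tibble(time = 0, survival = 1)
  expect_equal(reconstruct_ttp(pfs, os_flat)$survival[-1],
               pfs$survival[-1] * 0 + reconstruct_ttp(pfs, os_flat)$survival[-1])
  r <- reconstruct_ttp(pfs, os_flat)
  expect_equal(km_eval_step(r, pfs$time), pfs$survival)
  # hand ratio at one point
  os <- tibble::tibble(time = c(0, 2), survival = c(1, 0.8))
  r2 <- reconstruct_ttp(tibble::tibble(time = c(0, 2), survival = c(1, 0.5)),
                        os)
  expect_equal(km_eval_step(r2, 2), 0.625)
  # all first events are deaths: TTP is flat at 1
  same <- tibble::tibble(time = c(0, 1, 2), survival = c(1, 0.7, 0.4))
  expect_equal(reconstruct_ttp(same, same)$survival,
               rep(1, 3))
  # inconsistent curves are rejected
  bad_pfs <- tibble::tibble(time = c(0, 1), survival = c(1, 0.9))
  bad_os <- tibble::tibble(time = c(0, 1), survival = c(1, 0.5))
  expect_error(reconstruct_ttp(bad_pfs, bad_os), "exceed|inconsistent")
})

test_that("cohort sampling is seeded and respects degenerate distributions", {
  hp <- fixed_pop(0.2, 0.05, 0.09, 0.25, 0.5)
  a <- sample_patients(hp, 100, seed = 6)
  b <- sample_patients(hp, 100, seed = 6)
  expect_identical(a, b)
  deg <- sample_patients(fixed_pop(0.2, 0.05), 10, seed = 1)
  expect_equal(deg$lambda0, rep(0.2, 10))
  expect_equal(deg$k2, rep(0.05, 10))
  expect_equal(deg$tv0, rep(1, 10))
  big <- sample_patients(hp, 1e5, seed = 9)
  se <- sqrt(0.09 / 1e5)
  expect_lt(abs(mean(log(big$lambda0)) - log(0.2)), 3 * se)
})

test_that("degenerate virtual trials collapse to the closed-form time", {
  tr <- run_virtual_trials(fixed_pop(0.2, 0), conc = NULL,
                           n_patients = 20, n_replicates = 5, seed = 2)
  s <- tr$median_ttp_summary
  t_star <- 3 * log(1.2) / 0.2
  expect_equal(s$median, t_star, tolerance = 1e-3)
  expect_equal(s$pi_hi - s$pi_lo, 0, tolerance = 1e-9)
  expect_false(s$any_censored)
  # overwhelming drug effect: no progression at all
  conc <- constant_profile(10, seq(0, 14, 0.1), time_unit = "month")
  tr2 <- run_virtual_trials(fixed_pop(0.2, 1), conc,
                            n_patients = 20, n_replicates = 3, seed = 2)
  expect_true(tr2$median_ttp_summary$any_censored)
  expect_true(all(tr2$median_ttp$censored))
})

test_that("stronger potency never shortens any progression time", {
  conc <- gem_month_profile(horizon_months = 14)
  hp_lo <- fixed_pop(0.25, 0.3, 0.09, 0.25, 0.4)
  hp_hi <- fixed_pop(0.25, 0.6, 0.09, 0.25, 0.4)
  p_lo <- sample_patients(hp_lo, 100, seed = 12)
  p_hi <- sample_patients(hp_hi, 100, seed = 12)
  # same seed: identical random effects, potency scaled up only
  expect_equal(p_hi$k2 / p_lo$k2, rep(2, 100), tolerance = 1e-12)
  for (ref in c("baseline", "nadir")) {
    rule <- progression_rule(reference = ref)
    t_lo <- time_to_progression(p_lo, conc, rule)
    t_hi <- time_to_progression(p_hi, conc, rule)
    expect_true(all(t_hi$time >= t_lo$time - 1e-9))
  }
})

test_that("replicate streams are stable when the replicate count grows", {
  hp <- fixed_pop(0.25, 0.4, 0.09, 0.25, 0.4)
  conc <- gem_month_profile(horizon_months = 14)
  t5 <- run_virtual_trials(hp, conc, n_patients = 30, n_replicates = 5,
                           seed = 3)
  t10 <- run_virtual_trials(hp, conc, n_patients = 30, n_replicates = 10,
                            seed = 3)
  expect_equal(t5$median_ttp$median_months,
               t10$median_ttp$median_months[1:5])
})

test_that("trial bands are ordered and survival-shaped", {
  hp <- fixed_pop(0.25, 0.4, 0.09, 0.25, 0.4)
  conc <- gem_month_profile(horizon_months = 14)
  tr <- run_virtual_trials(hp, conc, n_patients = 50, n_replicates = 20,
                           seed = 7)
  b <- tr$ttp_bands
  expect_true(all(b$p05 <= b$p50 + 1e-12 & b$p50 <= b$p95 + 1e-12))
  expect_true(all(diff(b$p50) <= 1e-12))
  expect_equal(b$p50[1], 1)
  td <- tr$td_bands
  expect_true(all(td$p05 <= td$p50 + 1e-12 & td$p50 <= td$p95 + 1e-12))
  g <- glance(tr)
  expect_equal(g$n_replicates, 20)
})
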