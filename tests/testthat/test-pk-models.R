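test_that("standard regimens expand to the protocol event counts", {
  gem8 <- build_regimen("gemcitabine_standard", horizon = 56, bsa = 1.8)
  expect_equal(nrow(gem8), 7) # weekly for 7 weeks, then a rest week
  expect_equal(gem8$amount, rep(1800, 7)) # 1000 mg/m2 x 1.8 m2
  expect_equal(gem8$duration, rep(0.5 / 24, 7))

  gem16 <- build_regimen("gemcitabine_standard", horizon = 112, bsa = 1.8)
  # induction 7 + two maintenance cycles of 3 weekly doses
  expect_equal(gem16$time, c(7 * (0:6), 56, 63, 70, 84, 91, 98))

  sor <- suppressWarnings(build_regimen("sorafenib_standard", horizon = 7))
  expect_equal(nrow(sor), 14) # 400 mg every 12 h = 800 mg/day
  expect_equal(unique(sor$amount), 400)

  expect_error(build_regimen("gemcitabine_standard", horizon = 56, bsa = NULL),
               "bsa|BSA|m2")
  expect_warning(build_regimen("gemcitabine_standard", horizon = 28),
                 "truncated")
})

test_that("one-compartment bolus matches the analytic solution", {
  reg <- build_regimen("custom", horizon = 50,
                       events = data.frame(time = 0, amount = 100))
  pk <- pk_model(1, cl = 1, vc = 10, absorption = "iv") # k = 0.1/day
  prof <- simulate_pk(pk, reg)
  expect_equal(prof$conc[1], 10)
  expect_equal(prof$conc, 10 * exp(-0.1 * prof$time), tolerance = 1e-8)
})

test_that("two-compartment infusion matches a numerical ODE oracle", {
  reg <- build_regimen("custom", horizon = 10,
                       events = data.frame(time = 1, amount = 500,
                                           duration = 2))
  pk <- pk_model(2, cl = 20, vc = 15, q = 10, vp = 40, absorption = "iv")
  prof <- simulate_pk(pk, reg, dt = 0.05)
  rhs <- function(t, y, p) {
    inp <- if (t >= 1 && t < 3) 250 else 0
    list(c(inp - (20 / 15 + 10 / 15) * y[1] + (10 / 40) * y[2],
           (10 / 15) * y[1] - (10 / 40) * y[2]))
  }
  ode <- deSolve::ode(c(0, 0), prof$time, rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  oracle <- ode[, 2] / 15
  i <- oracle > 1e-6
  expect_lt(max(abs(prof$conc[i] / oracle[i] - 1)), 1e-3)
})

test_that("transit-chain absorption follows the Erlang-input convolution", {
  n <- 4; ktr <- 12; cl <- 30; vc <- 50; D <- 400
  reg <- build_regimen("custom", horizon = 3,
                       events = data.frame(time = 0, amount = D),
                       route = "oral")
  pk <- pk_model(1, cl = cl, vc = vc, absorption = "transit",
                 n_transit = n, ktr = ktr)
  prof <- simulate_pk(pk, reg, dt = 0.02)
  kel <- cl / vc
  # analytic convolution of the Erlang(n, ktr) input with the central decay
  oracle <- vapply(prof$time, function(t) {
    if (t == 0) return(0)
    stats::integrate(function(s) {
      ktr^n * s^(n - 1) * exp(-ktr * s) / gamma(n) * exp(-kel * (t - s))
    }, 0, t, rel.tol = 1e-10)$value * D / vc
  }, numeric(1))
  i <- oracle > max(oracle) * 1e-3
  expect_lt(max(abs(prof$conc[i] / oracle[i] - 1)), 5e-3)
})

test_that("cumulative exposure is exact on simple shapes and conserves AUC", {
  flat <- constant_profile(2, seq(0, 5, 0.5))
  expect_equal(tail(flat$cauc, 1), 10)
  expect_equal(flat$cauc[1], 0)
  expect_true(all(diff(flat$cauc) >= 0))

  # terminal AUC of any linear model = F * total dose / CL
  reg <- build_regimen("custom", horizon = 200,
                       events = data.frame(time = c(0, 10, 30),
                                           amount = c(100, 200, 50)))
  pk <- pk_model(2, cl = 4, vc = 10, q = 3, vp = 20, absorption = "first_order",
                 ka = 8, f = 0.7)
  prof <- simulate_pk(pk, reg)
  expect_equal(tail(prof$cauc, 1), 0.7 * 350 / 4, tolerance = 1e-3)

  expect_error(cumulative_exposure(tibble::tibble(time = c(1, 0.5),
                                                  conc = c(1, 1))),
               "increasing")
})

test_that("linear PK is dose-proportional and obeys superposition", {
  pk <- pk_model(2, cl = 10, vc = 20, q = 5, vp = 30, absorption = "iv")
  set.seed(7)
  times <- sort(runif(4, 0, 20))
  amts <- runif(4, 50, 500)
  grid <- seq(0, 40, 0.1)
  multi <- simulate_pk(pk, build_regimen("custom", horizon = 40,
                                         events = data.frame(time = times,
                                                             amount = amts)),
                       grid = grid)
  dbl <- simulate_pk(pk, build_regimen("custom", horizon = 40,
                                       events = data.frame(time = times,
                                                           amount = 2 * amts)),
                     grid = grid)
  expect_equal(dbl$conc, 2 * multi$conc, tolerance = 1e-9)
  expect_equal(tail(dbl$cauc, 1), 2 * tail(multi$cauc, 1), tolerance = 1e-9)

  summed <- rowSums(vapply(seq_along(times), function(i) {
    simulate_pk(pk, build_regimen("custom", horizon = 40,
                                  events = data.frame(time = times[i],
                                                      amount = amts[i])),
                grid = grid)$conc
  }, numeric(length(grid))))
  expect_equal(multi$conc, summed, tolerance = 1e-9)
})

test_that("profiles convert to months and load from CSV", {
  prof <- constant_profile(3, seq(0, 60, 1))
  m <- profile_to_months(prof)
  expect_equal(max(m$time), 2)
  expect_equal(tail(m$cauc, 1), tail(prof$cauc, 1) / 30)
  expect_error(profile_to_months(m), "day")

  f <- tempfile(fileext = ".csv")
  writeLines(c("# external profile", "time,conc_mg_per_L", "0,1", "1,2", "2,0"), f)
  ext <- read_concentration_csv(f)
  expect_equal(ext$cauc, c(0, 1.5, 2.5))
})

test_that("PK specs load from YAML", {
  pk <- read_pk_yaml(system.file("extdata", "pk_sorafenib_human.yaml",
                                 package = "xenoscale"))
  expect_s3_class(pk, "xeno_pk_model")
  expect_identical(pk$absorption, "transit")
  expect_equal(pk$n_transit, 4L)
})
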