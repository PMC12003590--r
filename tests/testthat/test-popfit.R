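test_that("noise-free studies return their generating parameters", {
  fx <- noisefree_study()
  fit <- fit_individual(fx$study, pk = fx$pk, error = "proportional",
                        hessian = FALSE)
  expect_true(fit$convergence %in% c(0L, 52L))
  for (p in c("lambda0", "lambda1", "k1", "k2", "w0")) {
    expect_equal(fit$params[[p]], unname(fx$truth[[p]]), tolerance = 0.01,
                 label = p)
  }
  expect_false(fit$non_responder)
})

test_that("control-only studies estimate growth but not the kill chain", {
  fx <- noisefree_study()
  ctrl_only <- tgi_study("C1", control = fx$study$control)
  fit <- fit_individual(ctrl_only, error = "proportional", hessian = FALSE)
  expect_equal(fit$params$lambda0, unname(fx$truth[["lambda0"]]),
               tolerance = 0.01)
  expect_equal(fit$params$lambda1, unname(fx$truth[["lambda1"]]),
               tolerance = 0.05)
  expect_true(is.na(fit$params$k1))
  expect_true(is.na(fit$params$k2))
})

test_that("the likelihood is maximal at the truth on noise-free data", {
  fx <- noisefree_study()
  st <- fx$study
  reg <- st$regimen
  conc <- simulate_pk(fx$pk, reg, dt = 0.1) # same exposure as the fixture
  forc <- cbind(conc$time, conc$conc)
  grid <- sort(unique(c(0, st$treated$time_day)))
  sel <- match(st$treated$time_day, grid)
  nll_at <- function(p) {
    pred_c <- xenoscale:::simeoni_w(p[["lambda0"]], p[["lambda1"]], 1, 0,
                                    p[["w0"]], 20, grid, cbind(c(0, 35), c(0, 0)),
                                    1e-8, 1e-10)[sel]
    pred_t <- xenoscale:::simeoni_w(p[["lambda0"]], p[["lambda1"]], p[["k1"]],
                                    p[["k2"]], p[["w0"]], 20, grid, forc,
                                    1e-8, 1e-10)[sel]
    xenoscale:::gauss_nll(st$control$tumor_cm3, pred_c, "proportional", 0, 0.1) +
      xenoscale:::gauss_nll(st$treated$tumor_cm3, pred_t, "proportional", 0, 0.1)
  }
  base <- nll_at(fx$truth)
  for (p in names(fx$truth)) {
    for (f in c(0.95, 1.05)) {
      pert <- fx$truth
      pert[[p]] <- pert[[p]] * f
      expect_gt(nll_at(pert), base - 1e-8, label = sprintf("%s x %.2f", p, f))
    }
  }
})

make_fits <- function(lambda0, lambda1 = 0.2, k1 = 0.5, k2 = 0.3) {
  n <- length(lambda0)
  structure(
    tibble::tibble(study_id = paste0("S", seq_len(n)),
                   lambda0 = lambda0,
                   lambda1 = rep_len(lambda1, n),
                   k1 = rep_len(k1, n),
                   k2 = rep_len(k2, n),
                   w0 = 0.1, sigma_a = 0, sigma_b = 0.1,
                   logLik = 0, converged = TRUE, non_responder = FALSE),
    error_kind = "proportional")
}

test_that("population summary is the geometric mean / log covariance", {
  fits <- make_fits(c(0.05, 0.10, 0.20))
  pop <- suppressWarnings(fit_population(fits))
  expect_equal(unname(pop$theta[["lambda0"]]), 0.1, tolerance = 1e-12)
  expect_equal(pop$omega["lambda0", "lambda0"],
               var(log(c(0.05, 0.10, 0.20))), tolerance = 1e-12)
  # structural sparsity: only the lambda0-k2 off-diagonal may be nonzero
  off <- pop$omega
  off["lambda0", "k2"] <- off["k2", "lambda0"] <- 0
  diag(off) <- 0
  expect_true(all(off == 0))
})

test_that("degenerate panels give zero variance with a warning", {
  fits <- make_fits(rep(0.1, 4))
  expect_warning(pop <- fit_population(fits), "degenerate")
  expect_equal(pop$omega["lambda0", "lambda0"], 0)
  expect_error(fit_population(make_fits(c(0.1, 0.2))), "at least 3")
})

test_that("the lambda0-k2 covariance is clipped to a PSD matrix", {
  l0 <- c(0.05, 0.1, 0.2, 0.4)
  fits <- make_fits(l0, k2 = l0 * 3) # perfectly correlated
  pop <- fit_population(fits)
  rho <- pop$omega["lambda0", "k2"] /
    sqrt(pop$omega["lambda0", "lambda0"] * pop$omega["k2", "k2"])
  expect_lte(abs(rho), 1)
  expect_gte(min(eigen(pop$omega, only.values = TRUE)$values), -1e-12)
})

test_that("bootstrap is deterministic under a seed and degenerates cleanly", {
  fits <- make_fits(c(0.05, 0.08, 0.12, 0.2, 0.3))
  b1 <- suppressWarnings(bootstrap_population(fits, B = 5, seed = 4))
  b2 <- suppressWarnings(bootstrap_population(fits, B = 5, seed = 4))
  expect_equal(lapply(b1, `[[`, "theta"), lapply(b2, `[[`, "theta"))
  expect_equal(length(b1), 5)
  # identical studies: every replicate collapses to the same estimate
  same <- make_fits(rep(0.1, 5))
  bs <- suppressWarnings(bootstrap_population(same, B = 3, seed = 1))
  th <- vapply(bs, function(x) x$theta[["lambda0"]], numeric(1))
  expect_equal(th, rep(0.1, 3))
  expect_equal(bs[[1]]$omega["lambda0", "lambda0"], 0)
})

test_that("bootstrap spread tracks the analytic SE of a lognormal mean", {
  set.seed(21)
  n <- 27
  l0 <- 0.1 * exp(rnorm(n, 0, 0.3))
  fits <- make_fits(l0, k2 = 0.3 * exp(rnorm(n, 0, 0.5)))
  bs <- suppressWarnings(bootstrap_population(fits, B = 200, seed = 2))
  boot_sd <- sd(vapply(bs, function(x) log(x$theta[["lambda0"]]), numeric(1)))
  analytic <- sd(log(l0)) / sqrt(n)
  expect_lt(abs(boot_sd / analytic - 1), 0.3)
})

test_that("population estimates round-trip through JSON", {
  fits <- make_fits(c(0.05, 0.1, 0.2), k2 = c(0.2, 0.3, 0.45))
  pop <- fit_population(fits)
  f <- tempfile(fileext = ".json")
  write_popest_json(pop, f)
  back <- read_popest_json(f)
  expect_equal(back$theta, pop$theta, tolerance = 1e-12)
  expect_equal(back$omega, pop$omega, tolerance = 1e-12)
  expect_equal(back$error$kind, pop$error$kind)
})
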