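#' Ground truth for a synthetic PDX panel
#'
#' Defines the population from which synthetic tumor-growth-inhibition
#' studies are generated: typical Simeoni parameters, lognormal inter-PDX
#' variability with a single lambda0-k2 covariance, a residual error
#' model, the observation design and a dosing-regimen template.
#'
#' The defaults emulate a gemcitabine-like PDX panel: 27 studies, about
#' nine arm-mean observations over four weeks, i.p.-style dosing every
#' third day for four doses at 100 mg/kg in a 25 g mouse. Typical values
#' are in the range reported for xenograft TGI analyses (slow-growing PDX
#' tumors, moderate potency) with ~30 percent geometric CV on the growth
#' rate and ~50 percent on potency.
#'
#' @param theta Named typical values `lambda0` [1/day], `lambda1`
#'   [cm3/day], `k1` [1/day], `k2` [L/mg·day].
#' @param omega_sq Named log-scale variances for the same four parameters.
#' @param corr_l0_k2 Correlation between the `lambda0` and `k2` random
#'   effects (the only allowed correlation).
#' @param error An [error_model()].
#' @param n_studies Number of PDX studies (>= 3).
#' @param design_days Observation days shared by both arms (>= 4).
#' @param regimen Dosing-regimen template applied to every treated arm.
#' @param w0 Typical implanted tumor burden [cm3] (lognormal with
#'   `omega_sq_w0`).
#' @param omega_sq_w0 Log-scale variance of the baseline burden.
#' @return An object of class `xeno_truth`.
#' @export
panel_truth <- function(theta = c(lambda0 = 0.10, lambda1 = 0.15,
                                  k1 = 0.6, k2 = 0.3),
                        omega_sq = c(lambda0 = 0.09, lambda1 = 0.09,
                                     k1 = 0.04, k2 = 0.25),
                        corr_l0_k2 = 0.4,
                        error = error_model("proportional", b = 0.10),
                        n_studies = 27,
                        design_days = c(0, 3, 7, 10, 14, 17, 21, 24, 28),
                        regimen = NULL, w0 = 0.15, omega_sq_w0 = 0.05) {
  stopifnot(all(pop_par_names %in% names(theta)),
            all(pop_par_names %in% names(omega_sq)))
  if (any(theta <= 0) || any(omega_sq < 0)) {
    abort("typical values must be > 0 and variances >= 0.")
  }
  if (abs(corr_l0_k2) > 1) abort("|corr| must be <= 1.")
  if (n_studies < 3) abort("`n_studies` must be >= 3.")
  if (length(design_days) < 4) abort("need >= 4 observation days per arm.")
  if (is.null(regimen)) {
    regimen <- build_regimen("custom", horizon = max(design_days) + 1,
                             events = tibble(time = c(0, 3, 6, 9),
                                             amount = 100 * 0.025),
                             route = "ip")
  }
  omega <- matrix(0, 4, 4, dimnames = list(pop_par_names, pop_par_names))
  diag(omega) <- omega_sq[pop_par_names]
  omega["lambda0", "k2"] <- omega["k2", "lambda0"] <-
    corr_l0_k2 * sqrt(omega_sq[["lambda0"]] * omega_sq[["k2"]])
  structure(list(theta = theta[pop_par_names], omega = omega, error = error,
                 n_studies = as.integer(n_studies),
                 design_days = sort(design_days), regimen = regimen,
                 w0 = w0, omega_sq_w0 = omega_sq_w0),
            class = "xeno_truth")
}

#' Default mouse PK model for synthetic panels
#'
#' A two-compartment disposition with first-order (i.p.-style) absorption
#' and parameter magnitudes typical of small-molecule chemotherapeutics in
#' mice: rapid clearance relative to the 25 g body size and an absorption
#' half-life of about 20 minutes.
#'
#' @return An `xeno_pk_model` in day units.
#' @export
default_mouse_pk <- function() {
  pk_model(n_compartments = 2, cl = 1.5, vc = 0.05, q = 0.15, vp = 0.05,
           absorption = "first_order", ka = 50, f = 1, time_unit = "day")
}

#' Generate a synthetic PDX panel
#'
#' Draws per-study Simeoni parameters from the truth's multivariate
#' lognormal distribution, simulates control and treated arm means on the
#' observation design, and adds residual noise per the error model.
#' Observations are kept strictly positive by redrawing the noise
#' (resampling, not clipping, to avoid biasing small tumors); a truncation
#' rate above 5 percent triggers a warning.
#'
#' @param truth An [panel_truth()].
#' @param pk An [pk_model()] used to simulate the treated arms' exposure.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return An object of class `xeno_panel`: a list with `panel` (tidy
#'   tibble `study_id`, `arm`, `time_day`, `tumor_cm3`), `params` (the true
#'   per-study parameters), `regimens` (shared template) and `truth`.
#' @export
generate_pdx_panel <- function(truth, pk = default_mouse_pk(), seed = 1) {
  stopifnot(inherits(truth, "xeno_truth"))
  set.seed(seed)
  n <- truth$n_studies
  eta <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = truth$omega)
  eta <- matrix(eta, ncol = 4)
  pars <- tibble(
    study_id = sprintf("PDX%02d", seq_len(n)),
    lambda0 = truth$theta[["lambda0"]] * exp(eta[, 1]),
    lambda1 = truth$theta[["lambda1"]] * exp(eta[, 2]),
    k1 = truth$theta[["k1"]] * exp(eta[, 3]),
    k2 = truth$theta[["k2"]] * exp(eta[, 4]),
    w0 = truth$w0 * exp(rnorm(n, 0, sqrt(truth$omega_sq_w0))))

  reg <- truth$regimen
  horizon <- max(truth$design_days)
  if (attr(reg, "horizon") < horizon) attr(reg, "horizon") <- horizon
  conc <- simulate_pk(pk, reg, dt = 0.1)
  days <- truth$design_days
  grid <- sort(unique(c(0, days)))

  n_trunc <- 0L
  n_draws <- 0L
  noisy <- function(pred) {
    sdv <- error_sd(pred, truth$error$kind, truth$error$a, truth$error$b)
    vapply(seq_along(pred), function(i) {
      repeat {
        n_draws <<- n_draws + 1L
        y <- pred[i] + rnorm(1, 0, sdv[i])
        if (y > 0) return(y)
        n_trunc <<- n_trunc + 1L
      }
    }, numeric(1))
  }
  rows <- purrr::map(seq_len(n), function(i) {
    p <- pars[i, ]
    ctrl <- simulate_simeoni(
      simeoni_params(p$lambda0, p$lambda1, p$k1, 0, p$w0), NULL, grid)
    trt <- simulate_simeoni(
      simeoni_params(p$lambda0, p$lambda1, p$k1, p$k2, p$w0), conc, grid)
    sel <- match(days, grid)
    bind_rows(
      tibble(study_id = p$study_id, arm = "control", time_day = days,
             tumor_cm3 = noisy(ctrl$tv_cm3[sel])),
      tibble(study_id = p$study_id, arm = "treated", time_day = days,
             tumor_cm3 = noisy(trt$tv_cm3[sel])))
  })
  if (n_trunc / max(n_draws, 1) > 0.05) {
    warn(sprintf("noise truncation rate %.1f%%: noise is large relative to signal.",
                 100 * n_trunc / n_draws))
  }
  structure(list(panel = bind_rows(rows), params = pars, regimens = reg,
                 truth = truth, pk = pk, seed = seed),
            class = "xeno_panel")
}

#' @exportS3Method base::print
print.xeno_panel <- function(x, ...) {
  cat(sprintf("<xeno_panel> %d studies x %d days, %s error (b = %g)\n",
              x$truth$n_studies, length(x$truth$design_days),
              x$truth$error$kind, x$truth$error$b))
  invisible(x)
}

#' Parameter-recovery report
#'
#' Compares a population estimate against the generating truth: relative
#' bias of each typical value, absolute error of the log-scale variance
#' entries and of the lambda0-k2 covariance, and (when bootstrap
#' replicates are supplied) whether the 90 percent bootstrap interval
#' covers the truth.
#'
#' @param truth An [panel_truth()].
#' @param estimate An `xeno_popest`.
#' @param boot Optional `xeno_popest_boot` list for coverage flags.
#' @return A tibble: `parameter`, `truth`, `estimate`, `rel_bias`,
#'   `omega_sq_truth`, `omega_sq_est`, `omega_sq_abs_err`, `covered`
#'   (NA without bootstrap).
#' @export
recovery_report <- function(truth, estimate, boot = NULL) {
  pars <- pop_par_names
  cover <- setNames(rep(NA, length(pars)), pars)
  if (!is.null(boot)) {
    bm <- vapply(boot, function(b) b$theta[pars], numeric(length(pars)))
    for (p in pars) {
      ci <- quantile(bm[p, ], c(0.05, 0.95), na.rm = TRUE, names = FALSE)
      cover[p] <- truth$theta[[p]] >= ci[1] && truth$theta[[p]] <= ci[2]
    }
  }
  th_true <- unname(truth$theta[pars])
  th_est <- unname(estimate$theta[pars])
  om_true <- diag(truth$omega)[pars]
  om_est <- diag(estimate$omega)[pars]
  out <- tibble(
    parameter = pars,
    truth = th_true,
    estimate = th_est,
    rel_bias = th_est / th_true - 1,
    omega_sq_truth = unname(om_true),
    omega_sq_est = unname(om_est),
    omega_sq_abs_err = unname(abs(om_est - om_true)),
    covered = unname(cover))
  cov_true <- truth$omega["lambda0", "k2"]
  cov_est <- estimate$omega["lambda0", "k2"]
  cov_row <- tibble(
    parameter = "cov_lambda0_k2",
    truth = cov_true,
    estimate = cov_est,
    rel_bias = NA_real_,
    omega_sq_truth = NA_real_, omega_sq_est = NA_real_,
    omega_sq_abs_err = abs(cov_est - cov_true),
    covered = NA)
  bind_rows(out, cov_row)
}

#' Packaged clinical median-TTP tables
#'
#' Published median times to progression (with 90 percent confidence
#' intervals) from clinical trials of single-agent gemcitabine in advanced
#' pancreatic cancer and of sorafenib in hepatocellular carcinoma (Asian
#' populations). These are observed reference values for overlay plots and
#' containment checks — never computational inputs.
#'
#' @param case `"gemcitabine"` or `"sorafenib"`.
#' @return A tibble: `study`, `n_patients`, `median_ttp_months`,
#'   `ci90_lo`, `ci90_hi`.
#' @export
clinical_ttp_table <- function(case = c("gemcitabine", "sorafenib")) {
  case <- match.arg(case)
  path <- system.file("extdata",
                      sprintf("clinical_ttp_%s.csv", case),
                      package = "xenoscale", mustWork = TRUE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
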