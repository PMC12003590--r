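#' Residual error model
#'
#' Observation noise on arm-mean tumor burden. `"proportional"`:
#' `SD(y) = b * y_pred`; `"combined"`: `SD(y) = sqrt(a^2 + (b * y_pred)^2)`
#' with an additive floor `a` [cm3].
#'
#' @param kind `"proportional"` or `"combined"`.
#' @param a Additive SD [cm3] (combined only).
#' @param b Proportional SD (dimensionless CV).
#' @return An object of class `xeno_error`.
#' @export
error_model <- function(kind = c("proportional", "combined"), a = 0, b = 0.1) {
  kind <- match.arg(kind)
  if (a < 0 || b < 0) abort("error SDs must be >= 0.")
  if (a == 0 && b == 0) abort("`a` and `b` cannot both be zero.")
  if (kind == "proportional" && a != 0) {
    abort("proportional error has no additive component; use kind = \"combined\".")
  }
  structure(list(kind = kind, a = a, b = b), class = "xeno_error")
}

error_sd <- function(pred, kind, a, b) {
  if (kind == "combined") sqrt(a^2 + (b * pred)^2) else b * pred
}

#' A single PDX tumor-growth-inhibition study
#'
#' One PDX experiment: a control arm and (optionally) a treated arm of
#' arm-mean tumor burdens over time, plus the treated arm's dosing regimen.
#'
#' @param study_id Identifier.
#' @param control,treated Data frames with columns `time_day` and
#'   `tumor_cm3`; `treated` may be `NULL` (control-only study). Each arm
#'   needs at least 4 observations with strictly positive burdens; both
#'   arms share the `t = 0` baseline definition.
#' @param regimen An [build_regimen()] regimen for the treated arm.
#' @param route Route tag (`"iv"`, `"ip"`, `"oral"`).
#' @return An object of class `xeno_study`.
#' @export
tgi_study <- function(study_id, control, treated = NULL, regimen = NULL,
                      route = NULL) {
  check_arm <- function(arm, what) {
    arm <- as_tibble(arm)
    if (!all(c("time_day", "tumor_cm3") %in% names(arm))) {
      abort(sprintf("%s arm needs columns `time_day` and `tumor_cm3`.", what))
    }
    if (nrow(arm) < 4) abort(sprintf("%s arm needs >= 4 observations.", what))
    if (any(arm$tumor_cm3 <= 0)) abort("tumor burdens must be > 0.")
    arrange(arm, .data$time_day)
  }
  control <- check_arm(control, "control")
  if (!is.null(treated)) {
    treated <- check_arm(treated, "treated")
    if (is.null(regimen)) abort("a treated arm needs its dosing regimen.")
  }
  structure(list(study_id = study_id, control = control, treated = treated,
                 regimen = regimen,
                 route = route %||% attr(regimen, "route")),
            class = "xeno_study")
}

# Raw total-burden solve used inside likelihood evaluations: no tibble
# construction, forcing matrix prepared once by the caller.
simeoni_w <- function(lambda0, lambda1, k1, k2, w0, psi, grid, forc,
                      rtol, atol) {
  sol <- deSolve::ode(c(w0, 0, 0, 0), grid, "simeoni_deriv",
                      parms = c(lambda0, lambda1, k1, k2, psi),
                      dllname = "xenoscale", initfunc = "simeoni_init",
                      initforc = "simeoni_forc", forcings = forc,
                      fcontrol = list(method = "linear", rule = 2),
                      rtol = rtol, atol = atol)
  if (nrow(sol) < length(grid)) stop("integration failure", call. = FALSE)
  rowSums(sol[, 2:5, drop = FALSE])
}

gauss_nll <- function(obs, pred, kind, a, b) {
  sdv <- error_sd(pred, kind, a, b)
  if (any(!is.finite(sdv)) || any(sdv <= 0) || any(!is.finite(pred))) {
    return(1e10)
  }
  v <- sum(log(sdv) + 0.5 * ((obs - pred) / sdv)^2)
  if (is.finite(v)) v else 1e10
}

# Data-driven initial values for one study.
fit_heuristics <- function(study, conc) {
  ctrl <- study$control
  k <- min(4L, nrow(ctrl))
  early <- head(ctrl, k)
  l0 <- tryCatch(unname(coef(lm(log(tumor_cm3) ~ time_day, early))[2]),
                 error = function(e) NA_real_)
  if (!is.finite(l0) || l0 <= 0) l0 <- 0.05
  late <- tail(ctrl, 3L)
  l1 <- (tail(late$tumor_cm3, 1) - late$tumor_cm3[1]) /
    max(tail(late$time_day, 1) - late$time_day[1], 1e-6)
  if (!is.finite(l1) || l1 <= 0) l1 <- l0 * max(ctrl$tumor_cm3)
  w0 <- max(ctrl$tumor_cm3[1], 1e-3)
  k2 <- NA_real_
  if (!is.null(study$treated) && !is.null(conc)) {
    tt <- tail(study$treated$time_day, 1)
    ratio <- tail(ctrl$tumor_cm3, 1) / tail(study$treated$tumor_cm3, 1)
    cauc_t <- approx(conc$time, conc$cauc, xout = tt, rule = 2)$y
    k2 <- log(max(ratio, 1.01)) / max(cauc_t, 1e-6)
    k2 <- min(max(k2, 1e-4), 50)
  }
  list(lambda0 = min(max(l0, 1e-3), 1), lambda1 = min(max(l1, 1e-3), 50),
       k1 = 0.5, k2 = k2, w0 = w0)
}

#' Fit the Simeoni model to one PDX study
#'
#' Joint Gaussian maximum likelihood over both arms under the chosen
#' residual error model: the control arm informs (`lambda0`, `lambda1`,
#' `w0`), the treated arm adds (`k1`, `k2`). Optimization is bounded
#' quasi-Newton (L-BFGS-B) on log parameters, staged for speed and
#' robustness: a control-arm prefit of the growth parameters, a
#' multi-start lattice over `(k1, k2)` spanning about a decade around
#' data-driven heuristics on the treated arm, and a final joint polish of
#' all parameters over both arms. Standard errors come from the observed
#' information at the joint optimum.
#'
#' @param study An [tgi_study()].
#' @param pk An [pk_model()] for the study's route (used to simulate the
#'   treated arm's exposure); ignored for control-only studies.
#' @param error `"proportional"` or `"combined"`.
#' @param psi Simeoni switch exponent (fixed, not estimated).
#' @param n_starts Size of the `(k1, k2)` multi-start lattice (<= 8).
#' @param rtol,atol ODE tolerances used during fitting.
#' @param hessian Compute log-scale standard errors at the optimum.
#' @return An object of class `xeno_fit`: `params` ([simeoni_params()] or
#'   `NA` entries for control-only fits), error estimates, `logLik`,
#'   `convergence` (0 = ok), `se_log`, `non_responder` flag (potency at its
#'   lower bound).
#' @export
fit_individual <- function(study, pk = NULL, error = c("proportional", "combined"),
                           psi = 20, n_starts = 8, rtol = 1e-7, atol = 1e-9,
                           hessian = TRUE) {
  error <- match.arg(error)
  stopifnot(inherits(study, "xeno_study"))
  has_trt <- !is.null(study$treated)
  conc <- NULL
  forc_trt <- NULL
  if (has_trt) {
    if (is.null(pk)) abort("a treated arm needs a PK model.")
    horizon <- max(study$treated$time_day)
    reg <- study$regimen
    if (attr(reg, "horizon") < horizon) attr(reg, "horizon") <- horizon
    conc <- simulate_pk(pk, reg,
                        grid = pk_time_grid(reg, horizon = horizon, dt = 0.1))
    # thin the forcing polyline: repeated solves pay per forcing node
    conc_fit <- thin_profile(conc, tol = 2e-4 * max(conc$conc))
    forc_trt <- cbind(conc_fit$time, conc_fit$conc)
  }
  h <- fit_heuristics(study, conc)
  forc0 <- cbind(c(0, max(study$control$time_day)), c(0, 0))
  grid_c <- sort(unique(c(0, study$control$time_day)))
  sel_c <- match(study$control$time_day, grid_c)
  obs_c <- study$control$tumor_cm3
  lower <- log(c(lambda0 = 1e-4, lambda1 = 1e-4, k1 = 1e-3, k2 = 1e-6,
                 w0 = 1e-5, b = 1e-4, a = 1e-6))
  upper <- log(c(lambda0 = 5, lambda1 = 200, k1 = 100, k2 = 200,
                 w0 = 100, b = 5, a = 20))

  nll_control <- function(l0, l1, w0, a, b) {
    pred <- tryCatch(
      simeoni_w(l0, l1, 1, 0, w0, psi, grid_c, forc0, rtol, atol)[sel_c],
      error = function(e) NA_real_)
    gauss_nll(obs_c, pred, error, a, b)
  }

  # stage A: control-arm prefit of (lambda0, lambda1, w0) + error
  nm_a <- c("lambda0", "lambda1", "w0", "b", if (error == "combined") "a")
  obj_a <- function(lp) {
    p <- exp(lp)
    nll_control(p[1], p[2], p[3], if (error == "combined") p[5] else 0, p[4])
  }
  best_a <- NULL
  for (f in c(1, 0.3, 3)) {
    s <- c(h$lambda0 * f, h$lambda1, h$w0, 0.15,
           if (error == "combined") 0.05)
    fit <- tryCatch(
      optim(log(s), obj_a, method = "L-BFGS-B",
            lower = lower[nm_a], upper = upper[nm_a],
            control = list(maxit = 150)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best_a) || fit$value < best_a$value)) {
      best_a <- fit
    }
  }
  if (is.null(best_a) || best_a$value >= 1e10) {
    return(structure(list(study_id = study$study_id, params = NULL,
                          error = NULL, logLik = NA_real_, convergence = 1L,
                          se_log = NULL, non_responder = FALSE),
                     class = "xeno_fit"))
  }
  pa <- exp(best_a$par)

  if (!has_trt) {
    est <- setNames(pa, nm_a)
    se_log <- rep(NA_real_, length(est))
    if (hessian) {
      hs <- tryCatch(optim(best_a$par, obj_a, method = "L-BFGS-B",
                           lower = lower[nm_a], upper = upper[nm_a],
                           control = list(maxit = 1), hessian = TRUE)$hessian,
                     error = function(e) NULL)
      if (!is.null(hs)) {
        se_log <- tryCatch(sqrt(diag(solve(hs))),
                           error = function(e) se_log)
      }
    }
    names(se_log) <- nm_a
    params <- structure(list(lambda0 = est[["lambda0"]],
                             lambda1 = est[["lambda1"]],
                             k1 = NA_real_, k2 = NA_real_,
                             w0 = est[["w0"]], psi = psi),
                        class = "xeno_simeoni_params")
    err <- error_model(error, a = if (error == "combined") est[["a"]] else 0,
                       b = est[["b"]])
    return(structure(list(study_id = study$study_id, params = params,
                          error = err, logLik = -best_a$value,
                          convergence = best_a$convergence,
                          se_log = se_log, non_responder = FALSE),
                     class = "xeno_fit"))
  }

  # stage B: (k1, k2) lattice on the treated arm, growth parameters fixed
  grid_t <- sort(unique(c(0, study$treated$time_day)))
  sel_t <- match(study$treated$time_day, grid_t)
  obs_t <- study$treated$tumor_cm3
  a_fix <- if (error == "combined") pa[5] else 0
  # floor the stage-B error SD: a near-zero control-arm b (noise-free data)
  # would turn small treated-arm residuals into likelihood cliffs
  b_fix <- max(pa[4], 0.05)
  nll_treated <- function(k1v, k2v, l0, l1, w0, a, b) {
    pred <- tryCatch(
      simeoni_w(l0, l1, k1v, k2v, w0, psi, grid_t, forc_trt, rtol, atol)[sel_t],
      error = function(e) NA_real_)
    gauss_nll(obs_t, pred, error, a, b)
  }
  obj_b <- function(lp) {
    p <- exp(lp)
    nll_treated(p[1], p[2], pa[1], pa[2], pa[3], a_fix, b_fix)
  }
  lattice <- expand.grid(k1 = c(0.2, 1), k2 = h$k2 * c(0.3, 1, 3, 9))
  lattice <- lattice[seq_len(min(nrow(lattice), max(1L, n_starts))), ]
  best_b <- NULL
  stage_b <- list()
  for (i in seq_len(nrow(lattice))) {
    fit <- tryCatch(
      optim(log(c(lattice$k1[i], lattice$k2[i])), obj_b, method = "L-BFGS-B",
            lower = lower[c("k1", "k2")], upper = upper[c("k1", "k2")],
            control = list(maxit = 50, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(fit)) stage_b <- c(stage_b, list(fit))
    if (!is.null(fit) && (is.null(best_b) || fit$value < best_b$value)) {
      best_b <- fit
    }
  }
  if (is.null(best_b) || best_b$value >= 1e10) {
    return(structure(list(study_id = study$study_id, params = NULL,
                          error = NULL, logLik = NA_real_, convergence = 1L,
                          se_log = NULL, non_responder = FALSE),
                     class = "xeno_fit"))
  }

  # stage C: joint polish over both arms
  nm <- c("lambda0", "lambda1", "k1", "k2", "w0", "b",
          if (error == "combined") "a")
  obj <- function(lp) {
    p <- exp(lp)
    a <- if (error == "combined") p[7] else 0
    nll_control(p[1], p[2], p[5], a, p[6]) +
      nll_treated(p[3], p[4], p[1], p[2], p[5], a, p[6])
  }
  polish <- function(kpar, hess) {
    start <- log(c(pa[1], pa[2], exp(kpar), pa[3], max(pa[4], 0.02),
                   if (error == "combined") pa[5]))
    optim(start, obj, method = "L-BFGS-B",
          lower = lower[nm], upper = upper[nm],
          control = list(maxit = 300, factr = 1e9), hessian = hess)
  }
  best <- polish(best_b$par, hessian)
  # a near-zero damage-chain rate with inflated potency is a known flat
  # degenerate mode of the likelihood; retry from the best non-collapsing
  # lattice optimum and keep the better fit
  if (exp(best$par[3]) < 5e-3 && length(stage_b) > 1) {
    ok_b <- Filter(function(f) exp(f$par[1]) >= 5e-2, stage_b)
    if (length(ok_b) > 0) {
      alt_b <- ok_b[[which.min(vapply(ok_b, `[[`, numeric(1), "value"))]]
      alt <- polish(alt_b$par, hessian)
      if (alt$value <= best$value + 2) best <- alt
    }
  }

  est <- setNames(exp(best$par), nm)
  se_log <- rep(NA_real_, length(est))
  if (hessian) {
    se_log <- tryCatch(sqrt(diag(solve(best$hessian))),
                       error = function(e) rep(NA_real_, length(est)))
  }
  names(se_log) <- nm
  non_resp <- est[["k2"]] <= 1e-5 * 1.01
  params <- simeoni_params(est[["lambda0"]], est[["lambda1"]], est[["k1"]],
                           est[["k2"]], est[["w0"]], psi)
  err <- error_model(error, a = if (error == "combined") est[["a"]] else 0,
                     b = est[["b"]])
  structure(list(study_id = study$study_id, params = params, error = err,
                 logLik = -best$value, convergence = best$convergence,
                 se_log = se_log, non_responder = non_resp),
            class = "xeno_fit")
}

#' Fit a whole PDX panel
#'
#' Runs [fit_individual()] on every study of a tidy panel and returns one
#' row per study. Non-converged studies are kept with `converged = FALSE`
#' and excluded downstream with a message.
#'
#' @param panel Tidy panel data frame: columns `study_id`, `arm`
#'   (`"control"`/`"treated"`), `time_day`, `tumor_cm3`. An `xeno_panel`
#'   from [generate_pdx_panel()] is also accepted.
#' @param regimens A single regimen used for every treated arm, or a named
#'   list keyed by `study_id`.
#' @param pk An [pk_model()] for the treated arms.
#' @param error Residual error model kind.
#' @param ... Passed to [fit_individual()].
#' @return A tibble of class `xeno_fits`: `study_id`, `lambda0`, `lambda1`,
#'   `k1`, `k2`, `w0`, `sigma_a`, `sigma_b`, `logLik`, `converged`,
#'   `non_responder`.
#' @export
fit_pdx_panel <- function(panel, regimens, pk = NULL,
                          error = c("proportional", "combined"),
                          hessian = FALSE, ...) {
  error <- match.arg(error)
  if (inherits(panel, "xeno_panel")) {
    if (missing(regimens)) regimens <- panel$regimens
    if (is.null(pk)) pk <- panel$pk
    panel <- panel$panel
  }
  if (is.null(pk)) pk <- default_mouse_pk()
  panel <- as_tibble(panel)
  ids <- unique(panel$study_id)
  rows <- purrr::map(ids, function(id) {
    d <- panel[panel$study_id == id, ]
    reg <- if (inherits(regimens, "xeno_regimen")) regimens else regimens[[as.character(id)]]
    trt <- d[d$arm == "treated", c("time_day", "tumor_cm3")]
    st <- tgi_study(id,
                    control = d[d$arm == "control", c("time_day", "tumor_cm3")],
                    treated = if (nrow(trt) > 0) trt else NULL,
                    regimen = reg)
    f <- fit_individual(st, pk = pk, error = error, hessian = hessian, ...)
    ok <- !is.null(f$params) && f$convergence %in% c(0L, 52L)
    tibble(study_id = id,
           lambda0 = if (ok) f$params$lambda0 else NA_real_,
           lambda1 = if (ok) f$params$lambda1 else NA_real_,
           k1 = if (ok) f$params$k1 else NA_real_,
           k2 = if (ok) f$params$k2 else NA_real_,
           w0 = if (ok) f$params$w0 else NA_real_,
           sigma_a = if (ok) f$error$a else NA_real_,
           sigma_b = if (ok) f$error$b else NA_real_,
           logLik = f$logLik, converged = ok,
           non_responder = isTRUE(f$non_responder))
  })
  out <- bind_rows(rows)
  if (any(!out$converged)) {
    warn(sprintf("%d studies did not converge and are flagged.",
                 sum(!out$converged)))
  }
  structure(out, class = c("xeno_fits", class(tibble())), error_kind = error)
}

pop_par_names <- c("lambda0", "lambda1", "k1", "k2")

#' Summarise per-study fits into a population distribution
#'
#' Two-stage summary: all parameters are lognormal across PDX models, so
#' the typical value of each parameter is the geometric mean of the
#' per-study estimates and the random-effect covariance is the sample
#' covariance of their logs. Correlation is allowed only between the
#' random effects of `lambda0` and `k2`; every other off-diagonal is
#' structurally zero, and the one free covariance is clipped so the matrix
#' stays positive semidefinite.
#'
#' @param fits An `xeno_fits` tibble (or data frame with columns `lambda0`,
#'   `lambda1`, `k1`, `k2`, optionally `converged`, `non_responder`,
#'   `sigma_a`, `sigma_b`).
#' @param error An [error_model()]; defaults to the median of the
#'   per-study error estimates under the panel's error kind.
#' @return An object of class `xeno_popest` with fields `theta` (named
#'   typical values), `omega` (4x4 log-scale covariance), `error`,
#'   `n_studies` and the retained `fits`.
#' @export
fit_population <- function(fits, error = NULL) {
  d <- as_tibble(fits)
  if (!is.null(d[["converged"]])) d <- d[d$converged, ]
  if (nrow(d) < 3) abort("need at least 3 successful fits.")
  has_k2 <- !is.null(d[["k2"]]) && any(is.finite(d$k2))
  use <- d
  if (has_k2 && !is.null(d[["non_responder"]])) {
    nr <- sum(d$non_responder)
    if (nr > 0) {
      warn(sprintf("%d non-responder fits (k2 at bound) excluded from the potency summary.", nr))
      use <- d[!d$non_responder, ]
    }
  }
  pars <- pop_par_names[pop_par_names %in% names(use)]
  logm <- log(as.matrix(use[, pars]))
  keep <- pars[colSums(is.finite(logm)) >= 3]
  logm <- logm[, keep, drop = FALSE]

  theta <- setNames(rep(NA_real_, 4), pop_par_names)
  theta[keep] <- exp(colMeans(logm, na.rm = TRUE))
  omega <- matrix(0, 4, 4, dimnames = list(pop_par_names, pop_par_names))
  for (p in keep) {
    v <- var(logm[, p], na.rm = TRUE)
    omega[p, p] <- if (is.finite(v)) v else 0
  }
  if (all(c("lambda0", "k2") %in% keep)) {
    cc <- stats::cov(logm[, "lambda0"], logm[, "k2"],
                     use = "complete.obs")
    lim <- sqrt(omega["lambda0", "lambda0"] * omega["k2", "k2"])
    cc <- max(min(cc, lim), -lim) # PSD projection for the single free entry
    omega["lambda0", "k2"] <- omega["k2", "lambda0"] <- cc
  }
  if (all(omega[cbind(keep, keep)] == 0)) {
    warn("degenerate panel: all log-variances are zero.")
  }
  if (is.null(error)) {
    kind <- attr(fits, "error_kind") %||% "proportional"
    b <- median(use$sigma_b, na.rm = TRUE)
    a <- if (kind == "combined") median(use$sigma_a, na.rm = TRUE) else 0
    if (!is.finite(b)) b <- 0.1
    error <- error_model(kind, a = if (is.finite(a)) a else 0, b = b)
  }
  structure(list(theta = theta, omega = omega, error = error,
                 n_studies = nrow(d), fits = d),
            class = "xeno_popest")
}

#' @exportS3Method base::print
print.xeno_popest <- function(x, ...) {
  cat(sprintf("<xeno_popest> %d studies\n", x$n_studies))
  tv <- x$theta
  cv <- sqrt(exp(diag(x$omega)) - 1)
  for (p in names(tv)) {
    cat(sprintf("  %-8s theta = %-10.4g omega^2 = %-8.4g (CV %.0f%%)\n",
                p, tv[[p]], x$omega[p, p], 100 * cv[[p]]))
  }
  v <- x$omega["lambda0", "lambda0"] * x$omega["k2", "k2"]
  if (is.finite(v) && v > 0) {
    cat(sprintf("  corr(log lambda0, log k2) = %.3f\n",
                x$omega["lambda0", "k2"] / sqrt(v)))
  }
  invisible(x)
}

#' Nonparametric bootstrap of the population summary
#'
#' Resamples studies (rows of the cached per-study fits) with replacement,
#' re-summarising each resample with [fit_population()]. Deterministic
#' under `seed`. Replicates that degenerate to fewer than 3 distinct
#' studies are redrawn.
#'
#' @param fits An `xeno_fits` tibble (cached per-study fits).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param error Optional fixed [error_model()] passed through.
#' @return A list of `B` `xeno_popest` objects (class
#'   `xeno_popest_boot`).
#' @export
bootstrap_population <- function(fits, B = 200, seed = 1, error = NULL) {
  stopifnot(B >= 1)
  d <- as_tibble(fits)
  if (!is.null(d[["converged"]])) d <- d[d$converged, ]
  n <- nrow(d)
  if (n < 3) abort("need at least 3 successful fits to bootstrap.")
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(d$study_id[idx])) >= 3) break
    }
    sub <- d[idx, ]
    attr(sub, "error_kind") <- attr(fits, "error_kind")
    reps[[b]] <- suppressWarnings(fit_population(sub, error = error))
  }
  structure(reps, class = "xeno_popest_boot")
}

#' Read / write a population estimate as JSON
#'
#' The JSON layout (`theta`, `omega`, `error`, `n_studies`) lets externally
#' obtained population parameters — e.g. estimates transcribed from a
#' published analysis — drive the scaling and virtual-trial stages.
#'
#' @param x An `xeno_popest`.
#' @param path JSON path.
#' @return `read_popest_json()` returns an `xeno_popest`.
#' @export
write_popest_json <- function(x, path) {
  jsonlite::write_json(
    list(theta = as.list(x$theta), omega = as.vector(x$omega),
         error = list(kind = x$error$kind, a = x$error$a, b = x$error$b),
         n_studies = x$n_studies),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_popest_json
#' @export
read_popest_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- unlist(j$theta)[pop_par_names]
  names(theta) <- pop_par_names
  omega <- matrix(j$omega, 4, 4,
                  dimnames = list(pop_par_names, pop_par_names))
  structure(list(theta = theta, omega = omega,
                 error = error_model(j$error$kind, a = j$error$a, b = j$error$b),
                 n_studies = j$n_studies, fits = NULL),
            class = "xeno_popest")
}
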