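#' Baseline tumor volume specification
#'
#' Either a fixed baseline (`tv0` for every patient) or a lognormal
#' distribution `tv0 * exp(eta)`, `eta ~ N(0, omega_tv0_sq)`. Because the
#' human model is exponential growth with a first-order kill, times to
#' progression do not depend on the baseline; it only scales the diameter
#' trajectories.
#'
#' @param kind `"fixed"` or `"lognormal"`.
#' @param tv0 Typical baseline volume [cm3].
#' @param omega_tv0_sq Log-scale variance (lognormal only).
#' @return An object of class `xeno_baseline`.
#' @examples
#' baseline_spec()                        # 1 cm3 for everyone
#' baseline_spec("lognormal", 115.3, 0.16) # advanced-disease SLD-derived mix
#' @export
baseline_spec <- function(kind = c("fixed", "lognormal"), tv0 = 1,
                          omega_tv0_sq = 0) {
  kind <- match.arg(kind)
  if (tv0 <= 0) abort("`tv0` must be > 0.")
  if (omega_tv0_sq < 0) abort("`omega_tv0_sq` must be >= 0.")
  structure(list(kind = kind, tv0 = tv0,
                 omega_tv0_sq = if (kind == "lognormal") omega_tv0_sq else 0),
            class = "xeno_baseline")
}

#' Progression rule
#'
#' A progressive-disease event is a relative increase of the tumor
#' diameter (single-lesion SLD) of `threshold_fraction` over the reference:
#' either the baseline diameter or the running minimum (nadir, closest to
#' RECIST's "smallest sum on study"). Patients without an event by
#' `horizon` are censored there. An optional absolute diameter floor
#' [cm] can additionally be required for an event (off by default).
#'
#' @param threshold_fraction Relative SLD increase defining progression.
#' @param reference `"nadir"` or `"baseline"`.
#' @param horizon Simulation horizon [month].
#' @param abs_increase_cm Optional absolute diameter increase floor [cm].
#' @return An object of class `xeno_rule`.
#' @export
progression_rule <- function(threshold_fraction = 0.20,
                             reference = c("nadir", "baseline"),
                             horizon = 14, abs_increase_cm = 0) {
  reference <- match.arg(reference)
  if (threshold_fraction <= 0) abort("`threshold_fraction` must be > 0.")
  if (horizon <= 0) abort("`horizon` must be > 0.")
  structure(list(threshold_fraction = threshold_fraction,
                 reference = reference, horizon = horizon,
                 abs_increase_cm = abs_increase_cm),
            class = "xeno_rule")
}

#' Sample a virtual patient cohort
#'
#' Draws individual `(lambda0, k2)` pairs from the scaled multivariate
#' lognormal distribution and a baseline volume per the baseline spec.
#'
#' @param humanpop An `xeno_humanpop` from [build_human_distribution()].
#' @param n Number of patients.
#' @param baseline An [baseline_spec()].
#' @param seed Integer seed; same seed, same cohort.
#' @return A tibble: `patient_id`, `lambda0` [1/month], `k2` [L/mg·month],
#'   `tv0` [cm3].
#' @export
sample_patients <- function(humanpop, n, baseline = baseline_spec(),
                            seed = NULL) {
  stopifnot(n >= 1)
  om <- humanpop$omega
  ev <- eigen((om + t(om)) / 2, only.values = TRUE)$values
  if (any(ev < -1e-10)) abort("omega is not positive semidefinite.")
  if (!is.null(seed)) set.seed(seed)
  eta <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = om)
  eta <- matrix(eta, ncol = 2)
  tv0 <- if (baseline$kind == "fixed") {
    rep(baseline$tv0, n)
  } else {
    baseline$tv0 * exp(rnorm(n, 0, sqrt(baseline$omega_tv0_sq)))
  }
  tibble(patient_id = seq_len(n),
         lambda0 = humanpop$lambda0_pop * exp(eta[, 1]),
         k2 = humanpop$k2_pop * exp(eta[, 2]),
         tv0 = tv0)
}

# Progression evaluation grid: a uniform 0.01-month grid plus every node
# of the concentration profile within the horizon. The log-volume gain is
# piecewise linear between profile nodes, so on this grid the running
# minimum and the linear crossing inversion are exact.
ttp_time_grid <- function(conc, horizon, dt = 0.01) {
  grid <- seq(0, horizon, by = dt)
  if (!is.null(conc)) {
    grid <- c(grid, conc$time[conc$time <= horizon], horizon)
  }
  sort(unique(grid))
}

# Core progression computation on the log-volume gain.
# g is a (time x patient) matrix of lambda0*t - k2*CAUC(t); returns per
# patient the first time the diameter ratio over the reference exceeds
# 1 + threshold, located by linear inversion on the grid segment (g is
# piecewise linear in t because CAUC is trapezoidal).
ttp_from_gain <- function(times, g, rule, td0 = NULL) {
  delta <- 3 * log(1 + rule$threshold_fraction)
  excess <- if (rule$reference == "nadir") {
    g - apply(g, 2, cummin)
  } else {
    g # reference g(0) = 0
  }
  if (rule$abs_increase_cm > 0 && !is.null(td0)) {
    # absolute-increase floor: td(t) - td_ref(t) must also exceed the floor
    td <- sweep(exp(g / 3), 2, td0, "*")
    td_ref <- if (rule$reference == "nadir") apply(td, 2, cummin) else
      matrix(rep(td0, each = nrow(td)), nrow = nrow(td))
    excess[td - td_ref < rule$abs_increase_cm] <- -Inf
  }
  n <- ncol(g)
  out_time <- rep(rule$horizon, n)
  out_event <- rep(FALSE, n)
  hit <- excess >= delta
  any_hit <- colSums(hit) > 0
  for (j in which(any_hit)) {
    i <- which.max(hit[, j])
    if (i == 1L) {
      out_time[j] <- times[1]
    } else {
      e0 <- excess[i - 1L, j]
      e1 <- excess[i, j]
      out_time[j] <- times[i - 1L] +
        (delta - e0) / (e1 - e0) * (times[i] - times[i - 1L])
    }
    out_event[j] <- out_time[j] <= rule$horizon
    if (!out_event[j]) out_time[j] <- rule$horizon
  }
  list(time = pmin(out_time, rule$horizon), event = out_event)
}

#' Time to progression of virtual patients
#'
#' Simulates each patient's tumor under the shared concentration profile
#' (closed form: log-volume gain `g(t) = lambda0*t - k2*CAUC(t)`) and
#' returns the first time the diameter exceeds the progression threshold
#' over the reference, or censoring at the horizon. The crossing time is
#' located exactly on the piecewise-linear gain between grid points.
#'
#' @param patients Tibble from [sample_patients()] (columns `lambda0`,
#'   `k2`, `tv0`).
#' @param conc Month-scale `xeno_profile` spanning the rule horizon.
#' @param rule An [progression_rule()].
#' @param grid Evaluation grid [month]; defaults to a 0.01-month grid over
#'   the horizon.
#' @return A tibble: `patient_id`, `time` [month], `event` (TRUE =
#'   progression, FALSE = censored at horizon).
#' @export
time_to_progression <- function(patients, conc, rule = progression_rule(),
                                grid = NULL) {
  if (!is.null(conc) && !identical(attr(conc, "time_unit"), "month")) {
    abort("`conc` must be on the month time scale.")
  }
  if (is.null(grid)) grid <- ttp_time_grid(conc, rule$horizon)
  if (!is.null(conc) && max(conc$time) < rule$horizon - 1e-9) {
    abort("concentration profile does not span the horizon.")
  }
  cauc <- if (is.null(conc)) rep(0, length(grid)) else cauc_at(conc, grid)
  g <- outer(grid, patients$lambda0) - outer(cauc, patients$k2)
  res <- ttp_from_gain(grid, g, rule, td0 = volume_to_diameter(patients$tv0))
  tibble(patient_id = patients$patient_id %||% seq_len(nrow(patients)),
         time = res$time, event = res$event)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival estimate for time-to-progression data: at each
#' distinct event time the survival drops by the factor
#' `1 - d/n_at_risk`; censored subjects leave the risk set without an
#' event. The returned step function is right-continuous and starts at
#' `S(0) = 1`.
#'
#' @param data A data frame with columns `time` and `event` (logical or
#'   0/1).
#' @return A tibble of class `xeno_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (one row per distinct observed time, plus the
#'   `time = 0` anchor).
#' @export
km_estimate <- function(data) {
  if (nrow(data) == 0) abort("empty survival input.")
  if (any(data$time < 0)) abort("times must be >= 0.")
  ev <- as.logical(data$event)
  tt <- data$time
  ut <- sort(unique(tt))
  n_risk <- n_event <- n_censor <- integer(length(ut))
  for (i in seq_along(ut)) {
    n_risk[i] <- sum(tt >= ut[i])
    n_event[i] <- sum(tt == ut[i] & ev)
    n_censor[i] <- sum(tt == ut[i] & !ev)
  }
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble(time = c(0, ut), n_risk = c(length(tt), n_risk),
                n_event = c(0L, n_event), n_censor = c(0L, n_censor),
                survival = c(1, surv))
  structure(out, class = c("xeno_km", class(tibble())))
}

#' Evaluate a survival step function
#'
#' Right-continuous evaluation of a KM curve at arbitrary times:
#' `S(t)` is the survival of the last step at or before `t` (1 before the
#' first step time).
#'
#' @param km A data frame with `time` and `survival`.
#' @param times Evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_eval_step <- function(km, times) {
  idx <- findInterval(times, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Median of a survival curve
#'
#' The smallest time at which the survival function reaches 0.5 or below
#' (first attainment on plateaus). `NA` with attribute `reached = FALSE`
#' if the curve never crosses 0.5 over its support.
#'
#' @param curve An `xeno_km` (or any data frame with `time`, `survival`).
#' @return The median time, or `NA_real_` if not reached.
#' @export
curve_median <- function(curve) {
  i <- which(curve$survival <= 0.5 + 1e-12)
  if (length(i) == 0) {
    return(structure(NA_real_, reached = FALSE))
  }
  structure(curve$time[min(i)], reached = TRUE)
}

#' Reconstruct a TTP curve from PFS and OS
#'
#' Under independence of progression and death, progression-free survival
#' factors as `S_PFS(t) = S_TTP(t) * S_OS(t)`, so the TTP curve is the
#' ratio `S_PFS / S_OS` evaluated on the union of step times, clipped to
#' `[0, 1]` and forced non-increasing by a running minimum. `S_OS >= S_PFS`
#' must hold (progression-free implies alive); pointwise violations up to
#' 2 percent — digitization noise — are clipped, larger ones are an error.
#'
#' @param pfs,os Survival curves: data frames with `time` and `survival`.
#' @return A tibble of class `xeno_km` with `time` and `survival`.
#' @export
reconstruct_ttp <- function(pfs, os) {
  times <- sort(unique(c(pfs$time, os$time)))
  sp <- km_eval_step(pfs, times)
  so <- km_eval_step(os, times)
  bad <- sp > so
  if (any(sp - so > 0.02)) {
    abort("S_PFS exceeds S_OS by more than 2%: curves are inconsistent.")
  }
  sp[bad] <- so[bad]
  if (any(so == 0 & sp > 0)) {
    abort("S_OS reaches 0 while S_PFS > 0: TTP ratio is ill-posed.")
  }
  ratio <- ifelse(so == 0, 0, sp / so)
  ratio <- pmin(pmax(ratio, 0), 1)
  ratio <- cummin(ratio)
  out <- tibble(time = times, survival = ratio)
  if (times[1] > 0) out <- bind_rows(tibble(time = 0, survival = 1), out)
  structure(out, class = c("xeno_km", class(tibble())))
}

#' Run Monte Carlo virtual clinical trials
#'
#' For each replicate: pick a population-parameter draw (cycling through
#' the supplied bootstrap replicates, so parameter-estimation uncertainty
#' propagates), sample a fresh cohort, derive every patient's time to
#' progression under the shared concentration profile, and build the
#' cohort KM curve. Across replicates the function aggregates pointwise
#' 5th/50th/95th percentiles of the TTP curves and of the tumor diameter
#' percentile trajectories, plus the distribution of per-replicate median
#' TTP. Replicates whose KM never reaches 0.5 contribute their median as
#' censored at the horizon (flagged).
#'
#' @param humanpops A single `xeno_humanpop`, or a list of them (e.g. one
#'   per bootstrap replicate) to propagate estimation uncertainty.
#' @param conc Month-scale `xeno_profile` spanning the horizon.
#' @param baseline An [baseline_spec()].
#' @param rule An [progression_rule()].
#' @param n_patients Patients per cohort (default 200).
#' @param n_replicates Monte Carlo replicates (default 1000).
#' @param seed Master seed; per-replicate seeds are derived from it so the
#'   first `k` replicates are identical for any `n_replicates >= k`.
#' @param td_grid Time grid [month] for diameter trajectory bands.
#' @return An object of class `xeno_trial` with elements
#'   `ttp_bands` (tibble `time`, `p05`, `p50`, `p95`),
#'   `td_bands` (tibble `stat`, `time`, `p05`, `p50`, `p95`; `stat` is the
#'   within-cohort percentile the band tracks),
#'   `median_ttp` (per-replicate medians with censoring flags) and
#'   `median_ttp_summary` (median and 90 percent prediction interval).
#' @export
run_virtual_trials <- function(humanpops, conc, baseline = baseline_spec(),
                               rule = progression_rule(), n_patients = 200,
                               n_replicates = 1000, seed = 1,
                               td_grid = NULL) {
  if (inherits(humanpops, "xeno_humanpop")) humanpops <- list(humanpops)
  stopifnot(length(humanpops) >= 1, n_patients >= 1, n_replicates >= 1)
  if (is.null(td_grid)) td_grid <- seq(0, rule$horizon, by = 0.25)
  ttp_grid <- ttp_time_grid(conc, rule$horizon)
  cauc <- if (is.null(conc)) rep(0, length(ttp_grid)) else
    cauc_at(conc, ttp_grid)
  cauc_td <- if (is.null(conc)) rep(0, length(td_grid)) else
    cauc_at(conc, td_grid)

  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_replicates)

  km_mat <- matrix(NA_real_, length(ttp_grid), n_replicates)
  td_q <- array(NA_real_, c(length(td_grid), 3, n_replicates))
  med <- numeric(n_replicates)
  med_censored <- logical(n_replicates)

  for (r in seq_len(n_replicates)) {
    hp <- humanpops[[((r - 1L) %% length(humanpops)) + 1L]]
    pats <- sample_patients(hp, n_patients, baseline, seed = rep_seeds[r])
    g <- outer(ttp_grid, pats$lambda0) - outer(cauc, pats$k2)
    res <- ttp_from_gain(ttp_grid, g, rule,
                         td0 = volume_to_diameter(pats$tv0))
    km <- km_estimate(tibble(time = res$time, event = res$event))
    km_mat[, r] <- km_eval_step(km, ttp_grid)
    m <- curve_median(km)
    med_censored[r] <- !isTRUE(attr(m, "reached"))
    med[r] <- if (med_censored[r]) rule$horizon else as.numeric(m)
    gd <- outer(td_grid, pats$lambda0) - outer(cauc_td, pats$k2)
    td <- sweep(exp(gd / 3), 2, volume_to_diameter(pats$tv0), "*")
    td_q[, , r] <- t(apply(td, 1, quantile, probs = c(0.05, 0.5, 0.95),
                           names = FALSE))
  }

  band <- function(m) {
    q <- apply(m, 1, quantile, probs = c(0.05, 0.5, 0.95), names = FALSE)
    tibble(p05 = q[1, ], p50 = q[2, ], p95 = q[3, ])
  }
  ttp_bands <- bind_cols(tibble(time = ttp_grid), band(km_mat))
  td_bands <- bind_rows(lapply(seq_along(c(0.05, 0.5, 0.95)), function(k) {
    stat <- c("p05_patients", "p50_patients", "p95_patients")[k]
    bind_cols(tibble(stat = stat, time = td_grid),
              band(td_q[, k, , drop = TRUE]))
  }))
  qs <- quantile(med, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  structure(
    list(ttp_bands = ttp_bands, td_bands = td_bands,
         median_ttp = tibble(replicate = seq_len(n_replicates),
                             median_months = med, censored = med_censored),
         median_ttp_summary = tibble(
           median = qs[2], pi_lo = qs[1], pi_hi = qs[3],
           any_censored = any(med_censored)),
         n_patients = n_patients, n_replicates = n_replicates,
         rule = rule, baseline = baseline),
    class = "xeno_trial"
  )
}

#' @exportS3Method base::print
print.xeno_trial <- function(x, ...) {
  s <- x$median_ttp_summary
  cat(sprintf("<xeno_trial> %d replicates x %d patients (%s reference)\n",
              x$n_replicates, x$n_patients, x$rule$reference))
  cat(sprintf("  median TTP %.2f months, 90%% PI [%.2f, %.2f]\n",
              s$median, s$pi_lo, s$pi_hi))
  if (s$any_censored) {
    cat("  note: some replicate medians were censored at the horizon.\n")
  }
  invisible(x)
}

#' Write a survival curve to CSV
#'
#' Columns `time`, `survival` and, when present, `n_risk`, `n_event`,
#' `n_censor`; the step convention (right-continuous) is stated in a
#' comment line.
#'
#' @param km An `xeno_km`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(km, path) {
  writeLines("# right-continuous step function; survival applies on [time, next time)",
             path)
  readr::write_csv(as_tibble(km), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a survival curve from CSV
#'
#' Expects columns `time` and `survival`; `#` lines are comments. Used for
#' digitized clinical KM curves (PFS/OS/TTP step functions).
#'
#' @param path CSV path.
#' @return An `xeno_km` tibble.
#' @export
read_survival_csv <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  structure(as_tibble(d), class = c("xeno_km", class(tibble())))
}
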