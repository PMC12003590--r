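#' Define a linear compartmental PK model
#'
#' Builds a mammillary 1- or 2-compartment disposition model with one of
#' three input routes: direct intravenous input (`"iv"`), a single first-order
#' absorption depot (`"first_order"`, typical for i.p. dosing in mice and
#' simple oral absorption), or a transit-compartment chain (`"transit"`,
#' used for delayed oral absorption such as sorafenib).
#'
#' Disposition is parametrised by clearance and volumes: `cl` [L/time] and
#' `vc` [L] for the central compartment, plus inter-compartmental clearance
#' `q` [L/time] and peripheral volume `vp` [L] when `n_compartments = 2`.
#' All rate parameters share one time unit (days throughout the package).
#'
#' @param n_compartments 1 or 2 disposition compartments.
#' @param cl Clearance from the central compartment [L/time].
#' @param vc Central volume of distribution [L].
#' @param q,vp Inter-compartmental clearance [L/time] and peripheral
#'   volume [L]; required when `n_compartments = 2`.
#' @param absorption One of `"iv"`, `"first_order"`, `"transit"`.
#' @param ka First-order absorption rate constant [1/time]
#'   (`absorption = "first_order"`).
#' @param n_transit,ktr Number of transit stages (>= 1) and the shared
#'   transit rate constant [1/time] (`absorption = "transit"`).
#' @param f Bioavailable fraction applied to every dose amount.
#' @param time_unit Time unit label; the package convention is `"day"`.
#'
#' @return An object of class `xeno_pk_model`.
#' @examples
#' pk_model(1, cl = 1, vc = 10, absorption = "iv")
#' @export
pk_model <- function(n_compartments = 2, cl, vc, q = NULL, vp = NULL,
                     absorption = c("iv", "first_order", "transit"),
                     ka = NULL, n_transit = 4, ktr = NULL, f = 1,
                     time_unit = "day") {
  absorption <- match.arg(absorption)
  stopifnot(n_compartments %in% c(1, 2))
  if (!is.numeric(cl) || cl <= 0 || !is.numeric(vc) || vc <= 0) {
    abort("`cl` and `vc` must be strictly positive.")
  }
  if (n_compartments == 2) {
    if (is.null(q) || is.null(vp) || q <= 0 || vp <= 0) {
      abort("2-compartment models need strictly positive `q` and `vp`.")
    }
  }
  if (absorption == "first_order" && (is.null(ka) || ka <= 0)) {
    abort("`absorption = \"first_order\"` needs a strictly positive `ka`.")
  }
  if (absorption == "transit") {
    if (is.null(ktr) || ktr <= 0) abort("transit absorption needs `ktr` > 0.")
    if (n_transit < 1) abort("`n_transit` must be >= 1.")
  }
  if (f <= 0 || f > 1) abort("`f` must lie in (0, 1].")
  structure(
    list(n_compartments = n_compartments, cl = cl, vc = vc, q = q, vp = vp,
         absorption = absorption, ka = ka,
         n_transit = if (absorption == "transit") as.integer(n_transit) else 0L,
         ktr = ktr, f = f, time_unit = time_unit),
    class = "xeno_pk_model"
  )
}

#' @exportS3Method base::print
print.xeno_pk_model <- function(x, ...) {
  cat(sprintf("<xeno_pk_model> %d-compartment, %s input\n",
              x$n_compartments, x$absorption))
  cat(sprintf("  CL = %g L/%s, Vc = %g L", x$cl, x$time_unit, x$vc))
  if (x$n_compartments == 2) cat(sprintf(", Q = %g, Vp = %g", x$q, x$vp))
  cat(sprintf(", F = %g\n", x$f))
  invisible(x)
}

#' Load a PK model specification from a YAML file
#'
#' The YAML keys mirror the arguments of [pk_model()].
#'
#' @param path Path to a YAML file.
#' @return An `xeno_pk_model`.
#' @export
read_pk_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pk_model, y[intersect(names(y), names(formals(pk_model)))])
}

# State layout: [absorption compartments][central][peripheral].
# Returns the rate matrix (amount units) plus the dose and central indices.
pk_system <- function(spec) {
  n_abs <- switch(spec$absorption,
                  iv = 0L, first_order = 1L, transit = spec$n_transit)
  n <- n_abs + spec$n_compartments
  A <- matrix(0, n, n)
  ic <- n_abs + 1L
  A[ic, ic] <- -spec$cl / spec$vc
  if (spec$n_compartments == 2) {
    ip <- ic + 1L
    A[ic, ic] <- A[ic, ic] - spec$q / spec$vc
    A[ip, ic] <- spec$q / spec$vc
    A[ic, ip] <- spec$q / spec$vp
    A[ip, ip] <- -spec$q / spec$vp
  }
  if (spec$absorption == "first_order") {
    A[1, 1] <- -spec$ka
    A[ic, 1] <- spec$ka
  } else if (spec$absorption == "transit") {
    for (j in seq_len(n_abs)) {
      A[j, j] <- -spec$ktr
      if (j < n_abs) A[j + 1L, j] <- spec$ktr
    }
    A[ic, n_abs] <- spec$ktr
  }
  list(A = A, dose_cpt = if (n_abs > 0) 1L else ic, central = ic, n = n)
}

#' Build an explicit dosing regimen
#'
#' Expands a named cyclic protocol (or custom event table) into explicit
#' dose events over a simulation horizon. Times are in days.
#'
#' Named protocols:
#' * `"gemcitabine_standard"`: 30-minute i.v. infusions of 1000 mg/m2 once
#'   weekly for 7 weeks, one rest week, then weekly on weeks 1-3 of every
#'   4-week cycle. Requires `bsa` to convert mg/m2 to mg.
#' * `"sorafenib_standard"`: 400 mg orally every 12 h (800 mg/day).
#'
#' @param protocol `"gemcitabine_standard"`, `"sorafenib_standard"` or
#'   `"custom"`.
#' @param horizon Simulation span [day]; events at `time >= horizon` are
#'   not generated.
#' @param bsa Body surface area [m2] for mg/m2 protocols (default 1.8 m2,
#'   the reference adult; required for gemcitabine).
#' @param events For `protocol = "custom"`: a data frame with columns
#'   `time` [day], `amount` [mg] and optionally `duration` [day]
#'   (0 = bolus/absorbed dose).
#' @param route Route tag for custom regimens (`"iv"`, `"oral"`, `"ip"`).
#'
#' @return A tibble of class `xeno_regimen` with columns `time`, `amount`,
#'   `duration` and attributes `horizon`, `route`, `time_unit`.
#' @examples
#' build_regimen("sorafenib_standard", horizon = 7)
#' @export
build_regimen <- function(protocol = c("gemcitabine_standard",
                                       "sorafenib_standard", "custom"),
                          horizon, bsa = 1.8, events = NULL, route = NULL) {
  protocol <- match.arg(protocol)
  if (!is.numeric(horizon) || horizon <= 0) abort("`horizon` must be > 0.")
  if (protocol == "gemcitabine_standard") {
    if (is.null(bsa) || bsa <= 0) {
      abort("gemcitabine_standard doses 1000 mg/m2: supply a positive `bsa`.")
    }
    if (horizon < 56) {
      warn("horizon shorter than the first 8-week gemcitabine cycle; expansion truncated.")
    }
    # induction: weekly infusions weeks 1-7, rest week 8
    times <- 7 * (0:6)
    # maintenance: weeks 1-3 of each 4-week cycle, starting day 56
    cycle_starts <- seq(56, by = 28, length.out = max(1, ceiling(horizon / 28)))
    times <- c(times, as.vector(outer(c(0, 7, 14), cycle_starts, "+")))
    times <- sort(times[times < horizon])
    ev <- tibble(time = times, amount = 1000 * bsa, duration = 30 / 60 / 24)
    route <- "iv"
  } else if (protocol == "sorafenib_standard") {
    if (horizon < 0.5) warn("horizon shorter than one 12-h dosing interval.")
    times <- seq(0, by = 0.5, length.out = max(1, ceiling(horizon / 0.5)))
    times <- times[times < horizon]
    ev <- tibble(time = times, amount = 400, duration = 0)
    route <- "oral"
  } else {
    if (is.null(events)) abort("custom protocol needs an `events` data frame.")
    ev <- as_tibble(events)
    if (!all(c("time", "amount") %in% names(ev))) {
      abort("`events` must have columns `time` and `amount`.")
    }
    if (is.null(ev[["duration"]])) ev$duration <- 0
    ev <- ev[ev$time < horizon, , drop = FALSE]
    route <- route %||% "iv"
  }
  if (any(ev$time < 0)) abort("dose times must be >= 0.")
  if (any(ev$amount <= 0)) abort("dose amounts must be > 0.")
  if (any(ev$duration < 0)) abort("infusion durations must be >= 0.")
  ev <- arrange(ev, .data$time)
  structure(ev, class = c("xeno_regimen", class(tibble())),
            horizon = horizon, route = route, time_unit = "day")
}

#' Event-refined simulation time grid
#'
#' Uniform grid over the regimen horizon plus log-spaced refinement after
#' every dose start and infusion end, so that trapezoidal cumulative
#' exposure is accurate (< 0.1 percent) even for drugs with half-lives much
#' shorter than the uniform step.
#'
#' @param regimen An `xeno_regimen`.
#' @param horizon Span [day]; defaults to the regimen horizon.
#' @param dt Uniform step [day].
#' @param n_refine Log-spaced points added after each anchor.
#' @param t_min Smallest refinement offset [day].
#' @return Sorted numeric vector of times.
#' @export
pk_time_grid <- function(regimen, horizon = attr(regimen, "horizon"),
                         dt = 0.25, n_refine = 64, t_min = 1e-4) {
  base <- seq(0, horizon, by = dt)
  anchors <- sort(unique(c(regimen$time,
                           regimen$time[regimen$duration > 0] +
                             regimen$duration[regimen$duration > 0])))
  # log-spaced refinement after each anchor spanning the whole gap to the
  # next anchor: bounds the trapezoid error of the running exposure for
  # any elimination rate, fast or slow
  gaps <- c(diff(anchors), max(horizon - anchors[length(anchors)], 2 * t_min))
  ref <- unlist(lapply(seq_along(anchors), function(i) {
    anchors[i] + exp(seq(log(t_min), log(max(gaps[i], 2 * t_min)),
                         length.out = n_refine))
  }))
  pre <- anchors[anchors > t_min] - t_min # bracket state jumps at bolus times
  grid <- sort(unique(c(base, anchors, pre, ref, horizon)))
  grid <- grid[grid <= horizon + 1e-12]
  # collapse float-ulp near-duplicates (e.g. anchor + exp(log(gap)) landing
  # one ulp past the next anchor), which would otherwise re-trigger a dose
  grid[c(TRUE, diff(grid) > 1e-9)]
}

#' Simulate plasma concentration from a linear compartmental model
#'
#' Propagates the linear system exactly on each inter-event interval using
#' the matrix exponential (with caching over repeated step sizes), treating
#' bolus doses as state jumps into the dose compartment and infusions as
#' piecewise-constant inputs. Central concentration is central amount / `vc`.
#' The running integral of concentration (cumulative exposure) is attached
#' by [cumulative_exposure()].
#'
#' @param spec An [pk_model()] specification.
#' @param regimen An [build_regimen()] regimen in the same time unit.
#' @param grid Output time grid; defaults to [pk_time_grid()] over the
#'   regimen horizon.
#' @param dt Uniform step for the default grid [day].
#'
#' @return A tibble of class `xeno_profile` with columns `time`,
#'   `conc` [mg/L] and `cauc` [mg·time/L], and a `time_unit` attribute.
#' @examples
#' reg <- build_regimen("custom", horizon = 48,
#'                      events = data.frame(time = 0, amount = 100))
#' pk <- pk_model(1, cl = 1, vc = 10, absorption = "iv")
#' prof <- simulate_pk(pk, reg)
#' @export
simulate_pk <- function(spec, regimen, grid = NULL, dt = 0.25) {
  stopifnot(inherits(spec, "xeno_pk_model"), inherits(regimen, "xeno_regimen"))
  if (!identical(spec$time_unit, attr(regimen, "time_unit"))) {
    abort("PK model and regimen must share one time unit.")
  }
  sys <- pk_system(spec)
  ev_vals <- eigen(sys$A, only.values = TRUE)$values
  if (any(Re(ev_vals) >= 0)) {
    abort("non-physical PK specification: system matrix has a non-negative eigenvalue.")
  }
  if (is.null(grid)) grid <- pk_time_grid(regimen, dt = dt)
  grid <- sort(unique(c(0, grid)))

  bolus <- regimen[regimen$duration == 0, , drop = FALSE]
  inf <- regimen[regimen$duration > 0, , drop = FALSE]
  # breakpoints where either state jumps or the input rate changes;
  # collapse float-ulp near-duplicates so each event maps to one break
  breaks <- sort(unique(c(grid, bolus$time, inf$time, inf$time + inf$duration)))
  breaks <- breaks[breaks <= max(grid)]
  breaks <- breaks[c(TRUE, diff(breaks) > 1e-9)]

  # each bolus event is applied exactly once, at its nearest break
  bolus_add <- numeric(length(breaks))
  for (b in seq_len(nrow(bolus))) {
    k <- which.min(abs(breaks - bolus$time[b]))
    bolus_add[k] <- bolus_add[k] + spec$f * bolus$amount[b]
  }

  # constant input-rate vector on each interval [breaks[k], breaks[k+1])
  rate_at <- function(t0, t1) {
    tm <- (t0 + t1) / 2
    active <- inf$time <= tm & (inf$time + inf$duration) > tm
    sum(spec$f * inf$amount[active] / inf$duration[active])
  }

  n <- sys$n
  x <- numeric(n)
  conc <- numeric(length(breaks))
  x[sys$dose_cpt] <- x[sys$dose_cpt] + bolus_add[1]
  conc[1] <- x[sys$central] / spec$vc

  cache <- new.env(parent = emptyenv())
  step_mats <- function(h) {
    key <- sprintf("%.15g", h)
    m <- cache[[key]]
    if (is.null(m)) {
      E <- expm::expm(sys$A * h)
      m <- list(E = E, S = solve(sys$A, E - diag(n)))
      cache[[key]] <- m
    }
    m
  }
  e_in <- numeric(n)
  for (k in seq_len(length(breaks) - 1L)) {
    h <- breaks[k + 1L] - breaks[k]
    r <- rate_at(breaks[k], breaks[k + 1L])
    m <- step_mats(h)
    x <- as.vector(m$E %*% x)
    if (r > 0) {
      e_in[sys$dose_cpt] <- r
      x <- x + as.vector(m$S %*% e_in)
      e_in[sys$dose_cpt] <- 0
    }
    x[sys$dose_cpt] <- x[sys$dose_cpt] + bolus_add[k + 1L]
    conc[k + 1L] <- x[sys$central] / spec$vc
  }
  prof <- tibble(time = breaks, conc = pmax(conc, 0))
  prof <- prof[findInterval(grid, prof$time), ]
  prof$time <- grid
  out <- cumulative_exposure(structure(prof,
                                       class = c("xeno_profile", class(tibble())),
                                       time_unit = spec$time_unit))
  out
}

#' Cumulative drug exposure (running AUC)
#'
#' Fills the `cauc` column of a concentration profile with the trapezoidal
#' running integral of concentration over time.
#'
#' @param profile A data frame with columns `time` and `conc`.
#' @return The profile as an `xeno_profile` tibble with `cauc` added;
#'   `cauc[1] = 0` and `cauc` is non-decreasing.
#' @export
cumulative_exposure <- function(profile) {
  if (is.unsorted(profile$time, strictly = TRUE)) {
    abort("`time` must be strictly increasing.")
  }
  if (any(profile$conc < 0)) abort("`conc` must be non-negative.")
  dt <- diff(profile$time)
  mid <- (head(profile$conc, -1) + tail(profile$conc, -1)) / 2
  profile$cauc <- c(0, cumsum(dt * mid))
  if (!inherits(profile, "xeno_profile")) {
    profile <- structure(as_tibble(profile),
                         class = c("xeno_profile", class(tibble())),
                         time_unit = attr(profile, "time_unit") %||% "day")
  }
  profile
}

#' Convert a day-based concentration profile to months
#'
#' Human tumor dynamics are modeled on a month time scale; PK is simulated
#' in days. This divides times by 30 (the fixed day-to-month factor) and
#' rescales the cumulative exposure to mg·month/L. Concentrations are
#' unchanged.
#'
#' @param profile An `xeno_profile` with `time_unit = "day"`.
#' @param day_to_month Conversion factor (exactly 30).
#' @return An `xeno_profile` with `time_unit = "month"`.
#' @export
profile_to_months <- function(profile, day_to_month = 30) {
  if (!identical(attr(profile, "time_unit"), "day")) {
    abort("profile is not on a day time scale.")
  }
  profile$time <- profile$time / day_to_month
  profile$cauc <- profile$cauc / day_to_month
  attr(profile, "time_unit") <- "month"
  profile
}

#' Read an externally supplied concentration profile
#'
#' Accepts a two-column CSV (`time`, `conc_mg_per_L` or `conc`) such as a
#' published PK profile, and attaches cumulative exposure. Lines starting
#' with `#` are treated as comments.
#'
#' @param path CSV path.
#' @param time_unit Declared unit of the time column.
#' @return An `xeno_profile`.
#' @export
read_concentration_csv <- function(path, time_unit = "day") {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  names(d)[1] <- "time"
  names(d)[2] <- "conc"
  cumulative_exposure(structure(as_tibble(d[, c("time", "conc")]),
                                class = c("xeno_profile", class(tibble())),
                                time_unit = time_unit))
}

#' Constant-concentration profile
#'
#' Convenience constructor used in tests and for steady-state reasoning:
#' a flat concentration over a time grid.
#'
#' @param conc Concentration [mg/L].
#' @param times Time grid.
#' @param time_unit Time unit label.
#' @return An `xeno_profile`.
#' @export
constant_profile <- function(conc, times, time_unit = "day") {
  cumulative_exposure(structure(tibble(time = times, conc = conc),
                                class = c("xeno_profile", class(tibble())),
                                time_unit = time_unit))
}

# Piecewise-linear polyline reduction (Douglas-Peucker) of a concentration
# profile: keeps the fewest nodes such that linear interpolation through
# the kept nodes reproduces every dropped node within `tol` (absolute,
# chosen by callers as a small fraction of the peak concentration).
# Used to make repeated ODE solves with the profile as a forcing cheap.
thin_profile <- function(profile, tol) {
  x <- profile$time
  y <- profile$conc
  n <- length(x)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    idx <- (i + 1L):(j - 1L)
    yhat <- y[i] + (y[j] - y[i]) * (x[idx] - x[i]) / (x[j] - x[i])
    err <- abs(y[idx] - yhat)
    m <- which.max(err)
    if (err[m] > tol) {
      k <- idx[m]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  out <- profile[keep, ]
  cumulative_exposure(structure(out, class = class(profile),
                                time_unit = attr(profile, "time_unit")))
}
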