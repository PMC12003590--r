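#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a population estimate
#'
#' One row per Simeoni parameter: typical value, log-scale variance,
#' geometric CV, and the lambda0-k2 correlation in `glance()`.
#'
#' @param x An `xeno_popest`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.xeno_popest <- function(x, ...) {
  pars <- names(x$theta)
  tibble(parameter = pars,
         theta = unname(x$theta),
         omega_sq = diag(x$omega)[pars],
         cv_geometric = sqrt(exp(diag(x$omega)[pars]) - 1))
}

#' @rdname tidy.xeno_popest
#' @export
glance.xeno_popest <- function(x, ...) {
  v <- x$omega["lambda0", "lambda0"] * x$omega["k2", "k2"]
  tibble(n_studies = x$n_studies,
         corr_lambda0_k2 = if (is.finite(v) && v > 0)
           x$omega["lambda0", "k2"] / sqrt(v) else NA_real_,
         error_kind = x$error$kind,
         sigma_a = x$error$a, sigma_b = x$error$b)
}

#' Tidy virtual-trial results
#'
#' `tidy()` returns the pointwise TTP prediction bands (and diameter bands
#' with `type = "td"`); `glance()` the replicate-median summary.
#'
#' @param x An `xeno_trial`.
#' @param type `"ttp"` or `"td"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.xeno_trial <- function(x, type = c("ttp", "td"), ...) {
  type <- match.arg(type)
  if (type == "ttp") x$ttp_bands else x$td_bands
}

#' @rdname tidy.xeno_trial
#' @export
glance.xeno_trial <- function(x, ...) {
  bind_cols(x$median_ttp_summary,
            tibble(n_patients = x$n_patients,
                   n_replicates = x$n_replicates,
                   reference = x$rule$reference))
}

#' Tidy a Kaplan-Meier curve
#'
#' @param x An `xeno_km`.
#' @param ... Unused.
#' @return The underlying step-function tibble.
#' @export
tidy.xeno_km <- function(x, ...) as_tibble(x)
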