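#' Interspecies scaling configuration
#'
#' Settings of the allometric mouse-to-human translation:
#' `lambda0_human [1/month] = 30 * lambda0_mouse * (BW_human/BW_mouse)^(-alpha)`
#' and the same factor times `fu_ratio` for the potency. The factor 30
#' converts days to months; `alpha = 1/3` is the allometric exponent;
#' `fu_ratio` is the human/mouse unbound-fraction ratio (1 for drugs whose
#' plasma protein binding is comparable across the two species, the default
#' used for both gemcitabine and sorafenib).
#'
#' @param bw_human,bw_mouse Reference body weights [kg].
#' @param alpha Allometric exponent.
#' @param day_to_month Unit conversion factor (exactly 30).
#' @param fu_ratio Unbound-fraction ratio f_u,human / f_u,mouse.
#' @return An object of class `xeno_scaling`.
#' @export
scaling_config <- function(bw_human = 70, bw_mouse = 0.025, alpha = 1 / 3,
                           day_to_month = 30, fu_ratio = 1) {
  vals <- c(bw_human, bw_mouse, alpha, day_to_month, fu_ratio)
  if (any(!is.finite(vals)) || any(c(bw_human, bw_mouse, day_to_month,
                                     fu_ratio) <= 0)) {
    abort("all scaling settings must be positive and finite.")
  }
  structure(list(bw_human = bw_human, bw_mouse = bw_mouse, alpha = alpha,
                 day_to_month = day_to_month, fu_ratio = fu_ratio),
            class = "xeno_scaling")
}

allometric_factor <- function(cfg) {
  cfg$day_to_month * (cfg$bw_human / cfg$bw_mouse)^(-cfg$alpha)
}

#' Scale the exponential growth rate from mouse to human
#'
#' @param lambda0_mouse Mouse growth rate [1/day], > 0.
#' @param cfg An [scaling_config()].
#' @return Human growth rate [1/month].
#' @examples
#' scale_growth_rate(0.1) # ~0.2129 per month at the defaults
#' @export
scale_growth_rate <- function(lambda0_mouse, cfg = scaling_config()) {
  if (any(lambda0_mouse <= 0)) abort("`lambda0_mouse` must be > 0.")
  allometric_factor(cfg) * lambda0_mouse
}

#' Scale the drug potency from mouse to human
#'
#' Same allometric factor as [scale_growth_rate()], multiplied by the
#' unbound-fraction ratio. Concentrations stay in mg/L and potencies in
#' L/mg throughout the package, so the scaled unit is L/mg·month.
#'
#' @param k2_mouse Mouse potency [L/mg·day], >= 0.
#' @param cfg An [scaling_config()].
#' @return Human potency [L/mg·month].
#' @export
scale_potency <- function(k2_mouse, cfg = scaling_config()) {
  if (any(k2_mouse < 0)) abort("`k2_mouse` must be >= 0.")
  allometric_factor(cfg) * cfg$fu_ratio * k2_mouse
}

#' Translate a mouse population estimate to a human population
#'
#' Scales the typical values of the growth rate and potency with the
#' allometric rules and copies the mouse log-scale covariance submatrix of
#' (lambda0, k2) verbatim: inter-PDX variability is propagated, not
#' rescaled, so geometric CVs and the lambda0-k2 correlation are preserved
#' exactly.
#'
#' @param popest An `xeno_popest` from [fit_population()], or any list with
#'   elements `theta` (named, containing `lambda0` and `k2`) and `omega`
#'   (log-scale covariance with rows/columns named `lambda0`, `k2`).
#' @param cfg An [scaling_config()].
#' @return An object of class `xeno_humanpop` with fields `lambda0_pop`
#'   [1/month], `k2_pop` [L/mg·month] and `omega` (2x2 log-scale
#'   covariance).
#' @export
build_human_distribution <- function(popest, cfg = scaling_config()) {
  theta <- popest$theta
  if (is.null(theta[["k2"]]) || is.na(theta[["k2"]])) {
    abort("population estimate carries no potency (control-only population?).")
  }
  om <- popest$omega[c("lambda0", "k2"), c("lambda0", "k2")]
  if (any(is.na(om))) abort("population omega lacks the (lambda0, k2) submatrix.")
  structure(
    list(lambda0_pop = scale_growth_rate(theta[["lambda0"]], cfg),
         k2_pop = scale_potency(theta[["k2"]], cfg),
         omega = om, scaling = cfg),
    class = "xeno_humanpop"
  )
}

#' @exportS3Method base::print
print.xeno_humanpop <- function(x, ...) {
  cv <- sqrt(exp(diag(x$omega)) - 1)
  rho <- if (all(diag(x$omega) > 0)) {
    x$omega[1, 2] / sqrt(prod(diag(x$omega)))
  } else 0
  cat("<xeno_humanpop>\n")
  cat(sprintf("  lambda0 = %.4g /month (geometric CV %.1f%%)\n",
              x$lambda0_pop, 100 * cv[1]))
  cat(sprintf("  k2      = %.4g L/mg·month (geometric CV %.1f%%)\n",
              x$k2_pop, 100 * cv[2]))
  cat(sprintf("  corr(log lambda0, log k2) = %.3f\n", rho))
  invisible(x)
}

#' Read / write human population JSON
#'
#' Serialises an `xeno_humanpop` (or population estimate) so scaled
#' distributions can be exchanged between pipeline stages.
#'
#' @param x An `xeno_humanpop`.
#' @param path JSON path.
#' @return `read_humanpop_json()` returns an `xeno_humanpop`.
#' @export
write_humanpop_json <- function(x, path) {
  jsonlite::write_json(
    list(lambda0_pop = x$lambda0_pop, k2_pop = x$k2_pop,
         omega = as.vector(x$omega)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_humanpop_json
#' @export
read_humanpop_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  om <- matrix(j$omega, 2, 2,
               dimnames = list(c("lambda0", "k2"), c("lambda0", "k2")))
  structure(list(lambda0_pop = j$lambda0_pop, k2_pop = j$k2_pop,
                 omega = om, scaling = scaling_config()),
            class = "xeno_humanpop")
}
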