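#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_ribbon geom_line
#'   labs facet_wrap scale_y_continuous theme_bw
#' @export
ggplot2::autoplot

#' Plot virtual-trial TTP bands (KM-VPC)
#'
#' Median and 90 percent prediction interval of the time-to-progression
#' curve across Monte Carlo replicates; optionally overlays observed
#' clinical curves supplied as step functions.
#'
#' @param object An `xeno_trial`.
#' @param observed Optional named list of `xeno_km` curves to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xeno_trial <- function(object, observed = NULL, ...) {
  b <- object$ttp_bands
  p <- ggplot(b, aes(x = .data$time)) +
    geom_ribbon(aes(ymin = .data$p05, ymax = .data$p95),
                fill = "grey70", alpha = 0.6) +
    geom_line(aes(y = .data$p50), linewidth = 0.8) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Time [months]", y = "TTP survival",
         title = sprintf("Virtual trials: %d x %d patients (%s reference)",
                         object$n_replicates, object$n_patients,
                         object$rule$reference)) +
    theme_bw()
  if (!is.null(observed)) {
    obs <- bind_rows(lapply(names(observed), function(nm) {
      mutate(as_tibble(observed[[nm]]), study = nm)
    }))
    p <- p + geom_step(data = obs,
                       aes(y = .data$survival, colour = .data$study))
  }
  p
}

#' Plot tumor-diameter trajectory bands
#'
#' For each within-cohort percentile (5th, median, 95th across patients),
#' the across-replicate median and 90 percent prediction interval of the
#' tumor diameter over time.
#'
#' @param trial An `xeno_trial`.
#' @return A ggplot.
#' @export
plot_td_bands <- function(trial) {
  ggplot(trial$td_bands, aes(x = .data$time)) +
    geom_ribbon(aes(ymin = .data$p05, ymax = .data$p95),
                fill = "grey70", alpha = 0.6) +
    geom_line(aes(y = .data$p50)) +
    facet_wrap(~stat, scales = "free_y") +
    labs(x = "Time [months]", y = "Tumor diameter [cm]") +
    theme_bw()
}

#' Plot a synthetic PDX panel
#'
#' Arm-mean tumor burdens per study, control vs treated.
#'
#' @param object An `xeno_panel`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xeno_panel <- function(object, ...) {
  ggplot(object$panel,
         aes(x = .data$time_day, y = .data$tumor_cm3, colour = .data$arm)) +
    geom_line() +
    facet_wrap(~study_id, scales = "free_y") +
    labs(x = "Time [days]", y = "Tumor burden [cm3]") +
    theme_bw()
}

#' Plot a Kaplan-Meier curve
#'
#' @param object An `xeno_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xeno_km <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$time, y = .data$survival)) +
    geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Time", y = "Survival") +
    theme_bw()
}
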