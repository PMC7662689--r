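#' Plot a ROC curve
#'
#' @param object An `lcenet_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lcenet_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::coord_equal()
}

#' Plot Kaplan-Meier curves for the two expression strata
#'
#' @param object An `lcenet_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lcenet_km <- function(object, ...) {
  d <- tidy(object)
  d0 <- bind_rows(
    tibble(stratum = unique(d$stratum), time = 0, n_risk = NA_integer_,
           n_event = NA_integer_, survival = 1),
    d
  )
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "Time (days)", y = "Survival probability", colour = "Expression",
      title = sprintf("Kaplan-Meier, log-rank p = %.3g", object$p)
    )
}

#' Plot a degree distribution with its power-law fit
#'
#' @param object An `lcenet_powerlaw` from [power_law_fit()] or
#'   [topology_report()].
#' @param ... Unused.
#' @return A ggplot on log10-log10 axes.
#' @export
autoplot.lcenet_powerlaw <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Frequency",
                  title = "Node degree distribution")
  if (!is.na(object$slope)) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  linetype = "dashed") +
      ggplot2::labs(subtitle = sprintf("slope = %.2f, R² = %.3f",
                                       object$slope, object$r_squared))
  }
  p
}

#' NSM distribution of selected biomarkers versus all lncRNAs
#'
#' Mirrors the biomarker-versus-background comparison used to justify
#' NSM-based selection: pair-level NSM values of the selected lncRNAs
#' against the pooled values of the whole network.
#'
#' @param profiles NSM profiles from [compute_nsm_profiles()].
#' @param biomarkers Character vector of selected lncRNA ids.
#' @return A ggplot.
#' @export
plot_nsm_distribution <- function(profiles, biomarkers) {
  long <- profiles %>%
    select("lncrna_id", "nsm_values") %>%
    tidyr::unnest("nsm_values") %>%
    mutate(group = if_else(.data$lncrna_id %in% biomarkers,
                           "biomarker", "all lncRNAs"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$nsm_values)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "Pair-level NSM")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
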