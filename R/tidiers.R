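#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-record table of a result,
#' `glance()` a one-row summary.
#'
#' @param x A fitted lcenet object.
#' @param ... Unused.
#' @return A tibble.
#' @name lcenet-tidiers
NULL

#' @rdname lcenet-tidiers
#' @export
tidy.lcenet_global <- function(x, ...) x$pairs

#' @rdname lcenet-tidiers
#' @export
glance.lcenet_global <- function(x, ...) {
  tibble(
    n_tested_pairs = nrow(x$pairs),
    n_significant_pairs = sum(x$pairs$significant),
    n_triplets = nrow(x$triplets),
    alpha = x$alpha,
    n_mirna_universe = x$n_mirna_universe
  )
}

#' @rdname lcenet-tidiers
#' @export
tidy.lcenet_context <- function(x, ...) x$triplets

#' @rdname lcenet-tidiers
#' @export
glance.lcenet_context <- function(x, ...) {
  tibble(
    label = x$label,
    n_triplets = nrow(x$triplets),
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_lncrna = sum(x$nodes$class == "lncRNA"),
    n_mirna = sum(x$nodes$class == "miRNA"),
    n_mrna = sum(x$nodes$class == "mRNA")
  )
}

#' @rdname lcenet-tidiers
#' @export
tidy.lcenet_roc <- function(x, ...) x$curve

#' @rdname lcenet-tidiers
#' @export
glance.lcenet_roc <- function(x, ...) tibble(auc = x$auc)

#' @rdname lcenet-tidiers
#' @export
tidy.lcenet_km <- function(x, ...) {
  fit <- x$fit
  strata <- rep(sub("^stratum=", "", names(fit$strata)), fit$strata)
  tibble(stratum = strata, time = fit$time, n_risk = fit$n.risk,
         n_event = fit$n.event, survival = fit$surv)
}

#' @rdname lcenet-tidiers
#' @export
glance.lcenet_km <- function(x, ...) {
  tibble(chisq = x$chisq, p = x$p,
         n_high = sum(x$data$stratum == "high"),
         n_low = sum(x$data$stratum == "low"),
         n_events = sum(x$data$event))
}

#' @rdname lcenet-tidiers
#' @export
tidy.lcenet_powerlaw <- function(x, ...) x$points

#' @rdname lcenet-tidiers
#' @export
glance.lcenet_powerlaw <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n_points = nrow(x$points))
}
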