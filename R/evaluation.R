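#' ROC curve and AUC for a diagnostic score
#'
#' Evaluates how well an expression score separates tumour from normal
#' samples. The AUC is computed from the rank statistic (midranks for ties),
#' which equals the trapezoidal area under the ROC curve over all score
#' thresholds.
#'
#' @param scores Numeric score per sample (e.g. CPM of a biomarker).
#' @param labels Binary labels (logical, or 0/1) with `TRUE`/1 = tumour.
#'   Both classes must be present.
#' @return An `lcenet_roc`: list with `auc` and `curve`
#'   (tibble of `fpr`, `tpr` from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    abort("`scores` and `labels` must be equal-length and complete.")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) abort("Both classes must be present.")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(s, fromLast = TRUE) # one curve point per threshold
  curve <- tibble(
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
  structure(list(auc = auc, curve = curve), class = "lcenet_roc")
}

#' @export
print.lcenet_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d curve points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' Kaplan-Meier curves with a log-rank test after expression stratification
#'
#' Splits patients into high- and low-expression strata by expression
#' percentile (the default median split assigns the top 50% to `high`;
#' asymmetric splits, e.g. upper versus lower thirds, are obtained by
#' shrinking `lower`/`upper`, which excludes the middle), fits Kaplan-Meier
#' curves per
#' stratum with [survival::survfit()], and tests the difference with the
#' two-group log-rank test ([survival::survdiff()]).
#'
#' @param records Tibble with columns `time` (days), `event` (logical or
#'   0/1; `FALSE` = censored) and `expression`.
#' @param lower,upper Fractions defining the low and high strata. Defaults
#'   `0.5`/`0.5` (median split, no excluded middle).
#' @return An `lcenet_km`: list with `data` (records plus `stratum`), `fit`
#'   (a `survfit` object), `chisq` and `p` (`NA` when no events or a single
#'   stratum remain).
#' @export
km_logrank <- function(records, lower = 0.5, upper = 0.5) {
  records <- as_tibble(records)
  if (lower + upper > 1 + 1e-9) abort("`lower` + `upper` must be <= 1.")
  q_lo <- quantile(records$expression, lower, names = FALSE)
  q_hi <- quantile(records$expression, 1 - upper, names = FALSE)
  stratum <- dplyr::case_when(
    records$expression > q_hi ~ "high",
    records$expression <= q_lo ~ "low",
    TRUE ~ NA_character_
  )
  data <- records %>%
    mutate(stratum = stratum, event = as.integer(.data$event)) %>%
    filter(!is.na(.data$stratum))
  if (min(table(data$stratum)) < 2L || length(unique(data$stratum)) < 2L) {
    abort("Need at least 2 records in each stratum after the split.")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = data)
  chisq <- NA_real_; p <- NA_real_
  if (sum(data$event) > 0) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                             data = data)
    chisq <- sd$chisq
    p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(data = data, fit = fit, chisq = chisq, p = p),
            class = "lcenet_km")
}

#' @export
print.lcenet_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier (%d high / %d low): log-rank chisq = %.3f, p = %.4g\n",
              sum(x$data$stratum == "high"), sum(x$data$stratum == "low"),
              x$chisq, x$p))
  invisible(x)
}

#' Pearson correlation of two expression vectors
#'
#' Correlation is computed on untransformed expression values (log scaling
#' is a display concern only), with the two-sided p-value from the
#' t transform.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with `r`, `p`, `n` and `defined`; a zero-variance input
#'   yields `defined = FALSE` with `r`/`p` `NA` rather than an error.
#' @export
correlate_pair <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must be equal-length with n >= 3.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Over-representation analysis of a query gene set
#'
#' One-sided hypergeometric test of the overlap between a query set (e.g.
#' differentially expressed mRNAs) and each annotated gene set, sharing the
#' same hypergeometric core as the ceRNA competition test, with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param query Character vector of query gene ids (subset of `universe`).
#' @param universe Character vector: the gene background.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]);
#'   each set is intersected with the universe before testing.
#' @param alpha Significance threshold on `adj_p` (strict `<`). Default 0.05.
#' @param top_k Number of top sets flagged for reporting. Default 5.
#' @return Tibble with `set_name`, `overlap`, `set_size`, `universe_size`,
#'   `query_size`, `p_value`, `adj_p`, `significant`, `top`, ordered by
#'   `adj_p`.
#' @export
gene_set_ora <- function(query, universe, sets, alpha = 0.05, top_k = 5) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("`universe` must be non-empty.")
  query <- unique(query)
  if (!all(query %in% universe)) abort("`query` must be a subset of `universe`.")
  res <- purrr::imap_dfr(sets, function(members, name) {
    members <- intersect(unique(members), universe)
    k <- length(intersect(query, members))
    tibble(
      set_name = name,
      overlap = k,
      set_size = length(members),
      universe_size = length(universe),
      query_size = length(query),
      p_value = hypergeom_tail(length(universe), length(members),
                               length(query), k)
    )
  })
  res %>%
    mutate(adj_p = bh_adjust(.data$p_value),
           significant = .data$adj_p < alpha) %>%
    arrange(.data$adj_p, .data$p_value, .data$set_name) %>%
    mutate(top = row_number() <= top_k)
}
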