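#' NSM profiles: shared-miRNA competition strength per lncRNA
#'
#' The NSM (number of shared miRNAs) of a competing lncRNA-mRNA pair is the
#' count of miRNAs the two transcripts share within the context network; it
#' measures the lncRNA's ability to competitively bind miRNAs. For each
#' lncRNA the profile collects the NSM values of all its competing pairs and
#' tests, with a one-sided Wilcoxon rank-sum test (alternative: greater),
#' whether they are higher than the pooled pair-level NSM values of the whole
#' network (the background includes the focal lncRNA's own pairs by default,
#' matching a comparison against "all lncRNAs").
#'
#' @param net An `lcenet_context`.
#' @param include_self Keep the focal lncRNA's own pairs in the background
#'   pool (default `TRUE`).
#' @return Tibble with `lncrna_id`, `n_pairs`, `nsm_values` (list column),
#'   `mean_nsm`, `test_p`, and `degenerate` (`TRUE` when the network holds a
#'   single lncRNA, so the comparison is against its own values only).
#' @export
compute_nsm_profiles <- function(net, include_self = TRUE) {
  pairs <- context_pairs(net)
  if (nrow(pairs) == 0L) abort("Network has no competing pairs.")
  pooled <- pairs$x
  degenerate <- dplyr::n_distinct(pairs$lncrna_id) == 1L
  if (degenerate) {
    inform("Single lncRNA in network; NSM test is a degenerate self-comparison.")
  }
  pairs %>%
    group_by(.data$lncrna_id) %>%
    summarise(
      n_pairs = n(),
      nsm_values = list(.data$x),
      mean_nsm = mean(.data$x),
      .groups = "drop"
    ) %>%
    mutate(
      test_p = purrr::map_dbl(.data$nsm_values, function(v) {
        bg <- if (include_self) pooled else setdiff_values(pooled, v)
        ranksum_greater(v, bg)
      }),
      degenerate = degenerate
    )
}

# remove one occurrence of each element of v from pooled
setdiff_values <- function(pooled, v) {
  for (value in v) pooled <- pooled[-match(value, pooled)]
  pooled
}

ranksum_greater <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  if (all(c(x, y) == c(x, y)[1])) return(1)
  suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  )
}

#' Select lncRNA biomarkers by NSM significance
#'
#' @param profiles NSM profiles from [compute_nsm_profiles()].
#' @param alpha Significance level (strict `<`). Default 0.05.
#' @return Character vector of selected lncRNA ids.
#' @export
select_lncrna_biomarkers <- function(profiles, alpha = 0.05) {
  sort(profiles$lncrna_id[!is.na(profiles$test_p) & profiles$test_p < alpha])
}

#' NSR profiles: single-line regulation per miRNA
#'
#' A target (lncRNA or mRNA) is single-line regulated when exactly one miRNA
#' edge is incident to it in the context network; such sites are vulnerable
#' control points. The NSR of a miRNA is the number of its single-line
#' targets. `passes_mean` flags miRNAs with NSR strictly above the network
#' average; `test_p` is a one-sided rank-sum test of the miRNA's per-target
#' single-line indicators against the pooled indicators of all miRNAs.
#'
#' @param net An `lcenet_context`.
#' @return Tibble with `mirna_id`, `n_targets`, `nsr`, `passes_mean`,
#'   `test_p`.
#' @export
compute_nsr_profiles <- function(net) {
  edges <- distinct(net$edges, .data$mirna_id, .data$target_id)
  if (nrow(edges) == 0L) abort("Network has no edges.")
  regulators <- count(edges, .data$target_id, name = "n_regulators")
  edges <- edges %>%
    left_join(regulators, by = "target_id") %>%
    mutate(single_line = .data$n_regulators == 1L)
  pooled <- edges$single_line
  profiles <- edges %>%
    group_by(.data$mirna_id) %>%
    summarise(
      n_targets = n(),
      nsr = sum(.data$single_line),
      indicators = list(.data$single_line),
      .groups = "drop"
    )
  mean_nsr <- mean(profiles$nsr)
  profiles %>%
    mutate(
      passes_mean = .data$nsr > mean_nsr,
      test_p = purrr::map_dbl(.data$indicators, function(v) {
        ranksum_greater(as.numeric(v), as.numeric(pooled))
      })
    ) %>%
    select(-"indicators")
}

#' Select miRNA biomarkers by NSR
#'
#' Keeps miRNAs with `NSR > mean(NSR)` and rank-sum `P < alpha`; both gates
#' can be toggled.
#'
#' @param profiles NSR profiles from [compute_nsr_profiles()].
#' @param alpha Significance level (strict `<`). Default 0.05.
#' @param require_mean,require_test Apply the NSR-above-mean / significance
#'   gate (both default `TRUE`).
#' @return Character vector of selected miRNA ids.
#' @export
select_mirna_biomarkers <- function(profiles, alpha = 0.05,
                                    require_mean = TRUE,
                                    require_test = TRUE) {
  keep <- rep(TRUE, nrow(profiles))
  if (require_mean) keep <- keep & profiles$passes_mean
  if (require_test) {
    keep <- keep & !is.na(profiles$test_p) & profiles$test_p < alpha
  }
  sort(profiles$mirna_id[keep])
}

#' Screen key ceRNA triplets
#'
#' Keeps the context-network triplets in which (1) the lncRNA is a selected
#' lncRNA biomarker, (2) the miRNA is a selected miRNA biomarker, (3) the
#' mRNA is either listed as a tumour-associated gene (TAG) or
#' prognosis-associated (log-rank `p < 0.05`), and (4) the miRNA's expression
#' direction is opposite to both the lncRNA's and the mRNA's, consistent with
#' miRNA-mediated repression. Triplets with a missing DE direction for any
#' member are skipped with a message.
#'
#' @param net An `lcenet_context`.
#' @param lnc_biomarkers,mir_biomarkers Character vectors of biomarker ids.
#' @param de_records DE records (needs `feature_id`, `direction`) for the
#'   same contrast.
#' @param tag_list Character vector of TAG symbols.
#' @param prognosis Optional tibble (`feature_id`, `p_value`) of per-mRNA
#'   log-rank results; `p < 0.05` marks prognosis-associated genes.
#' @return Tibble of retained triplets with the rule flags
#'   (`lnc_direction`, `mir_direction`, `mrna_direction`, `is_tag`,
#'   `prognosis_associated`).
#' @export
screen_key_triplets <- function(net, lnc_biomarkers, mir_biomarkers,
                                de_records, tag_list = character(),
                                prognosis = NULL) {
  dirs <- distinct(as_tibble(de_records), .data$feature_id, .data$direction)
  lookup <- setNames(dirs$direction, dirs$feature_id)
  trip <- net$triplets %>%
    mutate(
      lnc_direction = unname(lookup[.data$lncrna_id]),
      mir_direction = unname(lookup[.data$mirna_id]),
      mrna_direction = unname(lookup[.data$mrna_id])
    )
  missing_dir <- !complete.cases(trip[, c("lnc_direction", "mir_direction",
                                          "mrna_direction")])
  if (any(missing_dir)) {
    inform(sprintf("%d triplet(s) skipped: missing DE direction.",
                   sum(missing_dir)))
  }
  prog_ids <- character()
  if (!is.null(prognosis)) {
    prognosis <- as_tibble(prognosis)
    prog_ids <- prognosis$feature_id[!is.na(prognosis$p_value) &
                                       prognosis$p_value < 0.05]
  }
  trip %>%
    filter(!missing_dir) %>%
    mutate(
      is_tag = .data$mrna_id %in% tag_list,
      prognosis_associated = .data$mrna_id %in% prog_ids
    ) %>%
    filter(
      .data$lncrna_id %in% lnc_biomarkers,
      .data$mirna_id %in% mir_biomarkers,
      .data$is_tag | .data$prognosis_associated,
      .data$mir_direction != .data$lnc_direction,
      .data$mir_direction != .data$mrna_direction
    ) %>%
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
}
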