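#' Assemble an expression study
#'
#' Bundles a count matrix with feature classes and sample annotations into a
#' single object used by the filtering, differential-expression and
#' correlation stages. Samples are annotated with a tissue label (`normal`,
#' `M0` tumours without distant metastasis, `M1` tumours with distant
#' metastasis) and an anatomical site (`colon`, `rectal`).
#'
#' @param counts Non-negative integer matrix, features x samples, with row
#'   and column names.
#' @param features Data frame with columns `feature_id` and `feature_class`
#'   (`lncRNA`, `miRNA` or `mRNA`), one row per count row.
#' @param samples Data frame with columns `sample_id`, `tissue`
#'   (`normal`/`M0`/`M1`) and `site` (`colon`/`rectal`), one row per count
#'   column.
#' @param library_sizes Optional per-sample totals; defaults to column sums.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(counts, features, samples, library_sizes = NULL) {
  counts <- as.matrix(counts)
  features <- as_tibble(features)
  samples <- as_tibble(samples)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (nrow(features) != nrow(counts) ||
      !identical(features$feature_id, rownames(counts))) {
    abort("`features$feature_id` must match rownames(counts).")
  }
  if (nrow(samples) != ncol(counts) ||
      !identical(samples$sample_id, colnames(counts))) {
    abort("`samples$sample_id` must match colnames(counts).")
  }
  bad <- !samples$tissue %in% c("normal", "M0", "M1") |
    !samples$site %in% c("colon", "rectal")
  if (any(bad)) abort("Every sample needs tissue in {normal, M0, M1} and site in {colon, rectal}.")
  library_sizes <- library_sizes %||% colSums(counts)
  structure(
    list(counts = counts, features = features, samples = samples,
         library_sizes = setNames(as.numeric(library_sizes),
                                  samples$sample_id)),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(count(x$features, .data$feature_class))
  print(count(x$samples, .data$site, .data$tissue))
  invisible(x)
}

#' Counts per million
#'
#' @param counts Count matrix (features x samples) or an `expression_study`.
#' @param library_sizes Per-sample totals; defaults to column sums. A zero
#'   library size is an error naming the sample.
#' @return Matrix of CPM values, same shape as `counts`.
#' @export
cpm <- function(counts, library_sizes = NULL) {
  if (inherits(counts, "expression_study")) {
    library_sizes <- library_sizes %||% counts$library_sizes
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  library_sizes <- library_sizes %||% colSums(counts)
  zero <- library_sizes <= 0
  if (any(zero)) {
    abort(sprintf("Zero library size for sample(s): %s",
                  paste(colnames(counts)[zero], collapse = ", ")))
  }
  sweep(counts, 2L, library_sizes, "/") * 1e6
}

#' Filter sufficiently expressed features
#'
#' Keeps features with CPM above `cpm_threshold` in at least
#' `ceiling(sample_fraction * n)` of the selected samples (the combined
#' sample set of a contrast, by default all samples).
#'
#' @param study An `expression_study`.
#' @param sample_ids Samples over which the rule is evaluated (default: all).
#' @param cpm_threshold CPM cut-off (strict `>`). Default 1.
#' @param sample_fraction Fraction of samples required. Default 0.8.
#' @return The filtered `expression_study`, with a `filter_report` attribute
#'   listing the number of features dropped.
#' @export
filter_expressed <- function(study, sample_ids = NULL, cpm_threshold = 1,
                             sample_fraction = 0.8) {
  sample_ids <- sample_ids %||% study$samples$sample_id
  mat <- cpm(study)[, sample_ids, drop = FALSE]
  need <- ceiling(sample_fraction * length(sample_ids))
  keep <- rowSums(mat > cpm_threshold) >= need
  out <- expression_study(
    study$counts[keep, , drop = FALSE],
    study$features[keep, , drop = FALSE],
    study$samples,
    study$library_sizes
  )
  attr(out, "filter_report") <- list(
    n_in = length(keep), n_kept = sum(keep), n_dropped = sum(!keep),
    dropped = study$features$feature_id[!keep]
  )
  out
}

#' Define the four tumour-versus-normal contrasts
#'
#' Builds the contrast sample sets `colon_M0N`, `colon_M1N`, `rectal_M0N`,
#' `rectal_M1N`: each compares one tumour group (M0 or M1) of one site
#' against the normal samples of the same site.
#'
#' @param samples Sample annotation tibble (`sample_id`, `tissue`, `site`).
#' @return Named list of contrasts, each a list with `label`, `site`,
#'   `group` (tumour tissue label), `group_a` (tumour sample ids) and
#'   `group_b` (normal sample ids).
#' @export
de_contrasts <- function(samples) {
  samples <- as_tibble(samples)
  grid <- expand.grid(site = c("colon", "rectal"), group = c("M0", "M1"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    site <- grid$site[i]; group <- grid$group[i]
    list(
      label = sprintf("%s_%sN", site, group),
      site = site, group = group,
      group_a = samples$sample_id[samples$site == site & samples$tissue == group],
      group_b = samples$sample_id[samples$site == site & samples$tissue == "normal"]
    )
  })
  setNames(out, vapply(out, `[[`, "", "label"))
}

#' Differential expression for one contrast
#'
#' The default engine performs, per feature, a two-sided Wilcoxon rank-sum
#' test on CPM values between the tumour and normal groups, with
#' `log2FC = log2((mean CPM_a + 0.5) / (mean CPM_b + 0.5))` (pseudo-count 0.5
#' for stability) and Benjamini-Hochberg adjustment run separately within
#' each feature class, mirroring separate RNA-seq and miRNA-seq analyses.
#' Alternatively an externally computed DE table (e.g. from a count-model
#' package) can be ingested verbatim via `engine = "table"`.
#'
#' @param study A (typically filtered) `expression_study`.
#' @param contrast One element of [de_contrasts()].
#' @param engine `"ranksum"` (default) or `"table"`.
#' @param de_table For `engine = "table"`: data frame with columns
#'   `feature_id`, `log2_fold_change`, `fdr` (and optionally
#'   `feature_class`).
#' @return Tibble of DE records: `feature_id`, `feature_class`,
#'   `log2_fold_change`, `p_value`, `fdr`, `direction` (`"up"` iff strictly
#'   positive fold change, else `"down"`).
#' @export
differential_expression <- function(study, contrast,
                                    engine = c("ranksum", "table"),
                                    de_table = NULL) {
  engine <- match.arg(engine)
  if (engine == "table") {
    tab <- as_tibble(de_table)
    need <- c("feature_id", "log2_fold_change", "fdr")
    if (!all(need %in% names(tab))) {
      abort("External DE table needs feature_id, log2_fold_change, fdr.")
    }
    if (!"feature_class" %in% names(tab)) {
      tab <- left_join(tab, study$features, by = "feature_id")
    }
    if (!"p_value" %in% names(tab)) tab$p_value <- tab$fdr
    return(mutate(tab, direction = if_else(.data$log2_fold_change > 0,
                                           "up", "down")))
  }
  a <- contrast$group_a; b <- contrast$group_b
  if (length(a) < 2L || length(b) < 2L) {
    abort("Both contrast groups need at least 2 samples.")
  }
  mat <- cpm(study)
  ca <- mat[, a, drop = FALSE]
  cb <- mat[, b, drop = FALSE]
  pvals <- vapply(seq_len(nrow(mat)), function(i) {
    xa <- ca[i, ]; xb <- cb[i, ]
    if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) return(1)
    suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
  }, 1)
  lfc <- unname(log2((rowMeans(ca) + 0.5) / (rowMeans(cb) + 0.5)))
  out <- tibble(
    feature_id = rownames(mat),
    feature_class = study$features$feature_class,
    log2_fold_change = lfc,
    p_value = pvals
  ) %>%
    group_by(.data$feature_class) %>%
    mutate(fdr = bh_adjust(.data$p_value)) %>%
    ungroup() %>%
    mutate(direction = if_else(.data$log2_fold_change > 0, "up", "down"))
  out
}

#' Select differentially expressed features
#'
#' Applies the selection rule `|log2FC| >= lfc_min` (inclusive) and
#' `FDR < fdr_max` (strict).
#'
#' @param records DE records from [differential_expression()].
#' @param lfc_min Minimum absolute log2 fold change. Default 1.
#' @param fdr_max FDR threshold. Default 0.05.
#' @return The surviving subset of `records`.
#' @export
select_de <- function(records, lfc_min = 1, fdr_max = 0.05) {
  filter(records, abs(.data$log2_fold_change) >= lfc_min,
         .data$fdr < fdr_max)
}

#' Venn partition of DE sets across contrasts
#'
#' @param sets Named list of character vectors (one DE id set per contrast).
#' @return A list with `regions`, a tibble of all `2^k - 1` Venn region
#'   counts (`region` is the `+`-joined combination of contrast names), and
#'   `common`, the ids present in every set.
#' @export
overlap_de_sets <- function(sets) {
  if (length(sets) < 2L) abort("Need at least two DE sets.")
  ids <- sort(unique(unlist(sets)))
  member <- matrix(FALSE, nrow = length(ids), ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  for (j in seq_along(sets)) member[, j] <- ids %in% sets[[j]]
  combos <- rev(expand.grid(rep(list(c(TRUE, FALSE)), length(sets))))[
    , rev(seq_along(sets)), drop = FALSE]
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  regions <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    pattern <- as.logical(combos[i, ])
    inside <- rowSums(member == matrix(pattern, nrow = length(ids),
                                       ncol = length(sets),
                                       byrow = TRUE)) == length(sets)
    tibble(region = paste(names(sets)[pattern], collapse = "+"),
           count = sum(inside))
  })
  list(regions = regions,
       common = ids[rowSums(member) == length(sets)])
}
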