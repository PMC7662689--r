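#' Build the global lncRNA-associated ceRNA network
#'
#' For every lncRNA-mRNA pair sharing at least one miRNA regulator in the
#' catalog, tests whether the number of shared miRNAs `x` is larger than
#' expected by chance with [hypergeom_tail()] (population `N_T`, successes
#' `N_lnc`, draws `N_mRNA`), adjusts the p-values with Benjamini-Hochberg
#' jointly over all tested pairs, and keeps pairs with `adj_p < alpha`.
#' ceRNA triplets (lncRNA, miRNA, mRNA) are then enumerated from the kept
#' pairs: one triplet per shared miRNA, so the triplet count equals the sum of
#' `x` over significant pairs.
#'
#' Pair testing streams over lncRNAs, so candidate pairs with their shared
#' miRNA sets are never materialised all at once; triplets are enumerated for
#' significant pairs only.
#'
#' @param catalog An `lcenet_catalog` from [harmonize_and_merge()] (or any
#'   tibble with `mirna_id`, `target_id`, `target_class`).
#' @param alpha Significance threshold on the BH-adjusted p-value (strict
#'   `<`). Default 0.01.
#' @param n_mirna_universe Optional override of the catalog's background
#'   `N_T`.
#' @return An object of class `lcenet_global`: a list with `pairs` (all
#'   tested pairs: `lncrna_id`, `mrna_id`, `x`, `n_lnc`, `n_mrna`, `p_value`,
#'   `adj_p`, `significant`), `triplets` (for significant pairs), `alpha` and
#'   `n_mirna_universe`. Pairs with `x = 0` are not part of the BH family.
#' @export
build_global_lcenet <- function(catalog, alpha = 0.01,
                                n_mirna_universe = NULL) {
  stopifnot_scalar_number(alpha, "alpha")
  n_t <- as.integer(n_mirna_universe %||% mirna_universe_size(catalog))

  lnc_edges <- filter(as_tibble(catalog), .data$target_class == "lncRNA")
  mrna_edges <- filter(as_tibble(catalog), .data$target_class == "mRNA")
  if (nrow(lnc_edges) == 0L || nrow(mrna_edges) == 0L) {
    abort("Catalog must contain both lncRNA and mRNA targets.")
  }

  mrna_degree <- count(mrna_edges, .data$target_id, name = "n_mrna")
  lnc_sets <- split(lnc_edges$mirna_id, lnc_edges$target_id)
  mrna_by_mirna <- split(mrna_edges$target_id, mrna_edges$mirna_id)

  # stream over lncRNAs: count shared miRNAs against every co-targeted mRNA
  pair_chunks <- lapply(names(lnc_sets), function(lnc) {
    mirnas <- lnc_sets[[lnc]]
    hits <- unlist(mrna_by_mirna[mirnas], use.names = FALSE)
    if (length(hits) == 0L) return(NULL)
    tab <- table(hits)
    tibble(lncrna_id = lnc, mrna_id = names(tab),
           x = as.integer(tab), n_lnc = length(mirnas))
  })
  pairs <- bind_rows(pair_chunks)

  if (nrow(pairs) == 0L) {
    warn("No lncRNA-mRNA pair shares a miRNA; the global network is empty.")
    empty <- tibble(lncrna_id = character(), mrna_id = character(),
                    x = integer(), n_lnc = integer(), n_mrna = integer(),
                    p_value = double(), adj_p = double(),
                    significant = logical())
    return(new_lcenet_global(empty, empty_triplets(), alpha, n_t))
  }

  pairs <- pairs %>%
    inner_join(mrna_degree, by = c(mrna_id = "target_id")) %>%
    mutate(
      p_value = hypergeom_tail(n_t, .data$n_lnc, .data$n_mrna, .data$x),
      adj_p = bh_adjust(.data$p_value),
      significant = .data$adj_p < alpha
    ) %>%
    arrange(.data$adj_p, .data$lncrna_id, .data$mrna_id)

  sig <- filter(pairs, .data$significant)
  triplets <- if (nrow(sig) == 0L) {
    empty_triplets()
  } else {
    lnc_long <- filter(lnc_edges, .data$target_id %in% sig$lncrna_id)
    mrna_long <- filter(mrna_edges, .data$target_id %in% sig$mrna_id)
    sig %>%
      select("lncrna_id", "mrna_id") %>%
      inner_join(rename(lnc_long, lncrna_id = "target_id"),
                 by = "lncrna_id", relationship = "many-to-many") %>%
      semi_join(rename(mrna_long, mrna_id = "target_id"),
                by = c("mrna_id", "mirna_id")) %>%
      select("lncrna_id", "mirna_id", "mrna_id") %>%
      arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  }
  new_lcenet_global(pairs, triplets, alpha, n_t)
}

empty_triplets <- function() {
  tibble(lncrna_id = character(), mirna_id = character(),
         mrna_id = character())
}

new_lcenet_global <- function(pairs, triplets, alpha, n_t) {
  structure(
    list(pairs = pairs, triplets = triplets, alpha = alpha,
         n_mirna_universe = n_t),
    class = "lcenet_global"
  )
}

#' Significant competing pairs of a global network
#' @param x An `lcenet_global`.
#' @return Tibble of pairs with `adj_p < alpha`.
#' @export
significant_pairs <- function(x) filter(x$pairs, .data$significant)

#' @export
print.lcenet_global <- function(x, ...) {
  cat(sprintf(
    "Global ceRNA network: %d tested pairs, %d significant (adj_p < %g), %d triplets, N_T = %d\n",
    nrow(x$pairs), sum(x$pairs$significant), x$alpha, nrow(x$triplets),
    x$n_mirna_universe
  ))
  invisible(x)
}
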