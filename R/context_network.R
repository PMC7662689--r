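#' Map differentially expressed RNAs into the global network
#'
#' First step of context-specific network reconstruction: keep the global
#' triplets whose lncRNA, miRNA and mRNA are all differentially expressed in
#' the contrast of interest.
#'
#' @param global_net An `lcenet_global` from [build_global_lcenet()].
#' @param de_lncrna,de_mirna,de_mrna Character vectors of DE feature ids per
#'   class.
#' @return Tibble of candidate triplets (`lncrna_id`, `mirna_id`,
#'   `mrna_id`). Empty (with a warning) when any DE class is empty.
#' @export
extract_context_candidates <- function(global_net, de_lncrna, de_mirna,
                                       de_mrna) {
  if (length(de_lncrna) == 0L || length(de_mirna) == 0L ||
      length(de_mrna) == 0L) {
    warn("At least one DE class is empty; no candidate triplets.")
    return(empty_triplets())
  }
  filter(global_net$triplets,
         .data$lncrna_id %in% de_lncrna,
         .data$mirna_id %in% de_mirna,
         .data$mrna_id %in% de_mrna)
}

#' Positive co-expression filter and context network assembly
#'
#' Second step of context-specific network reconstruction: for every distinct
#' lncRNA-mRNA pair among the candidate triplets, computes the Pearson
#' correlation of their expression over the contrast's tumour samples and
#' keeps pairs with `R > r_min` and two-sided `P < p_max` (the ceRNA
#' hypothesis predicts positively correlated competing partners). Triplets
#' whose pair fails are removed; the survivors induce the tripartite edge
#' list (lncRNA-miRNA and miRNA-mRNA edges).
#'
#' @param candidates Candidate triplets from [extract_context_candidates()].
#' @param expr Numeric expression matrix (features x samples) restricted to
#'   the contrast's tumour samples, e.g. `cpm(study)[, tumour_ids]`. At least
#'   3 samples are required.
#' @param r_min Correlation threshold (strict `>`). Default 0.5.
#' @param p_max p-value threshold (strict `<`). Default 0.05.
#' @param label Contrast label stored on the result.
#' @return An object of class `lcenet_context`: list with `label`,
#'   `triplets`, `edges` (tripartite edge list), `nodes` (id, class, degree)
#'   and `pair_cor` (per-pair `r`, `p_value`, `kept`). Pairs with a
#'   zero-variance vector are skipped (correlation undefined) and dropped.
#' @export
pearson_filter <- function(candidates, expr, r_min = 0.5, p_max = 0.05,
                           label = "context") {
  if (ncol(expr) < 3L) abort("Need >= 3 tumour samples for correlation.")
  pairs <- distinct(candidates, .data$lncrna_id, .data$mrna_id)
  pair_cor <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    lnc <- pairs$lncrna_id[i]; mrna <- pairs$mrna_id[i]
    x <- expr[lnc, ]; y <- expr[mrna, ]
    res <- correlate_pair(x, y)
    tibble(lncrna_id = lnc, mrna_id = mrna, r = res$r, p_value = res$p,
           defined = res$defined)
  })
  if (nrow(pair_cor) == 0L) {
    pair_cor <- tibble(lncrna_id = character(), mrna_id = character(),
                       r = double(), p_value = double(), defined = logical())
  }
  n_undef <- sum(!pair_cor$defined)
  if (n_undef > 0L) {
    inform(sprintf("%d pair(s) had zero-variance expression; skipped.", n_undef))
  }
  pair_cor <- mutate(pair_cor,
                     kept = .data$defined & .data$r > r_min &
                       .data$p_value < p_max)
  kept_triplets <- semi_join(candidates, filter(pair_cor, .data$kept),
                             by = c("lncrna_id", "mrna_id"))
  new_lcenet_context(label, kept_triplets, pair_cor)
}

#' Build a context network directly from a triplet table
#'
#' Constructs an `lcenet_context` from an already-screened table of
#' lncRNA-miRNA-mRNA triplets (e.g. imported from another tool), deriving
#' the tripartite edge list and node degrees.
#'
#' @param triplets Data frame with columns `lncrna_id`, `mirna_id`,
#'   `mrna_id`.
#' @param label Contrast label.
#' @return An `lcenet_context`.
#' @export
context_network <- function(triplets, label = "context") {
  new_lcenet_context(label, triplets)
}

new_lcenet_context <- function(label, triplets, pair_cor = NULL) {
  triplets <- distinct(as_tibble(triplets))
  edges <- bind_rows(
    triplets %>% distinct(.data$mirna_id, .data$lncrna_id) %>%
      transmute_edge("lncrna_id", "lncRNA"),
    triplets %>% distinct(.data$mirna_id, .data$mrna_id) %>%
      transmute_edge("mrna_id", "mRNA")
  )
  nodes <- bind_rows(
    tibble(id = unique(triplets$lncrna_id), class = "lncRNA"),
    tibble(id = unique(triplets$mirna_id), class = "miRNA"),
    tibble(id = unique(triplets$mrna_id), class = "mRNA")
  )
  degree <- count(
    tibble(id = c(edges$mirna_id, edges$target_id)), .data$id,
    name = "degree"
  )
  nodes <- nodes %>%
    left_join(degree, by = "id") %>%
    mutate(degree = if_else(is.na(.data$degree), 0L, as.integer(.data$degree)))
  structure(
    list(label = label, triplets = triplets, edges = edges, nodes = nodes,
         pair_cor = pair_cor),
    class = "lcenet_context"
  )
}

transmute_edge <- function(df, target_col, class) {
  tibble(mirna_id = df$mirna_id, target_id = df[[target_col]],
         target_class = class)
}

#' In-network competing pairs with shared-miRNA counts
#'
#' Distinct lncRNA-mRNA pairs of a context network with `x`, the number of
#' shared miRNAs within the network (the pair-level NSM value).
#' @param net An `lcenet_context`.
#' @return Tibble `lncrna_id`, `mrna_id`, `x`.
#' @export
context_pairs <- function(net) {
  count(net$triplets, .data$lncrna_id, .data$mrna_id, name = "x")
}

#' @export
print.lcenet_context <- function(x, ...) {
  cat(sprintf("Context ceRNA network '%s': %d triplets, %d nodes, %d edges\n",
              x$label, nrow(x$triplets), nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Topology diagnostics of a context network
#'
#' Node degrees on the tripartite edge list, hub calling (top
#' `ceil(hub_fraction * n_nodes)` nodes by degree, ties broken
#' lexicographically by id after degree) and a power-law fit of the degree
#' distribution: least squares of `log10(frequency)` on `log10(degree)` over
#' distinct observed degrees, reporting the slope and R squared. Scale-free
#' networks show a close log-log linear fit.
#'
#' @param net An `lcenet_context`.
#' @param hub_fraction Fraction of nodes called hubs. Default 0.05.
#' @return A list with `nodes` (id, class, degree, is_hub) and `fit` (an
#'   `lcenet_powerlaw`: slope, intercept, r_squared, points; all `NA` when
#'   fewer than 3 distinct degrees are observed).
#' @export
topology_report <- function(net, hub_fraction = 0.05) {
  nodes <- arrange(net$nodes, desc(.data$degree), .data$id)
  if (nrow(nodes) == 0L) abort("Network is empty.")
  n_hub <- ceiling(hub_fraction * nrow(nodes))
  nodes <- mutate(nodes, is_hub = row_number() <= n_hub)
  fit <- power_law_fit(nodes$degree[nodes$degree > 0])
  list(nodes = nodes, fit = fit)
}

#' Log-log power-law fit of a degree distribution
#'
#' @param degrees Integer vector of node degrees (zeros ignored).
#' @return An `lcenet_powerlaw` list: `slope`, `intercept`, `r_squared`,
#'   `points` (tibble of degree, frequency). Undefined (`NA`) with fewer
#'   than 3 distinct positive degrees.
#' @export
power_law_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- count(tibble(degree = degrees), .data$degree, name = "frequency")
  out <- list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
              points = tab)
  if (nrow(tab) >= 3L) {
    # a perfect log-log line is legitimate here; silence lm's perfect-fit note
    fit <- suppressWarnings(lm(log10(frequency) ~ log10(degree), data = tab))
    out$slope <- unname(coef(fit)[2])
    out$intercept <- unname(coef(fit)[1])
    out$r_squared <- suppressWarnings(summary(fit)$r.squared)
  }
  structure(out, class = "lcenet_powerlaw")
}

#' Triplets shared by several context networks
#'
#' @param nets List of `lcenet_context` objects (>= 2).
#' @return Tibble of triplets present in every network.
#' @export
shared_interactions <- function(nets) {
  if (length(nets) < 2L) abort("Need at least two networks.")
  keys <- lapply(nets, function(n) {
    with(n$triplets, paste(lncrna_id, mirna_id, mrna_id, sep = "\r"))
  })
  common <- Reduce(intersect, keys)
  nets[[1]]$triplets %>%
    filter(paste(.data$lncrna_id, .data$mirna_id, .data$mrna_id,
                 sep = "\r") %in% common) %>%
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
}
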