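#' Run the full ceRNA biomarker pipeline
#'
#' Orchestrates every stage end to end: global network construction from the
#' interaction catalog, per-contrast CPM filtering and differential
#' expression, context-specific network reconstruction (DE mapping plus the
#' positive-correlation filter on tumour samples), NSM/NSR biomarker
#' screening, key-triplet screening against the TAG list, and evaluation
#' (ROC per biomarker; Kaplan-Meier log-rank per key mRNA when survival data
#' are supplied; over-representation of DE mRNAs when gene sets are
#' supplied). An empty stage (e.g. no DE features in a class) propagates as
#' empty downstream results, not as an error.
#'
#' @param catalog An `lcenet_catalog` (or a `synthetic_study`, in which case
#'   the remaining inputs are taken from it).
#' @param study An `expression_study`.
#' @param survival_data Optional tibble (`sample_id`, `site`, `time`,
#'   `event`).
#' @param tag_list Character vector of tumour-associated genes.
#' @param gene_sets Optional named list of gene sets for ORA.
#' @param alpha_pair BH threshold for competing pairs (default 0.01).
#' @param cpm_threshold,sample_fraction Expression-filter parameters
#'   (defaults 1, 0.8).
#' @param lfc_min,fdr_max DE selection thresholds (defaults 1, 0.05).
#' @param r_min,p_max Correlation-filter thresholds (defaults 0.5, 0.05).
#' @param hub_fraction Hub fraction (default 0.05).
#' @param alpha_biomarker NSM/NSR significance level (default 0.05).
#' @param split_lower,split_upper Survival stratification fractions
#'   (default median split).
#' @return An `lcenet_run`: list with `global`, `de` (per contrast),
#'   `contexts`, `topology`, `biomarkers`, `key_triplets`, `overlap`,
#'   `shared`, `evaluation` and `manifest` (tibble of per-stage record
#'   counts; wall time is kept in the `elapsed` attribute so manifests of
#'   identical runs compare equal).
#' @export
run_lcenet <- function(catalog, study = NULL, survival_data = NULL,
                       tag_list = character(), gene_sets = NULL,
                       alpha_pair = 0.01, cpm_threshold = 1,
                       sample_fraction = 0.8, lfc_min = 1, fdr_max = 0.05,
                       r_min = 0.5, p_max = 0.05, hub_fraction = 0.05,
                       alpha_biomarker = 0.05,
                       split_lower = 0.5, split_upper = 0.5) {
  t0 <- Sys.time()
  if (inherits(catalog, "synthetic_study")) {
    sim <- catalog
    catalog <- sim$catalog
    study <- study %||% sim$study
    survival_data <- survival_data %||% sim$survival
    if (length(tag_list) == 0L) tag_list <- sim$tag_list
  }
  stopifnot(inherits(study, "expression_study"))

  global <- build_global_lcenet(catalog, alpha = alpha_pair)
  contrasts <- de_contrasts(study$samples)
  expr_all <- cpm(study)

  manifest <- list(
    catalog_edges = nrow(catalog),
    global_tested_pairs = nrow(global$pairs),
    global_significant_pairs = sum(global$pairs$significant),
    global_triplets = nrow(global$triplets)
  )

  de <- list(); contexts <- list(); topology <- list()
  biomarkers <- list(); key_triplets <- list()
  roc_rows <- list()

  for (ct in contrasts) {
    lab <- ct$label
    ids <- c(ct$group_a, ct$group_b)
    filtered <- filter_expressed(study, sample_ids = ids,
                                 cpm_threshold = cpm_threshold,
                                 sample_fraction = sample_fraction)
    records <- differential_expression(filtered, ct)
    selected <- select_de(records, lfc_min = lfc_min, fdr_max = fdr_max)
    de[[lab]] <- list(records = records, selected = selected)
    sel_by_class <- split(selected$feature_id, selected$feature_class)
    de_lnc <- sel_by_class[["lncRNA"]] %||% character()
    de_mir <- sel_by_class[["miRNA"]] %||% character()
    de_mrna <- sel_by_class[["mRNA"]] %||% character()
    manifest[[paste0(lab, "_de_lncrna")]] <- length(de_lnc)
    manifest[[paste0(lab, "_de_mirna")]] <- length(de_mir)
    manifest[[paste0(lab, "_de_mrna")]] <- length(de_mrna)

    candidates <- suppressWarnings(
      extract_context_candidates(global, de_lnc, de_mir, de_mrna)
    )
    manifest[[paste0(lab, "_candidates")]] <- nrow(candidates)
    net <- if (nrow(candidates) > 0L) {
      pearson_filter(candidates, expr_all[, ct$group_a, drop = FALSE],
                     r_min = r_min, p_max = p_max, label = lab)
    } else {
      new_lcenet_context(lab, empty_triplets())
    }
    contexts[[lab]] <- net
    manifest[[paste0(lab, "_triplets")]] <- nrow(net$triplets)
    manifest[[paste0(lab, "_nodes")]] <- nrow(net$nodes)

    if (nrow(net$triplets) > 0L) {
      topology[[lab]] <- topology_report(net, hub_fraction = hub_fraction)
      nsm <- compute_nsm_profiles(net)
      nsr <- compute_nsr_profiles(net)
      lnc_bio <- select_lncrna_biomarkers(nsm, alpha = alpha_biomarker)
      mir_bio <- select_mirna_biomarkers(nsr, alpha = alpha_biomarker)
      keys <- screen_key_triplets(net, lnc_bio, mir_bio, records,
                                  tag_list = tag_list)
    } else {
      topology[[lab]] <- NULL
      nsm <- NULL; nsr <- NULL
      lnc_bio <- character(); mir_bio <- character()
      keys <- empty_triplets()
    }
    biomarkers[[lab]] <- list(nsm = nsm, nsr = nsr, lncrna = lnc_bio,
                              mirna = mir_bio)
    key_triplets[[lab]] <- keys
    manifest[[paste0(lab, "_lnc_biomarkers")]] <- length(lnc_bio)
    manifest[[paste0(lab, "_mir_biomarkers")]] <- length(mir_bio)
    manifest[[paste0(lab, "_key_triplets")]] <- nrow(keys)

    for (id in c(lnc_bio, mir_bio)) {
      if (!id %in% rownames(expr_all)) next
      r <- roc_auc(expr_all[id, ids],
                   ids %in% ct$group_a)
      roc_rows[[length(roc_rows) + 1]] <-
        tibble(contrast = lab, feature_id = id, auc = r$auc)
    }
  }

  overlap <- lapply(c(lncRNA = "lncRNA", miRNA = "miRNA", mRNA = "mRNA"),
                    function(cl) {
    sets <- lapply(de, function(d) {
      d$selected$feature_id[d$selected$feature_class == cl]
    })
    overlap_de_sets(sets)
  })
  manifest$common_de_lncrna <- length(overlap$lncRNA$common)
  manifest$common_de_mirna <- length(overlap$miRNA$common)
  manifest$common_de_mrna <- length(overlap$mRNA$common)

  nonempty <- Filter(function(n) nrow(n$triplets) > 0L, contexts)
  shared <- if (length(nonempty) >= 2L) {
    shared_interactions(nonempty)
  } else {
    empty_triplets()
  }
  manifest$shared_triplets <- nrow(shared)

  km_rows <- list()
  if (!is.null(survival_data)) {
    surv <- as_tibble(survival_data)
    km_genes <- unique(unlist(lapply(key_triplets, function(k) k$mrna_id)))
    for (s in unique(surv$site)) {
      ss <- filter(surv, .data$site == s)
      for (gene in km_genes) {
        if (!gene %in% rownames(expr_all)) next
        recs <- mutate(ss, expression = expr_all[gene, ss$sample_id])
        res <- tryCatch(
          km_logrank(recs, lower = split_lower, upper = split_upper),
          error = function(e) NULL
        )
        if (!is.null(res)) {
          km_rows[[length(km_rows) + 1]] <-
            tibble(site = s, feature_id = gene, chisq = res$chisq, p = res$p)
        }
      }
    }
  }

  ora <- NULL
  if (!is.null(gene_sets)) {
    universe <- study$features$feature_id[study$features$feature_class == "mRNA"]
    ora <- lapply(de, function(d) {
      q <- intersect(d$selected$feature_id[d$selected$feature_class == "mRNA"],
                     universe)
      gene_set_ora(q, universe, gene_sets)
    })
  }

  evaluation <- list(
    roc = if (length(roc_rows)) bind_rows(roc_rows) else
      tibble(contrast = character(), feature_id = character(), auc = double()),
    km = if (length(km_rows)) bind_rows(km_rows) else
      tibble(site = character(), feature_id = character(), chisq = double(),
             p = double()),
    ora = ora
  )

  manifest_tbl <- tibble(stage = names(manifest),
                         count = as.integer(unlist(manifest)))
  out <- structure(
    list(global = global, de = de, contexts = contexts, topology = topology,
         biomarkers = biomarkers, key_triplets = key_triplets,
         overlap = overlap, shared = shared, evaluation = evaluation,
         manifest = manifest_tbl),
    class = "lcenet_run"
  )
  attr(out, "elapsed") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out
}

#' @export
print.lcenet_run <- function(x, ...) {
  cat("ceRNA biomarker pipeline run\n")
  print(x$manifest, n = nrow(x$manifest))
  invisible(x)
}
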