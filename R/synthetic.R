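#' Configuration for a synthetic ceRNA study
#'
#' Defines the study conditions emulated by the generator: catalog sizes,
#' per-group sample sizes per site, planted competing-pair structure,
#' differential-expression effects, the latent-factor co-expression strength
#' of planted ceRNA triplets, negative-binomial noise, and
#' expression-dependent hazards. The defaults are the canonical fixture
#' conditions (60 miRNAs, 80 lncRNAs, 400 mRNAs; 30 normal + 30 M0 + 20 M1
#' samples per site); `seed` fully determines every generated object.
#'
#' Planted structure, per biomarker lncRNA (of `n_nsm_lncrnas`): a block of
#' `nsm_shared` miRNAs shared with each of `nsm_partners` partner mRNAs (high
#' NSM); the first miRNA of each block is the planted miRNA biomarker, given
#' `n_nsr_pairs` additional competing pairs whose shared set contains no
#' other differentially expressed miRNA, so their endpoints are single-line
#' regulated in the context network (high NSR). `n_bg_pairs` background
#' competing pairs share `bg_shared` miRNAs drawn from a pool of `n_pool`
#' DE miRNAs (moderate NSM, no single-line structure). All remaining nodes
#' carry sparse background edges only.
#'
#' @param seed Integer seed.
#' @param n_mirna,n_lncrna,n_mrna Catalog sizes.
#' @param n_normal,n_m0,n_m1 Samples per group, per site.
#' @param n_nsm_lncrnas Number of planted biomarker lncRNAs (each paired
#'   with one planted biomarker miRNA).
#' @param nsm_partners,nsm_shared Partner mRNAs per biomarker lncRNA and the
#'   size of the shared miRNA block.
#' @param n_bg_pairs,bg_shared Background competing pairs and their shared
#'   miRNA count.
#' @param n_nsr_pairs Single-line pairs planted per biomarker miRNA.
#' @param n_pool DE background miRNA pool size.
#' @param extra_mirnas Non-shared miRNAs added to each planted node.
#' @param n_tag_per_lnc Partner mRNAs per biomarker lncRNA put on the TAG
#'   list (defines the planted key triplets).
#' @param mirnas_per_lncrna,mirnas_per_mrna Background degrees of unplanted
#'   nodes.
#' @param de_lfc Planted log2 fold change (tumour over normal).
#' @param n_extra_de Extra DE mRNAs outside the network (split into
#'   all-contrast, colon-only, rectal-only and M1-only subsets).
#' @param rho Target Pearson correlation of planted lncRNA-mRNA pairs in
#'   tumour samples, in (0, 1).
#' @param nb_dispersion Negative-binomial size parameter (shared across
#'   genes).
#' @param base_meanlog,base_sdlog Log-normal baseline-mean parameters for
#'   network features.
#' @param spare_meanlog,spare_sdlog Baseline-mean parameters for unplanted
#'   spare mRNAs (lower and more dispersed, so the CPM filter is exercised).
#' @param lib_variation Library sizes vary by this fraction around nominal.
#' @param hazard_ratio Hazard multiplier for the high-expression half of
#'   each hazard gene (first TAG mRNA per site).
#' @param base_hazard Baseline exponential hazard per day.
#' @param censor_time Upper bound of the uniform censoring time (days).
#' @param planted Set `FALSE` for a null study: no planted pairs, no DE
#'   effects, no hazard genes (background structure only).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 7L,
                             n_mirna = 60L, n_lncrna = 80L, n_mrna = 400L,
                             n_normal = 30L, n_m0 = 30L, n_m1 = 20L,
                             n_nsm_lncrnas = 2L, nsm_partners = 6L,
                             nsm_shared = 8L,
                             n_bg_pairs = 24L, bg_shared = 6L,
                             n_nsr_pairs = 6L, n_pool = 20L,
                             extra_mirnas = 2L, n_tag_per_lnc = 2L,
                             mirnas_per_lncrna = 5L, mirnas_per_mrna = 5L,
                             de_lfc = 2, n_extra_de = 50L,
                             rho = 0.8, nb_dispersion = 10,
                             base_meanlog = 5, base_sdlog = 0.7,
                             spare_meanlog = 4, spare_sdlog = 1.2,
                             lib_variation = 0.3,
                             hazard_ratio = 3, base_hazard = 1 / 1500,
                             censor_time = 3000,
                             planted = TRUE) {
  if (!planted) {
    n_nsm_lncrnas <- 0L; n_bg_pairs <- 0L; n_nsr_pairs <- 0L
    n_extra_de <- 0L; de_lfc <- 0
  }
  cfg <- list(
    seed = as.integer(seed), n_mirna = n_mirna, n_lncrna = n_lncrna,
    n_mrna = n_mrna, n_normal = n_normal, n_m0 = n_m0, n_m1 = n_m1,
    n_nsm_lncrnas = n_nsm_lncrnas, nsm_partners = nsm_partners,
    nsm_shared = nsm_shared, n_bg_pairs = n_bg_pairs, bg_shared = bg_shared,
    n_nsr_pairs = n_nsr_pairs, n_pool = n_pool, extra_mirnas = extra_mirnas,
    n_tag_per_lnc = n_tag_per_lnc,
    mirnas_per_lncrna = mirnas_per_lncrna, mirnas_per_mrna = mirnas_per_mrna,
    de_lfc = de_lfc, n_extra_de = n_extra_de, rho = rho,
    nb_dispersion = nb_dispersion, base_meanlog = base_meanlog,
    base_sdlog = base_sdlog, spare_meanlog = spare_meanlog,
    spare_sdlog = spare_sdlog, lib_variation = lib_variation,
    hazard_ratio = hazard_ratio, base_hazard = base_hazard,
    censor_time = censor_time, planted = planted
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_mirna", "n_lncrna", "n_mrna", "n_normal", "n_m0", "n_m1")
  for (nm in counts) {
    if (cfg[[nm]] < 1) abort(sprintf("`%s` must be positive.", nm))
  }
  if (cfg$rho <= 0 || cfg$rho >= 1) abort("`rho` must lie in (0, 1).")
  k <- cfg$n_nsm_lncrnas
  need_mirna <- k * cfg$nsm_shared + cfg$n_pool * (cfg$n_bg_pairs > 0) +
    max(cfg$bg_shared + cfg$extra_mirnas, 8L)
  if (cfg$nsm_shared > cfg$n_mirna || need_mirna > cfg$n_mirna) {
    abort("Planted structure does not fit in `n_mirna`.")
  }
  need_lnc <- k + cfg$n_bg_pairs + k * cfg$n_nsr_pairs
  need_mrna <- k * cfg$nsm_partners + cfg$n_bg_pairs + k * cfg$n_nsr_pairs +
    cfg$n_extra_de
  if (need_lnc > cfg$n_lncrna) abort("Planted structure does not fit in `n_lncrna`.")
  if (need_mrna > cfg$n_mrna) abort("Planted structure does not fit in `n_mrna`.")
  invisible(cfg)
}

mirna_ids <- function(n) sprintf("mir-%03d", seq_len(n))
lnc_ids <- function(n) sprintf("LNC%03d", seq_len(n))
mrna_ids <- function(n) sprintf("GENE%03d", seq_len(n))

# Role assignment is deterministic in the config (no RNG): blocks of ids are
# reserved for planted structure, the remainder are background spares.
assign_roles <- function(cfg) {
  k <- cfg$n_nsm_lncrnas
  mir <- mirna_ids(cfg$n_mirna)
  lnc <- lnc_ids(cfg$n_lncrna)
  mrna <- mrna_ids(cfg$n_mrna)

  shared_blocks <- lapply(seq_len(k), function(i) {
    mir[((i - 1) * cfg$nsm_shared + 1):(i * cfg$nsm_shared)]
  })
  used <- k * cfg$nsm_shared
  pool <- if (cfg$n_bg_pairs > 0) mir[(used + 1):(used + cfg$n_pool)] else character()
  used <- used + length(pool)
  nonde <- mir[seq.int(used + 1, cfg$n_mirna)]

  bio_lnc <- if (k > 0) lnc[seq_len(k)] else character()
  bg_lnc <- if (cfg$n_bg_pairs > 0) lnc[k + seq_len(cfg$n_bg_pairs)] else character()
  n_sl <- k * cfg$n_nsr_pairs
  sl_lnc <- if (n_sl > 0) lnc[k + cfg$n_bg_pairs + seq_len(n_sl)] else character()
  spare_lnc <- setdiff(lnc, c(bio_lnc, bg_lnc, sl_lnc))

  n_partner <- k * cfg$nsm_partners
  partner_mrna <- if (n_partner > 0) mrna[seq_len(n_partner)] else character()
  bg_mrna <- if (cfg$n_bg_pairs > 0) mrna[n_partner + seq_len(cfg$n_bg_pairs)] else character()
  sl_mrna <- if (n_sl > 0) mrna[n_partner + cfg$n_bg_pairs + seq_len(n_sl)] else character()
  extra_de_mrna <- if (cfg$n_extra_de > 0) {
    mrna[n_partner + cfg$n_bg_pairs + n_sl + seq_len(cfg$n_extra_de)]
  } else character()
  spare_mrna <- setdiff(mrna, c(partner_mrna, bg_mrna, sl_mrna, extra_de_mrna))

  list(
    mir = mir, lnc = lnc, mrna = mrna,
    shared_blocks = shared_blocks,
    bio_mirna = vapply(shared_blocks, `[`, "", 1),
    pool = pool, nonde = nonde,
    bio_lnc = bio_lnc, bg_lnc = bg_lnc, sl_lnc = sl_lnc,
    spare_lnc = spare_lnc,
    partner_mrna = partner_mrna, bg_mrna = bg_mrna, sl_mrna = sl_mrna,
    extra_de_mrna = extra_de_mrna, spare_mrna = spare_mrna
  )
}

#' Generate a synthetic interaction catalog with planted competing pairs
#'
#' Background edges are drawn uniformly at low density; planted pairs
#' receive the configured number of shared miRNA regulators so their
#' hypergeometric tail probability falls below the significance cut at the
#' configured background size. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `catalog` (an `lcenet_catalog`, `N_T = n_mirna`),
#'   `truth` (tibbles `pairs`, `key_triplets`, vectors `lnc_biomarkers`,
#'   `mir_biomarkers`, `tag_list`) and `roles` (internal id blocks, reused
#'   by the expression generator).
#' @export
simulate_catalog <- function(cfg) {
  set.seed(stage_seed(cfg$seed, 1L))
  roles <- assign_roles(cfg)
  k <- cfg$n_nsm_lncrnas
  edges <- list()
  truth_pairs <- list()

  add_edges <- function(mirnas, target, class) {
    tibble(mirna_id = mirnas, target_id = target, target_class = class,
           sources = "synthetic")
  }
  pick_extras <- function(exclude) {
    sample(setdiff(roles$nonde, exclude), cfg$extra_mirnas)
  }

  # biomarker lncRNAs: a block of nsm_shared miRNAs shared with each partner
  for (i in seq_len(k)) {
    block <- roles$shared_blocks[[i]]
    l <- roles$bio_lnc[i]
    edges[[length(edges) + 1]] <- add_edges(c(block, pick_extras(block)),
                                            l, "lncRNA")
    partners <- roles$partner_mrna[(i - 1) * cfg$nsm_partners +
                                     seq_len(cfg$nsm_partners)]
    for (m in partners) {
      edges[[length(edges) + 1]] <- add_edges(c(block, pick_extras(block)),
                                              m, "mRNA")
      truth_pairs[[length(truth_pairs) + 1]] <-
        tibble(lncrna_id = l, mrna_id = m, shared = cfg$nsm_shared,
               kind = "nsm")
    }
  }

  # background competing pairs: moderate sharing from the DE miRNA pool
  for (j in seq_len(cfg$n_bg_pairs)) {
    shared <- sample(roles$pool, cfg$bg_shared)
    l <- roles$bg_lnc[j]; m <- roles$bg_mrna[j]
    edges[[length(edges) + 1]] <- add_edges(c(shared, pick_extras(shared)),
                                            l, "lncRNA")
    edges[[length(edges) + 1]] <- add_edges(c(shared, pick_extras(shared)),
                                            m, "mRNA")
    truth_pairs[[length(truth_pairs) + 1]] <-
      tibble(lncrna_id = l, mrna_id = m, shared = cfg$bg_shared, kind = "bg")
  }

  # single-line pairs: shared set holds exactly one DE miRNA (the biomarker)
  for (i in seq_len(k)) {
    for (j in seq_len(cfg$n_nsr_pairs)) {
      idx <- (i - 1) * cfg$n_nsr_pairs + j
      shared <- c(roles$bio_mirna[i],
                  sample(roles$nonde, cfg$bg_shared - 1L))
      l <- roles$sl_lnc[idx]; m <- roles$sl_mrna[idx]
      edges[[length(edges) + 1]] <- add_edges(c(shared, pick_extras(shared)),
                                              l, "lncRNA")
      edges[[length(edges) + 1]] <- add_edges(c(shared, pick_extras(shared)),
                                              m, "mRNA")
      truth_pairs[[length(truth_pairs) + 1]] <-
        tibble(lncrna_id = l, mrna_id = m, shared = cfg$bg_shared,
               kind = "single_line")
    }
  }

  # background spares: uniform sparse edges over the whole miRNA universe
  for (l in roles$spare_lnc) {
    edges[[length(edges) + 1]] <- add_edges(
      sample(roles$mir, cfg$mirnas_per_lncrna), l, "lncRNA")
  }
  for (m in c(roles$extra_de_mrna, roles$spare_mrna)) {
    edges[[length(edges) + 1]] <- add_edges(
      sample(roles$mir, cfg$mirnas_per_mrna), m, "mRNA")
  }

  catalog <- harmonize_and_merge(bind_rows(edges),
                                 n_mirna_universe = cfg$n_mirna)
  tags <- unlist(lapply(seq_len(k), function(i) {
    roles$partner_mrna[(i - 1) * cfg$nsm_partners + seq_len(cfg$n_tag_per_lnc)]
  }))
  key <- empty_triplets()
  if (k > 0) {
    key <- purrr::map_dfr(seq_len(k), function(i) {
      tibble(
        lncrna_id = roles$bio_lnc[i],
        mirna_id = canonical_mirna(roles$bio_mirna[i]),
        mrna_id = roles$partner_mrna[(i - 1) * cfg$nsm_partners +
                                       seq_len(cfg$n_tag_per_lnc)]
      )
    })
  }
  truth <- list(
    pairs = if (length(truth_pairs)) bind_rows(truth_pairs) else
      tibble(lncrna_id = character(), mrna_id = character(),
             shared = integer(), kind = character()),
    lnc_biomarkers = roles$bio_lnc,
    mir_biomarkers = canonical_mirna(roles$bio_mirna),
    tag_list = tags %||% character(),
    key_triplets = key
  )
  list(catalog = catalog, truth = truth, roles = roles)
}

# planted DE table: feature, class, direction, scope of contrasts
planted_de_table <- function(cfg, roles) {
  k <- cfg$n_nsm_lncrnas
  up_lnc <- c(roles$bio_lnc, roles$bg_lnc, roles$sl_lnc)
  up_mrna <- c(roles$partner_mrna, roles$bg_mrna, roles$sl_mrna)
  down_mir <- canonical_mirna(c(unlist(roles$shared_blocks), roles$pool))
  base <- bind_rows(
    tibble(feature_id = up_lnc, feature_class = "lncRNA", direction = "up",
           scope = "all"),
    tibble(feature_id = up_mrna, feature_class = "mRNA", direction = "up",
           scope = "all"),
    tibble(feature_id = down_mir, feature_class = "miRNA",
           direction = "down", scope = "all")
  )
  extra <- roles$extra_de_mrna
  if (length(extra) > 0) {
    quarter <- ceiling(length(extra) / 5)
    n_common <- length(extra) - 3 * quarter
    scopes <- c(rep("all", n_common), rep("colon", quarter),
                rep("rectal", quarter), rep("M1", quarter))
    dirs <- rep(c("up", "down"), length.out = length(extra))
    base <- bind_rows(base, tibble(
      feature_id = extra, feature_class = "mRNA", direction = dirs,
      scope = scopes
    ))
  }
  base
}

#' Generate synthetic expression counts for a catalog
#'
#' Negative-binomial counts with log-normal baseline means and library sizes
#' varying by `lib_variation`. Planted DE features shift the tumour-group
#' mean by `2^de_lfc` in the configured direction. Planted ceRNA structure
#' is induced by a shared latent factor per competing-pair group in tumour
#' samples: the lncRNA and its partner mRNAs load positively, the shared
#' miRNA block negatively, giving lncRNA-mRNA Pearson correlation of about
#' `rho` and anti-correlated miRNAs. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param cat_out Output of [simulate_catalog()] for the same config.
#' @return List with `study` (an [expression_study()]) and `truth`
#'   (tibble `de`: feature, class, direction and contrast scope).
#' @export
simulate_expression <- function(cfg, cat_out) {
  set.seed(stage_seed(cfg$seed, 2L))
  roles <- cat_out$roles
  k <- cfg$n_nsm_lncrnas

  features <- bind_rows(
    tibble(feature_id = canonical_mirna(roles$mir), feature_class = "miRNA"),
    tibble(feature_id = roles$lnc, feature_class = "lncRNA"),
    tibble(feature_id = roles$mrna, feature_class = "mRNA")
  )
  samples <- purrr::map_dfr(c("colon", "rectal"), function(site) {
    tibble(
      sample_id = c(sprintf("%s_N_%02d", site, seq_len(cfg$n_normal)),
                    sprintf("%s_M0_%02d", site, seq_len(cfg$n_m0)),
                    sprintf("%s_M1_%02d", site, seq_len(cfg$n_m1))),
      tissue = c(rep("normal", cfg$n_normal), rep("M0", cfg$n_m0),
                 rep("M1", cfg$n_m1)),
      site = site
    )
  })
  n_feat <- nrow(features); n_samp <- nrow(samples)

  spare <- features$feature_id %in% roles$spare_mrna
  base_mean <- ifelse(
    spare,
    exp(rnorm(n_feat, cfg$spare_meanlog, cfg$spare_sdlog)),
    exp(rnorm(n_feat, cfg$base_meanlog, cfg$base_sdlog))
  )
  lib_factor <- runif(n_samp, 1 - cfg$lib_variation, 1 + cfg$lib_variation)

  mu <- outer(base_mean, lib_factor)
  rownames(mu) <- features$feature_id
  colnames(mu) <- samples$sample_id
  tumour <- samples$tissue != "normal"

  de <- planted_de_table(cfg, roles)
  scope_cols <- function(scope) {
    switch(scope,
      all = tumour,
      colon = tumour & samples$site == "colon",
      rectal = tumour & samples$site == "rectal",
      M1 = samples$tissue == "M1"
    )
  }
  for (i in seq_len(nrow(de))) {
    cols <- scope_cols(de$scope[i])
    fold <- 2^(cfg$de_lfc * if (de$direction[i] == "up") 1 else -1)
    mu[de$feature_id[i], cols] <- mu[de$feature_id[i], cols] * fold
  }

  # latent ceRNA factors (tumour samples only), variance-neutral loadings
  sigma <- sqrt(cfg$rho / (1 - cfg$rho) / cfg$nb_dispersion)
  groups <- list()
  for (i in seq_len(k)) {
    partners <- roles$partner_mrna[(i - 1) * cfg$nsm_partners +
                                     seq_len(cfg$nsm_partners)]
    groups[[length(groups) + 1]] <- list(
      pos = c(roles$bio_lnc[i], partners),
      neg = canonical_mirna(roles$shared_blocks[[i]])
    )
  }
  truth_bg <- cat_out$truth$pairs
  for (kind in c("bg", "single_line")) {
    rows <- truth_bg[truth_bg$kind == kind, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      groups[[length(groups) + 1]] <- list(
        pos = c(rows$lncrna_id[j], rows$mrna_id[j]), neg = character()
      )
    }
  }
  for (g in groups) {
    z <- rnorm(sum(tumour))
    bump_pos <- exp(sigma * z - sigma^2 / 2)
    bump_neg <- exp(-sigma * z - sigma^2 / 2)
    mu[g$pos, tumour] <- sweep(mu[g$pos, tumour, drop = FALSE], 2L,
                               bump_pos, "*")
    if (length(g$neg) > 0) {
      mu[g$neg, tumour] <- sweep(mu[g$neg, tumour, drop = FALSE], 2L,
                                 bump_neg, "*")
    }
  }

  counts <- matrix(
    rnbinom(n_feat * n_samp, mu = as.vector(mu), size = cfg$nb_dispersion),
    nrow = n_feat, dimnames = dimnames(mu)
  )
  study <- expression_study(counts, features, samples)
  list(study = study, truth = list(de = de))
}

#' Generate synthetic survival outcomes
#'
#' Exponential event times for the tumour patients of each site, with the
#' hazard multiplied by `hazard_ratio` for patients in the high-expression
#' half of the site's hazard gene (the first TAG mRNA of each biomarker
#' lncRNA, one per site; none in a null study). Censoring is independent
#' uniform on `(0, censor_time)`. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param expr_out Output of [simulate_expression()].
#' @param cat_out Output of [simulate_catalog()].
#' @return List with `survival` (tibble: `sample_id`, `site`, `time`,
#'   `event`) and `truth` (tibble of hazard genes per site).
#' @export
simulate_survival <- function(cfg, expr_out, cat_out) {
  set.seed(stage_seed(cfg$seed, 3L))
  study <- expr_out$study
  expr <- cpm(study)
  tumour <- study$samples[study$samples$tissue != "normal", ]
  tags <- cat_out$truth$tag_list
  sites <- c("colon", "rectal")
  hazard_genes <- tibble(
    site = sites,
    feature_id = if (cfg$planted && length(tags) >= 2) {
      # one hazard gene per site, taken from the TAG list
      tags[c(1, min(cfg$n_tag_per_lnc + 1, length(tags)))]
    } else {
      NA_character_
    },
    hazard_ratio = if (cfg$planted) cfg$hazard_ratio else 1
  )
  surv <- purrr::map_dfr(sites, function(s) {
    ids <- tumour$sample_id[tumour$site == s]
    rate <- rep(cfg$base_hazard, length(ids))
    gene <- hazard_genes$feature_id[hazard_genes$site == s]
    if (!is.na(gene)) {
      e <- expr[gene, ids]
      high <- e > median(e)
      rate[high] <- rate[high] * cfg$hazard_ratio
    }
    t_event <- rexp(length(ids), rate)
    t_cens <- runif(length(ids), 0, cfg$censor_time)
    tibble(sample_id = ids, site = s,
           time = pmin(t_event, t_cens),
           event = t_event <= t_cens)
  })
  list(survival = surv, truth = list(hazard_genes = hazard_genes))
}

#' Generate a complete synthetic study
#'
#' Chains [simulate_catalog()], [simulate_expression()] and
#' [simulate_survival()] under one seed, bundling the inputs of every
#' pipeline stage together with the planted ground truth.
#'
#' @param cfg A [synthetic_config()].
#' @return A `synthetic_study`: list with `catalog`, `study`, `survival`,
#'   `tag_list`, `truth` (pairs, DE, biomarkers, key triplets, hazard
#'   genes) and `config`.
#' @export
simulate_study <- function(cfg = synthetic_config()) {
  cat_out <- simulate_catalog(cfg)
  expr_out <- simulate_expression(cfg, cat_out)
  surv_out <- simulate_survival(cfg, expr_out, cat_out)
  structure(
    list(
      catalog = cat_out$catalog,
      study = expr_out$study,
      survival = surv_out$survival,
      tag_list = cat_out$truth$tag_list,
      truth = c(cat_out$truth, expr_out$truth, surv_out$truth),
      config = cfg
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic ceRNA study (seed %d): %d catalog edges, %d features x %d samples, %d planted pairs\n",
    x$config$seed, nrow(x$catalog), nrow(x$study$counts),
    ncol(x$study$counts), nrow(x$truth$pairs)
  ))
  invisible(x)
}

#' Write the canonical fixture study to disk
#'
#' Materialises the seed-7 fixture (or any configured study) in the exact
#' plain-text formats the pipeline reads: merged catalog TSV, counts TSV,
#' feature/sample annotation TSVs, survival TSV, TAG list, a small GMT of
#' gene sets derived from the planted structure, and a ground-truth JSON
#' sidecar.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [synthetic_config()]; defaults to the canonical seed-7
#'   fixture configuration.
#' @return The directory, invisibly; side effect: files written.
#' @export
make_fixture <- function(dir = tempfile("lcenet_fixture_"),
                         cfg = synthetic_config(seed = 7L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(cfg)
  write_catalog(sim$catalog, file.path(dir, "catalog.tsv"))
  counts <- as_tibble(sim$study$counts, rownames = "feature_id")
  readr::write_tsv(counts, file.path(dir, "counts.tsv"), progress = FALSE)
  readr::write_tsv(sim$study$features, file.path(dir, "features.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$study$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$survival, file.path(dir, "survival.tsv"),
                   progress = FALSE)
  writeLines(sim$tag_list, file.path(dir, "tags.txt"))
  sets <- list(
    planted_partners = unique(sim$truth$pairs$mrna_id),
    tag_genes = sim$tag_list,
    spare_background = utils::tail(sim$study$features$feature_id, 50)
  )
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  truth_json <- list(
    pairs = sim$truth$pairs,
    de = sim$truth$de,
    lnc_biomarkers = sim$truth$lnc_biomarkers,
    mir_biomarkers = sim$truth$mir_biomarkers,
    tag_list = sim$tag_list,
    key_triplets = sim$truth$key_triplets,
    hazard_genes = sim$truth$hazard_genes
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' Read a fixture study back from disk
#'
#' @param dir Directory written by [make_fixture()].
#' @return A list with `catalog`, `study`, `survival`, `tag_list`,
#'   `gene_sets` and `truth`.
#' @export
read_study <- function(dir) {
  counts_df <- readr::read_tsv(file.path(dir, "counts.tsv"),
                               show_col_types = FALSE, progress = FALSE)
  counts <- as.matrix(counts_df[, -1])
  rownames(counts) <- counts_df$feature_id
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  list(
    catalog = read_catalog(file.path(dir, "catalog.tsv")),
    study = expression_study(counts, features, samples),
    survival = readr::read_tsv(file.path(dir, "survival.tsv"),
                               show_col_types = FALSE, progress = FALSE),
    tag_list = readLines(file.path(dir, "tags.txt")),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  )
}
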