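# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# hypergeometric upper tail by direct combinatorial enumeration
hyper_tail_oracle <- function(n_total, n_lnc, n_mrna, x) {
  hi <- min(n_lnc, n_mrna)
  if (x > hi) return(0)
  i <- x:hi
  sum(choose(n_lnc, i) * choose(n_total - n_lnc, n_mrna - i)) /
    choose(n_total, n_mrna)
}

# Benjamini-Hochberg step-up applied from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# single-line recount straight from a raw edge list
nsr_oracle <- function(edges) {
  reg_count <- table(edges$target_id)
  single <- names(reg_count)[reg_count == 1]
  counts <- tapply(edges$target_id %in% single, edges$mirna_id, sum)
  tibble::tibble(mirna_id = names(counts), nsr = as.integer(counts))
}

# random tripartite context network for property tests
random_context <- function(n_lnc, n_mir, n_mrna, n_triplets) {
  trip <- tibble::tibble(
    lncrna_id = sprintf("L%02d", sample.int(n_lnc, n_triplets, replace = TRUE)),
    mirna_id = sprintf("m%02d", sample.int(n_mir, n_triplets, replace = TRUE)),
    mrna_id = sprintf("G%02d", sample.int(n_mrna, n_triplets, replace = TRUE))
  )
  context_network(trip)
}

# a small expression study with explicit CPM values (library sizes 1e6 so
# counts equal CPM)
study_from_values <- function(values, classes = NULL, tissue = NULL,
                              site = "colon") {
  values <- as.matrix(values)
  n <- ncol(values)
  if (is.null(tissue)) tissue <- rep(c("M0", "normal"), length.out = n)
  features <- tibble::tibble(
    feature_id = rownames(values) %||% sprintf("f%02d", seq_len(nrow(values))),
    feature_class = classes %||% rep("mRNA", nrow(values))
  )
  rownames(values) <- features$feature_id
  colnames(values) <- sprintf("s%02d", seq_len(n))
  samples <- tibble::tibble(sample_id = colnames(values), tissue = tissue,
                            site = rep(site, length.out = n))
  expression_study(values, features, samples, library_sizes = rep(1e6, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
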