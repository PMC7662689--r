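test_that("cpm performs the count-per-million normalisation", {
  m <- matrix(c(5, 0, 95), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(cpm(m, library_sizes = 100)["a", 1], 50000)
  expect_equal(cpm(m, library_sizes = 100)["b", 1], 0)
  col <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.vector(cpm(col, library_sizes = 4)),
               c(250000, 250000, 500000))
  # with default library sizes every column sums to one million
  set.seed(9)
  big <- matrix(rpois(60, 20), nrow = 6,
                dimnames = list(sprintf("f%d", 1:6), sprintf("s%d", 1:10)))
  expect_equal(unname(colSums(cpm(big))), rep(1e6, 10))
  bad <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "badsample"))
  expect_error(cpm(bad), "badsample")
})

test_that("expression filter applies the 80% CPM rule with a ceiling", {
  vals <- rbind(
    keep8 = c(rep(100, 8), 0, 0),    # CPM > 1 in exactly 8/10: boundary kept
    drop7 = c(rep(100, 7), 0, 0, 0), # 7/10: dropped
    keep10 = rep(50, 10),
    drop0 = rep(0, 10),
    ballast = rep(1000, 10)
  )
  study <- study_from_values(vals)
  filtered <- filter_expressed(study)
  expect_setequal(filtered$features$feature_id,
                  c("keep8", "keep10", "ballast"))
  expect_equal(attr(filtered, "filter_report")$n_dropped, 2)
})

test_that("the rank-sum DE engine matches the pseudo-count fold change", {
  vals <- rbind(
    shifted = c(100, 110, 90, 10, 9, 11),
    flat = c(20, 20, 20, 20, 20, 20)
  )
  study <- study_from_values(vals, tissue = rep(c("M0", "normal"), each = 3))
  ct <- de_contrasts(study$samples)$colon_M0N
  de <- differential_expression(study, ct)
  expect_equal(de$log2_fold_change[de$feature_id == "shifted"],
               log2(100.5 / 10.5), tolerance = 1e-12)
  flat <- de[de$feature_id == "flat", ]
  expect_equal(flat$log2_fold_change, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$direction, "down") # zero fold change is never "up"
  expect_equal(nrow(select_de(de)[select_de(de)$feature_id == "flat", ]), 0)
  tiny <- study_from_values(vals[, 1:3, drop = FALSE],
                            tissue = c("M0", "normal", "normal"))
  expect_error(
    differential_expression(tiny, de_contrasts(tiny$samples)$colon_M0N),
    "2 samples"
  )
})

test_that("an external DE table is ingested verbatim", {
  study <- study_from_values(rbind(a = 1:6, b = 6:1))
  tab <- tibble::tibble(feature_id = c("a", "b"),
                        log2_fold_change = c(2, -0.2), fdr = c(0.01, 0.9))
  de <- differential_expression(study, NULL, engine = "table",
                                de_table = tab)
  expect_equal(de$direction, c("up", "down"))
  expect_equal(select_de(de)$feature_id, "a")
})

test_that("DE selection applies the boundary rules and is monotone", {
  recs <- tibble::tibble(
    feature_id = sprintf("f%d", 1:6),
    feature_class = "mRNA",
    log2_fold_change = c(1.0, 0.99, -1.4, 2.0, -3.0, 0.2),
    fdr = c(0.049, 0.001, 0.05, 0.04, 0.2, 0.01),
    direction = c("up", "up", "down", "up", "down", "up")
  )
  sel <- select_de(recs)
  expect_setequal(sel$feature_id, c("f1", "f4"))
  # loosening thresholds never removes a survivor
  looser <- select_de(recs, lfc_min = 0.5, fdr_max = 0.1)
  expect_true(all(sel$feature_id %in% looser$feature_id))
})

test_that("planted four-fold changes are detected at high rate", {
  set.seed(799)
  # mirror the generator's conditions: a small planted fraction with
  # balanced directions, so library composition stays stable
  n_feat <- 300; n_up <- 20; n_down <- 20; n_planted <- n_up + n_down
  mu <- exp(rnorm(n_feat, 5, 0.5))
  group <- rep(c("M0", "normal"), each = 20)
  fold <- matrix(1, n_feat, 40)
  fold[seq_len(n_up), group == "M0"] <- 4
  fold[n_up + seq_len(n_down), group == "M0"] <- 0.25
  counts <- matrix(rnbinom(n_feat * 40, mu = mu * fold, size = 10),
                   nrow = n_feat,
                   dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                                   sprintf("s%02d", 1:40)))
  study <- expression_study(
    counts,
    tibble::tibble(feature_id = rownames(counts), feature_class = "mRNA"),
    tibble::tibble(sample_id = colnames(counts), tissue = group,
                   site = "colon")
  )
  de <- differential_expression(study, de_contrasts(study$samples)$colon_M0N)
  sel <- select_de(de)
  expect_gte(mean(sprintf("f%03d", seq_len(n_planted)) %in% sel$feature_id),
             0.9)
})

test_that("Venn regions match exhaustive membership tabulation", {
  a <- c("x", "y", "z"); b <- a
  same <- overlap_de_sets(list(A = a, B = b))
  expect_setequal(same$common, a)
  disjoint <- overlap_de_sets(list(A = c("x"), B = c("y")))
  expect_equal(disjoint$common, character(0))

  set.seed(11)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- sprintf("S%d", 1:4)
  ov <- overlap_de_sets(sets)
  expect_equal(nrow(ov$regions), 15)
  # brute force: classify every id by its membership pattern
  ids <- sort(unique(unlist(sets)))
  patt <- sapply(ids, function(id) {
    paste(names(sets)[vapply(sets, function(s) id %in% s, TRUE)],
          collapse = "+")
  })
  brute <- table(patt)
  for (r in seq_len(nrow(ov$regions))) {
    reg <- ov$regions$region[r]
    expect_equal(ov$regions$count[r],
                 if (reg %in% names(brute)) unname(brute[[reg]]) else 0L)
  }
  expect_equal(sum(ov$regions$count), length(ids))
})
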