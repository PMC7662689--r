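test_that("pair-level NSM values count shared miRNAs per partner", {
  trip <- tibble::tibble(
    lncrna_id = "L",
    mirna_id = c("m1", "m2", "m3", "m1"),
    mrna_id = c("A", "A", "A", "B")
  )
  net <- context_network(trip)
  prof <- suppressMessages(compute_nsm_profiles(net))
  expect_equal(sort(prof$nsm_values[[1]], decreasing = TRUE), c(3, 1))
  # a lone lncRNA compared against its own pooled values is degenerate
  expect_true(prof$degenerate)
  expect_gt(prof$test_p, 0.2)
  expect_lt(prof$test_p, 0.8)
})

test_that("a planted high-NSM lncRNA is the only one selected", {
  trip <- dplyr::bind_rows(
    tidyr::expand_grid(lncrna_id = "Lhigh",
                       mirna_id = sprintf("m%d", 1:5),
                       mrna_id = sprintf("A%d", 1:3)),
    tibble::tibble(lncrna_id = sprintf("Lbg%02d", 1:10),
                   mirna_id = sprintf("m%d", rep(1:5, 2)),
                   mrna_id = sprintf("B%d", 1:10))
  )
  net <- context_network(trip)
  prof <- compute_nsm_profiles(net)
  sel <- select_lncrna_biomarkers(prof)
  expect_equal(sel, "Lhigh")
  # strictness of the threshold
  fake <- tibble::tibble(lncrna_id = c("a", "b"), test_p = c(0.05, 0.04))
  expect_equal(select_lncrna_biomarkers(fake), "b")
})

test_that("NSM selection is invariant under node relabelling", {
  set.seed(31)
  net <- random_context(6, 6, 10, 80)
  sel <- select_lncrna_biomarkers(compute_nsm_profiles(net))
  ids <- unique(c(net$triplets$lncrna_id, net$triplets$mirna_id,
                  net$triplets$mrna_id))
  relabel <- setNames(sprintf("X%02d", sample(length(ids))), ids)
  trip2 <- dplyr::mutate(net$triplets,
                         lncrna_id = unname(relabel[lncrna_id]),
                         mirna_id = unname(relabel[mirna_id]),
                         mrna_id = unname(relabel[mrna_id]))
  sel2 <- select_lncrna_biomarkers(compute_nsm_profiles(context_network(trip2)))
  expect_setequal(sel2, unname(relabel[sel]))
})

test_that("NSR counts single-line regulated targets", {
  # m1 -> {g1, g2}, m2 -> {g2, g3}: g1 and g3 are single-line
  trip <- tibble::tibble(
    lncrna_id = c("g1", "g3"), mirna_id = c("m1", "m2"),
    mrna_id = c("g2", "g2")
  )
  net <- context_network(trip)
  prof <- compute_nsr_profiles(net)
  expect_equal(prof$nsr[prof$mirna_id == "m1"], 1)
  expect_equal(prof$nsr[prof$mirna_id == "m2"], 1)
  # complete bipartite graph: every target has every miRNA, no single lines
  full <- tidyr::expand_grid(lncrna_id = c("L1", "L2"),
                             mirna_id = c("m1", "m2", "m3"),
                             mrna_id = c("A1", "A2"))
  expect_true(all(compute_nsr_profiles(context_network(full))$nsr == 0))
})

test_that("NSR equals the brute-force recount on random graphs", {
  set.seed(13)
  for (i in 1:10) {
    net <- random_context(8, 6, 12, 100)
    prof <- compute_nsr_profiles(net)
    oracle <- nsr_oracle(dplyr::distinct(net$edges, mirna_id, target_id))
    joined <- dplyr::inner_join(prof, oracle, by = "mirna_id",
                                suffix = c("", "_oracle"))
    expect_equal(nrow(joined), nrow(prof))
    expect_equal(joined$nsr, joined$nsr_oracle)
    expect_true(all(prof$nsr <= prof$n_targets))
  }
})

test_that("miRNA biomarker selection applies both gates strictly", {
  prof <- tibble::tibble(
    mirna_id = c("a", "b", "c"),
    n_targets = c(10, 10, 10),
    nsr = c(5, 2, 6),
    passes_mean = c(TRUE, FALSE, TRUE),
    test_p = c(0.01, 0.001, 0.2)
  )
  expect_equal(select_mirna_biomarkers(prof), "a")
  expect_setequal(select_mirna_biomarkers(prof, require_test = FALSE),
                  c("a", "c"))
  # NSR equal to the mean fails the strict > gate
  net <- context_network(tibble::tibble(
    lncrna_id = c("L1", "L2"), mirna_id = c("m1", "m2"),
    mrna_id = c("A1", "A2")
  ))
  p2 <- compute_nsr_profiles(net)
  expect_true(all(!p2$passes_mean)) # all NSR equal => none strictly above
})

test_that("key-triplet screening applies all four rules", {
  trip <- tibble::tibble(
    lncrna_id = c("L1", "L1", "L1", "L2", "L1"),
    mirna_id = c("m1", "m1", "m2", "m1", "m1"),
    mrna_id = c("A", "B", "A", "A", "C")
  )
  net <- context_network(trip)
  de <- tibble::tibble(
    feature_id = c("L1", "L2", "m1", "m2", "A", "B"),
    direction = c("up", "up", "down", "up", "up", "up")
  )
  kept <- suppressMessages(screen_key_triplets(
    net, lnc_biomarkers = "L1", mir_biomarkers = c("m1", "m2"),
    de_records = de, tag_list = c("A", "B")
  ))
  # (L1, m1, A): all rules pass. (L1, m2, A): m2 not opposite. (L2,...): not
  # a biomarker. (L1, m1, C): missing direction, skipped.
  expect_setequal(paste(kept$lncrna_id, kept$mirna_id, kept$mrna_id),
                  c("L1 m1 A", "L1 m1 B"))
  expect_true(all(kept$is_tag))
  # prognosis path: mRNA not TAG-listed but log-rank significant
  prog <- tibble::tibble(feature_id = "A", p_value = 0.01)
  kept2 <- suppressMessages(screen_key_triplets(
    net, "L1", "m1", de, tag_list = character(), prognosis = prog
  ))
  expect_equal(unique(kept2$mrna_id), "A")
  expect_true(all(kept2$prognosis_associated))
  # output is a subset of the network and re-satisfies every rule
  expect_true(all(paste(kept$lncrna_id, kept$mirna_id, kept$mrna_id) %in%
                    paste(trip$lncrna_id, trip$mirna_id, trip$mrna_id)))
  expect_true(all(kept$mir_direction != kept$lnc_direction &
                    kept$mir_direction != kept$mrna_direction))
})
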