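test_that("reading drops blanks and collapses duplicates with a report", {
  path <- write_toy_table(tibble::tibble(
    mirna = c("miR-X", "miR-X", "miR-Y"),
    target = c("GENE1", "GENE1", "GENE2")
  ))
  frag <- read_interaction_table(path, "mRNA", source_label = "dbA")
  expect_equal(nrow(frag), 2)
  expect_equal(load_report(frag)$duplicates, 1)

  path2 <- write_toy_table(tibble::tibble(
    mirna = c("miR-X", "miR-Y"),
    target = c("GENE1", "")
  ))
  frag2 <- read_interaction_table(path2, "mRNA", source_label = "dbA")
  expect_equal(nrow(frag2), 1)
  expect_equal(load_report(frag2)$dropped_blank, 1)

  expect_error(
    read_interaction_table(path, "mRNA", "dbA", mirna_col = "missing"),
    "missing"
  )
})

test_that("merging unions evidence sources of the same pair", {
  p1 <- write_toy_table(tibble::tibble(mirna = "miR-X", target = "GENE1"))
  p2 <- write_toy_table(tibble::tibble(mirna = "miR-X", target = "GENE1"),
                        ext = "csv")
  frags <- list(
    read_interaction_table(p1, "mRNA", source_label = "dbA"),
    read_interaction_table(p2, "mRNA", source_label = "dbB")
  )
  cat <- harmonize_and_merge(frags)
  expect_equal(nrow(cat), 1)
  expect_equal(cat$sources, "dbA;dbB")
})

test_that("merging deduplicates, applies aliases, and flags ambiguity", {
  frag <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2"),
    target_id = c("A", "A", "B"),
    target_class = "mRNA", sources = "s"
  )
  expect_equal(nrow(harmonize_and_merge(frag)), 2)

  aliases <- tibble::tibble(raw = c("RAW1", "RAW2"),
                            canonical = c("GENE1", NA))
  frag2 <- tibble::tibble(
    mirna_id = "m1", target_id = c("RAW1", "RAW2"),
    target_class = "mRNA", sources = "s"
  )
  cat2 <- harmonize_and_merge(frag2, aliases = aliases)
  expect_equal(cat2$target_id, "GENE1")
  expect_equal(attr(cat2, "merge_report")$excluded_unmapped, 1)

  bad <- tibble::tibble(raw = c("RAW1", "RAW1"),
                        canonical = c("GENE1", "GENE2"))
  expect_error(harmonize_and_merge(frag2, aliases = bad), "Ambiguous")
})

test_that("five fragments with three cross-file redundancies merge to nine", {
  pairs <- list(
    c("m1", "A"), c("m1", "B"), c("m2", "A"),       # file 1
    c("m1", "A"), c("m3", "C"),                      # file 2 (1 redundant)
    c("m2", "A"), c("m4", "D"), c("m4", "E"),       # file 3 (1 redundant)
    c("m1", "B"), c("m5", "F"),                      # file 4 (1 redundant)
    c("m6", "G"), c("m6", "H")                       # file 5
  )
  sizes <- c(3, 2, 3, 2, 2)
  start <- cumsum(c(0, sizes[-5]))
  frags <- lapply(1:5, function(i) {
    rows <- pairs[start[i] + seq_len(sizes[i])]
    tibble::tibble(
      mirna_id = vapply(rows, `[`, "", 1),
      target_id = vapply(rows, `[`, "", 2),
      target_class = "mRNA", sources = sprintf("db%d", i)
    )
  })
  merged <- harmonize_and_merge(frags)
  expect_equal(nrow(merged), 9)
  # brute-force union over the listed rows
  all_rows <- unique(vapply(pairs, paste, "", collapse = "|"))
  expect_equal(nrow(merged), length(all_rows))
})

test_that("merging is idempotent, order-invariant, and only removes rows", {
  set.seed(1)
  frags <- lapply(1:4, function(i) {
    tibble::tibble(
      mirna_id = sprintf("hsa-miR-%d", sample(1:8, 6, replace = TRUE)),
      target_id = sprintf("G%d", sample(1:6, 6, replace = TRUE)),
      target_class = sample(c("mRNA", "lncRNA"), 6, replace = TRUE),
      sources = sprintf("db%d", i)
    )
  })
  once <- suppressWarnings(harmonize_and_merge(frags))
  twice <- suppressWarnings(harmonize_and_merge(once,
                                                n_mirna_universe = mirna_universe_size(once)))
  expect_equal(as.data.frame(once), as.data.frame(twice),
               ignore_attr = TRUE)
  shuffled <- suppressWarnings(harmonize_and_merge(rev(frags)))
  expect_equal(as.data.frame(once), as.data.frame(shuffled),
               ignore_attr = TRUE)
  per_source <- sum(vapply(frags, nrow, 1L))
  expect_gte(per_source, nrow(once))
})

test_that("identifier case conventions unify catalogs", {
  frag <- tibble::tibble(
    mirna_id = c("hsa-miR-484", "HSA-MIR-484"),
    target_id = c("abc", "ABC"),
    target_class = "mRNA", sources = c("a", "b")
  )
  cat <- harmonize_and_merge(frag)
  expect_equal(nrow(cat), 1)
  expect_equal(cat$mirna_id, "hsa-mir-484")
  expect_equal(cat$target_id, "ABC")
})

test_that("catalogs round-trip through TSV with their background size", {
  frag <- tibble::tibble(
    mirna_id = c("m1", "m2"), target_id = c("A", "L"),
    target_class = c("mRNA", "lncRNA"), sources = "s"
  )
  cat <- harmonize_and_merge(frag, n_mirna_universe = 50)
  path <- tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- read_catalog(path)
  expect_equal(mirna_universe_size(back), 50)
  expect_equal(as.data.frame(back), as.data.frame(cat), ignore_attr = TRUE)
})
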