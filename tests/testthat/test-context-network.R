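fake_global <- function(triplets) {
  structure(list(triplets = triplets), class = "lcenet_global")
}

test_that("context candidates require all three members to be DE", {
  trip <- tibble::tibble(
    lncrna_id = c("L1", "L1", "L2"),
    mirna_id = c("m1", "m2", "m1"),
    mrna_id = c("A", "A", "B")
  )
  g <- fake_global(trip)
  got <- extract_context_candidates(g, "L1", c("m1", "m2"), "A")
  expect_equal(nrow(got), 2)
  got2 <- extract_context_candidates(g, "L1", "m1", "A") # m2 not DE
  expect_equal(nrow(got2), 1)
  expect_warning(out <- extract_context_candidates(g, character(), "m1", "A"),
                 "empty")
  expect_equal(nrow(out), 0)
  # brute-force membership check on a random case
  set.seed(2)
  rnd <- tibble::tibble(
    lncrna_id = sample(sprintf("L%d", 1:6), 40, replace = TRUE),
    mirna_id = sample(sprintf("m%d", 1:6), 40, replace = TRUE),
    mrna_id = sample(sprintf("G%d", 1:6), 40, replace = TRUE)
  )
  de_l <- sprintf("L%d", 1:3); de_m <- sprintf("m%d", 2:5)
  de_g <- sprintf("G%d", c(1, 4, 6))
  got3 <- extract_context_candidates(fake_global(rnd), de_l, de_m, de_g)
  brute <- rnd[rnd$lncrna_id %in% de_l & rnd$mirna_id %in% de_m &
                 rnd$mrna_id %in% de_g, ]
  expect_equal(as.data.frame(got3), as.data.frame(brute))
})

test_that("the correlation filter keeps only strong positive pairs", {
  cand <- tibble::tibble(
    lncrna_id = c("Lpos", "Lneg"), mirna_id = c("m1", "m1"),
    mrna_id = c("Apos", "Aneg")
  )
  expr <- rbind(
    Lpos = c(1, 2, 3), Apos = c(2, 4, 6),
    Lneg = c(1, 2, 3), Aneg = c(6, 4, 2)
  )
  colnames(expr) <- sprintf("s%d", 1:3)
  net <- pearson_filter(cand, expr, label = "toy")
  expect_equal(net$triplets$lncrna_id, "Lpos")
  expect_true(all(net$pair_cor$kept == (net$pair_cor$r > 0.5 &
                                          net$pair_cor$p_value < 0.05)))
  expect_error(pearson_filter(cand, expr[, 1:2]), "3")
})

test_that("surviving pairs satisfy the thresholds when recomputed", {
  set.seed(21)
  ids_l <- sprintf("L%d", 1:8); ids_g <- sprintf("G%d", 1:8)
  cand <- tidyr::expand_grid(lncrna_id = ids_l, mirna_id = "m1",
                             mrna_id = ids_g)
  expr <- matrix(rnorm(16 * 10), nrow = 16,
                 dimnames = list(c(ids_l, ids_g), sprintf("s%d", 1:10)))
  expr["L1", ] <- expr["G1", ] + rnorm(10, sd = 0.1) # one planted pair
  net <- suppressMessages(pearson_filter(cand, expr))
  kept <- net$pair_cor[net$pair_cor$kept, ]
  expect_true(nrow(kept) >= 1)
  for (i in seq_len(nrow(kept))) {
    ct <- cor.test(expr[kept$lncrna_id[i], ], expr[kept$mrna_id[i], ])
    expect_gt(unname(ct$estimate), 0.5)
    expect_lt(ct$p.value, 0.05)
  }
  # triplets are a subset of candidates
  expect_true(all(paste(net$triplets$lncrna_id, net$triplets$mrna_id) %in%
                    paste(cand$lncrna_id, cand$mrna_id)))
})

test_that("hubs are the top 5% by degree with the centre of a star first", {
  trip <- tibble::tibble(
    lncrna_id = sprintf("L%02d", 1:10), mirna_id = "hub",
    mrna_id = sprintf("G%02d", 1:10)
  )
  net <- context_network(trip)
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  top <- topology_report(net)
  expect_equal(sum(top$nodes$is_hub), ceiling(0.05 * 21))
  expect_true("hub" %in% top$nodes$id[top$nodes$is_hub])
  expect_equal(top$nodes$degree[top$nodes$id == "hub"], 20)
})

test_that("an exact inverse-square degree histogram fits with R squared 1", {
  degrees <- rep(c(1, 2, 4, 8), c(256, 64, 16, 4)) # f(k) = 256 k^-2
  fit <- power_law_fit(degrees)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_true(is.na(power_law_fit(c(1, 1, 2))$slope)) # <3 distinct degrees
})

test_that("preferential-attachment degree sequences fit a power law", {
  set.seed(17)
  g <- igraph::sample_pa(400, m = 2, directed = FALSE)
  fit <- power_law_fit(igraph::degree(g))
  expect_gte(fit$r_squared, 0.8)
  expect_lt(fit$slope, -1)
})

test_that("shared interactions equal the brute-force intersection", {
  t1 <- tibble::tibble(lncrna_id = c("L1", "L2"), mirna_id = c("m1", "m2"),
                       mrna_id = c("A", "B"))
  n1 <- context_network(t1)
  expect_equal(nrow(shared_interactions(list(n1, n1))), 2)
  t2 <- tibble::tibble(lncrna_id = "L3", mirna_id = "m3", mrna_id = "C")
  expect_equal(nrow(shared_interactions(list(n1, context_network(t2)))), 0)

  set.seed(5)
  nets <- lapply(1:4, function(i) random_context(5, 5, 5, 60))
  got <- shared_interactions(nets)
  keys <- lapply(nets, function(n) {
    with(n$triplets, paste(lncrna_id, mirna_id, mrna_id))
  })
  brute <- Reduce(intersect, keys)
  expect_setequal(with(got, paste(lncrna_id, mirna_id, mrna_id)), brute)
})

test_that("network exports round-trip node classes", {
  trip <- tibble::tibble(lncrna_id = c("L1", "L2"), mirna_id = "m1",
                         mrna_id = c("A", "B"))
  net <- context_network(trip)
  sif <- tempfile(fileext = ".sif")
  export_sif(net, sif)
  expect_equal(length(readLines(sif)), nrow(net$edges))
  gml <- tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$type[igraph::V(back)$name == "m1"], "miRNA")
  expect_equal(igraph::ecount(back), nrow(net$edges))
})
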