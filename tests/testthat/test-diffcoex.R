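test_that("edge fold change follows the clamp and zero conventions", {
  fc <- edge_fold_change(0.30, 0.15)
  expect_equal(fc$fold_change, 2)
  expect_identical(fc$favored, "domestic")
  expect_equal(edge_fold_change(0.2, 0.2)$fold_change, 1)
  z <- edge_fold_change(0.2, 0)
  expect_identical(z$fold_change, Inf)
  expect_identical(z$favored, "domestic")
  expect_equal(edge_fold_change(0, 0)$fold_change, 1)
  # near-zero weights cannot manufacture fold changes past the clamp
  expect_lt(edge_fold_change(0.001, 0.0001)$fold_change, 1.5)
  expect_error(edge_fold_change(1.2, 0.5), "\\[0, 1\\]")
})

test_that("differential edge lists are empty in degenerate settings", {
  a <- random_symmetric_adjacency(10, seed = 4)^2
  tm <- tom_similarity(a)
  expect_equal(nrow(differential_edges(tm, tm)), 0)
  tm2 <- tom_similarity(random_symmetric_adjacency(10, seed = 5)^2)
  expect_equal(nrow(differential_edges(tm, tm2, fc_threshold = Inf)), 0)
  expect_error(differential_edges(tm, tm2[1:9, 1:9]), "disagree")
  expect_error(differential_edges(tm, tm2, node_universe = "nope"),
               "absent")
})

test_that("differential edges are ordered and correctly annotated", {
  tm1 <- diag(3); tm2 <- diag(3)
  dimnames(tm1) <- dimnames(tm2) <- list(c("b", "a", "c"), c("b", "a", "c"))
  tm1["a", "b"] <- tm1["b", "a"] <- 0.4; tm2["a", "b"] <- tm2["b", "a"] <- 0.1
  tm1["a", "c"] <- tm1["c", "a"] <- 0.1; tm2["a", "c"] <- tm2["c", "a"] <- 0.6
  de <- differential_edges(tm1, tm2)
  expect_identical(de$gene1, c("a", "a"))
  expect_identical(de$gene2, c("b", "c"))
  expect_identical(de$favored, c("domestic", "wild"))
  expect_equal(de$fold_change, c(4, 6))
})

test_that("seed networks honor the floor, roles and planted hubs", {
  seeds <- c("s1", "s2")
  modules <- setNames(c("M1", "M1", "M1", "M1", "M2", "unassigned"),
                      c("s1", "s2", "p1", "p2", "p3", "p4"))
  degs <- c("p1", "p2", "p3", "p4")
  de <- data.frame(
    gene1 = c("s1", "s1", "s2", "p1", "s1"),
    gene2 = c("p1", "p2", "p1", "p2", "s2"),
    weight_domestic = c(0.3, 0.04, 0.2, 0.5, 0.4),
    weight_wild = c(0.05, 0.01, 0.02, 0.1, 0.1),
    fold_change = c(6, 4, 10, 5, 4),
    favored = "domestic", stringsAsFactors = FALSE)
  nets <- build_seed_networks(seeds, modules, degs, de, weight_floor = 0.05)
  d <- nets$domestic
  # s1-p2 fails the floor; p1-p2 is partner-partner; s1-s2 is seed-seed
  expect_equal(nrow(d$edges), 2)
  expect_equal(sort(d$nodes$gene[d$nodes$role == "partner"]),
               c("p1"))
  expect_equal(d$nodes$degree[d$nodes$gene == "s1"], 1)
  expect_equal(d$nodes$degree[d$nodes$gene == "s2"], 1)
  expect_equal(nrow(d$seed_edges), 1)
  expect_equal(nrow(nets$wild$edges), 0)
  expect_error(build_seed_networks("absent", modules, degs, de),
               "no seed gene")
})

test_that("a list of module assignments widens partner candidacy", {
  seeds <- "s1"
  cons <- setNames(c("M1", "unassigned"), c("s1", "p1"))
  wild <- setNames(c("W3", "W3"), c("s1", "p1"))
  de <- data.frame(gene1 = "s1", gene2 = "p1",
                   weight_domestic = 0.4, weight_wild = 0.02,
                   fold_change = 8, favored = "domestic",
                   stringsAsFactors = FALSE)
  solo <- build_seed_networks(seeds, cons, "p1", de)
  expect_equal(nrow(solo$domestic$edges), 0)
  both <- build_seed_networks(seeds, list(cons, wild), "p1", de)
  expect_equal(nrow(both$domestic$edges), 1)
})

test_that("degree table equals an independent recount of edge lists", {
  cfg <- fixture_config()
  sim <- simulate_expression_dataset(cfg$expr, seed = 3)
  fp <- compute_fpkm(sim$counts, sim$gene_length, tmm_factors(sim$counts))
  toms <- lapply(c(domestic = "domestic", wild = "wild"), function(cond) {
    smp <- sim$design$sample[sim$design$condition == cond]
    tom_similarity(soft_adjacency(
      pearson_similarity(log2(fp[, smp] + 1)), 16))
  })
  seeds <- sim$truth$seed_genes
  partners <- sim$truth$de_genes$gene
  de <- differential_edges(toms$domestic, toms$wild,
                           union(seeds, partners))
  nets <- build_seed_networks(seeds, sim$truth$module_labels, partners, de)
  degrees <- seed_degree_table(nets)
  for (i in seq_len(nrow(degrees))) {
    e <- nets$domestic$edges
    expect_equal(degrees$degree_domestic[i],
                 sum(e$gene1 == degrees$seed[i] |
                       e$gene2 == degrees$seed[i]))
  }
})

test_that("swapping the TOMs swaps the two networks", {
  cfg <- fixture_config()
  sim <- simulate_expression_dataset(cfg$expr, seed = 3)
  fp <- compute_fpkm(sim$counts, sim$gene_length, tmm_factors(sim$counts))
  toms <- lapply(c(domestic = "domestic", wild = "wild"), function(cond) {
    smp <- sim$design$sample[sim$design$condition == cond]
    tom_similarity(soft_adjacency(
      pearson_similarity(log2(fp[, smp] + 1)), 16))
  })
  seeds <- sim$truth$seed_genes
  partners <- sim$truth$de_genes$gene
  uni <- union(seeds, partners)
  de1 <- differential_edges(toms$domestic, toms$wild, uni)
  de2 <- differential_edges(toms$wild, toms$domestic, uni)
  n1 <- build_seed_networks(seeds, sim$truth$module_labels, partners, de1)
  n2 <- build_seed_networks(seeds, sim$truth$module_labels, partners, de2)
  expect_equal(n1$domestic$edges[, c("gene1", "gene2")],
               n2$wild$edges[, c("gene1", "gene2")])
  expect_equal(n1$wild$edges[, c("gene1", "gene2")],
               n2$domestic$edges[, c("gene1", "gene2")])
})

test_that("pruning by selection genes is exact, idempotent and monotone", {
  seeds <- "s1"
  modules <- setNames(rep("M1", 11), c("s1", paste0("p", 1:10)))
  de <- data.frame(gene1 = "s1", gene2 = paste0("p", 1:10),
                   weight_domestic = 0.4, weight_wild = 0.01,
                   fold_change = 8, favored = "domestic",
                   stringsAsFactors = FALSE)
  nets <- build_seed_networks(seeds, modules, paste0("p", 1:10), de)
  expect_equal(nets$domestic$nodes$degree[1], 10)
  kept <- prune_by_selection(nets$domestic, paste0("p", 1:10))
  expect_equal(nrow(kept$edges), 10)
  none <- prune_by_selection(nets$domestic, character(0))
  expect_equal(nrow(none$edges), 0)
  expect_identical(none$nodes$gene, "s1")
  three <- prune_by_selection(nets$domestic, paste0("p", 1:3))
  expect_equal(three$nodes$degree[three$nodes$gene == "s1"], 3)
  expect_equal(prune_by_selection(three, paste0("p", 1:3))$nodes,
               three$nodes)
  expect_true(all(three$edges$gene2 %in% nets$domestic$edges$gene2))
})
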