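# Generator contracts: determinism, planted-signal realization,
# monotonicity, validation errors, file round-trips.

test_that("expression simulator is deterministic and validated", {
  cfg <- expression_sim_config(n_genes = 60L, module_sizes = c(20L, 15L))
  s1 <- simulate_expression_dataset(cfg, seed = 7)
  s2 <- simulate_expression_dataset(cfg, seed = 7)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$gene_length, s2$gene_length)
  s3 <- simulate_expression_dataset(cfg, seed = 8)
  expect_false(identical(s1$counts, s3$counts))
  expect_error(expression_sim_config(n_genes = 10L,
                                     module_sizes = c(8L, 8L)),
               "exceeds")
  expect_error(expression_sim_config(dispersion = -1), "dispersion")
  expect_error(expression_sim_config(within_module_cor = 1.4), "\\[0, 1\\]")
  bad_edges <- data.frame(gene1 = "g0001", gene2 = c("g0002", "g0003"),
                          favored = "domestic", coupling = 0.6,
                          group = c("a", "b"))
  cfg_bad <- expression_sim_config(n_genes = 20L,
                                   module_sizes = integer(0),
                                   diff_edges = bad_edges)
  expect_error(simulate_expression_dataset(cfg_bad, 1), "exceeds 1")
})

test_that("noiseless perfectly-coupled modules give |r| ~ 1", {
  # large baseline means so that integer rounding and the log pseudo-count
  # are negligible against the latent signal
  cfg <- expression_sim_config(n_genes = 30L, module_sizes = 10L,
                               within_module_cor = 1, dispersion = 0,
                               replicate_noise_share = 0, amplitude = 1,
                               base_mean_range = c(5000, 10000),
                               library_size_range = c(4e6, 4e6))
  sim <- simulate_expression_dataset(cfg, seed = 2)
  lab <- sim$truth$module_labels
  m <- log2(sim$counts[names(lab)[lab == "M1"], ] + 1)
  r <- abs(cor(t(m)))
  expect_gt(min(r[upper.tri(r)]), 0.999)
})

test_that("planted modules separate within from between correlations", {
  cfg <- expression_sim_config(n_genes = 150L,
                               module_sizes = c(50L, 50L, 50L),
                               within_module_cor = 0.9,
                               dispersion = 0.05)
  sim <- simulate_expression_dataset(cfg, seed = 1)
  lab <- sim$truth$module_labels
  r <- abs(cor(t(log2(sim$counts + 1))))
  within <- c(); between <- c()
  for (m in c("M1", "M2", "M3")) {
    idx <- which(lab == m)
    within <- c(within, r[idx, idx][upper.tri(r[idx, idx])])
    between <- c(between, as.vector(r[idx, which(lab != m)]))
  }
  expect_gte(mean(within) - mean(between), 0.4)
})

test_that("raising within-module correlation raises realized |r|", {
  realized <- vapply(c(0.3, 0.6, 0.9), function(rho) {
    cfg <- expression_sim_config(n_genes = 60L, module_sizes = 30L,
                                 within_module_cor = rho)
    sim <- simulate_expression_dataset(cfg, seed = 4)
    lab <- sim$truth$module_labels
    m <- log2(sim$counts[names(lab)[lab == "M1"], ] + 1)
    r <- abs(cor(t(m)))
    mean(r[upper.tri(r)])
  }, 0)
  expect_true(all(diff(realized) > 0))
})

test_that("planted DE shifts the domestic mean by the stated log2FC", {
  de <- data.frame(gene = c("g0001", "g0002"), stages = c("all", "0p"),
                   log2fc = c(2, -3))
  cfg <- expression_sim_config(n_genes = 40L, module_sizes = integer(0),
                               amplitude = 0, dispersion = 0,
                               library_size_range = c(200000, 200000),
                               de_genes = de)
  sim <- simulate_expression_dataset(cfg, seed = 3)
  d <- sim$design
  dom0 <- sim$counts[, d$condition == "domestic" & d$stage == "0p"]
  wld0 <- sim$counts[, d$condition == "wild" & d$stage == "0p"]
  expect_equal(log2(rowMeans(dom0)["g0001"] / rowMeans(wld0)["g0001"]),
               c(g0001 = 2), tolerance = 0.01)
  expect_equal(log2(rowMeans(dom0)["g0002"] / rowMeans(wld0)["g0002"]),
               c(g0002 = -3), tolerance = 0.01)
  domw <- sim$counts[, d$condition == "domestic" & d$stage == "w"]
  wldw <- sim$counts[, d$condition == "wild" & d$stage == "w"]
  expect_equal(log2(domw["g0002"] / wldw["g0002"]), c(g0002 = 0),
               tolerance = 0.01)
})

test_that("expression files round-trip losslessly", {
  cfg <- expression_sim_config(n_genes = 25L, module_sizes = 10L)
  sim <- simulate_expression_dataset(cfg, seed = 12)
  dir <- withr::local_tempdir()
  write_expression_dataset(sim, dir)
  back <- read_expression_dataset(dir)
  expect_equal(back$counts, sim$counts)
  expect_equal(back$gene_length, sim$gene_length)
  expect_equal(back$design$sample, sim$design$sample)
})

test_that("genotype simulator is deterministic with valid sweeps only", {
  cfg <- genotype_sim_config(chrom_length = 200000L, snp_density = 0.001)
  g1 <- simulate_genotype_panels(cfg, seed = 3)
  g2 <- simulate_genotype_panels(cfg, seed = 3)
  expect_identical(g1$panel1$geno, g2$panel1$geno)
  expect_identical(g1$panel2$sites, g2$panel2$sites)
  expect_error(genotype_sim_config(sweep_intervals = data.frame(
    start = c(0, 500), end = c(1000, 1500), factor = 2, boost = 0)),
    "overlap")
  expect_error(genotype_sim_config(sweep_intervals = data.frame(
    start = 0, end = 1000, factor = 0.5, boost = 0)), "factor")
})

test_that("null genotype configuration centers the pi ratio at 1", {
  cfg <- genotype_sim_config(chrom_length = 2000000L, snp_density = 0.004)
  g <- simulate_genotype_panels(cfg, seed = 9)
  ws <- window_stats(g$panel1, g$panel2, 50000, 50000, g$chrom_lengths)
  expect_gt(median(ws$pi_ratio, na.rm = TRUE), 0.85)
  expect_lt(median(ws$pi_ratio, na.rm = TRUE), 1.15)
})

test_that("a planted sweep drops the windowed pi ratio below the
           outside distribution", {
  cfg <- genotype_sim_config(
    chrom_length = 3000000L, snp_density = 0.004,
    sweep_intervals = data.frame(start = 1000000, end = 1300000,
                                 factor = 10, boost = 0.5))
  g <- simulate_genotype_panels(cfg, seed = 7)
  ws <- window_stats(g$panel1, g$panel2, 50000, 25000, g$chrom_lengths)
  inside <- ws$start >= 1000000 & ws$end <= 1300000
  expect_lt(max(ws$pi_ratio[inside], na.rm = TRUE),
            quantile(ws$pi_ratio[!inside], 0.05, na.rm = TRUE))
})

test_that("stronger diversity reduction lowers sweep-window pi", {
  pis <- vapply(c(2, 5, 20), function(f) {
    cfg <- genotype_sim_config(
      chrom_length = 1000000L, snp_density = 0.004,
      sweep_intervals = data.frame(start = 200000, end = 600000,
                                   factor = f, boost = 0))
    g <- simulate_genotype_panels(cfg, seed = 15)
    w <- window_pi(g$panel1, 50000, 50000, g$chrom_lengths)
    mean(w$pi[w$start >= 200000 & w$end <= 600000])
  }, 0)
  expect_true(all(diff(pis) < 0))
})

test_that("annotation generator gives ordered models and planted truth", {
  genes <- sprintf("g%03d", 1:50)
  ann <- simulate_annotation(genes, n_terms = 10,
                             planted_terms = list(T_p = genes[1:8]),
                             mean_terms_per_gene = 0, seed = 3)
  gm <- ann$gene_models
  expect_true(all(diff(gm$start) > 0))
  expect_true(all(gm$end > gm$start))
  expect_true(all(gm$start[-1] >= gm$end[-nrow(gm)]))
  # zero background terms: only the planted term appears
  expect_setequal(unique(ann$annotation$term), "T_p")
  expect_setequal(ann$annotation$gene, genes[1:8])
  ann2 <- simulate_annotation(genes, n_terms = 10,
                              planted_terms = list(T_p = genes[1:8]),
                              mean_terms_per_gene = 0, seed = 3)
  expect_identical(ann2$annotation, ann$annotation)
  expect_error(simulate_annotation(genes, n_terms = 0), "n_terms")
})
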