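write_mini_vcf <- function(path, extra_records = character(0)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "d1", "d2", "w1", "w2", sep = "\t"),
    paste("chr1", 100, ".", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "1/1", sep = "\t"),
    paste("chr1", 200, ".", "C", "T", ".", "PASS", ".", "GT",
          "./.", "./.", "./.", "./.", sep = "\t"),
    extra_records)
  writeLines(lines, path)
  path
}

mini_popmap <- data.frame(sample = c("d1", "d2", "w1", "w2"),
                          population = c("domestic", "domestic",
                                         "wild", "wild"),
                          stringsAsFactors = FALSE)

test_that("VCF reading filters non-SNPs and tallies genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  tri <- paste("chr1", 300, ".", "A", "G,T", ".", "PASS", ".", "GT",
               "0/0", "0/1", "0/2", "1/1", sep = "\t")
  indel <- paste("chr1", 400, ".", "AT", "A", ".", "PASS", ".", "GT",
                 "0/0", "0/1", "0/0", "1/1", sep = "\t")
  write_mini_vcf(path, c(tri, indel))
  panels <- read_vcf_panels(path, mini_popmap)
  expect_equal(panels$n_dropped, 2)
  expect_identical(panels$panel1$population, "domestic")
  # site 100: domestic dosages 0,1; wild 2,2
  expect_equal(unname(panels$panel1$geno[, 1]), c(0L, 1L))
  expect_equal(unname(panels$panel2$geno[, 1]), c(2L, 2L))
  # all-missing site retained but contributes no alleles
  expect_true(all(is.na(panels$panel1$geno[, 2])))
  expect_equal(unname(panels$chrom_lengths["chr1"]), 1000)
  bad <- rbind(mini_popmap, data.frame(sample = "ghost",
                                       population = "wild"))
  expect_error(read_vcf_panels(path, bad), "ghost")
})

test_that("simulated VCF round-trips through the reader", {
  cfg <- genotype_sim_config(n_pop1 = 4L, n_pop2 = 3L,
                             chrom_length = 100000L, snp_density = 0.001,
                             missing_rate = 0.1)
  g <- simulate_genotype_panels(cfg, seed = 6)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_vcf_panels(g, vcf, pm)
  back <- read_vcf_panels(vcf, pm)
  expect_equal(unname(back$panel1$geno), unname(g$panel1$geno))
  expect_equal(unname(back$panel2$geno), unname(g$panel2$geno))
  expect_equal(back$panel1$sites$pos, g$panel1$sites$pos)
  # allele counts agree with a naive line-by-line text parse
  lines <- grep("^chr", readLines(vcf), value = TRUE)
  fields <- strsplit(lines, "\t")
  ac_text <- vapply(fields, function(f) {
    gts <- f[10:13]
    sum(vapply(strsplit(gts, "/"), function(x)
      sum(x == "1"), 0L))
  }, 0L)
  ac_panel <- colSums(g$panel1$geno[1:4, ], na.rm = TRUE)
  expect_equal(unname(ac_text), unname(ac_panel))
})

test_that("window pi matches enumeration and scaling rules", {
  # one SNP, 2 diploid individuals with dosages 1/1: alleles 2/2
  p <- genotype_panel(rbind(c(1), c(1)), "chr1", 50)
  w <- window_pi(p, 100, 100, c(chr1 = 100))
  expect_equal(w$pi, (4 / 6) / 100)
  expect_equal(w$n_snps, 1)
  # empty window
  p2 <- genotype_panel(matrix(integer(0), 2, 0), "chr1", integer(0))
  expect_equal(window_pi(p2, 100, 100, c(chr1 = 100))$pi, 0)
  # doubling the window halves pi
  w2 <- window_pi(p, 200, 200, c(chr1 = 200))
  expect_equal(w2$pi, w$pi / 2)
})

test_that("window pi is invariant to individual relabeling and matches
           the pair-enumeration oracle", {
  rp <- random_panel_pair(6, 5, 40, 50000, seed = 21)
  w <- window_pi(rp$p1, 10000, 5000, rp$chrom_lengths)
  for (i in seq_len(nrow(w))) {
    expect_equal(w$pi[i],
                 oracle_window_pi(rp$p1, w$start[i], w$end[i], 10000),
                 tolerance = 1e-10)
  }
  shuffled <- rp$p1
  set.seed(1)
  shuffled$geno <- shuffled$geno[sample(nrow(shuffled$geno)), ]
  expect_equal(window_pi(shuffled, 10000, 5000, rp$chrom_lengths)$pi,
               w$pi, tolerance = 1e-12)
})

test_that("Fst reproduces closed forms for both estimators", {
  # fixed difference, equal sample sizes, no heterozygotes
  pd <- genotype_panel(matrix(2L, 5, 1), "chr1", 10)
  pw <- genotype_panel(matrix(0L, 5, 1), "chr1", 10)
  wf <- window_fst(pd, pw, 100, 100, c(chr1 = 100))
  expect_equal(wf$fst, 1)
  # Hudson with p = 0.5 in both, 10 alleles each: -2*(0.25/9)/0.5
  gh <- rbind(2, 2, 1, 0, 0)
  ph1 <- genotype_panel(matrix(gh, 5, 1), "chr1", 10)
  ph2 <- genotype_panel(matrix(gh, 5, 1), "chr1", 10)
  hf <- window_fst(ph1, ph2, 100, 100, c(chr1 = 100),
                   estimator = "hudson")
  expect_equal(hf$fst, (0 - 2 * (0.25 / 9)) / 0.5, tolerance = 1e-12)
  expect_lte(hf$fst, 0)   # reported as computed, not clamped
})

test_that("windowed Weir-Cockerham matches the component oracle", {
  rp <- random_panel_pair(7, 6, 60, 80000, seed = 13)
  w <- window_fst(rp$p1, rp$p2, 20000, 10000, rp$chrom_lengths)
  for (i in seq_len(nrow(w))) {
    o <- oracle_window_fst_wc(rp$p1, rp$p2, w$start[i], w$end[i])
    if (is.na(o)) expect_true(is.na(w$fst[i])) else
      expect_equal(w$fst[i], o, tolerance = 1e-10)
  }
  # symmetry under population swap
  w2 <- window_fst(rp$p2, rp$p1, 20000, 10000, rp$chrom_lengths)
  expect_equal(w$fst, w2$fst, tolerance = 1e-12)
})

test_that("selection calls apply the compound strict-quantile rule", {
  null_stats <- data.frame(chrom = "chr1",
                           start = seq(0, 99) * 1000,
                           end = seq(1, 100) * 1000,
                           n_snps = 10,
                           pi_ratio = rep(1, 100), pi_diff = 0,
                           fst = rep(0.1, 100))
  # identical statistics: strict inequalities against own quantiles
  expect_equal(nrow(call_selection_regions(null_stats)$regions), 0)
  planted <- null_stats
  planted$pi_ratio <- 0.8 + 0.4 * (seq_len(100) %% 7) / 7
  planted$fst <- 0.05 + 0.1 * (seq_len(100) %% 11) / 11
  planted$pi_ratio[42] <- 0.01
  planted$fst[42] <- 0.9
  sel <- call_selection_regions(planted)
  expect_equal(sel$outlier_windows, 42L)
  expect_equal(sel$regions$start, 41000)
  # extreme pi but median fst: the AND rule rejects
  only_pi <- planted
  only_pi$fst[42] <- median(only_pi$fst)
  expect_false(42L %in% call_selection_regions(only_pi)$outlier_windows)
  expect_error(call_selection_regions(null_stats[1:10, ]), "20")
})

test_that("relaxing quantiles never shrinks the called set", {
  rp <- random_panel_pair(8, 6, 300, 1000000, seed = 31,
                          missing_rate = 0)
  ws <- window_stats(rp$p1, rp$p2, 50000, 25000, rp$chrom_lengths)
  tight <- call_selection_regions(ws, lower_q = 0.05, upper_q = 0.95)
  loose <- call_selection_regions(ws, lower_q = 0.20, upper_q = 0.80)
  expect_true(all(tight$outlier_windows %in% loose$outlier_windows))
})

test_that("gene overlap respects the half-open convention", {
  regions <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  genes <- data.frame(gene = c("inside", "abut_left", "abut_right",
                               "spans", "other_chrom"),
                      chrom = c("chr1", "chr1", "chr1", "chr1", "chr9"),
                      start = c(1200, 500, 2000, 900, 1200),
                      end = c(1300, 1000, 2600, 2600, 1300),
                      stringsAsFactors = FALSE)
  expect_setequal(overlap_genes(regions, genes), c("inside", "spans"))
  expect_equal(overlap_genes(regions[0, ], genes), character(0))
})

test_that("planted sweep overlaps exactly the expected genes", {
  genes <- data.frame(gene = sprintf("g%02d", 1:20), chrom = "chr1",
                      start = (0:19) * 1000, end = (0:19) * 1000 + 800)
  regions <- data.frame(chrom = "chr1", start = 4500, end = 8200)
  expect_setequal(overlap_genes(regions, genes),
                  c("g05", "g06", "g07", "g08", "g09"))
})
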