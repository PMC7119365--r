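# The packaged synthetic study: one seeded call writes every pipeline
# input (counts, sample sheet, gene lengths, gene models, annotation,
# VCF, population map), the planted truth, and a ready-to-run config.

#' Default fixture configuration for the synthetic study
#'
#' The stated world the simulator emulates: 300 genes; three planted
#' co-expression modules of 40 genes; the six silk-coding seed genes
#' (Fib-H, Fib-L, P25, Sericin1/2/3) in module 1; 12 module-1 DEG
#' partners at |log2FC| = 2; domestic-favored hub couplings on Fib-H and
#' Sericin1, a wild-favored one on P25; a 10 vs 8 individual genotype
#' panel with one 250 kb sweep (10x diversity reduction, 0.5
#' differentiation boost); 40 random annotation terms plus a term planted
#' on module 1.
#'
#' @return list with `expr` ([expression_sim_config()]), `geno`
#'   ([genotype_sim_config()]), `annotation` parameters and
#'   `seed_genes`.
#' @export
fixture_config <- function() {
  seeds <- c("Fib-H" = 1, "Fib-L" = 1, "P25" = 1,
             "Sericin1" = 1, "Sericin2" = 1, "Sericin3" = 1)
  partners <- sprintf("g%04d", 7:18)
  diff_edges <- rbind(
    data.frame(gene1 = "Fib-H", gene2 = partners[1:4],
               favored = "domestic", coupling = 0.95, group = "hub_fibh"),
    data.frame(gene1 = "Sericin1", gene2 = partners[5:8],
               favored = "domestic", coupling = 0.95, group = "hub_ser1"),
    data.frame(gene1 = "P25", gene2 = partners[9:12],
               favored = "wild", coupling = 0.95, group = "hub_p25"))
  de_genes <- data.frame(gene = partners, stages = "all",
                         log2fc = rep(c(2, -2), 6))
  # the seed module is deliberately loose (|r| 0.5): the planted hub
  # couplings then dominate their pairs, while collateral correlation
  # changes to other module members stay below the edge-weight floor
  expr <- expression_sim_config(
    n_genes = 300L, module_sizes = c(40L, 40L, 40L),
    within_module_cor = c(0.5, 0.9, 0.9),
    seed_genes = seeds, diff_edges = diff_edges, de_genes = de_genes,
    dispersion = 0.05)
  geno <- genotype_sim_config(
    n_pop1 = 10L, n_pop2 = 8L, chrom_length = 6000000L,
    snp_density = 0.004,
    sweep_intervals = data.frame(start = 200000, end = 450000,
                                 factor = 10, boost = 0.5))
  list(expr = expr, geno = geno,
       annotation = list(n_terms = 40L, planted = "T_silk"),
       seed_genes = names(seeds))
}

#' Write the complete synthetic study to a directory
#'
#' Emits all pipeline inputs plus `truth.json` and `config.yaml`; the
#' same (fixture, seed) pair always produces byte-identical files.
#'
#' @param dir output directory.
#' @param seed root RNG seed; per-component seeds are derived from it.
#' @param fixture fixture description, see [fixture_config()].
#' @return invisible list with the generated objects and their truth.
#' @export
simulate_study_inputs <- function(dir, seed = 1L,
                                  fixture = fixture_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression_dataset(fixture$expr,
                                     derive_seed(seed, "expression"))
  write_expression_dataset(sim, dir)
  geno <- simulate_genotype_panels(fixture$geno,
                                   derive_seed(seed, "genotypes"))
  write_vcf_panels(geno, file.path(dir, "panel.vcf"),
                   file.path(dir, "popmap.tsv"))
  m1 <- names(sim$truth$module_labels)[sim$truth$module_labels == "M1"]
  planted <- setNames(list(m1), fixture$annotation$planted)
  ann <- simulate_annotation(rownames(sim$counts),
                             n_terms = fixture$annotation$n_terms,
                             planted_terms = planted,
                             chrom = fixture$geno$chrom,
                             chrom_length = fixture$geno$chrom_length,
                             seed = derive_seed(seed, "annotation"))
  write_tsv_table(ann$annotation, file.path(dir, "annotation.tsv"))
  write_tsv_table(ann$gene_models, file.path(dir, "gene_models.tsv"),
                  comment = "coordinates: 0-based half-open [start, end)")
  truth <- c(sim$truth, geno$truth, ann$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  # beta 16 is the paper-mode default; the tree cut sits at 0.97,
  # between the within-module merge heights (~0.95 for planted |r| = 0.9
  # at this network size) and the chance-correlation noise floor (~0.995
  # with 7 stages).  min_module_size 5 lets the five-gene silk hubs be
  # detected as modules in their favored condition.
  cfg <- list(counts = "counts.tsv", samples = "samples.tsv",
              genes = "genes.tsv", gene_models = "gene_models.tsv",
              vcf = "panel.vcf", popmap = "popmap.tsv",
              annotation = "annotation.tsv", out_dir = "results",
              beta = 16, cut_height = 0.97, min_module_size = 5,
              seed = seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(expression = sim, genotypes = geno, annotation = ann,
                 truth = truth))
}
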