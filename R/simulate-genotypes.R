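# Two-population genotype panel simulator with planted selective sweeps.
#
# Sites are independent (no LD): a shared ancestral frequency q is drawn
# from a U-shaped Beta spectrum and population frequencies follow a
# Balding-Nichols Beta around q (background differentiation).  Inside a
# sweep interval the population-1 (domestic) frequency is first pushed
# toward the allele that is rare in population 2 (differentiation boost),
# then compressed toward fixation so its expected heterozygosity drops by
# the requested diversity-reduction factor.  Genotypes are binomial(2, p)
# per diploid individual.

#' Configuration for the genotype simulator
#'
#' @param n_pop1 diploid individuals in population 1 (domestic); default
#'   10 as in the resequencing panel being emulated.
#' @param n_pop2 diploid individuals in population 2 (wild); default 8.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param snp_density expected SNPs per bp.
#' @param background_fst drift parameter of the Balding-Nichols model
#'   (typical between-population differentiation outside sweeps).
#' @param sweep_intervals data.frame with columns start, end (0-based
#'   half-open), factor (diversity reduction, >= 1) and boost
#'   (differentiation boost in \[0,1\]); intervals must not overlap.
#' @param missing_rate per-genotype missing-call probability.
#' @return validated config object (class `genotype_sim_config`).
#' @export
genotype_sim_config <- function(n_pop1 = 10L, n_pop2 = 8L,
                                chrom = "chr1", chrom_length = 6000000L,
                                snp_density = 0.004,
                                background_fst = 0.05,
                                sweep_intervals = NULL,
                                missing_rate = 0) {
  if (!is.null(sweep_intervals)) {
    need <- c("start", "end", "factor", "boost")
    if (!all(need %in% names(sweep_intervals)))
      stop("sweep_intervals needs columns: ", paste(need, collapse = ", "))
    if (any(sweep_intervals$factor < 1)) stop("sweep factor must be >= 1")
    if (any(sweep_intervals$boost < 0 | sweep_intervals$boost > 1))
      stop("sweep boost must lie in [0, 1]")
    if (any(sweep_intervals$start < 0 |
            sweep_intervals$end > chrom_length) ||
        any(sweep_intervals$end <= sweep_intervals$start))
      stop("sweep intervals must lie within [0, chrom_length)")
    s <- sweep_intervals[order(sweep_intervals$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("sweep intervals overlap")
  }
  structure(list(n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
                 chrom = chrom, chrom_length = as.integer(chrom_length),
                 snp_density = snp_density, background_fst = background_fst,
                 sweep_intervals = sweep_intervals,
                 missing_rate = missing_rate),
            class = "genotype_sim_config")
}

# move p toward the nearer of {0,1} so that heterozygosity 2p(1-p) is
# divided by `factor`
compress_frequency <- function(p, factor) {
  disc <- pmax(0, 0.25 - p * (1 - p) / factor)
  ifelse(p <= 0.5, 0.5 - sqrt(disc), 0.5 + sqrt(disc))
}

#' Simulate a two-population genotype panel with planted sweeps
#'
#' @param config see [genotype_sim_config()].
#' @param seed RNG seed.
#' @return list with `panel1`, `panel2` (each a `genotype_panel`: sites
#'   data.frame plus an individuals x sites dosage matrix in 0/1/2 with NA
#'   for missing), `chrom_lengths` (named vector) and `truth`
#'   (sweep intervals).
#' @export
simulate_genotype_panels <- function(config, seed = 1L) {
  stopifnot(inherits(config, "genotype_sim_config"))
  set.seed(as.integer(seed))
  L <- config$chrom_length
  n_sites <- round(L * config$snp_density)
  pos <- sort(sample.int(L, n_sites))        # 1-based positions
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  F <- config$background_fst
  q <- pmin(0.98, pmax(0.02, rbeta(n_sites, 0.7, 0.7)))
  a <- q * (1 - F) / F
  b <- (1 - q) * (1 - F) / F
  p1 <- rbeta(n_sites, a, b)
  p2 <- rbeta(n_sites, a, b)

  sw <- config$sweep_intervals
  if (!is.null(sw)) {
    for (i in seq_len(nrow(sw))) {
      # 0-based half-open interval [start, end) vs 1-based positions
      inside <- pos > sw$start[i] & pos <= sw$end[i]
      if (!any(inside)) next
      bo <- sw$boost[i]
      far <- ifelse(p2[inside] >= 0.5, 0, 1)   # allele rare in pop 2
      p_b <- (1 - bo) * p1[inside] + bo * far
      p1[inside] <- compress_frequency(p_b, sw$factor[i])
    }
  }

  draw_panel <- function(n_ind, p, pop_label) {
    geno <- matrix(rbinom(n_ind * n_sites, 2L, rep(p, each = n_ind)),
                   nrow = n_ind)
    if (config$missing_rate > 0) {
      miss <- matrix(runif(n_ind * n_sites) < config$missing_rate,
                     nrow = n_ind)
      geno[miss] <- NA_integer_
    }
    individuals <- sprintf("%s%02d", pop_label, seq_len(n_ind))
    rownames(geno) <- individuals
    structure(list(
      population = pop_label,
      individuals = individuals,
      sites = data.frame(chrom = config$chrom, pos = pos,
                         ref = ref, alt = alt, stringsAsFactors = FALSE),
      geno = geno), class = "genotype_panel")
  }
  panel1 <- draw_panel(config$n_pop1, p1, "D")
  panel2 <- draw_panel(config$n_pop2, p2, "W")
  list(panel1 = panel1, panel2 = panel2,
       chrom_lengths = setNames(L, config$chrom),
       truth = list(sweep_intervals = sw))
}

gt_string <- function(dosage) {
  out <- rep("./.", length(dosage))
  out[!is.na(dosage) & dosage == 0L] <- "0/0"
  out[!is.na(dosage) & dosage == 1L] <- "0/1"
  out[!is.na(dosage) & dosage == 2L] <- "1/1"
  out
}

#' Write a two-population panel as VCF v4.2 plus a population map
#'
#' @param panels result of [simulate_genotype_panels()].
#' @param vcf_path output VCF path (plain text).
#' @param popmap_path output population map TSV (sample, population).
#' @return `vcf_path`, invisibly.
#' @export
write_vcf_panels <- function(panels, vcf_path, popmap_path) {
  p1 <- panels$panel1; p2 <- panels$panel2
  stopifnot(identical(p1$sites$pos, p2$sites$pos))
  samples <- c(p1$individuals, p2$individuals)
  con <- file(vcf_path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>",
                       names(panels$chrom_lengths)[1],
                       panels$chrom_lengths[1]),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  gt1 <- apply(p1$geno, 2, gt_string)
  gt2 <- apply(p2$geno, 2, gt_string)
  body <- paste(p1$sites$chrom, p1$sites$pos, ".", p1$sites$ref,
                p1$sites$alt, ".", "PASS", ".", "GT",
                apply(cbind(t(gt1), t(gt2)), 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con)
  write_tsv_table(data.frame(sample = samples,
                             population = c(rep("domestic", nrow(p1$geno)),
                                            rep("wild", nrow(p2$geno)))),
                 popmap_path)
  invisible(vcf_path)
}
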