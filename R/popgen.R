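# Sliding-window nucleotide diversity and Fst from a two-population SNP
# panel, compound empirical-quantile calls of artificial-selection
# regions, and gene overlap.  Coordinates: VCF positions are 1-based;
# windows and gene models use 0-based half-open intervals.

#' Read a two-population VCF into genotype panels
#'
#' Biallelic SNP records are kept (multi-allelic and non-SNP records are
#' dropped and counted) and genotypes are tabulated per population as
#' alt-allele dosages.
#'
#' @param vcf_path VCF v4.2 file with GT fields.
#' @param popmap data.frame (sample, population) or path to such a TSV;
#'   exactly two populations, every mapped sample must be in the VCF.
#' @return list with `panel1` (first population, alphabetically
#'   "domestic" first), `panel2`, `chrom_lengths` (from contig headers,
#'   NA if absent), `n_dropped`.
#' @export
read_vcf_panels <- function(vcf_path, popmap) {
  if (is.character(popmap)) popmap <- read_tsv_table(popmap)
  pops <- unique(popmap$population)
  if (length(pops) != 2) stop("population map must define 2 populations")
  if ("domestic" %in% pops) pops <- c("domestic", setdiff(pops, "domestic"))
  vcf <- VariantAnnotation::readVcf(vcf_path)
  miss <- setdiff(popmap$sample, colnames(vcf))
  if (length(miss) > 0)
    stop("samples in population map absent from VCF: ",
         paste(miss, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  snp <- lengths(altl) == 1 & nchar(ref) == 1
  alt1 <- rep(NA_character_, length(ref))
  alt1[snp] <- as.character(unlist(altl[snp]))
  snp <- snp & !is.na(alt1) & nchar(alt1) == 1 &
    alt1 %in% c("A", "C", "G", "T")
  n_dropped <- sum(!snp)
  vcf <- vcf[snp]
  rr <- rr[snp]
  gt <- VariantAnnotation::geno(vcf)$GT
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  dosage[gt %in% c("0/0", "0|0")] <- 0L
  dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt %in% c("1/1", "1|1")] <- 2L
  sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      ref = as.character(rr$REF),
                      alt = alt1[snp],
                      stringsAsFactors = FALSE)
  sl <- GenomeInfoDb::seqlengths(vcf)
  make_panel <- function(pop) {
    ids <- popmap$sample[popmap$population == pop]
    structure(list(population = pop, individuals = ids,
                   sites = sites,
                   geno = t(dosage[, ids, drop = FALSE])),
              class = "genotype_panel")
  }
  list(panel1 = make_panel(pops[1]), panel2 = make_panel(pops[2]),
       chrom_lengths = sl, n_dropped = n_dropped)
}

#' Construct a genotype panel from a dosage matrix
#'
#' @param geno individuals x sites matrix of alt-allele dosages (0/1/2,
#'   NA = missing call).
#' @param chrom,pos site coordinates (pos is 1-based, as in VCF).
#' @param population population label.
#' @param ref,alt alleles (defaults A/G).
#' @return a `genotype_panel`.
#' @export
genotype_panel <- function(geno, chrom, pos, population = "pop",
                           ref = "A", alt = "G") {
  geno <- as.matrix(geno)
  if (ncol(geno) != length(pos)) stop("one column per site required")
  structure(list(
    population = population,
    individuals = rownames(geno) %||% paste0("i", seq_len(nrow(geno))),
    sites = data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
                       ref = rep_len(ref, length(pos)),
                       alt = rep_len(alt, length(pos)),
                       stringsAsFactors = FALSE),
    geno = geno), class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-site summaries from a panel: non-missing allele number, alt allele
# count, observed heterozygote count, called individuals
panel_site_stats <- function(panel) {
  g <- panel$geno
  called <- colSums(!is.na(g))
  data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
             an = 2L * called,
             ac = colSums(g, na.rm = TRUE),
             n_het = colSums(g == 1L, na.rm = TRUE),
             n_ind = called, stringsAsFactors = FALSE)
}

# sliding window starts (0-based half-open [start, start+size))
window_grid <- function(chrom_lengths, window_size, step) {
  if (step < 1 || window_size < step)
    stop("need window_size >= step >= 1")
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (is.na(len) || len < window_size) return(NULL)
    starts <- seq(0L, len - window_size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + window_size,
               stringsAsFactors = FALSE)
  }))
}

# assign each site (1-based pos) to the windows containing it and
# aggregate `values` (a data.frame) with colSums
aggregate_windows <- function(sites_pos, chrom, values, grid, step,
                              window_size) {
  agg <- matrix(0, nrow(grid), ncol(values),
                dimnames = list(NULL, colnames(values)))
  n_snps <- integer(nrow(grid))
  grid_key <- split(seq_len(nrow(grid)), grid$chrom)
  for (ch in names(grid_key)) {
    gi <- grid_key[[ch]]
    sel <- which(chrom == ch)
    if (length(sel) == 0) next
    pos0 <- sites_pos[sel] - 1L           # 0-based site coordinate
    # window indices within this chromosome covering pos0
    first <- pmax(0L, floor((pos0 - window_size) / step) + 1L)
    last <- floor(pos0 / step)
    for (j in seq_along(sel)) {
      wi <- first[j]:last[j]
      wi <- wi[wi < length(gi)]
      wi <- wi[grid$start[gi[wi + 1L]] <= pos0[j]]
      rows <- gi[wi + 1L]
      if (length(rows) == 0) next
      n_snps[rows] <- n_snps[rows] + 1L
      agg[rows, ] <- agg[rows, , drop = FALSE] +
        rep(as.numeric(values[sel[j], ]), each = length(rows))
    }
  }
  list(agg = as.data.frame(agg), n_snps = n_snps)
}

#' Sliding-window nucleotide diversity
#'
#' Per-site unbiased heterozygosity 2p(1-p) * n/(n-1) (n = non-missing
#' allele count) summed over the SNPs in each window and divided by the
#' full window length (all non-SNP positions count as invariant).
#'
#' @param panel a `genotype_panel`.
#' @param window_size,step window size and step in bp.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return data.frame chrom, start, end (0-based half-open), n_snps, pi.
#' @export
window_pi <- function(panel, window_size = 50000, step = 25000,
                      chrom_lengths) {
  st <- panel_site_stats(panel)
  usable <- st$an >= 2
  st <- st[usable, , drop = FALSE]
  p <- st$ac / st$an
  het <- 2 * p * (1 - p) * st$an / (st$an - 1)
  grid <- window_grid(chrom_lengths, window_size, step)
  ag <- aggregate_windows(st$pos, st$chrom, data.frame(het = het),
                          grid, step, window_size)
  data.frame(grid, n_snps = ag$n_snps,
             pi = ag$agg$het / window_size,
             n_skipped_sites = sum(!usable),
             stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) two-population variance components for one or
# more sites; inputs are per-site vectors.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Hudson/Bhatia estimator components; n1/n2 are allele counts.
hudson_components <- function(n1, p1, n2, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Sliding-window Fst between two panels
#'
#' Ratio-of-sums windowed Fst over the position intersection of the two
#' panels.  Default estimator is Weir-Cockerham (diploid, two
#' populations); `"hudson"` uses the Bhatia form with allele counts.
#' Negative values are reported as computed; windows without usable SNPs
#' are NA.
#'
#' @param panel_d,panel_w `genotype_panel` objects.
#' @param window_size,step window size and step in bp.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param estimator `"weir_cockerham"` or `"hudson"`.
#' @return data.frame chrom, start, end, n_snps, fst.
#' @export
window_fst <- function(panel_d, panel_w, window_size = 50000,
                       step = 25000, chrom_lengths,
                       estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  s1 <- panel_site_stats(panel_d)
  s2 <- panel_site_stats(panel_w)
  key1 <- paste(s1$chrom, s1$pos)
  key2 <- paste(s2$chrom, s2$pos)
  common <- intersect(key1, key2)
  i1 <- match(common, key1)
  i2 <- match(common, key2)
  s1 <- s1[i1, , drop = FALSE]
  s2 <- s2[i2, , drop = FALSE]
  ok <- s1$an >= 2 & s2$an >= 2
  s1 <- s1[ok, , drop = FALSE]
  s2 <- s2[ok, , drop = FALSE]
  p1 <- s1$ac / s1$an
  p2 <- s2$ac / s2$an
  if (estimator == "weir_cockerham") {
    comp <- wc_components(s1$n_ind, p1, s1$n_het / s1$n_ind,
                          s2$n_ind, p2, s2$n_het / s2$n_ind)
    vals <- data.frame(num = comp$a, den = comp$a + comp$b + comp$c)
  } else {
    comp <- hudson_components(s1$an, p1, s2$an, p2)
    vals <- data.frame(num = comp$num, den = comp$den)
  }
  grid <- window_grid(chrom_lengths, window_size, step)
  ag <- aggregate_windows(s1$pos, s1$chrom, vals, grid, step, window_size)
  fst <- ifelse(ag$n_snps > 0 & ag$agg$den != 0,
                ag$agg$num / ag$agg$den, NA_real_)
  data.frame(grid, n_snps = ag$n_snps, fst = fst,
             stringsAsFactors = FALSE)
}

#' Combined per-window statistics for a two-population comparison
#'
#' @inheritParams window_fst
#' @return data.frame chrom, start, end, n_snps, pi_d, pi_w, pi_ratio
#'   (NA when pi_w = 0), pi_diff, fst.
#' @export
window_stats <- function(panel_d, panel_w, window_size = 50000,
                         step = 25000, chrom_lengths,
                         estimator = "weir_cockerham") {
  pd <- window_pi(panel_d, window_size, step, chrom_lengths)
  pw <- window_pi(panel_w, window_size, step, chrom_lengths)
  fs <- window_fst(panel_d, panel_w, window_size, step, chrom_lengths,
                   estimator)
  data.frame(pd[, c("chrom", "start", "end")],
             n_snps = fs$n_snps,
             pi_d = pd$pi, pi_w = pw$pi,
             pi_ratio = ifelse(pw$pi > 0, pd$pi / pw$pi, NA_real_),
             pi_diff = pd$pi - pw$pi,
             fst = fs$fst, stringsAsFactors = FALSE)
}

#' Call artificial-selection regions by the compound quantile rule
#'
#' A window is an outlier iff its pi statistic (domestic/wild ratio or
#' difference) lies strictly below the `lower_q` empirical quantile and
#' its Fst strictly above the `upper_q` quantile of the defined windows'
#' own distributions; adjacent or overlapping outlier windows are merged.
#'
#' @param stats output of [window_stats()].
#' @param pi_stat `"ratio"` or `"diff"`.
#' @param lower_q,upper_q quantile thresholds (defaults 0.05 / 0.95).
#' @return list with `regions` (data.frame chrom, start, end),
#'   `thresholds`, `outlier_windows` (row indices into `stats`).
#' @export
call_selection_regions <- function(stats, pi_stat = c("ratio", "diff"),
                                   lower_q = 0.05, upper_q = 0.95) {
  pi_stat <- match.arg(pi_stat)
  x <- if (pi_stat == "ratio") stats$pi_ratio else stats$pi_diff
  defined <- !is.na(x) & !is.na(stats$fst)
  if (sum(defined) < 20)
    stop("fewer than 20 defined windows; empirical quantiles meaningless")
  thr_lo <- quantile(x[defined], lower_q, names = FALSE)
  thr_hi <- quantile(stats$fst[defined], upper_q, names = FALSE)
  out <- defined & x < thr_lo & stats$fst > thr_hi
  idx <- which(out)
  regions <- NULL
  if (length(idx) > 0) {
    o <- stats[idx, c("chrom", "start", "end")]
    o <- o[order(o$chrom, o$start), ]
    merged <- o[1, ]
    if (nrow(o) > 1) for (i in 2:nrow(o)) {
      last <- nrow(merged)
      if (o$chrom[i] == merged$chrom[last] &&
          o$start[i] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], o$end[i])
      } else {
        merged <- rbind(merged, o[i, ])
      }
    }
    rownames(merged) <- NULL
    regions <- merged
  } else {
    regions <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
  }
  list(regions = regions,
       thresholds = c(pi = thr_lo, fst = thr_hi),
       outlier_windows = idx)
}

#' Genes overlapping called selection regions
#'
#' A gene is selected iff its 0-based half-open interval intersects any
#' region by at least 1 bp (exact abutment does not count).
#'
#' @param regions data.frame chrom, start, end (0-based half-open), e.g.
#'   `call_selection_regions()$regions`.
#' @param gene_models data.frame gene, chrom, start, end (same
#'   convention).
#' @return character vector of selected gene ids.
#' @export
overlap_genes <- function(regions, gene_models) {
  if (nrow(regions) == 0) return(character(0))
  gr_r <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  gr_g <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start + 1L, gene_models$end))
  hits <- GenomicRanges::findOverlaps(gr_g, gr_r, minoverlap = 1L)
  sort(unique(gene_models$gene[S4Vectors::queryHits(hits)]))
}
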