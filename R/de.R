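# Stage-matched domestic-vs-wild differential expression: a
# negative-binomial exact test on library-size-equalized counts, BH
# correction within each stage contrast, and the dual DEG rule
# (adjusted p < 0.05 for replicated stages, < 0.01 for the single-sample
# stages, both with |log2FC| > 1).

#' Method-of-moments common NB dispersion
#'
#' Counts are scaled to a common library size; for every gene and every
#' group with >= 2 replicates the moment estimate
#' max(0, (s^2 - m) / m^2) is formed, gene values are averaged across
#' eligible groups, and the pooled dispersion is the median over genes.
#' The median is robust but biased low for very small replicate numbers
#' (the variance estimate's sampling median sits below its mean).
#'
#' @param counts gene x sample matrix for one contrast.
#' @param groups factor/vector of group membership per sample.
#' @param lib_size per-sample library sizes (default column sums).
#' @return scalar dispersion phi >= 0.
#' @export
estimate_common_dispersion <- function(counts, groups, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  groups <- as.character(groups)
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2]
  if (length(rep_groups) == 0)
    stop("no group with >= 2 replicates; use a fixed dispersion instead")
  y <- sweep(counts, 2, mean(lib_size) / lib_size, "*")
  per_gene <- matrix(NA_real_, nrow(counts), length(rep_groups))
  for (j in seq_along(rep_groups)) {
    yg <- y[, groups == rep_groups[j], drop = FALSE]
    m <- rowMeans(yg)
    v <- apply(yg, 1, var)
    ok <- m > 0
    per_gene[ok, j] <- pmax(0, (v[ok] - m[ok]) / m[ok]^2)
  }
  est <- rowMeans(per_gene, na.rm = TRUE)
  est <- est[is.finite(est)]
  if (length(est) == 0) return(0)
  median(est)
}

#' Negative-binomial exact test for a two-group count comparison
#'
#' Counts are rescaled to the geometric-mean common library size and
#' rounded; conditional on the rescaled total, the two-sided p-value is
#' the summed probability of all group-A sums no more likely than the
#' observed one, with group sums modeled as NB with the given common
#' dispersion.  `dispersion = 0` uses the exact binomial (Poisson) limit.
#'
#' @param counts_a,counts_b count vectors for the two groups.
#' @param lib_a,lib_b library sizes per sample (defaults 1, i.e. counts
#'   already comparable).
#' @param dispersion common NB dispersion phi >= 0.
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(counts_a, counts_b, lib_a = NULL, lib_b = NULL,
                          dispersion = 0) {
  if (any(counts_a < 0) || any(counts_b < 0))
    stop("negative counts")
  if (dispersion < 0) stop("dispersion must be >= 0")
  na <- length(counts_a); nb <- length(counts_b)
  if (na == 0 && nb == 0) stop("empty comparison")
  if (is.null(lib_a)) lib_a <- rep(1, na)
  if (is.null(lib_b)) lib_b <- rep(1, nb)
  common <- exp(mean(log(c(lib_a, lib_b))))
  sa <- sum(round(counts_a * common / lib_a))
  sb <- sum(round(counts_b * common / lib_b))
  t <- sa + sb
  if (t == 0) return(1)
  if (dispersion == 0) {
    prob <- dbinom(0:t, t, na / (na + nb))
  } else {
    mu <- t / (na + nb)
    prob <- dnbinom(0:t, size = na / dispersion, mu = na * mu) *
      dnbinom(t:0, size = nb / dispersion, mu = nb * mu)
    prob <- prob / sum(prob)
  }
  p_obs <- prob[sa + 1]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

#' Run one stage-matched domestic-vs-wild contrast
#'
#' @param counts gene x sample matrix (samples of one stage).
#' @param groups vector with values "domestic"/"wild" per sample.
#' @param lib_size effective library sizes (library size x TMM factor).
#' @param dispersion common dispersion; if `NULL` it is estimated when a
#'   replicated group exists, otherwise `fallback_dispersion` is used.
#' @param fallback_dispersion dispersion for non-replicated contrasts.
#' @param pseudo_count added to each normalized group mean before the
#'   log2 fold-change (default 0.5).
#' @return data.frame gene, log2fc (domestic over wild), p_value,
#'   replicated.
#' @export
de_contrast <- function(counts, groups, lib_size = NULL, dispersion = NULL,
                        fallback_dispersion = 0.1, pseudo_count = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (!all(groups %in% CONDITIONS))
    stop("groups must be 'domestic' or 'wild'")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  ia <- which(groups == "domestic"); ib <- which(groups == "wild")
  replicated <- length(ia) >= 2 && length(ib) >= 2
  if (is.null(dispersion)) {
    dispersion <- if (replicated)
      estimate_common_dispersion(counts, groups, lib_size)
    else fallback_dispersion
  }
  common <- exp(mean(log(lib_size)))
  norm <- sweep(counts, 2, common / lib_size, "*")
  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(g)
    nb_exact_test(counts[g, ia], counts[g, ib],
                  lib_size[ia], lib_size[ib], dispersion), 0)
  data.frame(gene = rownames(counts),
             log2fc = log2((ma + pseudo_count) / (mb + pseudo_count)),
             p_value = p, replicated = replicated,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag differentially expressed genes under the dual criteria
#'
#' DEG iff |log2FC| > 1 and adjusted p < 0.05 (replicated contrast) or
#' < 0.01 (non-replicated contrast); all inequalities strict.
#'
#' @param results data.frame with columns log2fc, adj_p, replicated.
#' @param lfc_cut log2 fold-change threshold (default 1).
#' @param p_replicated,p_single adjusted-p thresholds.
#' @return `results` with added columns is_deg and direction
#'   ("up"/"down" in the domestic condition, NA for non-DEGs).
#' @export
call_degs <- function(results, lfc_cut = 1, p_replicated = 0.05,
                      p_single = 0.01) {
  need <- c("log2fc", "adj_p", "replicated")
  if (!all(need %in% names(results)))
    stop("results needs columns: ", paste(need, collapse = ", "))
  if (anyNA(results$replicated)) stop("missing replication tag")
  cut_p <- ifelse(results$replicated, p_replicated, p_single)
  results$is_deg <- abs(results$log2fc) > lfc_cut & results$adj_p < cut_p
  results$direction <- ifelse(results$is_deg,
                              ifelse(results$log2fc > 0, "up", "down"),
                              NA_character_)
  results
}

#' Stage-by-stage differential expression across the full design
#'
#' Runs [de_contrast()] for every stage, applies BH within each stage
#' family (the study reports DEGs per time point), and flags DEGs.
#'
#' @param counts gene x sample matrix (all samples).
#' @param design sample sheet (sample, condition, stage).
#' @param factors TMM factors (default computed).
#' @param fallback_dispersion dispersion for the non-replicated stages.
#' @return data.frame with one row per gene x stage: gene, stage, log2fc,
#'   p_value, adj_p, replicated, is_deg, direction.
#' @export
run_differential_expression <- function(counts, design, factors = NULL,
                                        fallback_dispersion = 0.1) {
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% design$sample))
    stop("samples missing from design")
  if (is.null(factors)) factors <- tmm_factors(counts)
  d <- design[match(colnames(counts), design$sample), ]
  eff_lib <- colSums(counts) * factors[colnames(counts)]
  out <- lapply(unique(d$stage), function(st) {
    sel <- d$stage == st
    res <- de_contrast(counts[, sel, drop = FALSE], d$condition[sel],
                       eff_lib[sel],
                       fallback_dispersion = fallback_dispersion)
    res$adj_p <- bh_adjust(res$p_value)
    res$stage <- st
    call_degs(res)
  })
  do.call(rbind, out)[, c("gene", "stage", "log2fc", "p_value", "adj_p",
                          "replicated", "is_deg", "direction")]
}
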