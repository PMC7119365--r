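# Random functional annotation and gene models with a planted
# over-represented term, used as ground truth for the enrichment stage.

#' Simulate gene models and a gene-to-term annotation map
#'
#' Genes receive ordered, non-overlapping coordinates along one chromosome
#' and a random number of functional terms; each term in
#' `planted_terms` additionally annotates exactly the designated gene
#' set, making it maximally over-represented there.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_terms number of random background terms (>= 1).
#' @param planted_terms named list: term id -> character vector of genes
#'   it must annotate.
#' @param mean_terms_per_gene Poisson mean of background terms per gene
#'   (0 allowed: genes may end up unannotated).
#' @param chrom,chrom_length coordinate system for the gene models
#'   (0-based half-open intervals).
#' @param seed RNG seed.
#' @return list with `annotation` (data.frame gene, term), `gene_models`
#'   (data.frame gene, chrom, start, end) and `truth` (planted terms).
#' @export
simulate_annotation <- function(gene_ids, n_terms = 50L,
                                planted_terms = NULL,
                                mean_terms_per_gene = 2,
                                chrom = "chr1", chrom_length = 6000000L,
                                seed = 1L) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  if (!is.null(planted_terms)) {
    bad <- setdiff(unlist(planted_terms), gene_ids)
    if (length(bad) > 0)
      stop("planted terms name unknown genes: ", paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  n <- length(gene_ids)
  # one slot per gene; the gene occupies a random sub-interval of its slot
  slot <- floor(chrom_length / n)
  glen <- pmin(slot - 1L, round(runif(n, 0.2, 0.8) * slot))
  start <- (seq_len(n) - 1L) * slot +
    floor(runif(n) * (slot - glen))
  gene_models <- data.frame(gene = gene_ids, chrom = chrom,
                            start = as.integer(start),
                            end = as.integer(start + glen),
                            stringsAsFactors = FALSE)
  terms <- sprintf("T%04d", seq_len(n_terms))
  k <- pmin(rpois(n, mean_terms_per_gene), n_terms)
  ann <- data.frame(gene = rep(gene_ids, k),
                    term = unlist(lapply(k, function(ki)
                      sample(terms, ki))),
                    stringsAsFactors = FALSE)
  if (!is.null(planted_terms)) {
    extra <- data.frame(
      gene = unlist(planted_terms, use.names = FALSE),
      term = rep(names(planted_terms), lengths(planted_terms)),
      stringsAsFactors = FALSE)
    ann <- rbind(ann, extra)
  }
  ann <- unique(ann[order(ann$gene, ann$term), , drop = FALSE])
  rownames(ann) <- NULL
  list(annotation = ann, gene_models = gene_models,
       truth = list(planted_terms = planted_terms))
}
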