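# Hypergeometric over-representation tests with BH correction, and the
# cross-timepoint functional-shift comparison between up- and
# down-regulated gene sets.

#' Hypergeometric term over-representation test
#'
#' For every term, p = P(X >= k) under Hypergeometric(N, K, n) where N is
#' the annotated universe size, K the term size within the universe, n
#' the annotated study size, and k the study hits; BH correction across
#' the tested terms.
#'
#' @param study_genes study gene set (must be a subset of the universe).
#' @param universe_genes background gene set (restricted internally to
#'   annotated genes).
#' @param annotation data.frame with columns gene, term.
#' @param min_term_size smallest term tested (default 2).
#' @return data.frame term, k, n, K, N, fold_enrichment, p, adj_p,
#'   ordered by (p, term).
#' @export
hypergeom_enrich <- function(study_genes, universe_genes, annotation,
                             min_term_size = 2) {
  outside <- setdiff(study_genes, universe_genes)
  if (length(outside) > 0)
    stop("study genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  ann <- annotation[annotation$gene %in% universe_genes, , drop = FALSE]
  universe <- unique(ann$gene)
  study <- intersect(study_genes, universe)
  n_u <- length(universe)
  n_s <- length(study)
  term_genes <- split(ann$gene, ann$term)
  term_genes <- lapply(term_genes, unique)
  term_genes <- term_genes[lengths(term_genes) >= min_term_size]
  if (length(term_genes) == 0)
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      adj_p = numeric(0)))
  k <- vapply(term_genes, function(g) length(intersect(g, study)), 0L)
  K <- lengths(term_genes)
  p <- phyper(k - 1L, K, n_u - K, n_s, lower.tail = FALSE)
  fe <- if (n_s > 0) (k / n_s) / (K / n_u) else rep(NA_real_, length(k))
  res <- data.frame(term = names(term_genes), k = k, n = n_s, K = K,
                    N = n_u, fold_enrichment = fe, p = p,
                    adj_p = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  res[order(res$p, res$term), , drop = FALSE]
}

#' Terms persistently shifted between up- and down-regulated sets
#'
#' A term is up-shifted iff it is significant (adj_p < `sig_cut`) in the
#' up-regulated enrichment at every stage and significant in the
#' down-regulated enrichment at no stage; symmetric for down-shifted.
#'
#' @param up_by_stage,down_by_stage named lists (one
#'   [hypergeom_enrich()] result per stage, same stage names).
#' @param stages stage labels that must all be present.
#' @param sig_cut adjusted-p significance cut (default 0.05).
#' @return data.frame term, direction ("up"/"down").
#' @export
functional_shift <- function(up_by_stage, down_by_stage,
                             stages = STAGES, sig_cut = 0.05) {
  miss <- setdiff(stages, intersect(names(up_by_stage),
                                    names(down_by_stage)))
  if (length(miss) > 0)
    stop("missing enrichment results for stage(s): ",
         paste(miss, collapse = ", "))
  sig_terms <- function(res) res$term[res$adj_p < sig_cut]
  up_sig <- lapply(up_by_stage[stages], sig_terms)
  down_sig <- lapply(down_by_stage[stages], sig_terms)
  always_up <- Reduce(intersect, up_sig)
  never_down <- setdiff(always_up, unique(unlist(down_sig)))
  always_down <- Reduce(intersect, down_sig)
  never_up <- setdiff(always_down, unique(unlist(up_sig)))
  out <- rbind(
    if (length(never_down) > 0)
      data.frame(term = never_down, direction = "up",
                 stringsAsFactors = FALSE),
    if (length(never_up) > 0)
      data.frame(term = never_up, direction = "down",
                 stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(term = character(0), direction = character(0))
  out[order(out$direction, out$term), , drop = FALSE]
}
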