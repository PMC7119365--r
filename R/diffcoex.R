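# Differential co-expression between the domestic and wild networks:
# TOM-weight fold changes, condition-specific networks of silk-coding
# seed genes and their co-expressed DEGs, seed degrees, and pruning by
# artificial-selection genes.

#' Fold change between the two conditions' edge weights
#'
#' FC = max(w) / min(w); for the division the minimum is clamped at
#' `epsilon_floor` (so near-zero weights cannot manufacture huge fold
#' changes), but a true zero minimum with a positive maximum is reported
#' as `Inf`.  Both weights zero gives FC = 1.
#'
#' @param w_d,w_w edge weights in \[0,1\] (vectors allowed).
#' @param epsilon_floor clamp for the denominator (default 0.05).
#' @return data.frame with columns fold_change and favored
#'   ("domestic", "wild" or "none").
#' @export
edge_fold_change <- function(w_d, w_w, epsilon_floor = 0.05) {
  if (any(w_d < 0 | w_d > 1 | w_w < 0 | w_w > 1))
    stop("edge weights must lie in [0, 1]")
  hi <- pmax(w_d, w_w)
  lo <- pmin(w_d, w_w)
  fc <- hi / pmax(lo, epsilon_floor)
  fc[lo == 0 & hi > 0] <- Inf
  fc[hi == 0] <- 1
  favored <- ifelse(w_d > w_w, "domestic",
                    ifelse(w_w > w_d, "wild", "none"))
  data.frame(fold_change = fc, favored = favored,
             stringsAsFactors = FALSE)
}

#' All differentially co-expressed gene pairs
#'
#' Every unordered pair within `node_universe` whose TOM-weight fold
#' change strictly exceeds `fc_threshold` (default 1.5, the
#' differential-co-expression rule), in lexicographic pair order.
#'
#' @param tom_d,tom_w TOM matrices over the same gene index.
#' @param node_universe genes to consider (default: all).
#' @param fc_threshold strict fold-change threshold.
#' @param epsilon_floor see [edge_fold_change()].
#' @return data.frame gene1, gene2, weight_domestic, weight_wild,
#'   fold_change, favored.
#' @export
differential_edges <- function(tom_d, tom_w, node_universe = NULL,
                               fc_threshold = 1.5, epsilon_floor = 0.05) {
  if (!identical(dimnames(tom_d), dimnames(tom_w)) ||
      !identical(dim(tom_d), dim(tom_w)))
    stop("gene indices of the two TOMs disagree")
  genes <- rownames(tom_d)
  if (is.null(node_universe)) node_universe <- genes
  miss <- setdiff(node_universe, genes)
  if (length(miss) > 0)
    stop("node_universe genes absent from TOM: ",
         paste(utils::head(miss, 5), collapse = ", "))
  u <- sort(node_universe)
  td <- tom_d[u, u, drop = FALSE]
  tw <- tom_w[u, u, drop = FALSE]
  idx <- which(upper.tri(td), arr.ind = TRUE)
  fc <- edge_fold_change(td[idx], tw[idx], epsilon_floor)
  keep <- fc$fold_change > fc_threshold
  out <- data.frame(gene1 = u[idx[keep, 1]], gene2 = u[idx[keep, 2]],
                    weight_domestic = td[idx][keep],
                    weight_wild = tw[idx][keep],
                    fold_change = fc$fold_change[keep],
                    favored = fc$favored[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene1, out$gene2), , drop = FALSE]
}

new_condition_network <- function(condition, seeds, edges, seed_edges) {
  partners <- sort(unique(c(edges$gene1, edges$gene2)))
  partners <- setdiff(partners, seeds)
  nodes <- data.frame(gene = c(seeds, partners),
                      role = c(rep("seed", length(seeds)),
                               rep("partner", length(partners))),
                      stringsAsFactors = FALSE)
  nodes$degree <- vapply(nodes$gene, function(g)
    sum(edges$gene1 == g | edges$gene2 == g), 0L)
  structure(list(condition = condition, nodes = nodes, edges = edges,
                 seed_edges = seed_edges), class = "condition_network")
}

#' Condition-specific co-expression networks around the seed genes
#'
#' Candidate partners are DEGs sharing a module with at least one seed
#' gene.  A (seed, partner) edge enters the condition-c network iff it is
#' a differential edge favoring c and its TOM weight in c is at least
#' `weight_floor`.  Seed-seed differential edges are kept in a separate
#' slot and excluded from degrees.
#'
#' @param seeds character vector of silk-coding seed genes.
#' @param module_labels named vector gene -> module (from
#'   [detect_modules()] or [consensus_modules()]), or a list of such
#'   vectors: a partner qualifies if it shares a module with a seed under
#'   ANY of the assignments (a gene strongly re-coupled in one condition
#'   can drop out of the consensus modules yet still co-express with the
#'   seeds in the other condition's network).
#' @param deg_genes character vector of DEG identifiers.
#' @param diff_edges output of [differential_edges()].
#' @param weight_floor minimum TOM weight in the favored condition.
#' @return list with elements `domestic` and `wild`
#'   (`condition_network` objects) plus `missing_seeds`.
#' @export
build_seed_networks <- function(seeds, module_labels, deg_genes,
                                diff_edges, weight_floor = 0.05) {
  assignments <- if (is.list(module_labels)) module_labels
                 else list(module_labels)
  all_genes <- unique(unlist(lapply(assignments, names)))
  present <- intersect(seeds, all_genes)
  if (length(present) == 0)
    stop("no seed gene present in the filtered expression set")
  missing_seeds <- setdiff(seeds, present)
  comember <- unlist(lapply(assignments, function(lab) {
    sm <- setdiff(unique(lab[intersect(present, names(lab))]),
                  "unassigned")
    names(lab)[lab %in% sm]
  }))
  partners <- setdiff(intersect(deg_genes, unique(comember)), present)
  nets <- lapply(CONDITIONS, function(cond) {
    wcol <- if (cond == "domestic") "weight_domestic" else "weight_wild"
    fav <- diff_edges[diff_edges$favored == cond &
                        diff_edges[[wcol]] >= weight_floor, , drop = FALSE]
    sp <- fav[(fav$gene1 %in% present & fav$gene2 %in% partners) |
                (fav$gene2 %in% present & fav$gene1 %in% partners), ,
              drop = FALSE]
    ss <- fav[fav$gene1 %in% present & fav$gene2 %in% present, ,
              drop = FALSE]
    new_condition_network(cond, present, sp, ss)
  })
  names(nets) <- CONDITIONS
  c(nets, list(missing_seeds = missing_seeds))
}

#' Seed-gene degrees per condition
#'
#' @param networks result of [build_seed_networks()].
#' @return data.frame seed, degree_domestic, degree_wild.
#' @export
seed_degree_table <- function(networks) {
  d <- networks$domestic$nodes
  w <- networks$wild$nodes
  seeds <- d$gene[d$role == "seed"]
  data.frame(seed = seeds,
             degree_domestic = d$degree[match(seeds, d$gene)],
             degree_wild = w$degree[match(seeds, w$gene)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Prune a condition network by artificial-selection genes
#'
#' Partner nodes without a selection signature are removed with their
#' edges; seed genes are always retained and degrees recomputed.
#'
#' @param network a `condition_network`.
#' @param selected_genes genes overlapping called selection regions.
#' @return pruned `condition_network`.
#' @export
prune_by_selection <- function(network, selected_genes) {
  stopifnot(inherits(network, "condition_network"))
  seeds <- network$nodes$gene[network$nodes$role == "seed"]
  keep_nodes <- union(seeds, intersect(network$nodes$gene, selected_genes))
  e <- network$edges
  e <- e[e$gene1 %in% keep_nodes & e$gene2 %in% keep_nodes, , drop = FALSE]
  new_condition_network(network$condition, seeds, e, network$seed_edges)
}
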