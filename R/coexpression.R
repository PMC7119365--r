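# Weighted co-expression networks: unsigned Pearson similarity, soft
# thresholding with the approximate scale-free topology criterion,
# topological overlap, average-linkage module detection on 1-TOM, and
# cross-condition consensus modules.

#' Unsigned Pearson similarity matrix
#'
#' s_ij = |cor(x_i, x_j)| across the matrix columns.
#'
#' @param expr gene x column expression matrix (>= 3 columns); genes with
#'   zero variance must be removed first ([remove_nonvarying()]).
#' @return symmetric gene x gene matrix in \[0,1\] with unit diagonal.
#' @export
pearson_similarity <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need >= 3 columns for correlation")
  v <- apply(expr, 1, var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  s <- abs(cor(t(expr)))
  diag(s) <- 1
  s
}

#' Soft-threshold adjacency
#'
#' a_ij = s_ij^beta, element-wise.
#'
#' @param sim similarity matrix in \[0,1\].
#' @param beta soft-threshold power (>= 1).
#' @return adjacency matrix with attribute `beta`.
#' @export
soft_adjacency <- function(sim, beta) {
  if (beta < 1) stop("beta must be >= 1")
  a <- sim^beta
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology fit of a connectivity vector
#'
#' Bins connectivities into equal-width bins and regresses log10 of the
#' per-bin gene frequency on log10 of the per-bin mean connectivity; the
#' fit R^2 is set to 0 when the slope is positive (a scale-free network
#' must have a decreasing degree distribution).
#'
#' @param k per-gene connectivity vector.
#' @param n_bins number of bins (default 10).
#' @return list with `r_squared`, `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) == 0) stop("all connectivities are zero")
  if (length(unique(k)) < 2) return(list(r_squared = 0, slope = 0))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  freq <- as.numeric(table(bin)) / length(k)
  keep <- !is.na(dk) & freq > 0
  if (sum(keep) < 3) return(list(r_squared = 0, slope = 0))
  fit <- lm(log10(freq[keep]) ~ log10(dk[keep]))
  sl <- unname(coef(fit)[2])
  # a perfect log-log fit is a legitimate outcome here, not a modeling
  # accident; silence lm's essentially-perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(r_squared = if (sl > 0) 0 else r2, slope = sl)
}

#' Pick the soft-threshold power by the scale-free criterion
#'
#' For each candidate power the whole-network connectivities are scored
#' with [scale_free_fit()]; the chosen power is the smallest candidate
#' reaching `r2_target`, or the best-fitting candidate if none does.
#'
#' @param sim similarity matrix.
#' @param candidates candidate powers (default 1..20).
#' @param r2_target scale-free fit target (default 0.85).
#' @return list with `beta` (chosen power) and `report` (data.frame
#'   beta, r_squared, slope, mean_connectivity).
#' @export
pick_soft_threshold <- function(sim, candidates = 1:20, r2_target = 0.85) {
  if (nrow(sim) < 30)
    stop("need >= 30 genes for a meaningful scale-free fit")
  report <- do.call(rbind, lapply(candidates, function(b) {
    a <- sim^b
    diag(a) <- 0
    k <- rowSums(a)
    if (all(k == 0)) stop("all connectivities are zero at beta = ", b)
    f <- scale_free_fit(k)
    data.frame(beta = b, r_squared = f$r_squared, slope = f$slope,
               mean_connectivity = mean(k))
  }))
  hit <- which(report$r_squared >= r2_target)
  beta <- if (length(hit) > 0) report$beta[hit[1]] else
    report$beta[which.max(report$r_squared)]
  list(beta = beta, report = report)
}

#' Topological overlap matrix
#'
#' Unsigned TOM: TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij the shared-neighbor term sum_u a_iu a_uj and k the connectivity;
#' the diagonal is 1 by convention.
#'
#' @param adj symmetric adjacency matrix in \[0,1\] (diagonal ignored).
#' @return TOM matrix in \[0,1\].
#' @export
tom_similarity <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) ||
      max(abs(adj - t(adj))) > 1e-8)
    stop("adjacency must be a symmetric square matrix")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a            # L_ij = sum_u a_iu a_uj (u != i,j since diag 0)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# deterministic module labels: by decreasing size, ties broken by the
# lexicographically smallest member gene id
relabel_modules <- function(cl, genes, min_module_size) {
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  first_gene <- vapply(keep, function(x) min(genes[cl == x]), "")
  ord <- keep[order(-sizes[keep], first_gene)]
  lab <- setNames(rep("unassigned", length(cl)), genes)
  for (i in seq_along(ord)) lab[cl == ord[i]] <- paste0("M", i)
  lab
}

#' Detect modules by average-linkage clustering of 1 - TOM
#'
#' Static tree cut: the average-linkage dendrogram of dissimilarity
#' 1 - TOM is cut at `cut_height`; clusters below `min_module_size`
#' fall into the reserved "unassigned" label.  Labels are deterministic:
#' "M1", "M2", ... in decreasing size order.
#'
#' @param tom TOM (or any similarity) matrix.
#' @param cut_height tree cut height on the 1 - TOM scale, in (0, 1).
#' @param min_module_size smallest retained module (>= 2).
#' @return named character vector gene -> module label.
#' @export
detect_modules <- function(tom, cut_height = 0.995, min_module_size = 30) {
  tom <- as.matrix(tom)
  if (nrow(tom) != ncol(tom)) stop("TOM must be square")
  if (cut_height <= 0 || cut_height >= 1) stop("cut_height must be in (0,1)")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  d <- 1 - tom
  tree <- hclust(as.dist(d), method = "average")
  cl <- cutree(tree, h = cut_height)
  relabel_modules(cl, genes, min_module_size)
}

#' Consensus modules across the two condition networks
#'
#' Each TOM is rescaled so its 95th-percentile off-diagonal value matches
#' the smaller of the two (quantile alignment), the consensus TOM is the
#' element-wise minimum, and modules are detected on 1 - consensus as in
#' [detect_modules()].
#'
#' @param tom_d,tom_w TOM matrices over the same gene index.
#' @param cut_height,min_module_size see [detect_modules()].
#' @return named character vector gene -> consensus module label.
#' @export
consensus_modules <- function(tom_d, tom_w, cut_height = 0.995,
                              min_module_size = 30) {
  if (!identical(dimnames(tom_d), dimnames(tom_w)) ||
      !identical(dim(tom_d), dim(tom_w)))
    stop("gene indices of the two TOMs disagree")
  off <- upper.tri(tom_d)
  q_d <- quantile(tom_d[off], 0.95)
  q_w <- quantile(tom_w[off], 0.95)
  target <- min(q_d, q_w)
  cons <- pmin(tom_d * (target / q_d), tom_w * (target / q_w))
  diag(cons) <- 1
  detect_modules(cons, cut_height, min_module_size)
}
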