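# Count normalization and FPKM quantification: weighted trimmed mean of
# M-values (TMM) scaling factors, FPKM transformation, replicate
# collapsing, and the expression filters applied upstream of network
# construction.

#' TMM normalization factors
#'
#' Robinson-Oshlack weighted trimmed mean of M-values: per sample, the
#' per-gene log2 ratios (M) against a reference sample are doubly trimmed
#' (30% of M-values and 5% of A-values on each tail) and averaged with
#' inverse-asymptotic-variance weights.  Genes with a zero count in either
#' sample are excluded from the M/A set.  Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts non-negative gene x sample matrix.
#' @param lib_size per-sample library sizes; defaults to column sums.
#' @param reference reference sample name, or `NULL` for the canonical
#'   automatic choice (sample whose 75th-percentile count fraction is
#'   closest to the mean across samples).
#' @param logratio_trim,sum_trim tail trim fractions for M and A.
#' @return named vector of positive scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_size = NULL, reference = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (is.null(names(lib_size))) names(lib_size) <- colnames(counts)
  zero <- lib_size == 0 | colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  if (is.null(reference)) {
    uq <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib_size
    reference <- colnames(counts)[which.min(abs(uq - mean(uq)))]
  }
  if (!reference %in% colnames(counts))
    stop("unknown reference sample: ", reference)
  xr <- counts[, reference]
  nr <- lib_size[reference]
  f <- vapply(colnames(counts), function(s) {
    if (s == reference) return(1)
    x <- counts[, s]
    n <- lib_size[s]
    keep <- x > 0 & xr > 0
    if (!any(keep)) return(1)
    m <- log2((x[keep] / n) / (xr[keep] / nr))
    a <- 0.5 * log2((x[keep] / n) * (xr[keep] / nr))
    w <- (n - x[keep]) / (n * x[keep]) + (nr - xr[keep]) / (nr * xr[keep])
    ng <- length(m)
    lo_m <- floor(ng * logratio_trim) + 1
    hi_m <- ng + 1 - lo_m
    lo_a <- floor(ng * sum_trim) + 1
    hi_a <- ng + 1 - lo_a
    rm_ <- rank(m, ties.method = "first")
    ra_ <- rank(a, ties.method = "first")
    kept <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(kept) || sum(w[kept]) == 0) return(1)
    2^(sum(w[kept] * m[kept]) / sum(w[kept]))
  }, 0)
  f <- f / exp(mean(log(f)))
  f
}

#' FPKM from counts and normalization factors
#'
#' FPKM(g, s) = count * 1e9 / (length * lib_size * factor); the product
#' lib_size * factor is the TMM-effective sequencing depth.
#'
#' @param counts gene x sample count matrix.
#' @param gene_length named vector of gene lengths in bp (> 0).
#' @param factors per-sample TMM factors (default all 1).
#' @param lib_size per-sample library sizes (default column sums).
#' @return gene x sample FPKM matrix.
#' @export
compute_fpkm <- function(counts, gene_length, factors = NULL,
                         lib_size = NULL) {
  counts <- as.matrix(counts)
  gl <- gene_length[rownames(counts)]
  if (anyNA(gl)) stop("missing gene lengths")
  if (any(gl <= 0)) stop("gene lengths must be positive")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (is.null(names(lib_size))) names(lib_size) <- colnames(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  eff <- lib_size[colnames(counts)] * factors[colnames(counts)]
  sweep(counts / gl, 2, eff, "/") * 1e9
}

#' Average replicate FPKM columns into condition-stage columns
#'
#' Arithmetic mean across replicates of the same (condition, stage);
#' single samples pass through.  Column names become
#' `condition.stage`.
#'
#' @param fpkm gene x sample matrix.
#' @param design sample sheet with columns sample, condition, stage.
#' @return gene x condition-stage matrix.
#' @export
collapse_replicates <- function(fpkm, design) {
  miss <- setdiff(colnames(fpkm), design$sample)
  if (length(miss) > 0)
    stop("samples without a design record: ", paste(miss, collapse = ", "))
  d <- design[match(colnames(fpkm), design$sample), ]
  grp <- paste(d$condition, d$stage, sep = ".")
  out <- vapply(unique(grp), function(g)
    rowMeans(fpkm[, grp == g, drop = FALSE]), numeric(nrow(fpkm)))
  matrix(out, nrow = nrow(fpkm),
         dimnames = list(rownames(fpkm), unique(grp)))
}

#' Remove genes that are lowly expressed in too many samples
#'
#' A gene is dropped iff FPKM < `fpkm_floor` in strictly more than
#' `max_low_samples` samples.
#'
#' @param fpkm gene x sample (or gene x condition-stage) matrix.
#' @param fpkm_floor expression floor (default 1 FPKM).
#' @param max_low_samples tolerated number of low samples (default 10).
#' @return list with `kept` (filtered matrix) and `removed` (gene ids).
#' @export
filter_low_expression <- function(fpkm, fpkm_floor = 1,
                                  max_low_samples = 10) {
  if (fpkm_floor < 0 || max_low_samples < 0)
    stop("thresholds must be >= 0")
  n_low <- rowSums(fpkm < fpkm_floor)
  drop <- n_low > max_low_samples
  list(kept = fpkm[!drop, , drop = FALSE],
       removed = rownames(fpkm)[drop])
}

#' Remove non-varying genes
#'
#' Drops genes with zero variance across columns or more than 50% missing
#' values.
#'
#' @param expr gene x column matrix.
#' @return list with `kept` and `removed`.
#' @export
remove_nonvarying <- function(expr) {
  v <- apply(expr, 1, function(x) var(x, na.rm = TRUE))
  frac_na <- rowMeans(is.na(expr))
  drop <- is.na(v) | v == 0 | frac_na > 0.5
  list(kept = expr[!drop, , drop = FALSE],
       removed = rownames(expr)[drop])
}

#' Tally genes per expression band
#'
#' Counts genes per sample in the low (0 <= FPKM < 1), mid
#' (1 <= FPKM <= 1000) and super-high (FPKM > 1000) bands.
#'
#' @param fpkm gene x sample matrix.
#' @return data.frame with columns sample, low, mid, super_high.
#' @export
classify_expression_levels <- function(fpkm) {
  data.frame(sample = colnames(fpkm),
             low = colSums(fpkm < 1),
             mid = colSums(fpkm >= 1 & fpkm <= 1000),
             super_high = colSums(fpkm > 1000),
             row.names = NULL, stringsAsFactors = FALSE)
}
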