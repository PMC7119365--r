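# Shared helpers: multiple-testing adjustment, clustering agreement,
# deterministic seed derivation, small text-format IO.

#' Benjamini-Hochberg step-up adjustment
#'
#' Single shared FDR routine used by the differential-expression and
#' enrichment stages.  Step-up adjusted values are capped at 1, monotone in
#' rank order, and returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.005))
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] and contain no NA")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1L) * p[o]))[ro]
  adj
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same gene set;
#' used to score recovered co-expression modules against planted truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Derive a stage-specific 31-bit seed from a root seed, so that one root
# seed drives all stages reproducibly but stages are decoupled.
derive_seed <- function(root_seed, label) {
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(paste0(label, ":", root_seed))) {
    h <- bitwXor(as.integer(h), ch)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

# FNV-1a style hash of a character scalar, hex-encoded; used to fingerprint
# configurations in run summaries without a dependency on digest.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h), ch)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Write a data frame as a tab-separated file
#'
#' All pipeline tables are plain TSV with a header row and no quoting.
#'
#' @param df data.frame.
#' @param path output path.
#' @param comment optional character vector written as `# `-prefixed header
#'   lines (used to declare coordinate conventions).
#' @export
write_tsv_table <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table written by silknet
#'
#' @param path file path; `# ` comment lines are skipped.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  first <- readLines(path, n = 50L)
  n_skip <- sum(cumprod(startsWith(first, "# ")))
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = n_skip, data.table = FALSE,
                                  showProgress = FALSE))
}

# Read a genes x samples count TSV (first column = gene id).
read_count_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
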