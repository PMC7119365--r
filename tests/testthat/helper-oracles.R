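# Independent oracle implementations, written as literal transcriptions
# of the underlying formulas (loops, explicit enumeration) and kept free
# of the package's own code paths.

# --- TMM: direct transcription of the weighted-trimmed-mean formula ----
oracle_tmm_factor <- function(x, xr, n, nr,
                              trim_m = 0.3, trim_a = 0.05) {
  keep <- x > 0 & xr > 0
  x <- x[keep]; xr <- xr[keep]
  m <- log2((x / n) / (xr / nr))
  a <- 0.5 * log2((x / n) * (xr / nr))
  w <- (n - x) / (n * x) + (nr - xr) / (nr * xr)
  ng <- length(m)
  lo_m <- floor(ng * trim_m) + 1; hi_m <- ng + 1 - lo_m
  lo_a <- floor(ng * trim_a) + 1; hi_a <- ng + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  sel <- which(rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a)
  2^(sum(w[sel] * m[sel]) / sum(w[sel]))
}

# --- TOM: naive O(n^3) double loop ------------------------------------
oracle_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj; diag(a) <- 0
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(adj)
  out
}

# --- BH: brute-force step-up ------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# --- hypergeometric upper tail by full pmf enumeration ----------------
oracle_hyper_upper <- function(k, K, N, n) {
  num <- 0
  den <- choose(N, n)
  for (j in max(0, n - (N - K)):min(n, K)) {
    if (j >= k) num <- num + choose(K, j) * choose(N - K, n - j)
  }
  num / den
}

# --- window pi by explicit allele-pair enumeration --------------------
oracle_window_pi <- function(panel, start, end, window_size) {
  tot <- 0
  for (s in seq_len(nrow(panel$sites))) {
    pos0 <- panel$sites$pos[s] - 1
    if (pos0 < start || pos0 >= end) next
    g <- panel$geno[, s]
    alleles <- unlist(lapply(g[!is.na(g)], function(d) {
      c(rep(1, d), rep(0, 2 - d))
    }))
    n <- length(alleles)
    if (n < 2) next
    diff <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (alleles[i] != alleles[j]) diff <- diff + 1
    tot <- tot + diff / choose(n, 2)
  }
  tot / window_size
}

# --- per-site Weir-Cockerham a/b/c components (two populations) -------
oracle_wc_site <- function(g1, g2) {
  summ <- function(g) {
    g <- g[!is.na(g)]
    list(n = length(g), p = sum(g) / (2 * length(g)),
         h = mean(g == 1))
  }
  s1 <- summ(g1); s2 <- summ(g2)
  r <- 2
  n_bar <- (s1$n + s2$n) / r
  nc <- (r * n_bar - (s1$n^2 + s2$n^2) / (r * n_bar)) / (r - 1)
  p_bar <- (s1$n * s1$p + s2$n * s2$p) / (r * n_bar)
  s2v <- (s1$n * (s1$p - p_bar)^2 + s2$n * (s2$p - p_bar)^2) /
    ((r - 1) * n_bar)
  h_bar <- (s1$n * s1$h + s2$n * s2$h) / (r * n_bar)
  a <- (n_bar / nc) * (s2v - (1 / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2v - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
    ((r - 1) / r) * s2v - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

oracle_window_fst_wc <- function(p1, p2, start, end) {
  num <- 0; den <- 0
  for (s in seq_len(nrow(p1$sites))) {
    pos0 <- p1$sites$pos[s] - 1
    if (pos0 < start || pos0 >= end) next
    g1 <- p1$geno[, s]; g2 <- p2$geno[, s]
    if (sum(!is.na(g1)) < 1 || sum(!is.na(g2)) < 1) next
    comp <- oracle_wc_site(g1, g2)
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

# --- independent scale-free fit (histogram re-implementation) ---------
oracle_scale_free_scan <- function(sim, candidates, r2_target) {
  best_beta <- NA; best_r2 <- -Inf; chosen <- NA
  for (b in candidates) {
    a <- sim^b; diag(a) <- 0
    k <- rowSums(a); k <- k[k > 0]
    h <- hist(k, breaks = seq(min(k), max(k), length.out = 11),
              plot = FALSE)
    dk <- sapply(seq_len(10), function(i) {
      inb <- k >= h$breaks[i] & (k < h$breaks[i + 1] | i == 10)
      if (any(inb)) mean(k[inb]) else NA
    })
    freq <- h$counts / length(k)
    ok <- !is.na(dk) & freq > 0
    fit <- lm(log10(freq[ok]) ~ log10(dk[ok]))
    r2 <- summary(fit)$r.squared
    if (coef(fit)[2] > 0) r2 <- 0
    if (is.na(chosen) && r2 >= r2_target) chosen <- b
    if (r2 > best_r2) { best_r2 <- r2; best_beta <- b }
  }
  if (!is.na(chosen)) chosen else best_beta
}

# --- small helpers -----------------------------------------------------
random_symmetric_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

random_panel_pair <- function(n1, n2, n_sites, chrom_len, seed,
                              missing_rate = 0.05) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n_sites))
  p <- rbeta(n_sites, 0.8, 0.8)
  draw <- function(n, label) {
    g <- matrix(rbinom(n * n_sites, 2, rep(p, each = n)), nrow = n)
    g[matrix(runif(n * n_sites) < missing_rate, nrow = n)] <- NA
    rownames(g) <- paste0(label, seq_len(n))
    genotype_panel(g, "chr1", pos, label)
  }
  list(p1 = draw(n1, "D"), p2 = draw(n2, "W"),
       chrom_lengths = c(chr1 = chrom_len))
}
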