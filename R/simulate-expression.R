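# Seeded generator for the two-condition (domestic / wild) x seven-stage
# silk-gland expression design, with planted co-expression modules,
# condition-specific edge couplings, and differentially expressed genes.
#
# Generative model: each module m carries a latent stage trajectory
# z_m(stage); gene g in module m has standardized log-signal
#   sqrt(rho) * z_m + sqrt(1 - rho) * eps_g
# so any two module members correlate at rho in expectation.  Differential
# edges add an extra shared latent u to both pair members in the favored
# condition only.  The NB mean is basemean * 2^(amplitude * signal + DE),
# and counts are NB(mean * libsize-factor, phi); phi = 0 is treated as the
# noiseless limit (counts = rounded means), which forces within-module
# sample correlations to 1 when rho = 1.

STAGES <- c("0p", "1p", "2p", "3p", "4p", "5p", "w")
CONDITIONS <- c("domestic", "wild")

#' Default silk-gland sampling design
#'
#' Two conditions (domestic, wild) across the seven fifth-instar stages
#' 0p--5p and wandering (w), with 2 biological replicates at the
#' replicated stages (0p, 1p, 2p, 3p, 5p) and single samples at 4p and w.
#'
#' @param replicated_stages stages sampled in duplicate.
#' @param n_replicates replicate count at replicated stages.
#' @return data.frame with columns sample, condition, stage, replicate.
#' @export
silk_design <- function(replicated_stages = c("0p", "1p", "2p", "3p", "5p"),
                        n_replicates = 2L) {
  rows <- list()
  for (cond in CONDITIONS) {
    for (st in STAGES) {
      nr <- if (st %in% replicated_stages) n_replicates else 1L
      for (r in seq_len(nr)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_%s_r%d", substr(cond, 1, 1), st, r),
          condition = cond, stage = st, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Configuration for the expression simulator
#'
#' @param n_genes total number of genes.
#' @param module_sizes integer vector of planted module sizes; remaining
#'   genes are unstructured background.
#' @param within_module_cor target absolute Pearson correlation between
#'   members of the same module (scalar or one value per module).
#' @param module_conditions per-module activity: `"both"` (default),
#'   `"domestic"` or `"wild"`; a one-condition module has no shared latent
#'   in the other condition.
#' @param seed_genes named integer vector mapping seed-gene names (e.g.
#'   the fibroin/sericin genes) to the module index that hosts them; seeds
#'   replace the first genes of that module and keep their names.
#' @param diff_edges data.frame with columns gene1, gene2, favored
#'   (condition name), coupling (fraction of the genes' noise variance
#'   moved onto the pair's shared latent in the favored condition, in
#'   \[0,1\]; the planted pair correlation there is
#'   rho + (1 - rho) * coupling for module members, `coupling` for
#'   background genes) and optional group (pairs sharing a group id share
#'   one latent, giving hub structures).
#' @param de_genes data.frame with columns gene, stages
#'   (comma-separated stage labels or `"all"`), log2fc (shift applied to
#'   the domestic mean).
#' @param dispersion NB dispersion phi >= 0; 0 means noiseless counts.
#' @param replicate_noise_share fraction of each gene's latent variance
#'   that is replicate-specific rather than stage-specific (biological
#'   replicate variability; at the default amplitude the default 0.04
#'   corresponds to a typical bulk RNA-seq biological coefficient of
#'   variation of roughly 0.3).
#' @param base_mean_range range of per-gene baseline mean counts.
#' @param library_size_range range of target per-sample library sizes.
#' @param gene_length_range range of gene lengths (bp).
#' @param amplitude standard deviation of the log2 latent signal; controls
#'   the dynamic range of stage trajectories.
#' @param design sampling design, see [silk_design()].
#' @return a validated config object (class `expression_sim_config`).
#' @export
expression_sim_config <- function(n_genes = 400L,
                                  module_sizes = c(60L, 50L, 40L),
                                  within_module_cor = 0.8,
                                  module_conditions = NULL,
                                  seed_genes = NULL,
                                  diff_edges = NULL,
                                  de_genes = NULL,
                                  dispersion = 0.05,
                                  replicate_noise_share = 0.04,
                                  base_mean_range = c(50, 500),
                                  library_size_range = c(150000, 250000),
                                  gene_length_range = c(500, 5000),
                                  amplitude = 2,
                                  design = silk_design()) {
  if (sum(module_sizes) > n_genes)
    stop("module sizes sum (", sum(module_sizes), ") exceeds n_genes (",
         n_genes, ")")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (replicate_noise_share < 0 || replicate_noise_share > 1)
    stop("replicate_noise_share must lie in [0, 1]")
  if (any(within_module_cor < 0 | within_module_cor > 1))
    stop("within_module_cor must lie in [0, 1]")
  n_mod <- length(module_sizes)
  rho <- rep_len(within_module_cor, n_mod)
  if (is.null(module_conditions)) module_conditions <- rep("both", n_mod)
  if (length(module_conditions) != n_mod)
    stop("module_conditions must have one entry per module")
  if (!all(module_conditions %in% c("both", CONDITIONS)))
    stop("module_conditions entries must be 'both', 'domestic' or 'wild'")
  if (!is.null(seed_genes)) {
    if (is.null(names(seed_genes)) || any(names(seed_genes) == ""))
      stop("seed_genes must be a named vector (name -> module index)")
    if (any(seed_genes < 1 | seed_genes > n_mod))
      stop("seed gene module index out of range")
    placed <- table(seed_genes)
    if (any(placed > module_sizes[as.integer(names(placed))]))
      stop("more seed genes than slots in a module")
  }
  if (!is.null(diff_edges)) {
    need <- c("gene1", "gene2", "favored", "coupling")
    if (!all(need %in% names(diff_edges)))
      stop("diff_edges needs columns: ", paste(need, collapse = ", "))
    if (!all(diff_edges$favored %in% CONDITIONS))
      stop("diff_edges$favored must be 'domestic' or 'wild'")
    if (any(diff_edges$coupling < 0 | diff_edges$coupling > 1))
      stop("diff_edges$coupling must lie in [0, 1]")
    if (is.null(diff_edges$group))
      diff_edges$group <- paste0("pair", seq_len(nrow(diff_edges)))
  }
  if (!is.null(de_genes)) {
    need <- c("gene", "stages", "log2fc")
    if (!all(need %in% names(de_genes)))
      stop("de_genes needs columns: ", paste(need, collapse = ", "))
  }
  structure(list(
    n_genes = as.integer(n_genes), module_sizes = as.integer(module_sizes),
    within_module_cor = rho, module_conditions = module_conditions,
    seed_genes = seed_genes, diff_edges = diff_edges, de_genes = de_genes,
    dispersion = dispersion,
    replicate_noise_share = replicate_noise_share,
    base_mean_range = base_mean_range,
    library_size_range = library_size_range,
    gene_length_range = gene_length_range, amplitude = amplitude,
    design = design), class = "expression_sim_config")
}

# Orthogonalize latent trajectories across the stage dimension (rows =
# latents, columns = stages): center, successive Gram-Schmidt, rescale to
# unit sample sd.  With only 7 stages, independently drawn trajectories
# can be strongly collinear by chance, which would glue planted modules
# together; orthogonalization makes the planted structure identifiable.
# At most n_stage - 1 centered rows can be mutually orthogonal; excess
# rows are only standardized.
orthogonalize_latents <- function(lat, weights = rep(1, ncol(lat))) {
  if (nrow(lat) == 0) return(lat)
  w <- weights / sum(weights)
  wmean <- function(v) sum(w * v)
  std <- function(v) {
    v <- v - wmean(v)
    s <- sqrt(sum(w * v^2))
    if (s < 1e-8) v else v / s
  }
  for (i in seq_len(nrow(lat))) {
    v <- lat[i, ] - wmean(lat[i, ])
    if (i > 1 && i <= ncol(lat) - 1) {
      for (j in seq_len(i - 1)) {
        u <- lat[j, ]
        v <- v - sum(w * v * u) / sum(w * u * u) * u
      }
    }
    lat[i, ] <- std(v)
  }
  lat
}

# Resolve gene names: modules occupy the head of the index, seeds rename
# their slots, the rest is background.
sim_gene_names <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  labels <- rep("unassigned", config$n_genes)
  offset <- 0L
  for (m in seq_along(config$module_sizes)) {
    idx <- offset + seq_len(config$module_sizes[m])
    labels[idx] <- paste0("M", m)
    offset <- offset + config$module_sizes[m]
  }
  if (!is.null(config$seed_genes)) {
    for (m in unique(config$seed_genes)) {
      slot <- which(labels == paste0("M", m))
      nm <- names(config$seed_genes)[config$seed_genes == m]
      genes[slot[seq_along(nm)]] <- nm
    }
  }
  names(labels) <- genes
  list(genes = genes, labels = labels)
}

#' Simulate a silk-gland expression dataset with planted truth
#'
#' @param config see [expression_sim_config()].
#' @param seed integer RNG seed; identical (config, seed) pairs give
#'   bit-identical output.
#' @return list with elements `counts` (integer gene x sample matrix),
#'   `design`, `gene_length` (named vector, bp), and `truth` (planted
#'   module labels, differential edges, DE genes).
#' @export
simulate_expression_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(as.integer(seed))
  nm <- sim_gene_names(config)
  genes <- nm$genes
  labels <- nm$labels
  design <- config$design
  n_genes <- config$n_genes
  n_stage <- length(STAGES)

  gene_length <- round(runif(n_genes, config$gene_length_range[1],
                             config$gene_length_range[2]))
  names(gene_length) <- genes
  base_mean <- runif(n_genes, config$base_mean_range[1],
                     config$base_mean_range[2])
  lib_target <- round(runif(nrow(design), config$library_size_range[1],
                            config$library_size_range[2]))

  # Latent structure.  Every standardized column process is
  #   sqrt(1 - tau) * X_stage + sqrt(tau) * X_rep
  # with tau = replicate_noise_share: the stage part is shared across
  # replicates (and, for the noise terms, across conditions through the
  # matched replicate index), the replicate part is an independent draw
  # per replicate.  Because all noise is shared between conditions,
  # unplanted genes are true DE nulls at every matched sample; planted
  # effects (DE shifts, one-condition modules, differential-edge
  # couplings) are the only systematic condition differences.
  n_mod <- length(config$module_sizes)
  max_rep <- max(design$replicate)
  tau <- config$replicate_noise_share
  z <- if (n_mod > 0)
    matrix(rnorm(n_mod * n_stage), n_mod, n_stage,
           dimnames = list(paste0("M", seq_len(n_mod)), STAGES))
  else matrix(0, 0, n_stage)
  eps_stage <- matrix(rnorm(n_genes * n_stage), n_genes, n_stage,
                      dimnames = list(genes, STAGES))
  eps_rep <- array(rnorm(n_genes * n_stage * max_rep),
                   dim = c(n_genes, n_stage, max_rep),
                   dimnames = list(genes, STAGES, NULL))

  # differential-edge latents, same stage/replicate decomposition
  ed <- config$diff_edges
  u_stage <- NULL; u_rep <- NULL
  if (!is.null(ed)) {
    bad <- setdiff(unique(c(ed$gene1, ed$gene2)), genes)
    if (length(bad) > 0)
      stop("diff_edges name unknown genes: ", paste(bad, collapse = ", "))
    ugroups <- unique(ed$group)
    u_stage <- matrix(rnorm(length(ugroups) * n_stage), length(ugroups),
                      n_stage, dimnames = list(ugroups, STAGES))
    u_rep <- array(rnorm(length(ugroups) * n_stage * max_rep),
                   dim = c(length(ugroups), n_stage, max_rep),
                   dimnames = list(ugroups, STAGES, NULL))
    for (cond in CONDITIONS) {
      sub <- ed[ed$favored == cond, , drop = FALSE]
      for (g in unique(c(sub$gene1, sub$gene2))) {
        inv <- sub[sub$gene1 == g | sub$gene2 == g, , drop = FALSE]
        gam <- vapply(split(inv$coupling, inv$group), max, 0)
        if (sum(gam) > 1)
          stop("total coupling for gene ", g, " in condition ", cond,
               " exceeds 1")
      }
    }
  }

  # Balanced loadings: within each module, alternate genes load on the
  # latent with opposite signs.  Unsigned |correlation| within the module
  # is rho either way, but per-sample count totals stay nearly constant,
  # so FPKM's compositional normalization does not leak a shared swing
  # into every gene (which would glue unrelated modules together).
  load_sign <- setNames(rep(1, n_genes), genes)
  for (m in seq_len(n_mod)) {
    midx <- which(labels == paste0("M", m))
    load_sign[midx] <- rep_len(c(1, -1), length(midx))
  }
  # genes carrying planted differential edges keep a positive loading so
  # the coupling raises, never cancels, their pairwise correlation
  if (!is.null(config$diff_edges))
    load_sign[unique(c(config$diff_edges$gene1,
                       config$diff_edges$gene2))] <- 1

  # joint orthogonalization of module and edge-group trajectories, under
  # the inner product weighted by how often each stage is sampled (so
  # that trajectories are orthogonal across sample columns, not just
  # across the 7 nominal stages)
  stage_weights <- as.numeric(table(factor(design$stage,
                                           levels = STAGES)))
  lat <- orthogonalize_latents(rbind(z, u_stage), stage_weights)
  if (n_mod > 0) z <- lat[seq_len(n_mod), , drop = FALSE]
  if (!is.null(u_stage))
    u_stage <- lat[n_mod + seq_len(nrow(u_stage)), , drop = FALSE]

  # Standardized signal for one (condition, stage, replicate) column.
  # Differential-edge couplings blend the gene's NOISE component toward
  # the group latent in the favored condition only: module loadings stay
  # untouched in both conditions (co-membership is preserved) while the
  # within-pair correlation rises to rho + (1 - rho) * coupling (or to
  # `coupling` itself for background genes).
  column_signal <- function(ci, si, ri) {
    noise <- sqrt(1 - tau) * eps_stage[, si] + sqrt(tau) * eps_rep[, si, ri]
    if (!is.null(ed)) {
      u_col <- setNames(sqrt(1 - tau) * u_stage[, si] +
                          sqrt(tau) * u_rep[, si, ri], rownames(u_stage))
      sub <- ed[ed$favored == CONDITIONS[ci], , drop = FALSE]
      for (g in unique(c(sub$gene1, sub$gene2))) {
        inv <- sub[sub$gene1 == g | sub$gene2 == g, , drop = FALSE]
        gam <- vapply(split(inv$coupling, inv$group), max, 0)
        noise[g] <- sqrt(1 - sum(gam)) * noise[g] +
          sum(sqrt(gam) * u_col[names(gam)])
      }
    }
    sig <- noise
    for (m in seq_len(n_mod)) {
      active <- config$module_conditions[m] %in%
        c("both", CONDITIONS[ci])
      if (!active) next
      midx <- which(labels == paste0("M", m))
      rho <- config$within_module_cor[m]
      sig[midx] <- load_sign[midx] * sqrt(rho) * z[m, si] +
        sqrt(1 - rho) * noise[midx]
    }
    sig
  }

  # planted DE shifts on the domestic log2 mean
  de_shift <- matrix(0, n_genes, n_stage, dimnames = list(genes, STAGES))
  if (!is.null(config$de_genes)) {
    de <- config$de_genes
    bad <- setdiff(de$gene, genes)
    if (length(bad) > 0)
      stop("de_genes name unknown genes: ", paste(bad, collapse = ", "))
    for (i in seq_len(nrow(de))) {
      sts <- if (identical(de$stages[i], "all")) STAGES else
        strsplit(de$stages[i], ",", fixed = TRUE)[[1]]
      de_shift[de$gene[i], sts] <- de_shift[de$gene[i], sts] +
        de$log2fc[i]
    }
  }

  # counts: NB around mean * per-sample library factor; phi = 0 is the
  # noiseless limit (rounded means)
  counts <- matrix(0, n_genes, nrow(design),
                   dimnames = list(genes, design$sample))
  lib_ref <- sum(base_mean)
  for (s in seq_len(nrow(design))) {
    ci <- match(design$condition[s], CONDITIONS)
    si <- match(design$stage[s], STAGES)
    ri <- design$replicate[s]
    log2mu <- log2(base_mean) +
      config$amplitude * column_signal(ci, si, ri) +
      (if (ci == 1L) de_shift[, si] else 0)
    mu <- 2^log2mu * (lib_target[s] / lib_ref)
    if (config$dispersion == 0) {
      counts[, s] <- round(mu)
    } else {
      counts[, s] <- rnbinom(n_genes, mu = mu, size = 1 / config$dispersion)
    }
  }
  storage.mode(counts) <- "integer"

  truth <- list(module_labels = labels,
                diff_edges = config$diff_edges,
                de_genes = config$de_genes,
                seed_genes = names(config$seed_genes))
  list(counts = counts, design = design, gene_length = gene_length,
       truth = truth)
}

#' Write a simulated expression dataset as plain-text files
#'
#' Emits `counts.tsv` (genes x samples), `samples.tsv` (sample sheet),
#' `genes.tsv` (gene, length) and `truth.json` under `dir`.
#'
#' @param sim result of [simulate_expression_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cdf <- data.frame(gene = rownames(sim$counts), sim$counts,
                    check.names = FALSE)
  write_tsv_table(cdf, file.path(dir, "counts.tsv"))
  write_tsv_table(sim$design, file.path(dir, "samples.tsv"))
  write_tsv_table(data.frame(gene = names(sim$gene_length),
                             length = as.integer(sim$gene_length)),
                  file.path(dir, "genes.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read an expression dataset from disk
#'
#' Round-trips the files written by [write_expression_dataset()].
#'
#' @param dir directory holding counts.tsv, samples.tsv and genes.tsv.
#' @return list with `counts`, `design`, `gene_length`.
#' @export
read_expression_dataset <- function(dir) {
  counts <- read_count_tsv(file.path(dir, "counts.tsv"))
  storage.mode(counts) <- "integer"
  design <- read_tsv_table(file.path(dir, "samples.tsv"))
  gdf <- read_tsv_table(file.path(dir, "genes.tsv"))
  gl <- setNames(gdf$length, gdf$gene)
  if (!identical(sort(names(gl)), sort(rownames(counts))))
    stop("gene sets of counts.tsv and genes.tsv disagree")
  list(counts = counts, design = design,
       gene_length = gl[rownames(counts)])
}
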