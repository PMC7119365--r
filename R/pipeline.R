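# End-to-end orchestration: one YAML config drives quantification, DE,
# networks, differential co-expression, the selection scan, pruning and
# enrichment, with a machine-readable run summary.  The pipeline itself
# is deterministic; randomness only enters through the simulator.

pipeline_defaults <- function() list(
  fpkm_floor = 1, max_low_samples = 10,
  beta = 16, r2_target = 0.85,
  cut_height = 0.995, min_module_size = 30,
  similarity_columns = "samples",       # or "stages"
  expr_transform = "log2",              # or "none"; applied before cor()
  fc_threshold = 1.5, weight_floor = 0.05, epsilon_floor = 0.05,
  window_size = 50000, step = 25000,
  lower_q = 0.05, upper_q = 0.95, pi_stat = "ratio",
  fst_estimator = "weir_cockerham",
  fallback_dispersion = 0.1, sig_cut = 0.05,
  seed_genes = c("Fib-H", "Fib-L", "P25",
                 "Sericin1", "Sericin2", "Sericin3"),
  seed = 1)

#' Read and validate a pipeline configuration
#'
#' YAML key-value file; unset parameters fall back to package defaults
#' (each effective value is logged by [run_pipeline()]).
#'
#' @param path YAML file.
#' @param overrides named list overriding file values (CLI flags).
#' @return validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path, overrides = NULL) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  def <- pipeline_defaults()
  for (nm in names(def)) if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
  # resolve relative input paths against the config file location
  for (nm in c("counts", "samples", "genes", "gene_models", "vcf",
               "popmap", "annotation", "out_dir")) {
    if (!is.null(cfg[[nm]]) && !grepl("^/", cfg[[nm]]))
      cfg[[nm]] <- file.path(base, cfg[[nm]])
  }
  num_ok <- function(x, lo, hi) is.numeric(x) && x >= lo && x <= hi
  if (!num_ok(cfg$fc_threshold, 1, Inf))
    stop("fc_threshold must be >= 1")
  if (!num_ok(cfg$cut_height, 1e-6, 1 - 1e-6))
    stop("cut_height must be in (0, 1)")
  if (!num_ok(cfg$lower_q, 0, 1) || !num_ok(cfg$upper_q, 0, 1))
    stop("quantiles must lie in [0, 1]")
  if (!identical(cfg$beta, "auto") && !num_ok(cfg$beta, 1, Inf))
    stop("beta must be numeric >= 1 or 'auto'")
  structure(cfg, class = "pipeline_config")
}

log_param <- function(...) message("[silknet] ", ...)

require_inputs <- function(config, keys) {
  for (k in keys) {
    if (is.null(config[[k]]))
      stop("config key '", k, "' is required for this stage")
    if (!file.exists(config[[k]]))
      stop("input file for '", k, "' not found: ", config[[k]])
  }
}

#' Run the full comparative analysis
#'
#' Stages: quantify (TMM/FPKM/filters), de, network (per-condition TOMs
#' and consensus modules), diffcoex (differential edges + seed
#' networks), sweepscan (window pi/Fst + selection regions + gene
#' overlap; also prunes the seed networks when diffcoex ran), enrich.
#' Dependencies are pulled in automatically.
#'
#' @param config a `pipeline_config` (or path to one).
#' @param stages character vector of requested stages, or "all".
#' @return run summary (list), invisibly written as summary.json.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  all_stages <- c("quantify", "de", "network", "diffcoex", "sweepscan",
                  "enrich")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  want <- stages
  if ("diffcoex" %in% want) want <- union(want, c("network", "de"))
  if ("enrich" %in% want) want <- union(want, "de")
  if ("network" %in% want || "de" %in% want) want <- union(want, "quantify")
  out <- config$out_dir
  if (is.null(out)) stop("config key 'out_dir' is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  summary <- list(package_version =
                    as.character(utils::packageVersion("silknet")),
                  stages = want)
  hashed <- unclass(config)
  hashed$out_dir <- NULL     # output location must not change the hash
  cfg_txt <- paste(utils::capture.output(utils::str(hashed)),
                   collapse = "\n")
  summary$config_hash <- config_hash(cfg_txt)

  expr <- NULL; fpkm <- NULL; fpkm_stage <- NULL; filtered <- NULL
  de_res <- NULL; toms <- NULL; modules <- NULL; selected <- NULL
  modules_by_cond <- NULL

  if ("quantify" %in% want) {
    require_inputs(config, c("counts", "samples", "genes"))
    cm <- read_count_tsv(config$counts)
    gdf <- read_tsv_table(config$genes)
    expr <- list(counts = cm,
                 design = read_tsv_table(config$samples),
                 gene_length = setNames(gdf$length, gdf$gene)[rownames(cm)])
    log_param("quantify: ", nrow(expr$counts), " genes, ",
              ncol(expr$counts), " samples")
    factors <- tmm_factors(expr$counts)
    fpkm <- compute_fpkm(expr$counts, expr$gene_length, factors)
    fpkm_stage <- collapse_replicates(fpkm, expr$design)
    fl <- filter_low_expression(fpkm, config$fpkm_floor,
                                config$max_low_samples)
    nv <- remove_nonvarying(fl$kept)
    filtered <- nv$kept
    log_param("filters: fpkm_floor=", config$fpkm_floor,
              " max_low_samples=", config$max_low_samples, "; removed ",
              length(fl$removed), " low + ", length(nv$removed),
              " non-varying")
    write_tsv_table(data.frame(gene = rownames(fpkm), round(fpkm, 4),
                               check.names = FALSE),
                    file.path(out, "fpkm_samples.tsv"))
    write_tsv_table(data.frame(gene = rownames(fpkm_stage),
                               round(fpkm_stage, 4), check.names = FALSE),
                    file.path(out, "fpkm_stages.tsv"))
    write_tsv_table(data.frame(sample = names(factors),
                               tmm_factor = round(factors, 6)),
                    file.path(out, "tmm_factors.tsv"))
    rem <- data.frame(
      gene = c(fl$removed, nv$removed),
      reason = c(rep("low_expression", length(fl$removed)),
                 rep("non_varying", length(nv$removed))))
    write_tsv_table(rem, file.path(out, "filter_report.tsv"))
    summary$genes_total <- nrow(expr$counts)
    summary$genes_kept <- nrow(filtered)
    expr$factors <- factors
  }

  if ("de" %in% want) {
    de_res <- run_differential_expression(
      expr$counts, expr$design, expr$factors,
      fallback_dispersion = config$fallback_dispersion)
    log_param("de: fallback_dispersion=", config$fallback_dispersion)
    write_tsv_table(de_res, file.path(out, "de_results.tsv"))
    degs <- tapply(de_res$is_deg, de_res$stage, sum)
    summary$degs_per_stage <- as.list(degs[STAGES[STAGES %in% names(degs)]])
  }

  if ("network" %in% want) {
    keep <- rownames(filtered)
    cols_of <- function(cond) {
      m <- if (config$similarity_columns == "stages") {
        fpkm_stage[keep, grepl(paste0("^", cond, "\\."),
                               colnames(fpkm_stage)), drop = FALSE]
      } else {
        smp <- expr$design$sample[expr$design$condition == cond]
        fpkm[keep, smp, drop = FALSE]
      }
      if (config$expr_transform == "log2") log2(m + 1) else m
    }
    toms <- list()
    modules_by_cond <- list()
    beta_used <- config$beta
    st_report <- NULL
    for (cond in CONDITIONS) {
      m <- remove_nonvarying(cols_of(cond))$kept
      sim <- pearson_similarity(m)
      if (identical(config$beta, "auto")) {
        pk <- pick_soft_threshold(sim, r2_target = config$r2_target)
        beta_used <- pk$beta
        st_report <- pk$report
        log_param("network: auto beta for ", cond, " = ", beta_used)
      }
      adj <- soft_adjacency(sim, as.numeric(beta_used))
      toms[[cond]] <- tom_similarity(adj)
      modules_by_cond[[cond]] <- detect_modules(toms[[cond]],
                                                config$cut_height,
                                                config$min_module_size)
    }
    # the two TOMs must share a gene index for consensus/differential use
    shared <- intersect(rownames(toms$domestic), rownames(toms$wild))
    toms <- lapply(toms, function(t) t[shared, shared])
    log_param("network: beta=", beta_used, " cut_height=",
              config$cut_height, " min_module_size=",
              config$min_module_size, " similarity_columns=",
              config$similarity_columns)
    modules <- consensus_modules(toms$domestic, toms$wild,
                                 config$cut_height,
                                 config$min_module_size)
    if (!is.null(st_report))
      write_tsv_table(st_report, file.path(out, "soft_threshold.tsv"))
    write_tsv_table(data.frame(gene = names(modules),
                               consensus_module = modules,
                               module_domestic =
                                 modules_by_cond$domestic[names(modules)],
                               module_wild =
                                 modules_by_cond$wild[names(modules)]),
                    file.path(out, "modules.tsv"))
    summary$beta <- as.numeric(beta_used)
    summary$consensus_modules <-
      length(setdiff(unique(modules), "unassigned"))
  }

  if ("sweepscan" %in% want) {
    require_inputs(config, c("vcf", "popmap"))
    panels <- read_vcf_panels(config$vcf, config$popmap)
    cl <- panels$chrom_lengths
    if (!is.null(config$chrom_lengths)) cl <- unlist(config$chrom_lengths)
    ws <- window_stats(panels$panel1, panels$panel2,
                       config$window_size, config$step, cl,
                       estimator = config$fst_estimator)
    log_param("sweepscan: window_size=", config$window_size, " step=",
              config$step, " estimator=", config$fst_estimator,
              " pi_stat=", config$pi_stat, " quantiles=", config$lower_q,
              "/", config$upper_q)
    regions <- call_selection_regions(ws, config$pi_stat,
                                      config$lower_q, config$upper_q)
    write_tsv_table(ws, file.path(out, "windows.tsv"),
                    comment = "coordinates: 0-based half-open [start, end)")
    utils::write.table(regions$regions, file.path(out, "regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    summary$windows <- nrow(ws)
    summary$selection_regions <- nrow(regions$regions)
    if (!is.null(config$gene_models)) {
      gm <- read_tsv_table(config$gene_models)
      selected <- overlap_genes(regions$regions, gm)
      write_tsv_table(data.frame(gene = selected),
                      file.path(out, "selected_genes.tsv"))
      summary$selected_genes <- length(selected)
    }
  }

  if ("diffcoex" %in% want) {
    assignments <- c(list(consensus = modules), modules_by_cond)
    seeds <- intersect(config$seed_genes, names(modules))
    deg_genes <- unique(de_res$gene[de_res$is_deg])
    comember <- unique(unlist(lapply(assignments, function(lab) {
      sm <- setdiff(unique(lab[intersect(seeds, names(lab))]),
                    "unassigned")
      names(lab)[lab %in% sm]
    })))
    universe <- intersect(union(seeds, intersect(deg_genes, comember)),
                          rownames(toms$domestic))
    de_edges <- differential_edges(toms$domestic, toms$wild, universe,
                                   config$fc_threshold,
                                   config$epsilon_floor)
    nets <- build_seed_networks(config$seed_genes, assignments, deg_genes,
                                de_edges, config$weight_floor)
    log_param("diffcoex: fc_threshold=", config$fc_threshold,
              " weight_floor=", config$weight_floor,
              " epsilon_floor=", config$epsilon_floor)
    write_tsv_table(de_edges, file.path(out, "diff_edges.tsv"))
    for (cond in CONDITIONS) {
      write_tsv_table(nets[[cond]]$edges,
                      file.path(out, paste0("network_", cond,
                                            "_edges.tsv")))
      write_tsv_table(nets[[cond]]$nodes,
                      file.path(out, paste0("network_", cond,
                                            "_nodes.tsv")))
    }
    degrees <- seed_degree_table(nets)
    write_tsv_table(degrees, file.path(out, "seed_degrees.tsv"))
    summary$diff_edges <- nrow(de_edges)
    summary$network_edges <- list(domestic = nrow(nets$domestic$edges),
                                  wild = nrow(nets$wild$edges))
    summary$seed_degrees <- setNames(as.list(degrees$degree_domestic),
                                     degrees$seed)
    if (!is.null(selected)) {
      pruned <- lapply(nets[CONDITIONS], prune_by_selection, selected)
      for (cond in CONDITIONS)
        write_tsv_table(pruned[[cond]]$nodes,
                        file.path(out, paste0("network_", cond,
                                              "_pruned_nodes.tsv")))
      pd <- seed_degree_table(pruned)
      write_tsv_table(pd, file.path(out, "seed_degrees_pruned.tsv"))
      summary$pruned_network_edges <-
        list(domestic = nrow(pruned$domestic$edges),
             wild = nrow(pruned$wild$edges))
    }
  }

  if ("enrich" %in% want && !is.null(config$annotation)) {
    require_inputs(config, "annotation")
    ann <- read_tsv_table(config$annotation)
    universe <- rownames(filtered)
    enr_all <- list()
    for (dir_ in c("up", "down")) {
      for (st in unique(de_res$stage)) {
        sel <- de_res$stage == st & de_res$is_deg &
          de_res$direction == dir_
        study <- intersect(de_res$gene[sel & !is.na(de_res$direction)],
                           universe)
        res <- hypergeom_enrich(study, universe, ann)
        if (nrow(res) > 0) {
          res$stage <- st
          res$direction <- dir_
        }
        enr_all[[paste(dir_, st)]] <- res
      }
    }
    enr_df <- do.call(rbind, enr_all[vapply(enr_all, nrow, 0L) > 0])
    if (!is.null(enr_df)) rownames(enr_df) <- NULL
    write_tsv_table(if (is.null(enr_df))
      data.frame(term = character(0)) else enr_df,
      file.path(out, "enrichment.tsv"))
    stages_present <- unique(de_res$stage)
    up_l <- enr_all[paste("up", stages_present)]
    names(up_l) <- stages_present
    down_l <- enr_all[paste("down", stages_present)]
    names(down_l) <- stages_present
    shift <- functional_shift(up_l, down_l, stages_present,
                              config$sig_cut)
    write_tsv_table(shift, file.path(out, "functional_shift.tsv"))
    summary$shift_terms <- nrow(shift)
    log_param("enrich: sig_cut=", config$sig_cut)
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
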