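#' Pipeline configuration
#'
#' Bundles the simulation design with every analysis threshold so a run is
#' a pure function of its configuration.
#'
#' @param sim A `mempar_sim_config` (see [sim_config()]).
#' @param deg_lfc,deg_fdr DEG thresholds (inclusive fold-change rule).
#' @param dar_lfc,dar_fdr DAR thresholds (strict fold-change rule).
#' @param primed_rule Passed to [classify_par()].
#' @param alpha_enrich Motif enrichment threshold.
#' @param pagerank_d,pagerank_tol PageRank damping and tolerance.
#' @param bootstrap_B Dendrogram bootstrap resamples.
#' @param dispersion_mode Passed to [nb_wald()].
#' @return A validated `mempar_pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            deg_lfc = 1, deg_fdr = 0.05,
                            dar_lfc = 1.5, dar_fdr = 0.05,
                            primed_rule = "directional",
                            alpha_enrich = 0.05,
                            pagerank_d = 0.85, pagerank_tol = 1e-10,
                            bootstrap_B = 500,
                            dispersion_mode = "trend") {
  if (deg_lfc <= 0 || dar_lfc <= 0) abort("fold-change thresholds must be positive")
  if (deg_fdr <= 0 || deg_fdr > 1 || dar_fdr <= 0 || dar_fdr > 1) {
    abort("FDR thresholds must be in (0, 1]")
  }
  if (pagerank_d < 0 || pagerank_d >= 1) abort("pagerank_d must be in [0, 1)")
  stopifnot(inherits(sim, "mempar_sim_config"))
  structure(list(sim = sim, deg_lfc = deg_lfc, deg_fdr = deg_fdr,
                 dar_lfc = dar_lfc, dar_fdr = dar_fdr,
                 primed_rule = primed_rule, alpha_enrich = alpha_enrich,
                 pagerank_d = pagerank_d, pagerank_tol = pagerank_tol,
                 bootstrap_B = bootstrap_B, dispersion_mode = dispersion_mode),
            class = "mempar_pipeline_config")
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the stages in dependency order: simulate, differential testing,
#' gene categorization, module clustering, PAR classification, peak-gene
#' integration, motif enrichment (with dendrogram), TF network PageRank,
#' and metabolic metrics. Deterministic given the configuration.
#'
#' @param config A `mempar_pipeline_config`.
#' @param outdir Optional directory; when given, stage outputs are written
#'   as TSV and the manifest as JSON-like TSV.
#' @param quiet Suppress stage messages.
#' @return A `mempar_pipeline` list of stage outputs plus a `manifest`
#'   recording the configuration hash, seed, versions, and per-stage row
#'   counts.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "mempar_pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] seed %d: %d genes, %d peaks", config$sim$seed,
      config$sim$n_genes, config$sim$n_peaks)
  experiment <- simulate_experiment(config$sim)
  lineages <- config$sim$lineages

  say("[differential] contrasts per lineage (RNA + ATAC)")
  rna_contrasts <- purrr::map(lineages, function(l) {
    run_memory_contrasts(experiment$rna, experiment$samples, l,
                         dispersion_mode = config$dispersion_mode)
  }) |> setNames(lineages)
  atac_contrasts <- purrr::map(lineages, function(l) {
    run_memory_contrasts(experiment$atac, experiment$samples, l,
                         dispersion_mode = config$dispersion_mode)
  }) |> setNames(lineages)

  say("[categorize] expressed / induced / augmented")
  categories <- purrr::map_dfr(lineages, function(l) {
    flags <- contrast_flag_table(rna_contrasts[[l]], config$deg_lfc,
                                 config$deg_fdr, strict_lfc = FALSE) |>
      rename(I_N = "C1", R = "C2", S = "C3", I_M = "C4")
    classify_gene(flags) |> mutate(lineage = l, direction = "up")
  })

  say("[par] patterned accessibility regions")
  par_table <- purrr::map_dfr(lineages, function(l) {
    flags <- contrast_flag_table(atac_contrasts[[l]], config$dar_lfc,
                                 config$dar_fdr, strict_lfc = TRUE)
    classify_par(flags, primed_rule = config$primed_rule) |> mutate(lineage = l)
  })
  par_labels <- par_union(par_table)

  say("[modules] fuzzy c-means on DEG profiles")
  rpkm_tbl <- rpkm(experiment$rna)
  deg_union <- unique(unlist(lapply(lineages, function(l) {
    cl <- rna_contrasts[[l]]
    unlist(lapply(cl, function(res) {
      called <- call_features(res, config$deg_lfc, config$deg_fdr)
      called$feature_id[called$call != "ns"]
    }))
  })))
  modules <- tryCatch({
    kept <- filter_module_genes(rpkm_tbl, deg_union, experiment$samples)
    X <- expression_profiles(rpkm_tbl, experiment$samples, kept)
    sel <- select_c(X, candidates = 2:8, seed = config$sim$seed)
    fit <- fuzzy_cmeans(X, sel$c, seed = config$sim$seed)
    list(genes = kept, selection = sel, fit = fit, assignment = tidy(fit))
  }, error = function(e) {
    warn(paste("module stage skipped:", conditionMessage(e)))
    NULL
  })

  say("[integrate] nearest-TSS map and association statistics")
  map <- nearest_tss(experiment$peaks, experiment$genes)
  aug_genes <- unique(categories$feature_id[categories$category == "augmented"])
  coupling <- fraction_with_par(aug_genes, map, par_labels, "primed")
  deg_sets <- list(
    expressed = unique(categories$feature_id[categories$category == "expressed"]),
    induced = unique(categories$feature_id[categories$category == "induced"]),
    augmented = aug_genes,
    `All DEG` = unique(categories$feature_id[categories$category != "none"])
  )
  proportions <- par_proportions(map, par_labels, deg_sets)
  fc_cor <- purrr::map_dfr(lineages, function(l) {
    subs <- attr(rna_contrasts[[l]], "subsets")
    purrr::map_dfr(subs, function(m) {
      fc_correlation(rna_contrasts[[l]][[paste0("C2_", m)]],
                     atac_contrasts[[l]][[paste0("C2_", m)]], map) |>
        mutate(lineage = l, subset = m)
    })
  })

  say("[motifs] per-PAR enrichment, rank matrix, dendrogram")
  par_sets <- c("primed", "stimulated", "memory", "naive")
  enrich <- purrr::map_dfr(par_sets, function(ps) {
    fg <- par_labels$feature_id[par_labels$par == ps]
    if (!length(fg)) return(tibble())
    motif_enrichment(fg, setdiff(experiment$peaks$peak_id, fg),
                     experiment$motif_hits,
                     alpha_enrich = config$alpha_enrich) |>
      mutate(set = ps)
  })
  ranks <- rank_normalize(enrich)
  dendro <- if (length(unique(ranks$set)) >= 3) {
    bootstrap_dendrogram(rank_matrix(ranks), B = config$bootstrap_B,
                         seed = config$sim$seed)
  } else NULL

  say("[tfnet] personalized PageRank, memory vs naive")
  tf_map <- tibble(tf = experiment$motif_library$motif_id,
                   motif_id = experiment$motif_library$motif_id)
  sf_atac <- size_factors(experiment$atac)
  atac_norm <- count_matrix(experiment$atac) /
    rep(setNames(sf_atac$size_factor, sf_atac$sample_id)[sample_cols(experiment$atac)],
        each = config$sim$n_peaks)
  mean_by_condition <- function(m, cond) {
    cols <- experiment$samples$sample_id[experiment$samples$condition == cond]
    rowMeans(m[, cols, drop = FALSE])
  }
  rpkm_m <- count_matrix(rpkm_tbl)
  lin <- lineages[length(lineages)]
  mem_sub <- setdiff(config$sim$subsets_per_lineage[[lin]], "naive")[1]
  cond_mem <- paste(lin, mem_sub, "unstim", sep = "_")
  cond_nav <- paste(lin, "naive", "unstim", sep = "_")
  net <- function(cond) {
    build_tf_network(experiment$motif_hits, map,
                     mean_by_condition(atac_norm, cond),
                     mean_by_condition(rpkm_m, cond), tf_map)
  }
  pr_mem <- pagerank(net(cond_mem), d = config$pagerank_d,
                     tol = config$pagerank_tol, reverse = TRUE)
  pr_nav <- pagerank(net(cond_nav), d = config$pagerank_d,
                     tol = config$pagerank_tol, reverse = TRUE)
  tf_changes <- tf_rank_change(pr_mem, pr_nav)

  say("[metabolism] SCENITH + Seahorse metrics")
  metab_fix <- simulate_metabolism(config$sim)
  scenith <- scenith_metrics(metab_fix$scenith)
  seahorse <- seahorse_metrics(metab_fix$seahorse)

  result <- list(
    experiment = experiment,
    rna_contrasts = rna_contrasts, atac_contrasts = atac_contrasts,
    categories = categories, category_counts = gene_category_counts(categories),
    par_table = par_table, par_labels = par_labels,
    par_counts = par_category_counts(par_table),
    modules = modules, peak_gene_map = map,
    coupling = coupling, proportions = proportions, fc_correlation = fc_cor,
    enrichment = enrich, ranks = ranks, dendrogram = dendro,
    pagerank = list(memory = pr_mem, naive = pr_nav, changes = tf_changes,
                    conditions = c(memory = cond_mem, naive = cond_nav)),
    scenith = scenith, seahorse = seahorse
  )
  result$manifest <- pipeline_manifest(config, result, t0)
  class(result) <- "mempar_pipeline"
  if (!is.null(outdir)) write_pipeline(result, outdir)
  result
}

pipeline_manifest <- function(config, result, t0) {
  counts <- c(
    samples = nrow(result$experiment$samples),
    genes = nrow(result$experiment$rna),
    peaks = nrow(result$experiment$atac),
    gene_categories = nrow(result$categories),
    par_labels = nrow(result$par_table),
    module_genes = if (is.null(result$modules)) 0L else length(result$modules$genes),
    peak_gene_pairs = nrow(result$peak_gene_map),
    enrichment_rows = nrow(result$enrichment),
    scenith_rows = nrow(result$scenith)
  )
  list(
    config_hash = rlang::hash(unclass(config)),
    result_hash = rlang::hash(result[setdiff(names(result), "manifest")]),
    seed = config$sim$seed,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("mempar")),
    stage_rows = counts,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
}

#' Write pipeline outputs as TSV files
#' @param result A `mempar_pipeline`.
#' @param outdir Output directory.
#' @return Invisibly, `outdir`.
#' @export
write_pipeline <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_experiment(result$experiment, file.path(outdir, "simulated"))
  readr::write_tsv(result$categories, p("gene_categories.tsv"), progress = FALSE)
  readr::write_tsv(result$category_counts, p("gene_category_counts.tsv"), progress = FALSE)
  readr::write_tsv(result$par_table, p("par_table.tsv"), progress = FALSE)
  readr::write_tsv(result$par_counts, p("par_counts.tsv"), progress = FALSE)
  readr::write_tsv(result$peak_gene_map, p("peak_gene_map.tsv"), progress = FALSE)
  readr::write_tsv(result$proportions, p("par_proportions.tsv"), progress = FALSE)
  readr::write_tsv(result$enrichment, p("motif_enrichment.tsv"), progress = FALSE)
  readr::write_tsv(result$ranks, p("motif_ranks.tsv"), progress = FALSE)
  if (!is.null(result$modules)) {
    readr::write_tsv(result$modules$assignment, p("modules.tsv"), progress = FALSE)
    readr::write_tsv(result$modules$selection$wss, p("module_wss.tsv"), progress = FALSE)
  }
  if (!is.null(result$dendrogram)) {
    ape::write.tree(result$dendrogram$tree, p("par_dendrogram.nwk"))
  }
  readr::write_tsv(tidy(result$pagerank$memory), p("pagerank_memory.tsv"), progress = FALSE)
  readr::write_tsv(tidy(result$pagerank$naive), p("pagerank_naive.tsv"), progress = FALSE)
  readr::write_tsv(result$pagerank$changes, p("pagerank_changes.tsv"), progress = FALSE)
  readr::write_tsv(result$scenith, p("scenith_metrics.tsv"), progress = FALSE)
  readr::write_tsv(result$seahorse, p("seahorse_metrics.tsv"), progress = FALSE)
  manifest <- result$manifest
  manifest_tbl <- tibble(key = c("config_hash", "result_hash", "seed", "r_version",
                                 "package_version",
                                 paste0("rows_", names(manifest$stage_rows))),
                         value = c(manifest$config_hash, manifest$result_hash,
                                   manifest$seed, manifest$r_version,
                                   manifest$package_version,
                                   unname(manifest$stage_rows)))
  readr::write_tsv(manifest_tbl, p("manifest.tsv"), progress = FALSE)
  invisible(outdir)
}

#' @export
print.mempar_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("mempar pipeline run\n")
  cat(sprintf("  seed %s, config %s\n", m$seed, substr(m$config_hash, 1, 8)))
  for (nm in names(m$stage_rows)) {
    cat(sprintf("  %-18s %d\n", nm, m$stage_rows[[nm]]))
  }
  invisible(x)
}
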