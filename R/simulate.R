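#' Simulation configuration for a paired RNA/ATAC memory T-cell experiment
#'
#' Builds a validated configuration for [simulate_experiment()]. The design
#' mirrors a human memory T-cell sorting study: two lineages (CD4, CD8), the
#' naive/central-memory/effector-memory subsets (plus TEMRA for CD8 only),
#' resting and stimulated states, and four donors. Counts are negative
#' binomial with `Var = mu + dispersion * mu^2`; library sizes are
#' log-normal around `lib_size_mean` (CV 0.2 by default).
#'
#' Planted signal classes:
#' * genes: `expressed`, `induced`, `augmented` (memory-upregulated classes),
#'   plus `naive_high` and `stim_global` profiles that are differential but
#'   fall outside the three memory classes; together the five classes form
#'   five expression modules per lineage.
#' * peaks: `stimulated`, `primed`, `memory`, `naive` patterned-accessibility
#'   classes; unlisted peaks are flat (`conserved`).
#'
#' Naive-cell responses are planted at `effect_lfc` log2 units; memory-subset
#' effects are scaled by `gradient_scale` (TCM < TEM <= TEMRA) so effect
#' size grows along the differentiation gradient. With probability
#' `coupling_rate` each augmented gene receives one primed peak whose nearest
#' TSS is that gene; all other peaks land in intergenic gaps.
#'
#' @param seed Integer seed; all outputs are deterministic given it.
#' @param n_donors Donors per condition (default 4).
#' @param lineages Character vector among `"CD4"`, `"CD8"`.
#' @param n_genes,n_peaks Feature counts.
#' @param dispersion NB dispersion alpha (> 0).
#' @param lib_size_mean Mean library size (reads).
#' @param lib_cv Coefficient of variation of library sizes.
#' @param effect_lfc Planted |log2 fold-change| for naive-scale effects.
#' @param gradient_scale Named multipliers for `TCM`, `TEM`, `TEMRA`.
#' @param n_per_gene_category Named counts for `expressed`, `induced`,
#'   `augmented`, `naive_high`, `stim_global`.
#' @param n_per_par_category Named counts for `stimulated`, `primed`,
#'   `memory`, `naive`.
#' @param coupling_rate Probability an augmented gene gets a primed peak in
#'   cis (default 0.8).
#' @param donor_sd SD of the per-donor log2 random effect.
#' @param genome_length Genome size in bp (default scales with `n_genes`).
#' @param peak_width Fixed peak width in bp (default 250).
#' @param noise_sd Relative noise SD for metabolic fixtures.
#' @return A `mempar_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_donors = 4L,
                       lineages = c("CD4", "CD8"),
                       n_genes = 2000L,
                       n_peaks = 2000L,
                       dispersion = 0.05,
                       lib_size_mean = 1e6,
                       lib_cv = 0.2,
                       effect_lfc = 2.0,
                       gradient_scale = c(TCM = 1.0, TEM = 1.25, TEMRA = 1.5),
                       n_per_gene_category = c(expressed = 150L, induced = 150L,
                                               augmented = 200L, naive_high = 150L,
                                               stim_global = 150L),
                       n_per_par_category = c(stimulated = 200L, primed = 400L,
                                              memory = 150L, naive = 150L),
                       coupling_rate = 0.8,
                       donor_sd = 0.1,
                       genome_length = NULL,
                       peak_width = 250L,
                       noise_sd = 0.05) {
  if (dispersion <= 0) abort("dispersion must be > 0")
  if (coupling_rate < 0 || coupling_rate > 1) abort("coupling_rate must be in [0, 1]")
  if (!all(lineages %in% c("CD4", "CD8"))) abort("lineages must be CD4 and/or CD8")
  if (n_donors < 2) abort("need at least 2 donors per group")
  if (sum(n_per_gene_category) > n_genes) {
    abort("gene category counts exceed n_genes")
  }
  if (sum(n_per_par_category) > n_peaks) {
    abort("PAR category counts exceed n_peaks")
  }
  gs <- gradient_scale
  if (!(gs[["TCM"]] < gs[["TEM"]] && gs[["TEM"]] <= gs[["TEMRA"]]) &&
      !all(gs == gs[[1]])) {
    warn("gradient_scale does not follow TCM < TEM <= TEMRA")
  }
  genome_length <- genome_length %||% (n_genes * 20000L + 10000L)
  cfg <- list(seed = as.integer(seed), n_donors = as.integer(n_donors),
              lineages = lineages,
              subsets_per_lineage = list(CD4 = c("naive", "TCM", "TEM"),
                                         CD8 = c("naive", "TCM", "TEM", "TEMRA")),
              n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
              dispersion = dispersion, lib_size_mean = lib_size_mean,
              lib_cv = lib_cv, effect_lfc = effect_lfc,
              gradient_scale = gradient_scale,
              n_per_gene_category = n_per_gene_category,
              n_per_par_category = n_per_par_category,
              coupling_rate = coupling_rate, donor_sd = donor_sd,
              genome_length = genome_length, peak_width = as.integer(peak_width),
              noise_sd = noise_sd)
  structure(cfg, class = "mempar_sim_config")
}

# Planted log2 offsets by class for one (subset, stim) condition.
# d_naive: naive-scale effect; d_sub: gradient-scaled memory effect.
gene_class_offset <- function(class, subset, stim, d_naive, d_sub) {
  is_mem <- subset != "naive"
  switch(class,
    expressed = if (is_mem) (if (stim == "stim") d_naive else d_sub)
                else if (stim == "stim") d_naive else 0,
    induced = if (is_mem && stim == "stim") d_sub else 0,
    augmented = if (is_mem) d_sub * (if (stim == "stim") 1.5 else 1.0) else 0,
    naive_high = if (is_mem) 0 else d_naive,
    stim_global = if (stim == "stim") d_naive else 0,
    none = 0
  )
}

par_class_offset <- function(class, subset, stim, d_naive, d_sub) {
  is_mem <- subset != "naive"
  switch(class,
    stimulated = if (stim == "stim") (if (is_mem) d_sub else d_naive) else 0,
    primed = if (is_mem) d_sub else if (stim == "stim") d_naive else 0,
    memory = if (is_mem) d_sub else 0,
    naive = if (!is_mem && stim == "unstim") d_naive else 0,
    conserved = 0
  )
}

# Offset matrix: features x conditions (condition = lineage_subset_stim).
planted_offsets <- function(classes, conditions, config, kind = c("gene", "par")) {
  kind <- match.arg(kind)
  f <- if (kind == "gene") gene_class_offset else par_class_offset
  offs <- matrix(0, nrow = length(classes), ncol = nrow(conditions),
                 dimnames = list(NULL, conditions$condition))
  for (j in seq_len(nrow(conditions))) {
    subset <- conditions$subset[j]
    stim <- conditions$stim[j]
    d_sub <- config$effect_lfc *
      (if (subset == "naive") 1.0 else config$gradient_scale[[subset]])
    offs[, j] <- vapply(classes, f, numeric(1), subset = subset, stim = stim,
                        d_naive = config$effect_lfc, d_sub = d_sub)
  }
  offs
}

build_design <- function(config) {
  purrr::map_dfr(config$lineages, function(lin) {
    tidyr::expand_grid(lineage = lin,
                       subset = config$subsets_per_lineage[[lin]],
                       stim = c("unstim", "stim"),
                       donor = sprintf("d%d", seq_len(config$n_donors)))
  }) |>
    mutate(condition = paste(.data$lineage, .data$subset, .data$stim, sep = "_"),
           sample_id = paste(.data$condition, .data$donor, sep = "_")) |>
    select("sample_id", "lineage", "subset", "stim", "donor", "condition")
}

# NB counts for one assay given per-feature baselines and planted offsets.
draw_counts <- function(feature_ids, baselines, offsets, samples, config) {
  n <- length(feature_ids)
  sigma <- sqrt(log(1 + config$lib_cv^2))
  lib <- rlnorm(nrow(samples), meanlog = log(config$lib_size_mean) - sigma^2 / 2,
                sdlog = sigma)
  donors <- unique(samples$donor)
  donor_eff <- matrix(rnorm(n * length(donors), 0, config$donor_sd),
                      nrow = n, dimnames = list(NULL, donors))
  w <- 2^baselines
  w <- w / sum(w)
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(feature_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- lib[j] * w * 2^(offsets[, samples$condition[j]] + donor_eff[, samples$donor[j]])
    counts[, j] <- rnbinom(n, mu = mu, size = 1 / config$dispersion)
  }
  counts
}

#' Simulate a paired RNA-seq + ATAC-seq experiment with planted truth
#'
#' Draws gene- and peak-level count matrices, genome annotation, motif hits,
#' and ground-truth tables under the design described in [sim_config()].
#'
#' @param config A `mempar_sim_config` from [sim_config()].
#' @return A `mempar_experiment` list with elements `samples`, `rna`, `atac`
#'   (count tibbles), `genes`, `peaks`, `motif_hits`, `motif_library`, and
#'   `truth` (gene/peak class tables, planted offset matrices, coupling map).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "mempar_sim_config"))
  withr::with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(config) {
  samples <- build_design(config)
  conditions <- distinct(samples, .data$lineage, .data$subset, .data$stim, .data$condition)

  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  peak_ids <- sprintf("peak_%04d", seq_len(config$n_peaks))

  # class assignment
  gene_class <- rep("none", config$n_genes)
  idx <- sample.int(config$n_genes, sum(config$n_per_gene_category))
  gene_class[idx] <- rep(names(config$n_per_gene_category), config$n_per_gene_category)
  par_class <- rep("conserved", config$n_peaks)
  idx <- sample.int(config$n_peaks, sum(config$n_per_par_category))
  par_class[idx] <- rep(names(config$n_per_par_category), config$n_per_par_category)

  # genome layout: evenly spaced genes with jitter, one chromosome
  spacing <- 20000L
  gene_len <- sample(1000:5000, config$n_genes, replace = TRUE)
  gene_start <- 5000L + (seq_len(config$n_genes) - 1L) * spacing +
    sample(-1000:1000, config$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- tibble(gene_id = gene_ids, chrom = "chr1",
                  start = gene_start, end = gene_start + gene_len,
                  strand = strand, length = gene_len) |>
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end))

  # coupling: augmented genes receive a primed peak next to their TSS
  augmented_genes <- which(gene_class == "augmented")
  primed_peaks <- which(par_class == "primed")
  coupled_genes <- augmented_genes[runif(length(augmented_genes)) < config$coupling_rate]
  if (length(coupled_genes) > length(primed_peaks)) {
    abort("not enough primed peaks to couple augmented genes; increase n_per_par_category['primed']")
  }
  coupled_peaks <- if (length(coupled_genes)) primed_peaks[seq_along(coupled_genes)] else integer(0)

  peak_center <- integer(config$n_peaks)
  half <- config$peak_width %/% 2L
  # coupled peaks: a slot within 2 kb of the target TSS (nearest TSS is the target
  # by construction since genes are ~20 kb apart)
  if (length(coupled_genes)) {
    slot <- sample(c(-6:-2, 2:6), length(coupled_genes), replace = TRUE) * 300L
    peak_center[coupled_peaks] <- genes$tss[coupled_genes] + slot
  }
  # all other peaks: slots around intergenic gap midpoints
  others <- setdiff(seq_len(config$n_peaks), coupled_peaks)
  gap_mid <- (genes$end[-config$n_genes] + genes$start[-1]) %/% 2L
  slots <- as.vector(outer(gap_mid, (-12:12) * 300L, `+`))
  if (length(others) > length(slots)) abort("genome too small for requested peak count")
  peak_center[others] <- sample(slots, length(others))
  peaks <- tibble(peak_id = peak_ids, chrom = "chr1",
                  start = peak_center - half, end = peak_center - half + config$peak_width,
                  score = 0, strand = ".") |>
    arrange(.data$start)

  # planted offsets and counts
  gene_base <- runif(config$n_genes, log2(5), log2(500))
  peak_base <- runif(config$n_peaks, log2(10), log2(200))
  gene_off <- planted_offsets(gene_class, conditions, config, "gene")
  peak_off <- planted_offsets(par_class, conditions, config, "par")
  rownames(gene_off) <- gene_ids
  rownames(peak_off) <- peak_ids

  rna_m <- draw_counts(gene_ids, gene_base, gene_off, samples, config)
  atac_m <- draw_counts(peak_ids, peak_base, peak_off, samples, config)
  rna <- bind_cols(tibble(feature_id = gene_ids, length = gene_len),
                   as_tibble(rna_m))
  atac <- bind_cols(tibble(feature_id = peak_ids), as_tibble(atac_m))

  # motifs: activation motifs in primed+stimulated peaks, memory motifs in
  # memory peaks, the rest background
  lib <- synthetic_motif_library()
  hit_rate <- matrix(0.05, nrow = config$n_peaks, ncol = nrow(lib),
                     dimnames = list(peak_ids, lib$motif_id))
  hit_rate[, lib$group == "background"] <- 0.10
  hit_rate[par_class %in% c("primed", "stimulated"), lib$group == "activation"] <- 0.70
  hit_rate[par_class == "memory", lib$group == "memory"] <- 0.70
  hit_rate[par_class == "naive", lib$group == "naive"] <- 0.70
  hits <- which(matrix(runif(length(hit_rate)), nrow = nrow(hit_rate)) < hit_rate,
                arr.ind = TRUE)
  motif_hits <- tibble(
    peak_id = peak_ids[hits[, 1]],
    motif_id = lib$motif_id[hits[, 2]],
    strand = sample(c("+", "-"), nrow(hits), replace = TRUE),
    score = round(runif(nrow(hits), 8, 15), 3)
  ) |> arrange(.data$peak_id, .data$motif_id)

  module_of <- c(expressed = 1L, induced = 2L, augmented = 3L,
                 naive_high = 4L, stim_global = 5L)
  truth <- list(
    gene_truth = tibble(gene_id = gene_ids, class = gene_class,
                        module = unname(module_of[gene_class])),
    peak_truth = tibble(peak_id = peak_ids, class = par_class),
    coupling = tibble(gene_id = gene_ids[coupled_genes],
                      peak_id = peak_ids[coupled_peaks]),
    gene_offsets = gene_off,
    peak_offsets = peak_off,
    gene_baseline = setNames(gene_base, gene_ids),
    peak_baseline = setNames(peak_base, peak_ids)
  )
  structure(list(samples = samples, rna = rna, atac = atac, genes = genes,
                 peaks = peaks, motif_hits = motif_hits, motif_library = lib,
                 truth = truth, config = config),
            class = "mempar_experiment")
}

#' Built-in synthetic motif library
#'
#' Twelve position count matrices built from fixed consensus sequences: an
#' activation-associated group (AP1/BATF/IRF4-like, planted in primed and
#' stimulated peaks by the simulator), a memory-associated group
#' (TBX21/EOMES-like, planted in memory peaks), a naive-associated group
#' (TCF/LEF-like, planted in naive peaks), and background motifs. All
#' matrices are synthetic; identifiers follow familiar TF names only to make
#' outputs readable.
#'
#' @return A `motif_library` tibble (see [read_motifs()]) with an extra
#'   `group` column.
#' @export
synthetic_motif_library <- function() {
  defs <- tibble(
    motif_id = c("AP1", "BATF", "IRF4", "TBX21", "EOMES", "TCF7", "LEF1",
                 "CTCF", "SP1", "NFYA", "ELK1", "ZEB1"),
    consensus = c("TGACTCA", "TGASTCA", "GAAANTGAAA", "AGGTGTGA", "AGGTGTTA",
                  "CTTTGTTC", "CTTTGATC",
                  "CCGCGAGG", "GGGGCGGG", "CCAATCAG", "ACCGGAAG", "CACCTG"),
    group = c("activation", "activation", "activation", "memory", "memory",
              "naive", "naive",
              "background", "background", "background", "background", "background")
  )
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  make_pcm <- function(consensus) {
    chars <- strsplit(consensus, "")[[1]]
    pcm <- matrix(1, nrow = 4, ncol = length(chars),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (k in seq_along(chars)) {
      if (chars[k] == "S") pcm[c("C", "G"), k] <- 9
      else if (chars[k] == "N") pcm[, k] <- 4.5
      else pcm[base_idx[chars[k]], k] <- 17
    }
    pcm
  }
  defs$pcm <- lapply(defs$consensus, make_pcm)
  defs$width <- vapply(defs$pcm, ncol, integer(1))
  defs$ppm <- lapply(defs$pcm, function(p) (p + 0.5) / rep(colSums(p) + 2, each = 4))
  lib <- defs |> select("motif_id", "width", "pcm", "ppm", "group")
  attr(lib, "background") <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  class(lib) <- c("motif_library", class(lib))
  lib
}

#' Simulate SCENITH and Seahorse fixtures
#'
#' SCENITH rows carry puromycin MFIs under control, 2-deoxy-glucose (DG),
#' oligomycin (O), and combined (DGO) treatments; planted group-level
#' dependence percentages are recovered by [scenith_metrics()] exactly at
#' zero noise. The ECAR trace has a basal phase followed by glucose,
#' oligomycin, and 2-DG injections.
#'
#' @param config A `mempar_sim_config`; `noise_sd` sets the relative
#'   measurement noise.
#' @param planted Optional tibble with columns `group`, `mito_dependence`,
#'   `glucose_dependence` overriding the built-in group table.
#' @param n_per_group Rows per group (default `n_donors`).
#' @return List with `scenith` (one row per measurement, with planted truth
#'   columns) and `seahorse` (ECAR trace tibble with injection annotation and
#'   planted metric attributes).
#' @export
simulate_metabolism <- function(config, planted = NULL, n_per_group = NULL) {
  stopifnot(inherits(config, "mempar_sim_config"))
  n_per_group <- n_per_group %||% config$n_donors
  planted <- planted %||% tibble(
    group = c("naive_unstim", "TCM_unstim", "TEM_unstim",
              "naive_stim", "TCM_stim", "TEM_stim"),
    mito_dependence = c(75, 65, 60, 40, 35, 30),
    glucose_dependence = c(45, 40, 40, 70, 72, 75)
  )
  withr::with_seed(child_seed(config$seed, "metabolism"), {
    scenith <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
      ctrl <- 1000 * exp(rnorm(n_per_group, 0, 0.05))
      dgo <- ctrl * 0.08
      o <- ctrl - planted$mito_dependence[i] / 100 * (ctrl - dgo)
      dg <- ctrl - planted$glucose_dependence[i] / 100 * (ctrl - dgo)
      jitter <- function(x) x * (1 + rnorm(n_per_group, 0, config$noise_sd))
      tibble(sample_id = sprintf("%s_r%d", planted$group[i], seq_len(n_per_group)),
             group = planted$group[i],
             MFI_ctrl = jitter(ctrl), MFI_DG = jitter(dg),
             MFI_O = jitter(o), MFI_DGO = jitter(dgo),
             true_mito = planted$mito_dependence[i],
             true_glucose = planted$glucose_dependence[i])
    })
    basal <- 20; glyc <- 30; cap_extra <- 30
    phase <- rep(c("basal", "glucose", "oligomycin", "2DG"), each = 3)
    level <- rep(c(basal, basal + glyc, basal + glyc + cap_extra, basal * 0.9), each = 3)
    seahorse <- tibble(
      time = seq(0, by = 7, length.out = 12),
      ecar = level * (1 + rnorm(12, 0, config$noise_sd)),
      phase = phase
    )
    attr(seahorse, "planted") <- c(glycolysis = glyc,
                                   glycolytic_capacity = glyc + cap_extra,
                                   glycolytic_reserve = cap_extra)
    list(scenith = scenith, seahorse = seahorse)
  })
}

#' Write a simulated experiment to disk as plain-text files
#'
#' Emits the sample sheet, both count matrices, gene annotation, peak BED,
#' motif hits, motif library, and truth tables under `dir`.
#'
#' @param experiment A `mempar_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_sample_sheet(experiment$samples, p("samples.tsv"))
  write_counts(experiment$rna, p("rna_counts.tsv"))
  write_counts(experiment$atac, p("atac_counts.tsv"))
  write_gene_annotation(experiment$genes, p("genes.tsv"))
  write_bed(experiment$peaks, p("peaks.bed"))
  readr::write_tsv(experiment$motif_hits, p("motif_hits.tsv"), progress = FALSE)
  write_motifs(experiment$motif_library, p("motifs.meme"))
  readr::write_tsv(experiment$truth$gene_truth, p("truth_genes.tsv"), progress = FALSE)
  readr::write_tsv(experiment$truth$peak_truth, p("truth_peaks.tsv"), progress = FALSE)
  readr::write_tsv(experiment$truth$coupling, p("truth_coupling.tsv"), progress = FALSE)
  paths <- c(samples = p("samples.tsv"), rna = p("rna_counts.tsv"),
             atac = p("atac_counts.tsv"), genes = p("genes.tsv"),
             peaks = p("peaks.bed"), motif_hits = p("motif_hits.tsv"),
             motifs = p("motifs.meme"), truth_genes = p("truth_genes.tsv"),
             truth_peaks = p("truth_peaks.tsv"), truth_coupling = p("truth_coupling.tsv"))
  invisible(paths)
}
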