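#' Assign each peak to its nearest TSS
#'
#' Peak anchor is the interval midpoint; the TSS is the start of `+` genes
#' and the end of `-` genes. Ties in absolute distance resolve to the
#' lexicographically smallest gene id. Signed distances are positive
#' downstream of the TSS relative to gene strand.
#'
#' @param peaks Peak tibble (`peak_id`, `chrom`, `start`, `end`).
#' @param genes Gene annotation tibble (with `tss`, see
#'   [read_gene_annotation()]).
#' @param max_distance Optional cap in bp; peaks farther than this from any
#'   TSS are left unassigned (dropped from the map).
#' @return Tibble `peak_id`, `gene_id`, `distance` (signed bp).
#' @export
nearest_tss <- function(peaks, genes, max_distance = Inf) {
  if (nrow(genes) == 0) abort("empty gene annotation")
  if (!"tss" %in% names(genes)) {
    genes <- mutate(genes, tss = if_else(.data$strand == "+", .data$start, .data$end))
  }
  center <- (peaks$start + peaks$end) / 2
  out <- purrr::map_dfr(unique(peaks$chrom), function(ch) {
    pk <- peaks[peaks$chrom == ch, ]
    gn <- genes[genes$chrom == ch, ]
    if (nrow(gn) == 0) return(tibble())
    ctr <- (pk$start + pk$end) / 2
    # one candidate per distinct TSS position: the smallest gene id there
    pos <- gn |>
      group_by(.data$tss) |>
      summarise(gene_id = min(.data$gene_id),
                strand = .data$strand[order(.data$gene_id)[1]],
                .groups = "drop") |>
      arrange(.data$tss)
    idx <- findInterval(ctr, pos$tss)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, nrow(pos))
    d_left <- abs(ctr - pos$tss[left])
    d_right <- abs(ctr - pos$tss[right])
    d_left[idx < 1L] <- Inf
    take_left <- d_left < d_right |
      (d_left == d_right & pos$gene_id[left] <= pos$gene_id[right])
    pick <- if_else(take_left, left, right)
    tss <- pos$tss[pick]
    strand <- pos$strand[pick]
    tibble(peak_id = pk$peak_id,
           gene_id = pos$gene_id[pick],
           distance = if_else(strand == "+", ctr - tss, tss - ctr))
  })
  filter(out, abs(.data$distance) <= max_distance)
}

#' Fraction of category genes with a PAR of a given type in cis
#'
#' @param category_genes Character vector of gene ids in the category.
#' @param map Peak-gene map from [nearest_tss()].
#' @param par_labels Tibble with `feature_id` (peak) and `par` columns, e.g.
#'   [par_union()] output or one subset of [classify_pars()].
#' @param target_par PAR label of interest (default `"primed"`).
#' @return Tibble with `n_genes`, `n_with_par`, `fraction`. An empty
#'   category yields `NA` fraction with a warning, not 0.
#' @export
fraction_with_par <- function(category_genes, map, par_labels, target_par = "primed") {
  if (!length(category_genes)) {
    warn("empty gene category; fraction undefined")
    return(tibble(n_genes = 0L, n_with_par = 0L, fraction = NA_real_))
  }
  target_peaks <- par_labels$feature_id[par_labels$par == target_par]
  genes_with <- unique(map$gene_id[map$peak_id %in% target_peaks])
  n_with <- sum(category_genes %in% genes_with)
  tibble(n_genes = length(category_genes), n_with_par = n_with,
         fraction = n_with / length(category_genes))
}

#' PAR-type composition of peaks near gene sets, vs a background set
#'
#' For each gene set, the proportion of each PAR type among peaks assigned
#' to its genes, compared against the peaks of a background set (the All-DEG
#' set in the usual workflow) by a two-proportion z-test, with Fisher's
#' exact test when any expected cell count is below 5. P-values are BH
#' adjusted across PAR types within each gene set.
#'
#' @param map Peak-gene map from [nearest_tss()].
#' @param par_labels Tibble with `feature_id`, `par`.
#' @param gene_sets Named list of gene id vectors; must include
#'   `background`.
#' @param background Name of the background set (default `"All DEG"`).
#' @return Tibble: `set`, `par`, `n`, `n_total`, `proportion`,
#'   `bg_proportion`, `p`, `fdr`.
#' @export
par_proportions <- function(map, par_labels, gene_sets, background = "All DEG") {
  if (!background %in% names(gene_sets)) {
    abort(sprintf("gene_sets must include the background set '%s'", background))
  }
  labelled <- inner_join(map, select(par_labels, "feature_id", "par"),
                         by = c(peak_id = "feature_id"))
  peaks_of <- function(gs) labelled[labelled$gene_id %in% gs, ]
  bg <- peaks_of(gene_sets[[background]])
  par_types <- sort(unique(labelled$par))
  purrr::map_dfr(names(gene_sets), function(nm) {
    fg <- peaks_of(gene_sets[[nm]])
    purrr::map_dfr(par_types, function(pt) {
      x <- c(sum(fg$par == pt), sum(bg$par == pt))
      n <- c(nrow(fg), nrow(bg))
      p <- if (any(n == 0)) {
        NA_real_
      } else if (identical(fg$peak_id, bg$peak_id)) {
        1.0  # the background compared to itself is null by construction
      } else {
        expected <- outer(c(sum(x), sum(n - x)), n) / sum(n)
        if (any(expected < 5)) {
          fisher.test(cbind(x, n - x))$p.value
        } else {
          suppressWarnings(prop.test(x, n)$p.value)
        }
      }
      tibble(set = nm, par = pt, n = x[1], n_total = n[1],
             proportion = x[1] / max(n[1], 1),
             bg_proportion = x[2] / max(n[2], 1), p = p)
    }) |> mutate(fdr = bh_adjust(.data$p))
  })
}

#' Fold-change distributions of genes stratified by PAR presence
#'
#' Summarizes DEG log2 fold-changes for genes with vs without at least one
#' peak of `target_par` in cis, per contrast, with a Wilcoxon rank-sum test
#' between strata.
#'
#' @param deg_results Named list of contrast tibbles (e.g.
#'   `list(resting = ..., stimulated = ...)`).
#' @param map Peak-gene map.
#' @param par_labels Tibble with `feature_id`, `par`.
#' @param target_par PAR label of interest.
#' @param genes Optional gene universe to restrict to (default: all genes in
#'   each contrast).
#' @return Tibble: `contrast`, `stratum`, `n`, `median`, `q25`, `q75`, `p`
#'   (Wilcoxon, duplicated across the two strata rows; `NA` with a warning
#'   when a stratum has fewer than 3 genes).
#' @export
fc_by_par_presence <- function(deg_results, map, par_labels,
                               target_par = "primed", genes = NULL) {
  target_peaks <- par_labels$feature_id[par_labels$par == target_par]
  genes_with <- unique(map$gene_id[map$peak_id %in% target_peaks])
  purrr::map_dfr(names(deg_results), function(nm) {
    res <- deg_results[[nm]]
    if (!is.null(genes)) res <- filter(res, .data$feature_id %in% genes)
    res <- filter(res, !is.na(.data$log2FC))
    with_fc <- res$log2FC[res$feature_id %in% genes_with]
    without_fc <- res$log2FC[res$feature_id %not in% genes_with]
    p <- if (length(with_fc) < 3 || length(without_fc) < 3) {
      warn(sprintf("contrast '%s': stratum with < 3 genes; Wilcoxon test skipped", nm))
      NA_real_
    } else {
      suppressWarnings(wilcox.test(with_fc, without_fc)$p.value)
    }
    summarise_stratum <- function(v, lab) {
      tibble(contrast = nm, stratum = lab, n = length(v),
             median = median(v), q25 = unname(quantile(v, 0.25)),
             q75 = unname(quantile(v, 0.75)), p = p)
    }
    bind_rows(summarise_stratum(with_fc, "with_par"),
              summarise_stratum(without_fc, "without_par"))
  })
}

#' Correlation of expression and accessibility fold-changes
#'
#' Pairs each gene's DEG log2FC with the log2FC of its mapped peak (the
#' peak with the largest |log2FC| when several map to the gene) and reports
#' the Pearson correlation.
#'
#' @param deg_results Gene contrast tibble.
#' @param dar_results Peak contrast tibble.
#' @param map Peak-gene map.
#' @return Tibble with `n`, `r`, `p`.
#' @export
fc_correlation <- function(deg_results, dar_results, map) {
  peak_fc <- dar_results |>
    select(peak_id = "feature_id", peak_lfc = "log2FC") |>
    inner_join(map, by = "peak_id") |>
    filter(!is.na(.data$peak_lfc)) |>
    group_by(.data$gene_id) |>
    slice(which.max(abs(.data$peak_lfc))) |>
    ungroup()
  paired <- deg_results |>
    select(gene_id = "feature_id", gene_lfc = "log2FC") |>
    inner_join(select(peak_fc, "gene_id", "peak_lfc"), by = "gene_id") |>
    filter(!is.na(.data$gene_lfc))
  if (nrow(paired) < 3) abort("fewer than 3 gene-peak pairs")
  ct <- cor.test(paired$gene_lfc, paired$peak_lfc)
  tibble(n = nrow(paired), r = unname(ct$estimate), p = ct$p.value)
}
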