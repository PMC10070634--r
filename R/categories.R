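#' Classify memory-differential genes into Expressed / Induced / Augmented
#'
#' Flags per gene and memory subset (DEG preset calls):
#' * `R`: memory vs naive, resting (C2)
#' * `S`: memory vs naive, stimulated (C3)
#' * `I_M`: memory stim vs memory unstim (C4)
#' * `I_N`: naive stim vs naive unstim (C1; reported as an annotation for
#'   expressed genes, not a gating condition)
#'
#' Decision table (first match wins), for `direction = "up"`:
#'
#' 1. `augmented`: higher in memory in both resting and stimulated states
#'    (R up, S up).
#' 2. `induced`: equal at rest, memory-specific induction on stimulation
#'    (R ns, S up, I_M up).
#' 3. `expressed`: higher in resting memory, naive catches up after
#'    stimulation (R up, S ns).
#' 4. otherwise `none`.
#'
#' `direction = "down"` applies the mirror-image table (up and down
#' swapped) to classify memory-downregulated genes.
#'
#' @param flags Tibble with character columns `R`, `S`, `I_M` (and
#'   optionally `I_N`), values `up`/`down`/`ns`.
#' @param direction `"up"` (default) or `"down"`.
#' @param lenient_expressed If `TRUE`, the expressed rule does not require
#'   `S = ns` (off by default).
#' @return `flags` with a `category` column.
#' @export
classify_gene <- function(flags, direction = c("up", "down"),
                          lenient_expressed = FALSE) {
  direction <- match.arg(direction)
  assert_columns(flags, c("R", "S", "I_M"), "flags")
  ids <- if ("feature_id" %in% names(flags)) flags$feature_id else seq_len(nrow(flags))
  for (cn in c("R", "S", "I_M")) {
    bad <- !(flags[[cn]] %in% c("up", "down", "ns"))
    if (any(bad)) {
      abort(sprintf("invalid or missing %s flag for feature '%s'", cn,
                    ids[which(bad)[1]]))
    }
  }
  hi <- direction           # "up" in the up table, "down" in the mirror
  expressed_s_ok <- if (lenient_expressed) rep(TRUE, nrow(flags)) else flags$S == "ns"
  flags$category <- dplyr::case_when(
    flags$R == hi & flags$S == hi ~ "augmented",
    flags$R == "ns" & flags$S == hi & flags$I_M == hi ~ "induced",
    flags$R == hi & expressed_s_ok ~ "expressed",
    .default = "none"
  )
  flags
}

#' Classify all genes of a lineage into memory expression categories
#'
#' Runs the four differential-expression contrasts per memory subset (DEG
#' preset: |log2FC| >= 1, FDR <= 0.05) and applies [classify_gene()].
#'
#' @param rna Gene count tibble.
#' @param samples Sample sheet.
#' @param lineage `"CD4"` or `"CD8"`.
#' @inheritParams classify_gene
#' @param lfc_min,fdr_max DEG thresholds.
#' @param dispersion_mode Passed to [nb_wald()].
#' @return Tibble: `feature_id`, `subset`, `R`, `S`, `I_M`, `I_N`,
#'   `category`, `direction`.
#' @export
categorize_genes <- function(rna, samples, lineage, direction = "up",
                             lenient_expressed = FALSE,
                             lfc_min = 1, fdr_max = 0.05,
                             dispersion_mode = "trend") {
  contrasts <- run_memory_contrasts(rna, samples, lineage, dispersion_mode)
  flags <- contrast_flag_table(contrasts, lfc_min, fdr_max, strict_lfc = FALSE) |>
    rename(I_N = "C1", R = "C2", S = "C3", I_M = "C4")
  out <- classify_gene(flags, direction = direction,
                       lenient_expressed = lenient_expressed)
  out$direction <- direction
  select(out, "feature_id", "subset", "R", "S", "I_M", "I_N", "category", "direction")
}

#' Tally gene categories per subset
#' @param category_table Output of [categorize_genes()].
#' @return Tibble of counts per (subset, category), zero-filled.
#' @export
gene_category_counts <- function(category_table) {
  cats <- c("expressed", "induced", "augmented", "none")
  by <- intersect(c("lineage", "subset"), names(category_table))
  category_table |>
    group_by(across(all_of(by))) |>
    count(category = factor(.data$category, levels = cats), .drop = FALSE) |>
    ungroup() |>
    mutate(category = as.character(.data$category))
}
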