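# Contrast scheme shared by the PAR and gene-category classifiers.
# For a memory subset M of one lineage:
#   C1: naive stim    vs naive unstim
#   C2: M unstim      vs naive unstim
#   C3: M stim        vs naive stim
#   C4: M stim        vs M unstim
contrast_pairs <- function(subset) {
  list(
    C1 = list(a = c("naive", "stim"), b = c("naive", "unstim")),
    C2 = list(a = c(subset, "unstim"), b = c("naive", "unstim")),
    C3 = list(a = c(subset, "stim"), b = c("naive", "stim")),
    C4 = list(a = c(subset, "stim"), b = c(subset, "unstim"))
  )
}

condition_samples <- function(samples, lineage, subset, stim) {
  samples$sample_id[samples$lineage == lineage &
                    samples$subset == subset & samples$stim == stim]
}

#' Run the four classifier contrasts for each memory subset of a lineage
#'
#' @param counts Count tibble (genes or peaks).
#' @param samples Sample sheet tibble.
#' @param lineage `"CD4"` or `"CD8"`.
#' @param dispersion_mode Passed to [nb_wald()].
#' @return Named list of contrast tibbles: `C1` (shared across subsets) and
#'   `C2_<subset>`, `C3_<subset>`, `C4_<subset>` per memory subset, with a
#'   `"subsets"` attribute.
#' @export
run_memory_contrasts <- function(counts, samples, lineage,
                                 dispersion_mode = "trend") {
  samples <- filter(samples, .data$lineage == !!lineage)
  if (nrow(samples) == 0) abort(sprintf("no %s samples in sample sheet", lineage))
  mem_subsets <- setdiff(unique(samples$subset), "naive")
  sf <- size_factors(counts[c("feature_id", intersect(names(counts), samples$sample_id))])
  run <- function(a, b) {
    nb_wald(counts,
            condition_samples(samples, lineage, a[1], a[2]),
            condition_samples(samples, lineage, b[1], b[2]),
            size_factors = sf, dispersion_mode = dispersion_mode)
  }
  out <- list()
  p1 <- contrast_pairs(mem_subsets[1])$C1
  out$C1 <- run(p1$a, p1$b)
  for (m in mem_subsets) {
    cp <- contrast_pairs(m)
    for (cn in c("C2", "C3", "C4")) {
      out[[paste(cn, m, sep = "_")]] <- run(cp[[cn]]$a, cp[[cn]]$b)
    }
  }
  attr(out, "subsets") <- mem_subsets
  attr(out, "lineage") <- lineage
  out
}

# Flags tibble (feature_id, subset, C1..C4) from a contrast list.
contrast_flag_table <- function(contrasts, lfc_min, fdr_max, strict_lfc) {
  subsets <- attr(contrasts, "subsets")
  c1 <- call_features(contrasts$C1, lfc_min, fdr_max, strict_lfc)
  universe <- c1$feature_id
  purrr::map_dfr(subsets, function(m) {
    flags <- tibble(feature_id = universe, subset = m, C1 = c1$call)
    for (cn in c("C2", "C3", "C4")) {
      res <- contrasts[[paste(cn, m, sep = "_")]]
      if (is.null(res)) abort(sprintf("missing contrast %s for subset %s", cn, m))
      if (!identical(res$feature_id, universe)) {
        abort("contrasts computed on mismatched feature universes")
      }
      flags[[cn]] <- call_features(res, lfc_min, fdr_max, strict_lfc)$call
    }
    flags
  })
}

#' Classify peaks into patterned-accessibility-region (PAR) categories
#'
#' Applies the PAR decision table to differential-accessibility calls from
#' the four contrasts (see [run_memory_contrasts()]). Rules are evaluated
#' top-down, first match wins:
#'
#' 1. `primed`: opened by stimulation in naive cells (C1 up) and already
#'    accessible in resting memory cells (C2 up).
#' 2. `stimulated`: accessible only after stimulation in both naive and
#'    memory cells (C1 up, C4 up, C2 ns).
#' 3. `memory`: memory-specific and stimulation-independent (C2 up, C3 up,
#'    C1 ns, C4 ns).
#' 4. `naive`: accessible in resting naive cells only (C1 down, C2 down).
#' 5. `conserved`: no differential call in any contrast.
#' 6. otherwise `unclassified`.
#'
#' @param flags Tibble with character columns `C1`-`C4` (values `up`,
#'   `down`, `ns`).
#' @param primed_rule `"directional"` (default; primed requires C1 and C2
#'   up) or `"nonzero"` (any significant non-zero fold-change in C1 and C2).
#' @return `flags` with a `par` column added.
#' @export
classify_par <- function(flags, primed_rule = c("directional", "nonzero")) {
  primed_rule <- match.arg(primed_rule)
  assert_columns(flags, c("C1", "C2", "C3", "C4"), "flags")
  ids <- if ("feature_id" %in% names(flags)) flags$feature_id else seq_len(nrow(flags))
  for (cn in c("C1", "C2", "C3", "C4")) {
    bad <- !(flags[[cn]] %in% c("up", "down", "ns"))
    if (any(bad)) {
      abort(sprintf("invalid or missing %s flag for feature '%s'", cn,
                    ids[which(bad)[1]]))
    }
  }
  primed <- if (primed_rule == "directional") {
    flags$C1 == "up" & flags$C2 == "up"
  } else {
    flags$C1 != "ns" & flags$C2 != "ns"
  }
  all_ns <- flags$C1 == "ns" & flags$C2 == "ns" & flags$C3 == "ns" & flags$C4 == "ns"
  flags$par <- dplyr::case_when(
    primed ~ "primed",
    flags$C1 == "up" & flags$C4 == "up" & flags$C2 == "ns" ~ "stimulated",
    flags$C2 == "up" & flags$C3 == "up" & flags$C1 == "ns" & flags$C4 == "ns" ~ "memory",
    flags$C1 == "down" & flags$C2 == "down" ~ "naive",
    all_ns ~ "conserved",
    .default = "unclassified"
  )
  flags
}

#' Classify all peaks of a lineage into PAR categories
#'
#' Runs the four differential-accessibility contrasts per memory subset
#' (DAR preset: |log2FC| > 1.5, FDR <= 0.05), derives contrast flags, and
#' applies [classify_par()].
#'
#' @param atac Peak count tibble.
#' @param samples Sample sheet.
#' @param lineage `"CD4"` or `"CD8"`.
#' @inheritParams classify_par
#' @param lfc_min,fdr_max,strict_lfc DAR thresholds.
#' @param dispersion_mode Passed to [nb_wald()].
#' @return Tibble: `feature_id`, `subset`, `C1`-`C4`, `par`.
#' @export
classify_pars <- function(atac, samples, lineage,
                          primed_rule = "directional",
                          lfc_min = 1.5, fdr_max = 0.05, strict_lfc = TRUE,
                          dispersion_mode = "trend") {
  contrasts <- run_memory_contrasts(atac, samples, lineage, dispersion_mode)
  flags <- contrast_flag_table(contrasts, lfc_min, fdr_max, strict_lfc)
  classify_par(flags, primed_rule = primed_rule)
}

#' Tally PAR categories
#'
#' @param par_table Output of [classify_pars()] (or any tibble with `subset`
#'   and `par` columns).
#' @return Tibble of counts per (subset, par), all categories present
#'   (zero-filled).
#' @export
par_category_counts <- function(par_table) {
  cats <- c("conserved", "stimulated", "primed", "memory", "naive", "unclassified")
  by <- intersect(c("lineage", "subset"), names(par_table))
  par_table |>
    group_by(across(all_of(by))) |>
    count(par = factor(.data$par, levels = cats), .drop = FALSE) |>
    ungroup() |>
    mutate(par = as.character(.data$par))
}

#' Union PAR label across memory subsets
#'
#' Summarizes per-subset PAR labels into one label per peak: the most
#' informative non-conserved label by the classifier's precedence order
#' (primed > stimulated > memory > naive), `unclassified` if only
#' unclassified, else `conserved`.
#'
#' @param par_table Output of [classify_pars()].
#' @return Tibble `feature_id`, `par`.
#' @export
par_union <- function(par_table) {
  prec <- c(primed = 1, stimulated = 2, memory = 3, naive = 4,
            unclassified = 5, conserved = 6)
  par_table |>
    group_by(.data$feature_id) |>
    summarise(par = names(prec)[min(prec[.data$par])], .groups = "drop")
}

#' Noise-free classifier flags from planted offsets
#'
#' Re-derives contrast calls directly from a simulation's planted log2 mean
#' offsets (no sampling noise): a contrast is `up`/`down` when the planted
#' fold-change passes the threshold rule, `ns` otherwise. Used to check that
#' generator truth labels and classifier rule tables agree exactly.
#'
#' @param experiment A `mempar_experiment`.
#' @param kind `"par"` (peak offsets, DAR rule) or `"gene"` (gene offsets,
#'   DEG rule).
#' @param lineage Lineage to derive flags for.
#' @return Flags tibble as consumed by [classify_par()] /
#'   [classify_gene()].
#' @export
planted_flags <- function(experiment, kind = c("par", "gene"), lineage = "CD8") {
  kind <- match.arg(kind)
  offs <- if (kind == "par") experiment$truth$peak_offsets else experiment$truth$gene_offsets
  lfc_min <- if (kind == "par") 1.5 else 1.0
  strict <- kind == "par"
  subsets <- setdiff(experiment$config$subsets_per_lineage[[lineage]], "naive")
  cond <- function(subset, stim) paste(lineage, subset, stim, sep = "_")
  flag_of <- function(lfc) {
    pass <- if (strict) abs(lfc) > lfc_min else abs(lfc) >= lfc_min
    if_else(pass, if_else(lfc > 0, "up", "down"), "ns")
  }
  purrr::map_dfr(subsets, function(m) {
    cp <- contrast_pairs(m)
    out <- tibble(feature_id = rownames(offs), subset = m)
    for (cn in names(cp)) {
      a <- cond(cp[[cn]]$a[1], cp[[cn]]$a[2])
      b <- cond(cp[[cn]]$b[1], cp[[cn]]$b[2])
      out[[cn]] <- flag_of(offs[, a] - offs[, b])
    }
    out
  })
}
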