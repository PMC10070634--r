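#' Resize peaks to a fixed width
#'
#' Re-centers each interval on its midpoint (or on `summit`, if that column
#' is present) and sets a fixed width, the convention used before motif
#' analysis. Intervals running past coordinate 0 are clipped to `[0, width)`
#' with a warning.
#'
#' @param peaks Peak tibble.
#' @param width Target width in bp (default 250).
#' @return Peak tibble with resized `start`/`end`.
#' @export
resize_peaks <- function(peaks, width = 250L) {
  center <- if ("summit" %in% names(peaks)) {
    peaks$summit
  } else {
    (peaks$start + peaks$end) %/% 2
  }
  half <- width %/% 2L
  new_start <- center - half
  new_end <- new_start + width
  clipped <- new_start < 0
  if (any(clipped)) {
    warn(sprintf("%d peak(s) clipped at coordinate 0", sum(clipped)))
    new_start[clipped] <- 0
    new_end[clipped] <- width
  }
  mutate(peaks, start = !!new_start, end = !!new_end)
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

revcomp <- function(seqs) {
  chartr("ACGTN", "TGCAN", vapply(seqs, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Log-odds scores of one motif along one encoded sequence (integer codes).
scan_one <- function(code, lo) {
  w <- ncol(lo)
  n <- length(code)
  if (n < w) return(numeric(0))
  score <- numeric(n - w + 1L)
  for (k in seq_len(w)) {
    score <- score + unname(lo[code[k:(n - w + k)], k])
  }
  score
}

#' Scan sequences for motif occurrences
#'
#' Log-odds scoring of each motif's probability matrix against the
#' background model, both strands: `score = sum log2(p_base / bg_base)`
#' over motif positions. A position is a hit when its score reaches
#' `threshold` times the motif's maximum attainable score. `N` bases
#' contribute 0.
#'
#' @param seqs Named character vector of sequences (A/C/G/T/N), names are
#'   peak ids.
#' @param motifs A `motif_library` (see [read_motifs()]).
#' @param threshold Fraction of the maximum score required for a hit
#'   (default 0.8).
#' @return Tibble: `peak_id`, `motif_id`, `position` (1-based, forward
#'   strand), `strand`, `score`. Sequences shorter than a motif simply
#'   yield no hits.
#' @export
scan_motifs <- function(seqs, motifs, threshold = 0.8) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%04d", seq_along(seqs))
  bg <- attr(motifs, "background") %||% c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  codes_f <- lapply(seqs, function(s) unname(DNA_CODE[strsplit(s, "")[[1]]]))
  codes_r <- lapply(revcomp(seqs), function(s) unname(DNA_CODE[strsplit(s, "")[[1]]]))
  purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    ppm <- motifs$ppm[[i]]
    lo <- rbind(log2(ppm / bg), 0)  # 5th row: N scores as background
    w <- ncol(lo)
    cutoff <- threshold * sum(apply(lo[1:4, , drop = FALSE], 2, max))
    purrr::map_dfr(seq_along(seqs), function(j) {
      n <- length(codes_f[[j]])
      hits_f <- scan_one(codes_f[[j]], lo)
      hits_r <- scan_one(codes_r[[j]], lo)
      pf <- which(hits_f >= cutoff)
      pr <- which(hits_r >= cutoff)
      bind_rows(
        tibble(peak_id = names(seqs)[j], motif_id = motifs$motif_id[i],
               position = pf, strand = "+", score = hits_f[pf]),
        tibble(peak_id = names(seqs)[j], motif_id = motifs$motif_id[i],
               position = n - (pr + w - 1L) + 1L, strand = "-", score = hits_r[pr])
      )
    })
  })
}

#' Hypergeometric motif enrichment of a foreground peak set
#'
#' For each motif, counts foreground and background peaks containing at
#' least one hit and computes the hypergeometric upper-tail p-value
#' (drawing `n_fg` peaks from the fg+bg universe). P-values are BH adjusted
#' across motifs; the enrichment flag applies `alpha_enrich` to the
#' adjusted (default) or nominal p-value.
#'
#' @param fg_peaks,bg_peaks Disjoint character vectors of peak ids
#'   (background defaults to everything in `hits` minus the foreground).
#' @param hits Motif hit tibble (`peak_id`, `motif_id`).
#' @param motifs Motif universe (default: motifs present in `hits`).
#' @param alpha_enrich Enrichment threshold (default 0.05).
#' @param use_adjusted Flag enrichment on BH-adjusted p (default) or
#'   nominal p.
#' @return Tibble: `motif_id`, `n_fg_with`, `n_fg`, `n_bg_with`, `n_bg`,
#'   `percent_fg`, `percent_bg`, `p`, `fdr`, `enriched`.
#' @export
motif_enrichment <- function(fg_peaks, bg_peaks = NULL, hits, motifs = NULL,
                             alpha_enrich = 0.05, use_adjusted = TRUE) {
  if (!length(fg_peaks)) abort("empty foreground peak set")
  bg_peaks <- bg_peaks %||% setdiff(unique(hits$peak_id), fg_peaks)
  if (length(intersect(fg_peaks, bg_peaks))) {
    abort("foreground and background peak sets overlap")
  }
  motifs <- motifs %||% sort(unique(hits$motif_id))
  n_fg <- length(fg_peaks)
  n_bg <- length(bg_peaks)
  res <- purrr::map_dfr(motifs, function(mo) {
    with_hit <- unique(hits$peak_id[hits$motif_id == mo])
    k_fg <- sum(fg_peaks %in% with_hit)
    k_bg <- sum(bg_peaks %in% with_hit)
    p <- phyper(k_fg - 1, k_fg + k_bg, n_fg + n_bg - k_fg - k_bg, n_fg,
                lower.tail = FALSE)
    tibble(motif_id = mo, n_fg_with = k_fg, n_fg = n_fg,
           n_bg_with = k_bg, n_bg = n_bg,
           percent_fg = 100 * k_fg / n_fg, percent_bg = 100 * k_bg / n_bg,
           p = p)
  })
  res$fdr <- bh_adjust(res$p)
  res$enriched <- (if (use_adjusted) res$fdr else res$p) <= alpha_enrich
  res
}

#' Rank-normalize motif enrichment across peak sets
#'
#' Within each peak set, motifs are ranked by ascending enrichment p-value
#' (ties: average rank) and the rank is divided by the number of enriched
#' motifs in that set, so a value of 0.1 means "ranked 1st of 10 enriched";
#' non-enriched motifs keep their normalized rank (which can exceed 1).
#' Normalized ranks are then z-scored per motif across sets for relative
#' comparison.
#'
#' @param enrichments Tibble with columns `set`, `motif_id`, `p`,
#'   `enriched` (e.g. several [motif_enrichment()] results bound together
#'   with a `set` column).
#' @return Tibble: `set`, `motif_id`, `rank`, `norm_rank`, `z`. Sets with
#'   zero enriched motifs are dropped with a warning.
#' @export
rank_normalize <- function(enrichments) {
  assert_columns(enrichments, c("set", "motif_id", "p", "enriched"), "enrichments")
  n_enr <- enrichments |>
    group_by(.data$set) |>
    summarise(n_enriched = sum(.data$enriched), .groups = "drop")
  dead <- n_enr$set[n_enr$n_enriched == 0]
  if (length(dead)) {
    warn(sprintf("peak set(s) with no enriched motifs dropped: %s",
                 paste(dead, collapse = ", ")))
    enrichments <- filter(enrichments, .data$set %not in% dead)
  }
  if (!nrow(enrichments)) abort("no peak set with enriched motifs")
  out <- enrichments |>
    left_join(n_enr, by = "set") |>
    group_by(.data$set) |>
    mutate(rank = rank(.data$p, ties.method = "average"),
           norm_rank = .data$rank / .data$n_enriched) |>
    group_by(.data$motif_id) |>
    mutate(z = {
      s <- sd(.data$norm_rank)
      if (is.na(s) || s == 0) rep(0, dplyr::n())
      else (.data$norm_rank - mean(.data$norm_rank)) / s
    }) |>
    ungroup()
  select(out, "set", "motif_id", "rank", "norm_rank", "z")
}

#' Matrix view of a rank-normalized enrichment table
#'
#' @param rank_tbl Output of [rank_normalize()].
#' @param value Column to spread (`"norm_rank"` or `"z"`).
#' @return Numeric matrix, peak sets x motifs.
#' @export
rank_matrix <- function(rank_tbl, value = "norm_rank") {
  wide <- tidyr::pivot_wider(select(rank_tbl, "set", "motif_id", all_of(value)),
                             names_from = "motif_id", values_from = all_of(value))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$set
  m
}

#' Bootstrap support for a hierarchical clustering of peak sets
#'
#' Complete-linkage clustering of peak sets on Euclidean distances between
#' enrichment-rank profiles, with bipartition support estimated by
#' resampling motif columns with replacement `B` times.
#'
#' @param x Numeric matrix, peak sets (leaves) x motifs.
#' @param B Number of bootstrap resamples (default 500; < 100 warns).
#' @param seed RNG seed.
#' @return List: `tree` (an `ape` phylo with node labels = % support),
#'   `support` (numeric per internal node), `B`.
#' @export
bootstrap_dendrogram <- function(x, B = 500, seed = 1L) {
  if (nrow(x) < 3) abort("need at least 3 peak sets (leaves)")
  if (B < 100) warn("B < 100 gives unstable support values")
  build <- function(mat) ape::as.phylo(hclust(dist(mat), method = "complete"))
  tree <- build(x)
  boots <- withr::with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(x), replace = TRUE)
      build(x[, cols, drop = FALSE])
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / B
  tree$node.label <- formatC(support, format = "f", digits = 0)
  list(tree = tree, support = support, B = B)
}
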