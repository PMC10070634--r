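#' Build a TF-to-gene regulatory network for one condition
#'
#' Draws a directed edge TF -> gene whenever one of the TF's motifs hits a
#' peak that (a) is accessible in the condition (mean normalized
#' accessibility at or above `accessibility_floor`) and (b) maps to the
#' gene. Edge weight is the motif hit score times `log1p` of the peak's
#' accessibility, summed over supporting peaks. The personalization vector
#' is proportional to expression over all nodes (genes and TFs), floored at
#' a small positive value so every node retains restart mass.
#'
#' To rank regulators, run [pagerank()] with `reverse = TRUE`: expression
#' mass then flows from target genes back to the TFs that bind them, so a
#' TF scores high when it regulates many accessible, highly expressed
#' genes.
#'
#' @param hits Motif hit tibble (`peak_id`, `motif_id`, optionally `score`;
#'   missing scores count as 1).
#' @param map Peak-gene map from [nearest_tss()].
#' @param accessibility Named numeric: mean normalized ATAC signal per peak
#'   in the condition.
#' @param expression Named numeric: mean expression (e.g. RPKM) per gene in
#'   the condition; TF nodes use their own entry when present.
#' @param tf_map Tibble with `tf`, `motif_id` linking TF node names to
#'   motifs; TFs without any motif are excluded with a warning.
#' @param accessibility_floor Minimum accessibility for a peak to support
#'   edges (default 1).
#' @return A `mempar_tf_network`: list with `edges` (from, to, weight) and
#'   `nodes` (node, type, personalization).
#' @export
build_tf_network <- function(hits, map, accessibility, expression, tf_map,
                             accessibility_floor = 1) {
  assert_columns(tf_map, c("tf", "motif_id"), "tf_map")
  no_motif <- unique(tf_map$tf[is.na(tf_map$motif_id) |
                               tf_map$motif_id %not in% hits$motif_id])
  have <- setdiff(unique(tf_map$tf), no_motif)
  if (length(no_motif)) {
    warn(sprintf("TF(s) without motif hits excluded: %s",
                 paste(no_motif, collapse = ", ")))
  }
  if (!"score" %in% names(hits)) hits$score <- 1
  acc <- accessibility[accessibility >= accessibility_floor]
  edges <- hits |>
    filter(.data$peak_id %in% names(acc)) |>
    inner_join(filter(tf_map, .data$tf %in% have), by = "motif_id",
               relationship = "many-to-many") |>
    inner_join(map, by = "peak_id", relationship = "many-to-many") |>
    mutate(w = .data$score * log1p(acc[.data$peak_id])) |>
    group_by(from = .data$tf, to = .data$gene_id) |>
    summarise(weight = sum(.data$w), .groups = "drop")
  nodes <- tibble(node = union(have, unique(c(edges$to, names(expression)))),
                  type = if_else(union(have, unique(c(edges$to, names(expression)))) %in% have,
                                 "TF", "gene"))
  pers <- expression[nodes$node]
  pers[is.na(pers)] <- 0
  pers <- pmax(pers, 1e-8 * max(pers, 1))
  nodes$personalization <- pers / sum(pers)
  structure(list(edges = edges, nodes = nodes), class = "mempar_tf_network")
}

#' Personalized PageRank
#'
#' Power iteration of `score = d * W^T score + (1 - d) * personalization`
#' with out-weight-normalized columns; the mass of dangling nodes (no
#' outgoing edges) is redistributed according to the personalization
#' vector. Scores sum to 1 and are invariant to uniform edge-weight
#' scaling.
#'
#' @param network A `mempar_tf_network` (or any list with `edges` and
#'   `nodes` in the same shape).
#' @param d Damping factor (default 0.85); `d = 0` returns the
#'   personalization.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param reverse Walk the edges backwards (to -> from). For a TF -> gene
#'   regulatory network this sends expression mass from target genes to
#'   their regulators, the orientation under which a TF's score reflects
#'   the expression and accessibility of its targets.
#' @return A `mempar_pagerank` object; see [tidy.mempar_pagerank()].
#' @export
pagerank <- function(network, d = 0.85, tol = 1e-10, max_iter = 1000,
                     reverse = FALSE) {
  edges <- network$edges
  if (reverse) edges <- rename(edges, from = "to", to = "from")
  nodes <- network$nodes
  if (nrow(edges) == 0) abort("network has no edges")
  if (any(edges$weight < 0) || any(!is.finite(edges$weight))) {
    abort("edge weights must be finite and non-negative")
  }
  n <- nrow(nodes)
  id <- nodes$node
  from <- match(edges$from, id)
  to <- match(edges$to, id)
  if (anyNA(from) || anyNA(to)) abort("edge endpoints missing from node table")
  out_w <- numeric(n)
  agg <- rowsum(edges$weight, from)
  out_w[as.integer(rownames(agg))] <- agg[, 1]
  wn <- edges$weight / out_w[from]
  pers <- nodes$personalization / sum(nodes$personalization)
  dangling <- out_w == 0
  score <- pers
  residual <- Inf
  for (it in seq_len(max_iter)) {
    inflow <- numeric(n)
    contrib <- rowsum(wn * score[from], to)
    inflow[as.integer(rownames(contrib))] <- contrib[, 1]
    new <- d * (inflow + sum(score[dangling]) * pers) + (1 - d) * pers
    residual <- sum(abs(new - score))
    score <- new
    if (residual < tol) break
  }
  if (residual >= tol) {
    abort(sprintf("PageRank did not converge in %d iterations (residual %.3g)",
                  max_iter, residual))
  }
  structure(list(scores = setNames(score, id), type = nodes$type,
                 d = d, iterations = it, residual = residual,
                 n_edges = nrow(edges)),
            class = "mempar_pagerank")
}

#' @export
print.mempar_pagerank <- function(x, ...) {
  cat(sprintf("Personalized PageRank: %d nodes, %d edges, d = %.2f, %d iterations\n",
              length(x$scores), x$n_edges, x$d, x$iterations))
  invisible(x)
}

#' Tidy a PageRank result
#' @param x A `mempar_pagerank`.
#' @param ... Unused.
#' @return Tibble: `node`, `type`, `score`, sorted by decreasing score.
#' @export
tidy.mempar_pagerank <- function(x, ...) {
  tibble(node = names(x$scores), type = x$type, score = unname(x$scores)) |>
    arrange(desc(.data$score))
}

#' @rdname tidy.mempar_pagerank
#' @export
glance.mempar_pagerank <- function(x, ...) {
  tibble(n_nodes = length(x$scores), n_edges = x$n_edges, d = x$d,
         iterations = x$iterations, residual = x$residual)
}

#' Log2 change in TF PageRank between two networks
#'
#' @param pr_memory,pr_naive `mempar_pagerank` objects on the same TF
#'   universe (memory and naive conditions).
#' @param floor Score floor guarding against division by ~0.
#' @return Tibble: `node`, `log2_change` (positive = more important in the
#'   memory network); TFs missing from one network get `NA`.
#' @export
tf_rank_change <- function(pr_memory, pr_naive, floor = 1e-12) {
  tm <- tidy(pr_memory) |> filter(.data$type == "TF")
  tn <- tidy(pr_naive) |> filter(.data$type == "TF")
  all_tf <- sort(union(tm$node, tn$node))
  sm <- setNames(tm$score, tm$node)[all_tf]
  sn <- setNames(tn$score, tn$node)[all_tf]
  tibble(node = all_tf,
         log2_change = log2(pmax(sm, floor) / pmax(sn, floor)) +
           ifelse(is.na(sm) | is.na(sn), NA_real_, 0))
}
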