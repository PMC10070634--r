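#' Filter genes for module discovery
#'
#' Keeps differential genes with robust expression: RPKM >= `min_rpkm` in
#' every sample of at least one sample group (condition).
#'
#' @param rpkm_tbl RPKM tibble from [rpkm()].
#' @param deg_genes Character vector of differential gene ids (DEG union).
#' @param samples Sample sheet; groups are `lineage_subset_stim` conditions.
#' @param min_rpkm Expression floor (default 3 RPKM).
#' @return Character vector of retained gene ids.
#' @export
filter_module_genes <- function(rpkm_tbl, deg_genes, samples, min_rpkm = 3) {
  m <- count_matrix(rpkm_tbl)
  samples <- filter(samples, .data$sample_id %in% colnames(m))
  cond <- paste(samples$lineage, samples$subset, samples$stim, sep = "_")
  ok_any_group <- rep(FALSE, nrow(m))
  for (g in unique(cond)) {
    cols <- samples$sample_id[cond == g]
    grp_min <- apply(m[, cols, drop = FALSE], 1, min)
    ok_any_group <- ok_any_group | grp_min >= min_rpkm
  }
  keep <- rownames(m)[ok_any_group & rownames(m) %in% deg_genes]
  if (!length(keep)) {
    abort("no genes pass the module filter; review the DEG set and RPKM threshold")
  }
  keep
}

#' Per-gene z-scored group-mean expression profiles
#'
#' Averages log2(RPKM + 1) within each sample group and z-scores each gene's
#' profile, the input shape used for module clustering.
#'
#' @param rpkm_tbl RPKM tibble.
#' @param samples Sample sheet.
#' @param gene_ids Optional subset of genes (rows).
#' @return Numeric matrix, genes x groups, each row mean 0 / sd 1 (constant
#'   rows are centered only).
#' @export
expression_profiles <- function(rpkm_tbl, samples, gene_ids = NULL) {
  m <- log2(count_matrix(rpkm_tbl) + 1)
  if (!is.null(gene_ids)) m <- m[gene_ids, , drop = FALSE]
  samples <- filter(samples, .data$sample_id %in% colnames(m))
  cond <- paste(samples$lineage, samples$subset, samples$stim, sep = "_")
  groups <- unique(cond)
  gm <- vapply(groups, function(g) {
    rowMeans(m[, samples$sample_id[cond == g], drop = FALSE])
  }, numeric(nrow(m)))
  mu <- rowMeans(gm)
  s <- apply(gm, 1, sd)
  z <- (gm - mu) / ifelse(s > 0, s, 1)
  rownames(z) <- rownames(m)
  z
}

#' Estimate the fuzzy c-means fuzzifier from data dimensions
#'
#' Empirical formula relating the fuzzifier `m` to the number of clustered
#' items `N` and profile dimensionality `D`:
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#'
#' @param D Profile dimensionality (>= 2).
#' @param N Number of clustered features (>= 10).
#' @return The fuzzifier, a real > 1.
#' @export
estimate_fuzzifier <- function(D, N) {
  stopifnot(D >= 2, N >= 10)
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

# Seeded k-means++ initial centroids.
kmeanspp_init <- function(X, c) {
  n <- nrow(X)
  centers <- matrix(0, nrow = c, ncol = ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - rep(centers[1, ], each = n))^2)
  for (k in seq_len(c - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k + 1, ] <- X[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums((X - rep(centers[k + 1, ], each = n))^2))
  }
  centers
}

#' Fuzzy c-means clustering
#'
#' Alternating-optimization fuzzy c-means with Euclidean distances:
#' memberships `u_ic = (sum_k (d_ic/d_ik)^(2/(m-1)))^-1` and centroids
#' `v_c = sum_i u_ic^m x_i / sum_i u_ic^m`, iterated until the largest
#' centroid shift falls below `tol`. Initialization is k-means++ from a
#' seeded RNG, so results are deterministic given `seed`. A point that
#' coincides with a centroid receives membership 1 there (0 elsewhere). The
#' objective `J = sum u^m d^2` is checked to be non-increasing at every
#' iteration.
#'
#' @param X Numeric matrix (features x dimensions), finite.
#' @param c Number of clusters (2 <= c < nrow(X)).
#' @param m Fuzzifier (> 1); default from [estimate_fuzzifier()].
#' @param tol Convergence tolerance on centroid shift.
#' @param max_iter Iteration cap.
#' @param seed RNG seed for initialization.
#' @return A `mempar_fcm` object: memberships, centroids, hard labels
#'   (argmax membership, ties to the lowest cluster index), membership
#'   scores, and the objective trajectory. See [tidy.mempar_fcm()].
#' @export
fuzzy_cmeans <- function(X, c, m = NULL, tol = 1e-6, max_iter = 200, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("X must be finite")
  if (c < 2 || c >= nrow(X)) abort("need 2 <= c < number of rows")
  m <- m %||% estimate_fuzzifier(ncol(X), nrow(X))
  if (m <= 1) abort("fuzzifier must be > 1")
  n <- nrow(X)
  v <- withr::with_seed(seed, kmeanspp_init(X, c))
  expo <- -1 / (m - 1)
  objective <- numeric(0)
  memberships <- function(v) {
    d2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(v) +
      outer(rep(1, n), rowSums(v^2))
    d2 <- pmax(d2, 0)
    u <- d2^expo
    zero <- d2 < 1e-300
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- 0
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    u <- u / rowSums(u)
    list(u = u, d2 = d2)
  }
  for (it in seq_len(max_iter)) {
    mem <- memberships(v)
    um <- mem$u^m
    v_new <- (t(um) %*% X) / colSums(um)
    J <- sum(um * mem$d2)
    if (length(objective) && J > tail(objective, 1) + 1e-8 * abs(tail(objective, 1))) {
      abort(sprintf("fuzzy c-means objective increased at iteration %d", it))
    }
    objective <- c(objective, J)
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) break
  }
  mem <- memberships(v)
  hard <- max.col(mem$u, ties.method = "first")
  out <- list(membership = mem$u, centroids = v,
              hard_label = hard,
              membership_score = mem$u[cbind(seq_len(n), hard)],
              objective = objective, c = c, m = m,
              iterations = length(objective),
              converged = length(objective) < max_iter,
              feature_id = rownames(X) %||% as.character(seq_len(n)))
  class(out) <- "mempar_fcm"
  out
}

#' @export
print.mempar_fcm <- function(x, ...) {
  cat(sprintf("Fuzzy c-means: %d features, c = %d, m = %.3f, J = %.4g (%d iterations)\n",
              length(x$feature_id), x$c, x$m, tail(x$objective, 1), x$iterations))
  invisible(x)
}

#' Tidy a fuzzy c-means fit
#'
#' @param x A `mempar_fcm` object.
#' @param ... Unused.
#' @return One row per feature: `feature_id`, `module` (hard label),
#'   `membership_score`, and one `u<k>` column per cluster.
#' @export
tidy.mempar_fcm <- function(x, ...) {
  u <- as_tibble(x$membership, .name_repair = ~ sprintf("u%d", seq_along(.x)))
  bind_cols(tibble(feature_id = x$feature_id, module = x$hard_label,
                   membership_score = x$membership_score), u)
}

#' @rdname tidy.mempar_fcm
#' @export
glance.mempar_fcm <- function(x, ...) {
  tibble(c = x$c, m = x$m, objective = tail(x$objective, 1),
         iterations = x$iterations, converged = x$converged)
}

#' Select the cluster count by the within-SSE elbow
#'
#' Runs [fuzzy_cmeans()] over candidate cluster counts and picks the
#' smallest `c` whose relative objective decrease to `c + 1` falls below
#' `threshold` (default 10%). With no elbow anywhere the minimum candidate
#' is returned with a warning; an elbow already at the smallest candidate
#' also warns (no cluster structure detected).
#'
#' @inheritParams fuzzy_cmeans
#' @param candidates Integer vector of cluster counts to evaluate.
#' @param threshold Relative decrease defining the elbow.
#' @return List with `c` (selected count) and `wss` (tibble of `c`,
#'   `objective`).
#' @export
select_c <- function(X, candidates = 2:8, m = NULL, threshold = 0.10, seed = 1L) {
  candidates <- sort(unique(as.integer(candidates)))
  fits <- purrr::map_dbl(candidates, function(ci) {
    tail(fuzzy_cmeans(X, ci, m = m, seed = seed)$objective, 1)
  })
  wss <- tibble(c = candidates, objective = fits)
  drops <- -diff(fits) / fits[-length(fits)]
  below <- which(drops < threshold)
  if (!length(below)) {
    warn("no elbow found; returning the minimum candidate")
    sel <- candidates[1]
  } else {
    sel <- candidates[below[1]]
    if (sel == candidates[1]) {
      warn("elbow at the minimum candidate; data may lack cluster structure")
    }
  }
  list(c = sel, wss = wss)
}

#' Project three-group expression onto barycentric (tri-wise) coordinates
#'
#' Centers each row and projects onto three unit axes at 90, 210, and 330
#' degrees: `p = sum_g (e_g - mean(e)) v_g`. A gene upregulated in exactly
#' one group falls on that group's axis; radial distance scales with
#' fold-change magnitude.
#'
#' @param e Numeric matrix or data frame with 3 columns (log-expression per
#'   group), or a length-3 vector.
#' @return Tibble with `x`, `y`.
#' @export
triwise_project <- function(e) {
  if (is.null(dim(e))) e <- matrix(e, nrow = 1)
  e <- as.matrix(e)
  if (ncol(e) != 3) abort("triwise_project expects exactly 3 groups")
  if (!all(is.finite(e))) abort("e must be finite")
  ang <- c(90, 210, 330) * pi / 180
  v <- cbind(cos(ang), sin(ang))
  centered <- e - rowMeans(e)
  p <- centered %*% v
  tibble(x = p[, 1], y = p[, 2])
}
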