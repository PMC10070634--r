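#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each sample, the median across features of
#' the ratio between the sample's count and the feature's geometric mean,
#' computed over features with all-positive counts.
#'
#' @param counts Count tibble (see [read_counts()]).
#' @return A tibble with columns `sample_id`, `size_factor`.
#' @details If no feature has all-positive counts, falls back to ratios of
#'   library sizes (total counts over their geometric mean) with a warning.
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    warn("no feature with all-positive counts; using library-size ratios")
    ls <- colSums(m)
    s <- ls / geom_mean(ls)
  } else {
    mp <- m[pos, , drop = FALSE]
    loggm <- rowMeans(log(mp))
    s <- apply(mp / exp(loggm), 2, median)
  }
  if (any(!is.finite(s)) || any(s <= 0)) abort("non-positive size factor")
  tibble(sample_id = colnames(m), size_factor = unname(s))
}

#' RPKM normalization
#'
#' `rpkm = count / (length/1e3 * library_size/1e6)`.
#'
#' @param counts Count tibble with a `length` column (bp).
#' @param lib_sizes Optional named numeric of per-sample library sizes;
#'   defaults to column totals.
#' @return Tibble of RPKM values with the same shape as `counts`.
#' @export
rpkm <- function(counts, lib_sizes = NULL) {
  if (!"length" %in% names(counts)) abort("rpkm requires a 'length' column")
  if (any(counts$length <= 0)) abort("rpkm: zero or negative feature length")
  m <- count_matrix(counts)
  lib_sizes <- lib_sizes %||% colSums(m)
  lib_sizes <- lib_sizes[colnames(m)]
  out <- m / (counts$length / 1e3) / rep(lib_sizes / 1e6, each = nrow(m))
  bind_cols(tibble(feature_id = counts$feature_id, length = counts$length),
            as_tibble(out))
}

# Method-of-moments NB dispersion from normalized counts, per feature.
# Var(k/s) = mu/s + alpha*mu^2, so alpha = (v - mu*mean(1/s)) / mu^2.
mom_dispersion <- function(z, sf, groups) {
  ests <- ws <- matrix(0, nrow = nrow(z), ncol = length(groups))
  for (g in seq_along(groups)) {
    cols <- groups[[g]]
    zg <- z[, cols, drop = FALSE]
    mg <- rowMeans(zg)
    vg <- row_vars(zg)
    a <- (vg - mg * mean(1 / sf[cols])) / mg^2
    ok <- is.finite(a)
    ests[, g] <- ifelse(ok, a, 0)
    ws[, g] <- ifelse(ok, length(cols) - 1, 0)
  }
  raw <- rowSums(ests * ws) / pmax(rowSums(ws), 1)
  pmax(raw, 1e-8)
}

# Parametric mean-dispersion trend alpha(mu) = a0 + a1/mu, fit on features
# with usable moment estimates.
dispersion_trend <- function(alpha, base_mean) {
  ok <- is.finite(alpha) & alpha > 1e-6 & is.finite(base_mean) & base_mean > 0
  if (sum(ok) < 20) {
    a0 <- median(alpha[is.finite(alpha)], na.rm = TRUE)
    return(function(mu) rep(max(a0, 1e-8), length(mu)))
  }
  fit <- stats::lm(alpha[ok] ~ I(1 / base_mean[ok]))
  a0 <- max(unname(fit$coefficients[1]), 1e-8)
  a1 <- max(unname(fit$coefficients[2]), 0)
  function(mu) pmax(a0 + a1 / pmax(mu, 1e-8), 1e-8)
}

# Newton solve of the per-group NB mean with offsets log(s_j):
# sum_j (k_ij - s_j e^b) / (1 + alpha_i s_j e^b) = 0.
fit_group_log_mean <- function(k, sf, alpha, max_iter = 50, tol = 1e-12) {
  tot <- rowSums(k)
  zero <- tot == 0  # kept at a continuity-corrected mean, not iterated
  beta <- log((tot + 0.5 * zero) / sum(sf))
  for (it in seq_len(max_iter)) {
    mu <- exp(beta) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((k - mu) / denom)
    info <- rowSums(mu * (1 + alpha * k) / denom^2)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    step[zero] <- 0
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(beta) %o% sf
  list(beta = beta, info = rowSums(mu / (1 + alpha * mu)))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' A transparent NB generalized linear model with log link, group-saturated
#' design, and log size-factor offsets. Dispersion is estimated per feature
#' by method of moments on normalized counts (floored at 1e-8), optionally
#' shrunk to a parametric mean-dispersion trend. The Wald statistic
#' `log2FC / se` is referred to a standard normal, two-sided. Fold-changes
#' are reported as group A over group B.
#'
#' @param counts Count tibble.
#' @param group_a,group_b Character vectors of sample ids (>= 2 each).
#' @param size_factors Optional tibble from [size_factors()]; computed from
#'   the tested samples if omitted.
#' @param dispersion_mode `"trend"` (moment estimates shrunk toward the
#'   fitted trend; default), `"per_feature"` (raw moment estimates), or
#'   `"pooled"` (a single median dispersion for all features).
#' @return A contrast tibble: `feature_id`, `baseMean`, `log2FC`, `se`,
#'   `stat`, `p`, `fdr`. Features with all-zero counts across the tested
#'   samples get `NA` statistics and are excluded from the
#'   Benjamini-Hochberg denominator.
#' @export
nb_wald <- function(counts, group_a, group_b, size_factors = NULL,
                    dispersion_mode = c("trend", "per_feature", "pooled")) {
  dispersion_mode <- match.arg(dispersion_mode)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  m <- count_matrix(counts)
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) abort(paste("samples not in count table:", paste(missing, collapse = ", ")))
  m <- m[, c(group_a, group_b), drop = FALSE]

  if (is.null(size_factors)) {
    sub <- counts[c("feature_id", c(group_a, group_b))]
    size_factors <- size_factors(sub)
  }
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)[colnames(m)]
  if (anyNA(sf)) abort("size factors missing for some tested samples")

  nonzero <- rowSums(m) > 0
  z <- m / rep(sf, each = nrow(m))
  base_mean <- rowMeans(z)

  groups <- list(A = group_a, B = group_b)
  alpha_raw <- mom_dispersion(z, sf, groups)
  alpha <- switch(dispersion_mode,
    per_feature = alpha_raw,
    pooled = rep(max(median(alpha_raw[nonzero]), 1e-8), length(alpha_raw)),
    trend = {
      tr <- dispersion_trend(alpha_raw[nonzero], base_mean[nonzero])(base_mean)
      # moderate the per-feature estimate toward the trend; weights are the
      # residual degrees of freedom vs. a prior mass equivalent to 20 samples
      df <- ncol(m) - 2
      exp((df * log(pmax(alpha_raw, 1e-8)) + 20 * log(tr)) / (df + 20))
    })

  fa <- fit_group_log_mean(m[, group_a, drop = FALSE], sf[group_a], alpha)
  fb <- fit_group_log_mean(m[, group_b, drop = FALSE], sf[group_b], alpha)
  lfc <- (fa$beta - fb$beta) / log(2)
  se <- sqrt(1 / pmax(fa$info, 1e-12) + 1 / pmax(fb$info, 1e-12)) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))

  res <- tibble(feature_id = rownames(m), baseMean = unname(base_mean),
                log2FC = unname(lfc), se = unname(se), stat = unname(stat),
                p = unname(p))
  res$log2FC[!nonzero] <- NA_real_
  res$se[!nonzero] <- NA_real_
  res$stat[!nonzero] <- NA_real_
  res$p[!nonzero] <- NA_real_
  res$fdr <- bh_adjust(res$p)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#' `NA` p-values are propagated and excluded from the denominator.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Threshold differential calls
#'
#' Adds a `call` column (`up`, `down`, `ns`) to a contrast result. The DEG
#' preset uses an inclusive fold-change threshold (|log2FC| >= 1, FDR <=
#' 0.05); the DAR preset a strict one (|log2FC| > 1.5, FDR <= 0.05).
#'
#' @param res Contrast tibble from [nb_wald()].
#' @param lfc_min Fold-change threshold (log2).
#' @param fdr_max FDR threshold.
#' @param strict_lfc If `TRUE`, require `|log2FC| > lfc_min` instead of `>=`.
#' @return `res` with a `call` column (`NA` statistics give `ns`).
#' @export
call_features <- function(res, lfc_min = 1, fdr_max = 0.05, strict_lfc = FALSE) {
  assert_columns(res, c("log2FC", "fdr"), "contrast result")
  pass_lfc <- if (strict_lfc) abs(res$log2FC) > lfc_min else abs(res$log2FC) >= lfc_min
  sig <- !is.na(res$fdr) & !is.na(res$log2FC) & pass_lfc & res$fdr <= fdr_max
  res$call <- if_else(sig, if_else(res$log2FC > 0, "up", "down"), "ns")
  res
}

#' @rdname call_features
#' @export
deg_calls <- function(res) call_features(res, lfc_min = 1, fdr_max = 0.05, strict_lfc = FALSE)

#' @rdname call_features
#' @export
dar_calls <- function(res) call_features(res, lfc_min = 1.5, fdr_max = 0.05, strict_lfc = TRUE)

#' GSEA pre-ranking metric
#'
#' `sign(log2FC) * -log10(p)`; a fold-change of exactly zero scores 0, and
#' p = 0 is clamped to the smallest positive double with a warning.
#'
#' @param log2FC,p Numeric vectors of equal length.
#' @return Numeric scores.
#' @export
gsea_rank_metric <- function(log2FC, p) {
  stopifnot(length(log2FC) == length(p))
  if (any(p == 0, na.rm = TRUE)) {
    warn("p = 0 clamped to the smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  sign(log2FC) * -log10(p)
}
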