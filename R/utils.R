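# Internal helpers shared across modules.

# Convert a counts tibble (feature_id [, length], sample columns) to a
# numeric matrix with feature_id rownames.
count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "feature_id" %in% names(counts))
  meta <- intersect(names(counts), c("feature_id", "length"))
  m <- as.matrix(counts[setdiff(names(counts), meta)])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  m
}

# Sample columns of a counts tibble (everything except feature metadata).
sample_cols <- function(counts) {
  setdiff(names(counts), c("feature_id", "length"))
}

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

# Stable geometric mean of positive values on the log scale.
geom_mean <- function(x) exp(mean(log(x)))

`%not in%` <- function(x, table) !(x %in% table)

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Deterministic child seed derived from a base seed and a stage tag.
# Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}
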