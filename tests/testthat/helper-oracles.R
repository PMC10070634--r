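# Shared fixtures and independent oracles used across test files.

# Small, fast simulation configs.
tiny_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_genes = 300, n_peaks = 300, lineages = "CD8",
             n_per_gene_category = c(expressed = 25, induced = 25, augmented = 30,
                                     naive_high = 25, stim_global = 25),
             n_per_par_category = c(stimulated = 30, primed = 60,
                                    memory = 25, naive = 25), ...)
}

null_config <- function(seed = 1, n_genes = 2000, n_peaks = 50) {
  sim_config(seed = seed, n_genes = n_genes, n_peaks = n_peaks, lineages = "CD8",
             effect_lfc = 0, dispersion = 0.1, donor_sd = 0,
             n_per_gene_category = c(expressed = 0, induced = 0, augmented = 0,
                                     naive_high = 0, stim_global = 0),
             n_per_par_category = c(stimulated = 0, primed = 0,
                                    memory = 0, naive = 0))
}

# Adjusted Rand index from a confusion table.
ari <- function(truth, labels) {
  tab <- table(truth, labels)
  n <- sum(tab)
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  i <- sum(choose(tab, 2))
  e <- a * b / choose(n, 2)
  (i - e) / ((a + b) / 2 - e)
}

# Gaussian blob data with planted cluster structure.
make_blobs <- function(k = 5, per = 100, d = 8, sep = 3, sd = 0.1, seed = 42) {
  withr::with_seed(seed, {
    ctr <- matrix(rnorm(k * d), k, d)
    ctr <- ctr / sqrt(rowSums(ctr^2)) * sep
    X <- ctr[rep(1:k, each = per), ] + matrix(rnorm(k * per * d, 0, sd), k * per, d)
    rownames(X) <- sprintf("g%04d", seq_len(nrow(X)))
    list(X = X, truth = rep(1:k, each = per))
  })
}

# Independent PAR oracle: literal transcription of the verbal category
# definitions, one nested decision per category, no shared code with the
# package's case_when table.
par_oracle <- function(c1, c2, c3, c4) {
  opened_in_naive_by_stim <- c1 == "up"
  already_open_resting_memory <- c2 == "up"
  if (opened_in_naive_by_stim && already_open_resting_memory) return("primed")
  if (opened_in_naive_by_stim && c4 == "up" && c2 == "ns") return("stimulated")
  memory_specific <- c2 == "up" && c3 == "up"
  if (memory_specific && c1 == "ns" && c4 == "ns") return("memory")
  if (c1 == "down" && c2 == "down") return("naive")
  if (all(c(c1, c2, c3, c4) == "ns")) return("conserved")
  "unclassified"
}

# Independent gene-category oracle (up direction).
gene_oracle <- function(r, s, i_m) {
  higher_in_memory_both_states <- r == "up" && s == "up"
  if (higher_in_memory_both_states) return("augmented")
  equal_at_rest <- r == "ns"
  induced_on_stim_in_memory <- s == "up" && i_m == "up"
  if (equal_at_rest && induced_on_stim_in_memory) return("induced")
  if (r == "up" && s == "ns") return("expressed")
  "none"
}

flag_levels <- c("up", "down", "ns")
all_flag_combos <- function(n) {
  do.call(expand.grid, c(rep(list(flag_levels), n), stringsAsFactors = FALSE))
}

# Exhaustive hypergeometric upper-tail oracle: P(X >= k) by direct summation
# of the sampling distribution of marked peaks in the foreground draw.
hyper_tail_oracle <- function(k, n_marked, n_unmarked, n_draw) {
  ks <- k:min(n_draw, n_marked)
  sum(choose(n_marked, ks) * choose(n_unmarked, n_draw - ks)) /
    choose(n_marked + n_unmarked, n_draw)
}
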