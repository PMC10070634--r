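mini_genes <- function(...) {
  g <- tibble::tibble(...)
  dplyr::mutate(g, tss = dplyr::if_else(strand == "+", start, end))
}

test_that("nearest_tss picks the closest TSS with the documented conventions", {
  genes <- mini_genes(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(1000, 2200), end = c(1900, 3000),
                      strand = "+", length = c(900, 800))
  peaks <- tibble::tibble(peak_id = "p1", chrom = "chr1", start = 1375, end = 1625)
  map <- nearest_tss(peaks, genes)  # center 1500: 500 vs 700
  expect_equal(map$gene_id, "gA")
  expect_equal(map$distance, 500)

  # exact tie resolves to the lexicographically smaller gene id
  tie_genes <- mini_genes(gene_id = c("gB", "gA"), chrom = "chr1",
                          start = c(2000, 1000), end = c(2900, 1900),
                          strand = "+", length = 900)
  tie_peak <- tibble::tibble(peak_id = "p", chrom = "chr1", start = 1375, end = 1625)
  expect_equal(nearest_tss(tie_peak, tie_genes)$gene_id, "gA")

  # minus-strand gene: TSS at its end, upstream distances are positive
  minus <- mini_genes(gene_id = "gM", chrom = "chr1", start = 2000, end = 3000,
                      strand = "-", length = 1000)
  pk <- tibble::tibble(peak_id = "p", chrom = "chr1", start = 3375, end = 3625)
  mp <- nearest_tss(pk, minus)
  expect_equal(mp$distance, -500)  # peak lies downstream-negative side of a minus gene

  expect_error(nearest_tss(pk, minus[0, ]), "empty gene annotation")
})

test_that("nearest_tss agrees with a brute-force oracle and is total", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      genes <- mini_genes(gene_id = sprintf("g%02d", sample(1:50, 20)),
                          chrom = sample(c("chr1", "chr2"), 20, TRUE),
                          start = sample.int(1e5, 20),
                          end = 0, strand = sample(c("+", "-"), 20, TRUE),
                          length = sample(500:2000, 20, TRUE))
      genes$end <- genes$start + genes$length
      genes <- dplyr::mutate(genes,
                             tss = dplyr::if_else(strand == "+", start, end))
      peaks <- tibble::tibble(peak_id = sprintf("p%03d", 1:40),
                              chrom = sample(c("chr1", "chr2"), 40, TRUE),
                              start = sample.int(1e5, 40))
      peaks$end <- peaks$start + 250
      map <- nearest_tss(peaks, genes)
      expect_equal(sort(map$peak_id), sort(peaks$peak_id))  # total
      for (i in seq_len(nrow(peaks))) {
        ctr <- (peaks$start[i] + peaks$end[i]) / 2
        cand <- genes[genes$chrom == peaks$chrom[i], ]
        d <- abs(ctr - cand$tss)
        best <- cand$gene_id[d == min(d)]
        expect_equal(map$gene_id[map$peak_id == peaks$peak_id[i]], min(best))
      }
    }
  })
})

test_that("max_distance leaves far peaks unassigned", {
  genes <- mini_genes(gene_id = "g", chrom = "chr1", start = 1000, end = 2000,
                      strand = "+", length = 1000)
  peaks <- tibble::tibble(peak_id = c("near", "far"), chrom = "chr1",
                          start = c(900, 50000), end = c(1150, 50250))
  map <- nearest_tss(peaks, genes, max_distance = 5000)
  expect_equal(map$peak_id, "near")
})

test_that("fraction_with_par computes the documented share", {
  map <- tibble::tibble(peak_id = paste0("p", 1:5),
                        gene_id = c("g1", "g2", "g3", "g4", "g9"),
                        distance = 0)
  labels <- tibble::tibble(feature_id = paste0("p", 1:5),
                           par = c("primed", "primed", "primed", "primed", "conserved"))
  out <- fraction_with_par(paste0("g", 1:5), map, labels, "primed")
  expect_equal(out$fraction, 0.8)
  expect_equal(fraction_with_par(paste0("g", 1:5), map, labels, "memory")$fraction, 0)
  expect_warning(empty <- fraction_with_par(character(0), map, labels), "empty")
  expect_true(is.na(empty$fraction))
  # monotone non-decreasing as peaks are added
  more <- dplyr::bind_rows(map, tibble::tibble(peak_id = "p6", gene_id = "g5", distance = 0))
  labels2 <- dplyr::bind_rows(labels, tibble::tibble(feature_id = "p6", par = "primed"))
  expect_gte(fraction_with_par(paste0("g", 1:5), more, labels2, "primed")$fraction,
             out$fraction)
})

test_that("par_proportions flags extreme enrichment and is null on itself", {
  map <- tibble::tibble(peak_id = sprintf("p%03d", 1:110),
                        gene_id = c(rep("gset", 10), sprintf("gbg%02d", rep(1:50, 2))),
                        distance = 0)
  labels <- tibble::tibble(feature_id = sprintf("p%03d", 1:110),
                           par = c(rep("primed", 10), rep(c("primed", "conserved"),
                                                          c(20, 80))))
  sets <- list(focus = "gset", `All DEG` = unique(map$gene_id))
  out <- par_proportions(map, labels, sets)
  focus_primed <- out[out$set == "focus" & out$par == "primed", ]
  expect_equal(focus_primed$proportion, 1)
  expect_lt(focus_primed$p, 0.05)
  bg_rows <- out[out$set == "All DEG", ]
  expect_true(all(bg_rows$p == 1))
  expect_error(par_proportions(map, labels, list(a = "g1")), "background")
})

test_that("small-count enrichment p-values match exhaustive enumeration", {
  # 10 foreground peaks (6 with the mark) vs 100 background (30 with it)
  map <- tibble::tibble(peak_id = sprintf("p%03d", 1:110),
                        gene_id = c(rep("fg", 10), sprintf("bg%02d", rep(1:50, 2))),
                        distance = 0)
  labels <- tibble::tibble(feature_id = sprintf("p%03d", 1:110),
                           par = rep(c("primed", "other", "primed", "other"),
                                     c(6, 4, 30, 70)))
  out <- par_proportions(map, labels, list(fg = "fg", `All DEG` = unique(map$gene_id)))
  # oracle: Fisher-style enumeration of 2x2 tables at least as extreme,
  # computed from first principles via the hypergeometric pmf
  # focus set (6 primed of 10) against the full background (42 primed of 120):
  # condition on the margins and enumerate the first cell
  pm <- dhyper(0:10, 42, 78, 10)
  p_two_sided <- sum(pm[pm <= pm[7] * (1 + 1e-7)])
  got <- out$p[out$set == "fg" & out$par == "primed"]
  expect_equal(got, p_two_sided, tolerance = 1e-6)
})

test_that("fold-change stratification orders planted coupling correctly", {
  withr::with_seed(41, {
    deg <- list(resting = tibble::tibble(feature_id = sprintf("g%02d", 1:40),
                                         log2FC = c(rnorm(20, 2), rnorm(20, 0))))
  })
  map <- tibble::tibble(peak_id = sprintf("p%02d", 1:20),
                        gene_id = sprintf("g%02d", 1:20), distance = 0)
  labels <- tibble::tibble(feature_id = sprintf("p%02d", 1:20), par = "primed")
  out <- fc_by_par_presence(deg, map, labels, "primed")
  med_with <- out$median[out$stratum == "with_par"]
  med_without <- out$median[out$stratum == "without_par"]
  expect_gt(med_with, med_without)
  expect_lt(out$p[1], 0.01)

  # identical strata: p = 1
  deg_same <- list(x = tibble::tibble(feature_id = sprintf("g%02d", 1:40),
                                      log2FC = rep(c(1, 2, 3, 4), 10)))
  out_same <- fc_by_par_presence(deg_same, map, labels, "primed")
  expect_equal(out_same$p[1], 1, tolerance = 0.05)

  # small stratum warns and skips the test
  tiny_map <- map[1:2, ]
  tiny_labels <- labels[1:2, ]
  expect_warning(out_small <- fc_by_par_presence(
    list(x = tibble::tibble(feature_id = c("g01", "g02", "g03"),
                            log2FC = c(1, 2, 3))),
    tiny_map, tiny_labels, "primed"), "skipped")
  expect_true(all(is.na(out_small$p)))
})

test_that("expression-accessibility correlation tracks planted coupling", {
  withr::with_seed(43, {
    gene_fc <- rnorm(200)
    deg <- tibble::tibble(feature_id = sprintf("g%03d", 1:200), log2FC = gene_fc)
    dar_pos <- tibble::tibble(feature_id = sprintf("p%03d", 1:200),
                              log2FC = gene_fc + rnorm(200, 0, 0.2))
    dar_neg <- tibble::tibble(feature_id = sprintf("p%03d", 1:200),
                              log2FC = -gene_fc + rnorm(200, 0, 0.2))
    dar_null <- tibble::tibble(feature_id = sprintf("p%03d", 1:200),
                               log2FC = rnorm(200))
  })
  map <- tibble::tibble(peak_id = sprintf("p%03d", 1:200),
                        gene_id = sprintf("g%03d", 1:200), distance = 0)
  expect_gt(fc_correlation(deg, dar_pos, map)$r, 0.9)
  expect_lt(fc_correlation(deg, dar_neg, map)$r, -0.9)
  expect_lt(abs(fc_correlation(deg, dar_null, map)$r), 0.15)
  expect_error(fc_correlation(deg[1:2, ], dar_pos[1:2, ], map[1:2, ]), "fewer than 3")
})
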