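test_that("resize recenters on the midpoint at fixed width", {
  peaks <- tibble::tibble(peak_id = c("a", "b"), chrom = "chr1",
                          start = c(100, 1000), end = c(500, 1250))
  out <- resize_peaks(peaks, 250)
  expect_equal(out$start, c(175, 1000))  # centers 300 and 1125
  expect_equal(out$end, c(425, 1250))
  expect_true(all(out$end - out$start == 250))

  near0 <- tibble::tibble(peak_id = "o", chrom = "chr1", start = 0, end = 60)
  expect_warning(clipped <- resize_peaks(near0, 250), "clipped")
  expect_equal(c(clipped$start, clipped$end), c(0, 250))

  with_summit <- dplyr::mutate(peaks[1, ], summit = 400)
  out_s <- resize_peaks(with_summit, 250)
  expect_equal(c(out_s$start, out_s$end), c(275, 525))
})

test_that("motif scanning finds consensus sites on both strands", {
  lib <- synthetic_motif_library()
  ap1 <- lib[lib$motif_id == "AP1", ]
  hits_f <- scan_motifs(c(p1 = "AAATGACTCAAAA"), ap1)
  expect_equal(nrow(hits_f), 1)
  expect_equal(hits_f$strand, "+")
  expect_equal(hits_f$position, 4L)

  # reverse complement of the non-palindromic consensus: minus-strand hit only
  hits_r <- scan_motifs(c(p2 = "TTTTGAGTCATTT"), ap1)
  expect_equal(nrow(hits_r), 1)
  expect_equal(hits_r$strand, "-")

  # too-short sequences yield no hits, no error
  expect_equal(nrow(scan_motifs(c(s = "TGA"), ap1)), 0)

  # N bases score as background: consensus with N still reaches threshold 0.6
  hits_n <- scan_motifs(c(p3 = "AAATGACNCAAAA"), ap1, threshold = 0.6)
  expect_true(any(hits_n$strand == "+"))
})

test_that("scanning is strand-symmetric", {
  lib <- synthetic_motif_library()
  withr::with_seed(51, {
    seqs <- vapply(1:10, function(i) {
      paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("s%02d", 1:10)
  fwd <- scan_motifs(seqs, lib, threshold = 0.7)
  rc <- mempar:::revcomp(seqs)
  names(rc) <- names(seqs)
  rev <- scan_motifs(rc, lib, threshold = 0.7)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$score), sort(rev$score))
  tab_f <- table(factor(fwd$strand, c("+", "-")))
  tab_r <- table(factor(rev$strand, c("+", "-")))
  expect_equal(unname(tab_f[["+"]]), unname(tab_r[["-"]]))
})

test_that("background hit rates match the closed-form expectation", {
  lib <- synthetic_motif_library()
  ap1 <- lib[lib$motif_id == "AP1", ]
  lo <- rbind(log2(ap1$ppm[[1]] / 0.25), 0)
  cutoff <- 0.8 * sum(apply(lo[1:4, ], 2, max))
  # per-position hit probability under iid uniform bases, by enumeration
  # over the per-column score distributions (independent positions)
  probs <- rep(1 / 4, 4)
  dist <- 0
  for (k in seq_len(ncol(lo))) {
    dist <- outer(dist, lo[1:4, k], `+`)
  }
  p_pos <- mean(dist >= cutoff)
  withr::with_seed(53, {
    seqs <- vapply(1:300, function(i) {
      paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("s%03d", seq_along(seqs))
  hits <- scan_motifs(seqs, ap1, threshold = 0.8)
  n_windows <- 300 * (50 - 7 + 1) * 2
  observed_rate <- nrow(hits) / n_windows
  expect_lt(observed_rate, 2 * p_pos + 1e-4)
  expect_gt(observed_rate, p_pos / 2 - 1e-4)
})

test_that("hypergeometric enrichment equals brute-force enumeration", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      n_fg <- sample(4:12, 1)
      n_bg <- sample(20:60, 1)
      fg <- sprintf("f%02d", seq_len(n_fg))
      bg <- sprintf("b%02d", seq_len(n_bg))
      marked <- c(sample(fg, sample.int(n_fg, 1)), sample(bg, sample.int(n_bg, 1)))
      hits <- tibble::tibble(peak_id = marked, motif_id = "M")
      res <- motif_enrichment(fg, bg, hits, motifs = "M")
      k <- res$n_fg_with
      p_oracle <- hyper_tail_oracle(k, length(marked),
                                    n_fg + n_bg - length(marked), n_fg)
      expect_equal(res$p, p_oracle, tolerance = 1e-12)
    }
  })
})

test_that("enrichment behaves at the extremes and validates inputs", {
  fg <- sprintf("f%02d", 1:10); bg <- sprintf("b%02d", 1:50)
  all_fg <- tibble::tibble(peak_id = fg, motif_id = "M")
  res <- motif_enrichment(fg, bg, all_fg, motifs = "M")
  expect_equal(res$p, hyper_tail_oracle(10, 10, 50, 10), tolerance = 1e-12)
  expect_true(res$enriched)

  # equal frequencies: clearly not enriched
  eq <- tibble::tibble(peak_id = c(fg[1:5], bg[1:25]), motif_id = "M")
  res_eq <- motif_enrichment(fg, bg, eq, motifs = "M")
  expect_gt(res_eq$p, 0.4)
  expect_false(res_eq$enriched)

  expect_error(motif_enrichment(character(0), bg, all_fg), "empty")
  expect_error(motif_enrichment(fg, c(bg, fg[1]), all_fg), "overlap")
})

test_that("rank normalization divides by the enriched count and z-scales", {
  enr <- tibble::tibble(
    set = rep(c("s1", "s2"), each = 10),
    motif_id = rep(sprintf("m%02d", 1:10), 2),
    p = c(seq(0.001, 0.01, length.out = 10), seq(0.001, 0.01, length.out = 10)),
    enriched = c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)))
  out <- rank_normalize(enr)
  expect_equal(out$norm_rank[out$set == "s1" & out$motif_id == "m01"], 1 / 10)
  expect_equal(out$norm_rank[out$set == "s2" & out$motif_id == "m01"], 1 / 5)
  # identical p-values across sets: z degenerates to 0 only when sd = 0
  same <- tibble::tibble(set = rep(c("a", "b"), each = 3),
                         motif_id = rep(c("x", "y", "z"), 2),
                         p = rep(c(0.001, 0.01, 0.1), 2),
                         enriched = rep(c(TRUE, TRUE, FALSE), 2))
  expect_true(all(rank_normalize(same)$z == 0))
  # z rows have mean 0, sd 1 where defined
  withr::with_seed(57, {
    rnd <- tibble::tibble(set = rep(c("a", "b", "c"), each = 8),
                          motif_id = rep(sprintf("m%d", 1:8), 3),
                          p = runif(24), enriched = rep(TRUE, 24))
  })
  zt <- rank_normalize(rnd) |>
    dplyr::group_by(motif_id) |>
    dplyr::summarise(mu = mean(z), s = sd(z))
  expect_true(all(abs(zt$mu) < 1e-9))
  expect_true(all(abs(zt$s - 1) < 1e-9 | zt$s == 0))

  dead <- dplyr::mutate(same, enriched = dplyr::if_else(set == "b", FALSE, enriched))
  expect_warning(out2 <- rank_normalize(dead), "dropped")
  expect_false("b" %in% out2$set)
})

test_that("bootstrap dendrograms recover planted block structure", {
  withr::with_seed(59, {
    block1 <- matrix(rnorm(3 * 20, mean = 0, sd = 0.3), 3, 20)
    block2 <- matrix(rnorm(3 * 20, mean = 3, sd = 0.3), 3, 20)
  })
  x <- rbind(block1, block2)
  rownames(x) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  out <- bootstrap_dendrogram(x, B = 200, seed = 3)
  # the bipartition separating the two blocks must be near-universally supported
  expect_gte(max(out$support), 95)
  # determinism
  out2 <- bootstrap_dendrogram(x, B = 200, seed = 3)
  expect_equal(out$support, out2$support)
  expect_equal(ape::write.tree(out$tree), ape::write.tree(out2$tree))

  expect_warning(b1 <- bootstrap_dendrogram(x, B = 50, seed = 1), "unstable")
  expect_true(all(b1$support %in% seq(0, 100, by = 2)))
  one <- bootstrap_dendrogram(x, B = 101, seed = 1)
  expect_true(all(one$support >= 0 & one$support <= 100))
  expect_error(bootstrap_dendrogram(x[1:2, ], B = 200), "at least 3")

  # duplicated leaves sit at distance zero and always cluster together
  dup <- rbind(x, a1b = x["a1", ])
  outd <- bootstrap_dendrogram(dup, B = 120, seed = 2)
  expect_equal(min(dist(dup[c("a1", "a1b"), ])), 0)
})
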