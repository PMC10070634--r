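counts_2x2 <- tibble::tibble(feature_id = c("f1", "f2"),
                             s1 = c(10L, 30L), s2 = c(20L, 60L))

test_that("size factors match the median-of-ratios hand computation", {
  sf <- size_factors(counts_2x2)
  # geometric means: sqrt(200), sqrt(1800); ratios both 1/sqrt(2) and sqrt(2)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

  same <- tibble::tibble(feature_id = c("f1", "f2"), a = c(5L, 9L), b = c(5L, 9L))
  expect_equal(size_factors(same)$size_factor, c(1, 1))

  # ratios to the geometric mean are invariant to global rescaling
  all_scaled <- dplyr::mutate(counts_2x2, s1 = s1 * 2L, s2 = s2 * 2L)
  expect_equal(size_factors(all_scaled)$size_factor,
               size_factors(counts_2x2)$size_factor)
  # scaling one column scales the ratio of size factors by the same amount
  one_scaled <- dplyr::mutate(counts_2x2, s2 = s2 * 2L)
  r0 <- with(size_factors(counts_2x2), size_factor[2] / size_factor[1])
  r1 <- with(size_factors(one_scaled), size_factor[2] / size_factor[1])
  expect_equal(r1, 2 * r0)

  zeroy <- tibble::tibble(feature_id = c("f1", "f2"), a = c(0L, 4L), b = c(3L, 0L))
  expect_warning(sf0 <- size_factors(zeroy), "library-size")
  expect_equal(sf0$size_factor, c(4 / sqrt(12), 3 / sqrt(12)))
})

test_that("rpkm follows its defining arithmetic", {
  tbl <- tibble::tibble(feature_id = "g", length = 2000, s1 = 100L)
  expect_equal(rpkm(tbl, lib_sizes = c(s1 = 1e6))$s1, 50)
  tbl0 <- tibble::tibble(feature_id = "g", length = 2000, s1 = 0L)
  expect_equal(rpkm(tbl0, lib_sizes = c(s1 = 1e6))$s1, 0)
  expect_equal(rpkm(tbl, lib_sizes = c(s1 = 2e6))$s1, 25)
  bad <- tibble::tibble(feature_id = "g", length = 0, s1 = 1L)
  expect_error(rpkm(bad, lib_sizes = c(s1 = 1e6)), "length")
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.01, NA, 0.04, 0.5)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[-2], bh_adjust(p[-2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH is invariant under permutation of input order", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      p <- runif(50)
      perm <- sample.int(50)
      expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
    }
  })
})

test_that("threshold presets follow the inclusive/strict rules", {
  res <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        log2FC = c(1.2, 0.8, 1.5, -1.6),
                        fdr = c(0.01, 0.001, 0.01, 0.01))
  deg <- deg_calls(res)
  expect_equal(deg$call, c("up", "ns", "up", "down"))
  dar <- dar_calls(res)
  expect_equal(dar$call, c("ns", "ns", "ns", "down"))  # 1.5 fails the strict rule
  na_res <- tibble::tibble(feature_id = "x", log2FC = NA_real_, fdr = NA_real_)
  expect_equal(deg_calls(na_res)$call, "ns")
})

test_that("GSEA rank metric is the signed -log10 p", {
  expect_equal(gsea_rank_metric(2, 0.001), 3)
  expect_equal(gsea_rank_metric(-0.5, 0.01), -2)
  expect_equal(gsea_rank_metric(0, 0.01), 0)
  expect_warning(out <- gsea_rank_metric(1, 0), "clamped")
  expect_true(is.finite(out))
})

test_that("nb_wald returns null results for identical groups", {
  tbl <- tibble::tibble(feature_id = sprintf("g%d", 1:5),
                        a1 = c(10L, 40L, 5L, 100L, 7L), a2 = c(10L, 40L, 5L, 100L, 7L),
                        b1 = c(10L, 40L, 5L, 100L, 7L), b2 = c(10L, 40L, 5L, 100L, 7L))
  res <- nb_wald(tbl, c("a1", "a2"), c("b1", "b2"))
  expect_equal(res$log2FC, rep(0, 5), tolerance = 1e-8)
  expect_equal(res$p, rep(1, 5), tolerance = 1e-8)
})

test_that("nb_wald is antisymmetric under group swap and validates input", {
  withr::with_seed(4, {
    tbl <- tibble::tibble(feature_id = sprintf("g%d", 1:50),
                          a1 = rnbinom(50, mu = 50, size = 10),
                          a2 = rnbinom(50, mu = 50, size = 10),
                          a3 = rnbinom(50, mu = 50, size = 10),
                          b1 = rnbinom(50, mu = 100, size = 10),
                          b2 = rnbinom(50, mu = 100, size = 10),
                          b3 = rnbinom(50, mu = 100, size = 10))
  })
  ab <- nb_wald(tbl, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  ba <- nb_wald(tbl, c("b1", "b2", "b3"), c("a1", "a2", "a3"))
  expect_equal(ab$log2FC, -ba$log2FC, tolerance = 1e-8)
  expect_equal(ab$p, ba$p, tolerance = 1e-8)
  expect_error(nb_wald(tbl, "a1", c("b1", "b2")), "at least 2")
  expect_error(nb_wald(tbl, c("a1", "zz"), c("b1", "b2")), "not in")
})

test_that("all-zero features are excluded from the BH denominator", {
  tbl <- tibble::tibble(feature_id = c("z", sprintf("g%d", 1:9)),
                        a1 = c(0L, rep(20L, 9)), a2 = c(0L, rep(25L, 9)),
                        b1 = c(0L, rep(22L, 9)), b2 = c(0L, rep(18L, 9)))
  res <- nb_wald(tbl, c("a1", "a2"), c("b1", "b2"))
  expect_true(is.na(res$p[1]) && is.na(res$fdr[1]))
  expect_equal(res$fdr[-1], bh_adjust(res$p[-1]))
})

test_that("planted fold-changes are recovered without material bias", {
  withr::with_seed(14, {
    n <- 300
    mu_b <- runif(n, 50, 500)
    tbl <- tibble::tibble(feature_id = sprintf("g%d", 1:n))
    for (s in 1:4) tbl[[paste0("a", s)]] <- rnbinom(n, mu = mu_b * 4, size = 1 / 0.05)
    for (s in 1:4) tbl[[paste0("b", s)]] <- rnbinom(n, mu = mu_b, size = 1 / 0.05)
  })
  res <- nb_wald(tbl, paste0("a", 1:4), paste0("b", 1:4),
                 size_factors = tibble::tibble(sample_id = c(paste0("a", 1:4), paste0("b", 1:4)),
                                               size_factor = 1))
  expect_lt(abs(median(res$log2FC) - 2), 0.2)
})

test_that("null p-values are approximately uniform (small-scale check)", {
  fracs <- ks <- numeric(0)
  for (s in 1:3) {
    ex <- simulate_experiment(null_config(seed = 200 + s, n_genes = 1000))
    a <- ex$samples$sample_id[ex$samples$subset == "TCM" & ex$samples$stim == "unstim"]
    b <- ex$samples$sample_id[ex$samples$subset == "naive" & ex$samples$stim == "unstim"]
    res <- nb_wald(ex$rna, a, b)
    p <- res$p[!is.na(res$p)]
    fracs <- c(fracs, mean(p < 0.05))
    ks <- c(ks, suppressWarnings(stats::ks.test(p, "punif"))$statistic)
  }
  expect_lt(abs(mean(fracs) - 0.05), 0.03)
  expect_lt(mean(ks), 0.05)
})
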