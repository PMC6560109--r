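test_that("the G statistic matches an independent evaluation", {
  g <- g_test(matrix(c(10, 20, 30, 40), 2, byrow = TRUE))
  expect_equal(g$statistic, 0.8042, tolerance = 1e-3)
  # proportional rows are exactly independent
  expect_equal(g_test(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))$statistic,
               0, tolerance = 1e-12)
  # a diagonal table gives a large positive statistic over nonzero cells
  g <- g_test(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  expect_gt(g$statistic, 20)
  # oracle property: 1,000 random tables against the algebraic identity
  set.seed(77)
  for (i in 1:1000) {
    x <- matrix(rpois(4, 20) + 1, 2)
    expect_lt(abs(g_test(x)$statistic - oracle_g(x)),
              1e-9 * max(1, abs(oracle_g(x))))
  }
  expect_error(g_test(matrix(c(0, 0, 5, 5), 2)), "zero")
  # Williams correction shrinks the statistic
  x <- matrix(c(10, 20, 30, 40), 2)
  expect_lt(g_test(x, williams = TRUE)$statistic, g_test(x)$statistic)
})

test_that("hypergeometric p-values equal exact enumeration", {
  # worked example: N=20, K=5, n=6, overlap 4 -> 540/38760
  cats <- data.frame(category = "c1", gene_id = sprintf("g%02d", 1:5))
  fg <- sprintf("g%02d", c(1:4, 6, 7))           # 6 foreground, 4 in category
  bg <- sprintf("g%02d", 5:20)
  res <- category_tests(cats, foreground = fg, background = bg,
                        mode = "hypergeometric",
                        cfg = enrichment_config(n_random_sets = 50L,
                                                rng_seed = 1L))
  expect_equal(res$p_raw, 540 / 38760, tolerance = 1e-12)
  expect_equal(res$p_raw, oracle_hyper(20, 5, 6, 4), tolerance = 1e-12)
  # a sweep of small configurations against the enumeration oracle
  for (prm in list(c(12, 4, 5), c(20, 6, 4), c(25, 5, 5), c(30, 4, 6))) {
    N <- prm[1]; K <- prm[2]; n <- prm[3]
    for (k_obs in 1:min(K, n)) {
      expect_equal(phyper(k_obs - 1, K, N - K, n, lower.tail = FALSE),
                   oracle_hyper(N, K, n, k_obs), tolerance = 1e-10,
                   info = paste(N, K, n, k_obs))
    }
  }
})

test_that("the empirical length-matched test is seeded and sane at extremes", {
  set.seed(8)
  uni <- data.frame(gene_id = sprintf("g%04d", 1:400),
                    length_bp = as.integer(round(exp(rnorm(400, log(6000),
                                                           0.4)))))
  cfg <- enrichment_config(n_random_sets = 200L, rng_seed = 3L)
  tgt <- uni$gene_id[1:25]
  # empty hit set: observed 0, no random set has strictly fewer
  r <- empirical_length_matched_test(tgt, character(0), uni, cfg)
  expect_equal(r$observed, 0)
  expect_equal(r$empirical_fraction, 0)
  expect_false(r$decision)
  # target exactly the rare hit genes: near-certain enrichment
  r <- empirical_length_matched_test(tgt, tgt, uni, cfg)
  expect_gt(r$empirical_fraction, 0.95)
  expect_true(r$decision)
  # identical seeds reproduce the fraction exactly; different seeds agree
  # within binomial error
  hits <- sample(uni$gene_id, 80)
  r1 <- empirical_length_matched_test(tgt, hits, uni, cfg, label = "x")
  r2 <- empirical_length_matched_test(tgt, hits, uni, cfg, label = "x")
  expect_identical(r1$empirical_fraction, r2$empirical_fraction)
  cfg2 <- enrichment_config(n_random_sets = 200L, rng_seed = 4L)
  r3 <- empirical_length_matched_test(tgt, hits, uni, cfg2, label = "x")
  expect_lt(abs(r3$empirical_fraction - r1$empirical_fraction),
            4 * sqrt(0.5 * 0.5 / 200))
})

test_that("trait screening skips small traits and respects symmetry", {
  set.seed(12)
  uni <- data.frame(gene_id = sprintf("g%03d", 1:120),
                    length_bp = rep(c(5000L, 8000L, 11000L), 40))
  hh <- setNames(rpois(120, 1), uni$gene_id)
  aa <- setNames(rpois(120, 1), uni$gene_id)
  hh[1:12] <- hh[1:12] + 6   # strong human excess in the first 12 genes
  traits <- rbind(data.frame(trait = "big", gene_id = uni$gene_id[1:12]),
                  data.frame(trait = "small", gene_id = uni$gene_id[1:9]))
  cfg <- enrichment_config(n_random_sets = 200L, rng_seed = 5L)
  res <- quiet(gwas_trait_enrichment(traits, hh, aa, uni, cfg))
  expect_false("small" %in% res$trait)  # fewer than 10 loci: skipped
  expect_true(res$enriched[res$trait == "big" & res$lineage == "human"])
  expect_false(res$enriched[res$trait == "big" & res$lineage == "archaic"])
  # swapping the lineage count vectors flips the enrichment
  res_sw <- quiet(gwas_trait_enrichment(traits, aa, hh, uni, cfg))
  expect_true(res_sw$enriched[res_sw$trait == "big" &
                                res_sw$lineage == "archaic"])
  expect_false(res_sw$enriched[res_sw$trait == "big" &
                                 res_sw$lineage == "human"])
})

test_that("category tests control error rates under label permutation", {
  # Holm never decreases a p-value
  set.seed(21)
  cats <- data.frame(category = rep(paste0("c", 1:5), each = 8),
                     gene_id = sprintf("g%03d", sample(100, 40, TRUE)))
  fg <- sprintf("g%03d", sample(100, 30))
  bg <- setdiff(sprintf("g%03d", 1:100), fg)
  res <- category_tests(cats, fg, bg, mode = "hypergeometric",
                        cfg = enrichment_config(n_random_sets = 99L,
                                                rng_seed = 2L))
  expect_true(all(res$p_holm >= res$p_raw))

  # null calibration: random foregrounds rarely yield a reported category
  n_rep <- 200
  n_hits <- 0
  for (r in seq_len(n_rep)) {
    fg <- sprintf("g%03d", sample(100, 30))
    bg <- setdiff(sprintf("g%03d", 1:100), fg)
    res <- category_tests(cats, fg, bg, mode = "hypergeometric",
                          cfg = enrichment_config(n_random_sets = 59L,
                                                  rng_seed = 100L + r))
    n_hits <- n_hits + any(res$reported)
  }
  expect_lt(n_hits / n_rep, 0.08)  # at most around the nominal 5% level

  # wilcoxon mode: identical score distributions give uniform-ish p
  set.seed(22)
  med_p <- replicate(200, {
    sc <- setNames(rnorm(120), sprintf("g%03d", 1:120))
    cats1 <- data.frame(category = "c1",
                        gene_id = sprintf("g%03d", sample(120, 30)))
    category_tests(cats1, scores = sc, mode = "wilcoxon",
                   cfg = enrichment_config(n_random_sets = 19L,
                                           rng_seed = 7L))$p_raw
  })
  expect_gt(median(med_p), 0.4)
  expect_lt(median(med_p), 0.6)
})

test_that("sweep overlap applies the 50 kb window inclusively", {
  sweeps <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(100000, 120000))
  sweeps$name <- "s1"
  sweeps$feature_class <- "sweep_region"
  sites <- data.frame(chrom = "chr1",
                      pos = c(110000L,            # inside
                              120000L + 49999L,   # 49,999 bp away
                              120000L + 50001L,   # 50,001 bp away
                              99999L),            # 1 bp before the region
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  hit <- sweep_overlap(sites, sweeps, 50000L)
  expect_setequal(hit$pos, c(110000L, 169999L, 99999L))
  expect_equal(hit$sweep_distance[hit$pos == 110000L], 0L)
  # empty region list gives an empty result
  expect_equal(nrow(sweep_overlap(sites, sweeps[0], 50000L)), 0)
})
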