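test_that("size_factors implements median-of-ratios", {
  sf <- size_factors(cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60)))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  m <- matrix(rpois(50, 100), 10)
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1]))), c(1, 1))

  # permuting gene order leaves the factors unchanged
  set.seed(241)
  m <- matrix(rnbinom(400, mu = 200, size = 10), 100)
  expect_equal(size_factors(m[sample(100), ]), size_factors(m))

  # genes with a zero in any sample are excluded from the reference set
  mz <- rbind(m, c(0, 1e6, 1e6, 1e6))
  expect_equal(size_factors(mz), size_factors(m))

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive counts")
})

test_that("normalized counts re-center the median ratio at 1", {
  set.seed(251)
  g <- gen_counts(n_genes = 500, seed = 42)
  sf <- size_factors(g$counts)
  norm <- sweep(g$counts, 2, sf, "/")
  use <- rowSums(norm > 0) == ncol(norm)
  loggeo <- rowMeans(log(norm[use, ]))
  med_ratio <- apply(norm[use, ], 2, function(cnt) median(exp(log(cnt) - loggeo)))
  expect_equal(unname(med_ratio), rep(1, ncol(norm)), tolerance = 0.02)
})

test_that("nb_test is exact on degenerate input and calibrated under the null", {
  # identical samples duplicated into two conditions: log2FC identically 0
  set.seed(261)
  m <- matrix(rnbinom(200, mu = 100, size = 20), 50)
  counts <- cbind(m, m)
  cond <- rep(c("A", "B"), each = 4)
  res <- nb_test(counts, cond, "A", "B")
  expect_true(all(res$log2FC == 0))
  expect_true(all(res$padj >= res$pvalue))

  # label swap flips the sign of log2FC but not the p-value
  g <- gen_counts(n_genes = 300, seed = 31)
  r1 <- nb_test(g$counts, g$design$condition, "control", "mutant")
  r2 <- nb_test(g$counts, g$design$condition, "mutant", "control")
  expect_equal(r1$log2FC, -r2$log2FC, tolerance = 1e-12)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-12)

  # all-null matrices: raw p uniform enough, BH yields (almost) nothing
  pfrac <- numeric(10); ndisc <- numeric(10)
  for (i in 1:10) {
    gn <- gen_counts(n_genes = 2000, spike_log2fc = numeric(0), seed = 600 + i)
    rn <- nb_test(gn$counts, gn$design$condition, "control", "mutant")
    pfrac[i] <- mean(rn$pvalue < 0.05)
    ndisc[i] <- sum(rn$padj < 0.05)
  }
  expect_lt(abs(mean(pfrac) - 0.05), 0.02)
  expect_lte(median(ndisc), 1)

  expect_error(nb_test(g$counts, g$design$condition, "control", "missing"),
               "2 replicates")
})

test_that("nb_test recovers a known spiked fold change", {
  set.seed(271)
  lfc <- vapply(1:30, function(i) {
    g <- gen_counts(n_genes = 500, spike_log2fc = c(spiked = 1),
                    base_mean_range = c(500, 500), seed = 700 + i)
    res <- nb_test(g$counts, g$design$condition, "control", "mutant")
    res$log2FC[res$gene == "spiked"]
  }, numeric(1))
  expect_lt(abs(mean(lfc) - 1), 0.05)
})

test_that("de_set filters on padj and fold change with sign partitioning", {
  empty <- de_set(data.frame(gene = character(0), log2FC = numeric(0),
                             padj = numeric(0)))
  expect_equal(empty$up, character(0))
  expect_equal(empty$down, character(0))

  res <- data.frame(gene = c("up_big", "down_small", "null"),
                    log2FC = c(2, -0.58, 0.1),
                    padj = c(1e-6, 1e-4, 0.8))
  ds <- de_set(res)
  expect_equal(ds$up, "up_big")
  expect_equal(ds$down, "down_small")
  # a 1.5-fold gene is excluded by a 2-fold threshold despite small padj
  ds2 <- de_set(res, fc_threshold = 2)
  expect_equal(ds2$down, character(0))
  expect_equal(ds2$up, "up_big")

  # 50 four-fold spiked genes among 2000: high recovery and few false hits,
  # as a median over simulations (single draws vary with the mean grid)
  spikes <- setNames(rep(2, 50), sprintf("spike_%02d", 1:50))
  found <- false <- numeric(40)
  for (i in 1:40) {
    g <- gen_counts(n_genes = 2000, spike_log2fc = spikes, seed = 5000 + i)
    r <- nb_test(g$counts, g$design$condition, "control", "mutant")
    hits <- de_set(r)
    found[i] <- sum(names(spikes) %in% c(hits$up, hits$down))
    false[i] <- sum(!c(hits$up, hits$down) %in% names(spikes))
  }
  expect_gte(median(found), 45)
  expect_lte(median(false), 5)
})

test_that("go_overrep computes hypergeometric enrichment with BH control", {
  universe <- sprintf("g%03d", 1:100)
  de <- universe[1:10]
  tm <- rbind(data.frame(term = "hit_term", gene = universe[1:10]),
              data.frame(term = "whole_universe", gene = universe),
              data.frame(term = "disjoint", gene = universe[51:60]))
  res <- go_overrep(de, universe, tm)
  expect_equal(res$p[res$term == "whole_universe"], 1)
  expect_lt(res$p[res$term == "hit_term"], 1e-12)
  expect_equal(res$p[res$term == "hit_term"], 1 / choose(100, 10),
               tolerance = 1e-9)
  # disjoint term: survival at overlap 0 is the whole mass
  expect_equal(res$p[res$term == "disjoint"], 1)
  expect_true(all(res$padj >= res$p - 1e-15))
  expect_error(go_overrep("not_there", universe, tm), "universe")
})
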