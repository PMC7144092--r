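test_that("fisher_exact reproduces known two-sided p-values and odds ratios", {
  # 105/150 vs 40/44 affected: the GstO1-O4 thorax comparison
  ft <- fisher_exact(105, 45, 40, 4)
  expect_equal(signif(ft$p_value, 2), 0.0052)
  expect_equal(ft$odds_ratio, 105 * 4 / (45 * 40))

  # identical proportions
  expect_equal(fisher_exact(5, 5, 5, 5)$p_value, 1)

  # full enumeration over margins (3,3)/(3,3): tail masses 0.05/0.45/0.45/0.05
  expect_equal(fisher_exact(2, 1, 1, 2)$p_value, 1)

  # odds-ratio edge cases
  expect_identical(fisher_exact(3, 0, 2, 5)$odds_ratio, Inf)
  ft0 <- fisher_exact(0, 3, 0, 5)  # both cross-products zero
  expect_true(ft0$or_undefined)
  expect_true(is.nan(ft0$odds_ratio))

  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact(0, 0, 0, 0), "all-zero")
})

test_that("fisher_exact agrees with the hypergeometric-mass oracle and fisher.test", {
  # exhaustive over a margin grid at moderate N, random spot checks vs fisher.test
  for (n in c(7L, 13L, 21L)) {
    for (m1 in 1:(n - 1)) {
      for (n1 in 1:(n - 1)) {
        for (a in max(0, n1 - (n - m1)):min(m1, n1)) {
          b <- m1 - a; c <- n1 - a; d <- n - m1 - c
          expect_equal(fisher_exact(a, b, c, d)$p_value,
                       fisher_oracle(a, b, c, d), tolerance = 1e-12)
        }
      }
    }
  }
  set.seed(11)
  for (i in 1:50) {
    t <- matrix(rpois(4, 10), 2)
    if (sum(t) == 0) next
    expect_equal(fisher_exact(t)$p_value, fisher.test(t)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("fisher_exact two-sided p is invariant to row and column swaps", {
  set.seed(21)
  for (i in 1:25) {
    t <- matrix(rpois(4, 8) + c(1, 0, 0, 0), 2)
    p <- fisher_exact(t)$p_value
    expect_equal(fisher_exact(t[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact(t[, 2:1])$p_value, p, tolerance = 1e-12)
  }
})

test_that("bonferroni_threshold divides alpha by the family size", {
  expect_equal(bonferroni_threshold(0.05, 11), 0.05 / 11)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0))
  expect_error(bonferroni_threshold(1.2, 3))
})

test_that("bh_adjust matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.2, 1, 0.5))[2], 1)
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # family larger than the tested set: ranks stay 1..n but m scales the ratio
  expect_equal(bh_adjust(c(0.001, 0.01), m = 10), c(0.01, 0.05))
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("holm_sidak_adjust follows the step-down formula and is monotone", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak_adjust(0.5), 0.5)
  expect_equal(holm_sidak_adjust(c(0, 0, 0)), c(0, 0, 0))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(15)
    for (fn in list(bh_adjust, holm_sidak_adjust)) {
      adj <- fn(p)
      expect_true(all(adj >= 0 & adj <= 1))
      # monotone: larger raw p never maps to smaller adjusted p
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-12))
    }
  }
})

test_that("mann_whitney_u statistic and exact p agree with enumeration", {
  # identical multisets: U at its null mean
  x <- c(1, 2, 2, 5)
  expect_equal(mann_whitney_u(x, x)$U, length(x)^2 / 2)

  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 2 / choose(4, 2))
  expect_identical(mw$method, "exact")

  # exact path vs independent loop enumeration, with and without ties
  set.seed(51)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, u_enumeration_p(x, y))
  }
  # tie-free exact p matches wilcox.test's exact distribution
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney_u normal approximation matches wilcox.test with ties", {
  set.seed(61)
  for (i in 1:20) {
    x <- sample(1:8, 25, replace = TRUE)
    y <- sample(1:8, 30, replace = TRUE) + rbinom(30, 2, 0.3)
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_identical(mine$method, "normal")
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    mine_nc <- mann_whitney_u(x, y, correct = FALSE)
    ref_nc <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mine_nc$p_value, ref_nc$p.value, tolerance = 1e-10)
  }
  # clearly shifted large samples are detected
  set.seed(62)
  x <- rnorm(50); y <- rnorm(50, 2)
  expect_lt(mann_whitney_u(x, y)$p_value, 0.05)
})

test_that("kruskal_wallis matches kruskal.test and degenerates sensibly", {
  expect_equal(kruskal_wallis(list(a = rep(3, 5), b = rep(3, 4)))$H, 0)
  set.seed(71)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    samples <- lapply(seq_len(k), function(j) sample(1:10, sample(3:12, 1), replace = TRUE))
    names(samples) <- letters[seq_len(k)]
    mine <- kruskal_wallis(samples)
    ref <- kruskal.test(samples)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  # two-group case tracks the Mann-Whitney normal approximation
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(25, 0.5)
    pkw <- kruskal_wallis(list(x = x, y = y))$p_value
    pmw <- mann_whitney_u(x, y, correct = FALSE)$p_value
    expect_lt(abs(pkw - pmw), 0.02)
  }
  expect_error(kruskal_wallis(list(a = 1:3)), "at least 2")
})

test_that("kruskal_wallis controls type I error under the null", {
  set.seed(81)
  nrej <- 0L
  nsim <- 2000L
  for (i in seq_len(nsim)) {
    samples <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    nrej <- nrej + (kruskal_wallis(samples)$p_value < 0.05)
  }
  mc_se <- sqrt(0.05 * 0.95 / nsim)
  expect_lte(nrej / nsim, 0.05 + 2 * mc_se)
})

test_that("dunn_posthoc flags only genuinely shifted groups", {
  # identical groups: adjusted p clipped to 1
  g <- list(ctrl = rep(1, 10), a = rep(1, 10), b = rep(1, 10))
  expect_true(all(dunn_posthoc(g, "ctrl")$p_adj == 1))

  set.seed(91)
  hits_shift <- 0L; hits_null <- 0L
  for (i in 1:30) {
    g <- list(ctrl = rnorm(30), near = rnorm(30), far = rnorm(30, 3))
    d <- dunn_posthoc(g, "ctrl")
    hits_shift <- hits_shift + (d$p_adj[d$group == "far"] < 0.001)
    hits_null <- hits_null + (d$p_adj[d$group == "near"] > 0.05)
  }
  expect_gte(hits_shift, 28L)
  expect_gte(hits_null, 26L)

  # two-group case reduces to a two-sided normal-approximation rank test
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15, 1)
    d <- dunn_posthoc(list(ctrl = x, trt = y), "ctrl")
    pmw <- mann_whitney_u(x, y, correct = FALSE)$p_value
    expect_equal(d$p_raw, pmw, tolerance = 1e-10)
  }
  expect_error(dunn_posthoc(list(a = 1:3, b = 1:3), "zz"), "control")
})

test_that("rm_anova_two_way matches the aov Error() decomposition", {
  set.seed(101)
  for (i in 1:5) {
    a <- sample(2:3, 1); s <- sample(3:5, 1); t <- sample(3:6, 1)
    d <- expand.grid(genotype = letters[1:a], subject = seq_len(s),
                     time = seq_len(t))
    d$y <- rnorm(nrow(d)) + as.numeric(d$genotype == "a") * 0.4 +
      0.05 * as.numeric(d$time)
    mine <- rm_anova_two_way(d, posthoc = FALSE)
    ref <- summary(aov(y ~ genotype * factor(time) +
                         Error(interaction(genotype, subject)), data = d))
    btw <- ref[["Error: interaction(genotype, subject)"]][[1]]
    wth <- ref[["Error: Within"]][[1]]
    expect_equal(mine$F_genotype, btw["genotype", "F value"], tolerance = 1e-8)
    expect_equal(mine$p_genotype, btw["genotype", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(mine$F_time, wth["factor(time)", "F value"], tolerance = 1e-8)
    expect_equal(mine$F_interaction,
                 wth["genotype:factor(time)", "F value"], tolerance = 1e-8)
  }
})

test_that("rm_anova_two_way reproduces hand-computed sums of squares", {
  # 2 genotypes x 3 subjects x 4 times, fixed values; brute-force SS from the
  # textbook definitions, written independently of the implementation
  set.seed(111)
  d <- expand.grid(genotype = c("g1", "g2"), subject = 1:3, time = 1:4)
  d$y <- round(runif(nrow(d)), 3)
  y <- d$y; grand <- mean(y)
  cell <- function(g, tt) mean(y[d$genotype == g & d$time == tt])
  mg <- sapply(c("g1", "g2"), function(g) mean(y[d$genotype == g]))
  mt <- sapply(1:4, function(tt) mean(y[d$time == tt]))
  msub <- sapply(split(y, interaction(d$genotype, d$subject)), mean)
  ss_g <- 3 * 4 * sum((mg - grand)^2)
  ss_subj <- 4 * sum((msub - grand)^2) - ss_g
  ss_t <- 2 * 3 * sum((mt - grand)^2)
  ss_gt <- 3 * sum(sapply(c("g1", "g2"), function(g)
    sapply(1:4, function(tt)
      (cell(g, tt) - mg[g] - mt[tt] + grand)^2)))
  ss_err <- sum((y - grand)^2) - ss_g - ss_subj - ss_t - ss_gt
  mine <- rm_anova_two_way(d, posthoc = FALSE)$anova
  expect_equal(mine$SS, c(ss_g, ss_subj, ss_t, ss_gt, ss_err), tolerance = 1e-10)
})

test_that("rm_anova_two_way handles degenerate and invalid designs", {
  d <- expand.grid(genotype = c("g1", "g2"), subject = 1:3, time = 1:4)
  set.seed(121)
  base <- rnorm(12)  # same subject x time surface for both genotypes
  d$y <- base[as.integer(interaction(d$subject, d$time, drop = TRUE))]
  mine <- rm_anova_two_way(d, posthoc = FALSE)
  expect_equal(mine$F_genotype, 0, tolerance = 1e-12)

  expect_error(rm_anova_two_way(d[-1, ]), "balanced")

  # Greenhouse-Geisser epsilon stays in its admissible range
  d$y <- rnorm(nrow(d))
  gg <- rm_anova_two_way(d, sphericity = "greenhouse-geisser", posthoc = FALSE)
  expect_gte(gg$epsilon, 1 / 3)
  expect_lte(gg$epsilon, 1)

  # posthoc table is Holm-Sidak adjusted and covers every bin
  ph <- rm_anova_two_way(d)$posthoc
  expect_equal(nrow(ph), 4)
  expect_equal(ph$p_adj, holm_sidak_adjust(ph$p_raw))
})
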