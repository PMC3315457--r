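# Expression filtering, overlap/fold-enrichment, concordance, direction
# quadrants, attenuation, Venn regions.

test_that("filter_expressed applies the strict > min_reads rule", {
  m <- matrix(c(6, 0, 5, 5, 0, 7), 3, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("l1", "l2")))
  expect_setequal(filter_expressed(m), c("g1", "g3"))   # 5 is not > 5
  expect_length(filter_expressed(matrix(0, 3, 2,
    dimnames = list(paste0("g", 1:3), NULL))), 0)
  expect_setequal(filter_expressed(m, min_reads = 0), c("g1", "g2", "g3"))
  expect_error(filter_expressed(matrix(numeric(0), 0, 0)), "empty")
})

test_that("overlap_test matches explicit hypergeometric summation", {
  universe <- sprintf("g%05d", 1:9323)
  A <- universe[1:85]
  B <- c(universe[1:42], universe[1000:1139])   # |B| = 182, overlap 42
  res <- overlap_test(A, B, universe)
  expect_equal(res$k, 42)
  expect_equal(res$fold, 42 / (85 * 182 / 9323), tolerance = 1e-12)
  expect_gt(res$fold, 25)
  expect_lt(res$p_enrich, 1e-40)
  expect_equal(res$p_enrich, oracle_hyper_ge(42, 85, 182, 9323),
               tolerance = 1e-9)

  # explicit small case: N=20, n=5, K=5, k=3
  u <- letters[1:20]
  r2 <- overlap_test(u[1:5], u[c(1:3, 6:7)], u)
  expect_equal(r2$p_enrich, 1126 / 15504, tolerance = 1e-6)
  expect_equal(r2$fold, 2.4)

  # disjoint lists
  r0 <- overlap_test(u[1:5], u[6:10], u)
  expect_equal(r0$k, 0)
  expect_equal(r0$fold, 0)
  expect_equal(r0$p_enrich, 1)

  # tail decomposition: p_enrich + p_deplete >= 1 (shared point mass)
  expect_gte(r2$p_enrich + r2$p_deplete, 1)

  expect_error(overlap_test(c("zz"), u[1:2], u), "subsets")
})

test_that("overlap_test agrees with Monte-Carlo resampling at small N", {
  set.seed(61)
  N <- 150; n <- 20; K <- 30
  universe <- sprintf("u%03d", 1:N)
  A <- universe[1:n]; B <- universe[c(1:8, 50:71)]
  res <- overlap_test(A, B, universe)
  in_b <- universe %in% B
  draws <- replicate(1e5, sum(in_b[sample.int(N, n)]))
  p_mc <- mean(draws >= res$k)
  se <- sqrt(p_mc * (1 - p_mc) / 1e5)
  expect_lt(abs(res$p_enrich - p_mc), 3 * se + 1e-12)
})

test_that("foldchange_concordance and direction_classification", {
  genes <- sprintf("g%02d", 1:42)
  ta <- data.frame(gene_id = genes, log2fc = seq(-2, 2, length.out = 42))
  expect_equal(foldchange_concordance(ta, ta, genes)$r, 1)
  tb <- ta; tb$log2fc <- -tb$log2fc
  expect_equal(foldchange_concordance(ta, tb, genes)$r, -1)

  # planted rho = 0.57 at n = 97 recovered within the 95% CI
  set.seed(62)
  n <- 97
  z1 <- rnorm(n); z2 <- 0.57 * z1 + sqrt(1 - 0.57^2) * rnorm(n)
  g2 <- sprintf("h%03d", 1:n)
  r <- foldchange_concordance(data.frame(gene_id = g2, log2fc = z1),
                              data.frame(gene_id = g2, log2fc = z2), g2)$r
  expect_lt(abs(atanh(r) - atanh(0.57)), 1.96 / sqrt(n - 3))

  # 33 of 42 down-in-A / up-in-B
  fa <- c(rep(-1, 33), rep(1, 9))
  fb <- rep(1, 42)
  dc <- direction_classification(
    data.frame(gene_id = genes, log2fc = fa),
    data.frame(gene_id = genes, log2fc = fb), genes)
  expect_equal(unname(dc$counts["down_up"]), 33L)
  expect_equal(sum(dc$counts), 42L)
  expect_equal(dc$dominant, "down_up")
  expect_equal(dc$dominant_pct, 100 * 33 / 42, tolerance = 1e-9)

  # balanced quadrants
  dcb <- direction_classification(
    data.frame(gene_id = genes[1:4], log2fc = c(1, 1, -1, -1)),
    data.frame(gene_id = genes[1:4], log2fc = c(1, -1, 1, -1)), genes[1:4])
  expect_true(all(dcb$counts == 1))
  expect_equal(dcb$dominant_pct, 25)

  # gene ordering invariance
  dc2 <- direction_classification(
    data.frame(gene_id = genes, log2fc = fa),
    data.frame(gene_id = genes, log2fc = fb), rev(genes))
  expect_equal(dc2$counts, dc$counts)

  expect_error(foldchange_concordance(ta, tb, c(genes, "missing")), "missing")
})

test_that("attenuation_test matches exact binomial oracles", {
  g10 <- sprintf("a%02d", 1:10)
  ctrl <- setNames(rep(2, 10), g10)
  kd <- setNames(rep(1, 10), g10)
  res <- attenuation_test(ctrl, kd, g10)
  expect_equal(res$n_smaller, 10)
  expect_equal(res$p_binomial, 2 * 2^-10, tolerance = 1e-12)

  # 27 of 33: one-sided tail = 1391842 / 2^33
  g33 <- sprintf("b%02d", 1:33)
  ctrl33 <- setNames(rep(2, 33), g33)
  kd33 <- setNames(c(rep(1, 27), rep(3, 6)), g33)
  r33 <- attenuation_test(ctrl33, kd33, g33)
  expect_equal(r33$n_smaller, 27)
  expect_equal(r33$p_one_sided, 1391842 / 2^33, tolerance = 1e-9)
  expect_equal(r33$p_one_sided, oracle_binom_ge_half(27, 33),
               tolerance = 1e-12)

  # exhaustive-enumeration agreement for all n_total <= 20
  for (n in c(5, 12, 20)) for (k in c(0, floor(n / 2), n)) {
    gg <- sprintf("c%02d", 1:n)
    rr <- attenuation_test(setNames(rep(2, n), gg),
                           setNames(c(rep(1, k), rep(3, n - k)), gg), gg)
    expect_equal(rr$p_one_sided, oracle_binom_ge_half(k, n),
                 tolerance = 1e-12)
  }

  # ties are excluded but counted
  gt <- sprintf("d%02d", 1:6)
  rt <- attenuation_test(setNames(c(2, 2, 2, 1, 1, 1), gt),
                         setNames(c(1, 1, 1, 1, 1, 1), gt), gt)
  expect_equal(rt$n_ties, 3)
  expect_equal(rt$n_total, 3)

  # absolute-magnitude reading: sign flips don't count as attenuation
  gs <- c("e1", "e2", "e3")
  rs <- attenuation_test(setNames(c(1, 1, 1), gs),
                         setNames(c(-2, 0.5, 0.5), gs), gs)
  expect_equal(rs$n_smaller, 2)
})

test_that("attenuation background comparison is calibrated", {
  set.seed(63)
  universe <- sprintf("u%04d", 1:500)
  ctrl <- setNames(rnorm(500, 1), universe)
  kd <- setNames(rnorm(500, 1), universe)
  ps <- replicate(100, {
    genes <- sample(universe, 30)
    attenuation_test(ctrl, kd, genes, background = universe)$p_background
  })
  expect_gt(mean(ps > 0.05), 0.80)   # no differential attenuation planted
})

test_that("build_venn partitions lists exactly", {
  universe <- sprintf("v%04d", 1:2000)
  lists <- list(RNAi = universe[1:85], ChIP = universe[c(1:5, 100:942)])
  v <- build_venn(lists, universe)
  expect_equal(unname(v$regions["RNAi&ChIP"]), 5L)
  expect_equal(sum(v$regions), v$union_size)
  expect_equal(v$pairwise[["RNAi|ChIP"]]$k, 5)

  # three identical lists: only the triple region
  same <- list(A = universe[1:10], B = universe[1:10], C = universe[1:10])
  v3 <- build_venn(same, universe)
  expect_equal(unname(v3$regions["A&B&C"]), 10L)
  expect_length(v3$regions, 1)

  # random lists: regions partition the union
  set.seed(64)
  rl <- list(A = sample(universe, 50), B = sample(universe, 80),
             C = sample(universe, 30))
  vr <- build_venn(rl, universe)
  expect_equal(sum(vr$regions), vr$union_size)

  expect_error(build_venn(list(A = c("v0001", "v0001"), B = universe[1:3]),
                          universe), "duplicate")
})
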