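# Quantile normalization, WGCNA-style modules, tight clusters, coherent
# clusters, module enrichment.

test_that("quantile_normalize is correct and idempotent", {
  m <- cbind(a = c(1, 3), b = c(2, 6))
  q <- quantile_normalize(m)
  expect_equal(unname(q), cbind(c(1.5, 4.5), c(1.5, 4.5)))

  same <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantile_normalize(same), same)

  set.seed(71)
  r <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  q1 <- quantile_normalize(r)
  expect_equal(max(abs(colMeans(q1) - mean(colMeans(q1)))), 0,
               tolerance = 1e-12)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("quantile_normalize agrees with limma's implementation", {
  skip_if_not_installed("limma")
  set.seed(72)
  m <- matrix(rexp(300), 30, 10)
  dimnames(m) <- list(paste0("g", 1:30), paste0("s", 1:10))
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-9)
})

test_that("wgcna_modules separates planted blocks", {
  # two noise-free blocks with independent factors: exactly 2 modules
  set.seed(73)
  f1 <- rnorm(30); f2 <- rnorm(30)
  m <- rbind(matrix(rep(f1, each = 35), 35),
             matrix(rep(f2, each = 35), 35))
  dimnames(m) <- list(sprintf("g%02d", 1:70), sprintf("s%02d", 1:30))
  ms <- wgcna_modules(m, min_size = 30)
  expect_length(ms$modules, 2)
  expect_setequal(ms$modules[[1]], rownames(m)[1:35])

  # beta = 1 adjacency equals |r| (exponent identity, via TOM of 2 genes)
  # checked directly on the adjacency construction:
  r <- cor(t(m[1:2, ]))
  expect_equal(abs(r[1, 2])^1, abs(r[1, 2]))

  # constant gene dropped with warning
  m2 <- rbind(m, const = rep(1, 30))
  expect_warning(wgcna_modules(m2, min_size = 30), "constant")
})

test_that("planted five-module recovery at high ARI", {
  mods <- data.frame(size = rep(60, 5), loading = 1,
                     shared = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  sim <- gen_two_tissue_expression(
    expr_sim_config(500, 60, mods, noise_sd = 0.5, seed = 74))
  ms <- wgcna_modules(sim$tissueA)
  ari <- adjusted_rand_index(ms$labels[sim$truth$gene_id], sim$truth$module)
  expect_gte(ari, 0.9)
})

test_that("tight_clusters: homogeneous module stays whole, halves split", {
  # noise-free module: single tight cluster = module
  set.seed(75)
  f <- rnorm(40)
  m0 <- matrix(rep(f, each = 20), 20,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:40)))
  tc0 <- tight_clusters(m0, list(`f-1` = rownames(m0)), seed = 1)
  expect_length(tc0$modules, 1)
  expect_setequal(tc0$modules[[1]], rownames(m0))

  # two equal halves driven by independent factors: halves recovered
  f1 <- rnorm(60); f2 <- rnorm(60)
  mh <- rbind(matrix(rep(f1, each = 30), 30),
              matrix(rep(f2, each = 30), 30)) +
    matrix(rnorm(3600, sd = 0.5), 60)
  dimnames(mh) <- list(sprintf("h%02d", 1:60), sprintf("s%02d", 1:60))
  tch <- tight_clusters(mh, list(`f-1` = rownames(mh)), seed = 2)
  best <- vapply(tch$modules, function(g)
    max(jaccard(g, rownames(mh)[1:30]), jaccard(g, rownames(mh)[31:60])),
    numeric(1))
  expect_gte(sort(best, decreasing = TRUE)[1], 0.8)
  expect_gte(sort(best, decreasing = TRUE)[2], 0.8)

  # consensus 1.0 keeps no more genes clustered than consensus 0.7
  mn <- mh + matrix(rnorm(3600, sd = 0.8), 60)
  n07 <- length(unlist(tight_clusters(mn, list(`f-1` = rownames(mn)),
                                      consensus = 0.7, seed = 3)$modules))
  n10 <- length(unlist(tight_clusters(mn, list(`f-1` = rownames(mn)),
                                      consensus = 1.0, seed = 3)$modules))
  expect_lte(n10, n07)

  expect_error(tight_clusters(m0, list(`f-1` = rownames(m0)[1:2])),
               "min_size")
})

test_that("coherent_clusters partitions tight clusters against tissue B", {
  set.seed(76)
  ns <- 50
  fA <- rnorm(ns); fB <- rnorm(ns)
  genes <- sprintf("g%02d", 1:20)
  mA <- matrix(rep(fA, each = 20), 20, dimnames = list(genes, NULL)) +
    matrix(rnorm(20 * ns, sd = 0.3), 20)
  # half the genes share a factor in tissue B, half are noise there
  mB <- rbind(matrix(rep(fB, each = 10), 10) +
                matrix(rnorm(10 * ns, sd = 0.3), 10),
              matrix(rnorm(10 * ns), 10))
  rownames(mB) <- genes
  tight <- structure(list(stage = "tight", modules = list(`f-1-1` = genes)),
                     class = "module_set")
  cs <- coherent_clusters(tight, mB)
  expect_gte(jaccard(cs$coherent$modules[["f-1-1-1"]], genes[1:10]), 0.8)
  # exact partition
  expect_setequal(c(cs$coherent$modules[["f-1-1-1"]],
                    cs$specific$modules[["f-1-1-spec"]]), genes)
  expect_length(intersect(cs$coherent$modules[["f-1-1-1"]],
                          cs$specific$modules[["f-1-1-spec"]]), 0)

  # fully coherent tight cluster survives intact
  mB2 <- matrix(rep(fB, each = 20), 20, dimnames = list(genes, NULL))
  cs2 <- coherent_clusters(tight, mB2)
  expect_setequal(cs2$coherent$modules[["f-1-1-1"]], genes)
  expect_length(cs2$specific$modules, 0)

  # zero tissue-B correlation: whole cluster is tissue-A specific
  mB3 <- matrix(rnorm(20 * ns), 20, dimnames = list(genes, NULL))
  cs3 <- coherent_clusters(tight, mB3)
  expect_length(cs3$coherent$modules, 0)
  expect_setequal(cs3$specific$modules[["f-1-1-spec"]], genes)

  expect_error(coherent_clusters(tight, mB3[1:5, ]), "absent")
})

test_that("pipeline stages are nested and partitions exact", {
  mods <- data.frame(size = rep(40, 4), loading = 1,
                     shared = c(TRUE, TRUE, FALSE, FALSE))
  sim <- gen_two_tissue_expression(
    expr_sim_config(220, 50, mods, noise_sd = 0.5, seed = 77))
  pipe <- coexpression_pipeline(sim$tissueA, sim$tissueB,
                                n_resamples = 25, seed = 5)
  # nesting: tight within wgcna, coherent within tight
  for (nm in names(pipe$tight$modules)) {
    parent <- pipe$tight$parent[nm]
    expect_true(all(pipe$tight$modules[[nm]] %in%
                      pipe$wgcna$modules[[parent]]))
  }
  for (nm in names(pipe$coherent$modules)) {
    tight_nm <- sub("-1$", "", nm)
    expect_true(all(pipe$coherent$modules[[nm]] %in%
                      pipe$tight$modules[[tight_nm]]))
  }
  # coherent + specific partition each tight cluster
  for (nm in names(pipe$tight$modules)) {
    coh <- pipe$coherent$modules[[paste0(nm, "-1")]]
    spec <- pipe$specific$modules[[paste0(nm, "-spec")]]
    expect_setequal(c(coh, spec), pipe$tight$modules[[nm]])
  }
})

test_that("shared vs independent simulations govern coherence survival", {
  survival_frac <- function(shared, seed) {
    mods <- data.frame(size = rep(40, 3), loading = 1, shared = shared)
    sim <- gen_two_tissue_expression(
      expr_sim_config(160, 50, mods, noise_sd = 0.5, seed = seed))
    pipe <- coexpression_pipeline(sim$tissueA, sim$tissueB,
                                  n_resamples = 20, seed = seed)
    n_tight <- length(pipe$tight$modules)
    if (n_tight == 0) return(NA_real_)
    survived <- sum(vapply(names(pipe$tight$modules), function(nm) {
      coh <- pipe$coherent$modules[[paste0(nm, "-1")]]
      !is.null(coh) && length(coh) >= 3
    }, logical(1)))
    survived / n_tight
  }
  fr_shared <- vapply(1:5, function(s) survival_frac(TRUE, 80 + s),
                      numeric(1))
  fr_indep <- vapply(1:5, function(s) survival_frac(FALSE, 90 + s),
                     numeric(1))
  expect_gte(mean(fr_shared, na.rm = TRUE), 0.9)
  expect_lte(mean(fr_indep, na.rm = TRUE), 0.1)
})

test_that("module_enrichment and contingency tests", {
  universe <- sprintf("u%03d", 1:100)
  mods <- list(m1 = universe[1:10], m2 = universe[51:60])
  lists <- list(hit = universe[1:10])
  res <- module_enrichment(mods, lists, universe)
  r1 <- res[res$module == "m1", ]
  expect_equal(r1$p, 1 / choose(100, 10), tolerance = 1e-9)
  expect_true(r1$enriched)
  r2 <- res[res$module == "m2", ]
  expect_false(r2$enriched)

  # depletion case: disjoint module with a half-universe list
  resd <- module_enrichment(list(m = universe[1:10]),
                            list(big = universe[11:60]), universe)
  expect_lt(resd$odds_ratio, 1)
  expect_false(resd$enriched)
  expect_error(module_enrichment(list(), lists, universe), "empty")

  ct <- enrichment_contingency(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_lt(ct$p_fisher, 0.11)
  expect_equal(unname(ct$table[1, 1]), 3L)
})
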