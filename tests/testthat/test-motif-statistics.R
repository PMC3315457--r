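# Enrichment, class association, spacing histograms and the shuffle-null
# spacing-constraint test.

test_that("motif_presence collapses overlapping sites", {
  sites <- data.frame(seq_id = c("s1", "s1", "s1", "s3"),
                      start = c(0, 1, 2, 5), motif = "M")
  pres <- motif_presence(sites, c("s1", "s2", "s3"))
  expect_equal(unname(pres), c(TRUE, FALSE, TRUE))
})

test_that("enrichment_test matches the hypergeometric worked example", {
  # presence 8/10 peaks vs 2/10 background, via synthetic sequences:
  # plant a consensus word in 8 peak and 2 background sequences
  m <- iupac_to_pwm("TGACGTCA")
  word <- "TGACGTCA"
  # A/C-only background cannot contain the word (needs G and T), so the
  # presence counts are exact by construction
  mk <- function(n, n_with, seed) {
    set.seed(seed)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C"), 120, TRUE), collapse = ""), character(1))
    for (i in seq_len(n_with))
      substr(seqs[i], 50, 57) <- word
    setNames(seqs, sprintf("q%d_%02d", seed, seq_len(n)))
  }
  pk <- mk(10, 8, 1); bg <- mk(10, 2, 2)
  res <- enrichment_test(pk, bg, m, alpha = 1e-4)
  expect_equal(c(res$a, res$b, res$c, res$d), c(8, 2, 2, 8))
  expect_equal(res$p, oracle_fisher_2x2(matrix(c(8, 2, 2, 8), 2)),
               tolerance = 1e-9)
  expect_equal(res$p, 0.0230, tolerance = 1e-3)
  expect_true(res$enriched)

  # identical presence fractions: OR 1, p 1
  res0 <- enrichment_test(mk(10, 5, 3), mk(10, 5, 4), m, alpha = 1e-4)
  expect_equal(res0$odds_ratio, 1)
  expect_equal(res0$p, 1)

  expect_error(enrichment_test(character(0), bg, m), "empty")
})

test_that("planted motif is recovered by the enrichment screen", {
  motifs <- demo_motifs()
  cfg <- seq_sim_config(120, c(300L, 500L),
                        planted = list(list(motif = motifs$CREB, copies = 1)),
                        seed = 21L)
  sim <- gen_peaks(cfg)
  set.seed(22)
  bg <- setNames(vapply(nchar(sim$sequences), function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
    character(1)), paste0("bg_", seq_along(sim$sequences)))
  res <- enrichment_test(sim$sequences, bg, motifs$CREB)
  expect_lt(res$p, 1e-10)
})

test_that("class_association_test detects and calibrates", {
  m <- iupac_to_pwm("TGACGTCA")
  word <- "TGACGTCA"
  set.seed(300)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C"), 150, TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("locus_%02d", 1:20)
  for (i in 1:10) substr(seqs[i], 30, 37) <- word
  classes <- setNames(rep(c("forager", "nurse"), each = 10), names(seqs))
  res <- class_association_test(seqs, classes, m, alpha = 1e-4)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(res$direction, "forager")

  expect_error(class_association_test(seqs, setNames(rep("x", 20), names(seqs)), m),
               "two locus classes")

  # permutation calibration: p roughly uniform when label is independent
  set.seed(31)
  ps <- replicate(200, {
    perm <- setNames(sample(classes), names(seqs))
    class_association_test(seqs, perm, m, alpha = 1e-4)$p
  })
  expect_gt(mean(ps > 0.5), 0.4)   # conservative discrete uniformity check
})

test_that("spacing_histogram implements the signed adjacency rule", {
  sites <- data.frame(seq_id = "s1", start = c(10L, 13L),
                      motif = c("ANCH", "COF"))
  h <- spacing_histogram(sites, "ANCH", "COF")
  expect_equal(h$spacings, 3L)
  expect_equal(h$mode, 3L)

  # merged list A@0, B@5, A@9 -> spacings +5 and -4
  s2 <- data.frame(seq_id = "s1", start = c(0L, 5L, 9L),
                   motif = c("A", "B", "A"))
  h2 <- spacing_histogram(s2, "A", "B")
  expect_setequal(h2$spacings, c(5L, -4L))

  # homotypic neighbours skipped: A@0, A@2, B@5 -> only (A@2, B@5)
  s3 <- data.frame(seq_id = "s1", start = c(0L, 2L, 5L),
                   motif = c("A", "A", "B"))
  expect_equal(spacing_histogram(s3, "A", "B")$spacings, 3L)

  # anchors only: no pairs
  s4 <- data.frame(seq_id = "s1", start = c(0L, 9L), motif = "A")
  expect_length(spacing_histogram(s4, "A", "B")$spacings, 0)
})

test_that("shuffle_sites conserves counts and is uniform", {
  sites <- data.frame(seq_id = rep(c("s1", "s2"), c(3, 2)),
                      start = c(0L, 10L, 20L, 5L, 15L),
                      width = 5L,
                      motif = c("A", "A", "B", "A", "B"))
  sl <- c(s1 = 100L, s2 = 50L)
  sh <- shuffle_sites(sites, sl, seed = 3)
  expect_equal(table(sh$seq_id, sh$motif), table(sites$seq_id, sites$motif))
  expect_true(all(sh$start >= 0 & sh$start <= sl[sh$seq_id] - sh$width))

  # forced placement: L - w + 1 = 1
  s1 <- data.frame(seq_id = "x", start = 0L, width = 5L, motif = "A")
  expect_equal(shuffle_sites(s1, c(x = 5L), seed = 1)$start, 0L)

  # empirical uniformity of a single site over 100 positions
  s2 <- data.frame(seq_id = "y", start = 0L, width = 1L, motif = "A")
  starts <- vapply(1:10000, function(i)
    shuffle_sites(s2, c(y = 100L), seed = i)$start, integer(1))
  chi <- chisq.test(table(factor(starts, levels = 0:99)))
  expect_gt(chi$p.value, 0.01)
})

test_that("spacing_constraint_test handles unconstrained and empty input", {
  set.seed(41)
  # all observed pairs far apart, shuffles similar: not significant
  sites <- do.call(rbind, lapply(1:30, function(i)
    data.frame(seq_id = sprintf("s%02d", i),
               start = sample.int(392, 2) - 1L, width = 9L,
               motif = c("A", "B"))))
  sl <- setNames(rep(400L, 30), sprintf("s%02d", 1:30))
  res <- spacing_constraint_test(sites, sl, "A", "B", seed = 42)
  expect_gt(res$p, 0.01)
  expect_equal(res$b_le + res$b_gt, 50 * (res$n_le + res$n_gt))

  # zero heterotypic pairs: p = 1 with warning flag
  only_a <- data.frame(seq_id = "s1", start = c(0L, 20L), width = 9L,
                       motif = "A")
  expect_warning(r0 <- spacing_constraint_test(only_a, c(s1 = 400L), "A", "B"),
                 "no heterotypic")
  expect_equal(r0$p, 1)
  expect_true(r0$no_pairs)
})

test_that("tiny-instance Monte-Carlo null matches exhaustive enumeration", {
  # 3 sequences, one anchor + one cofactor each, L - w + 1 = 12 positions;
  # exhaustive placement enumeration gives the exact null fraction of
  # close pairs, which pooled shuffles must approach
  L <- 20L; w <- 9L
  npos <- L - w + 1L
  ids <- c("t1", "t2", "t3")
  sites <- data.frame(seq_id = rep(ids, each = 2),
                      start = rep(c(2L, 11L), 3), width = w,
                      motif = rep(c("A", "B"), 3))
  sl <- setNames(rep(L, 3), ids)
  # exhaustive: all anchor x cofactor placements in one sequence
  grid <- expand.grid(a = 0:(npos - 1), b = 0:(npos - 1))
  frac_close <- mean(abs(grid$b - grid$a) <= 5)
  n_sh <- 400
  res <- spacing_constraint_test(sites, sl, "A", "B", cutoff = 5L,
                                 n_shuffles = n_sh, seed = 7)
  n_pairs_total <- res$b_le + res$b_gt
  phat <- res$b_le / n_pairs_total
  se <- sqrt(frac_close * (1 - frac_close) / n_pairs_total)
  expect_lt(abs(phat - frac_close), 2 * se + 1e-12)
})

test_that("histogram total equals n_le + n_gt", {
  set.seed(51)
  sites <- do.call(rbind, lapply(1:20, function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(seq_id = sprintf("s%02d", i),
               start = sample.int(200, k) - 1L, width = 8L,
               motif = sample(c("A", "B"), k, TRUE))
  }))
  sl <- setNames(rep(250L, 20), sprintf("s%02d", 1:20))
  res <- spacing_constraint_test(sites, sl, "A", "B", n_shuffles = 5,
                                 seed = 52)
  expect_equal(sum(res$histogram), res$n_le + res$n_gt)
})
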