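# Independent oracles used across the suite. These deliberately avoid the
# package's code paths (and stats::dhyper, which the implementation uses):
# everything is explicit choose()-arithmetic or brute-force enumeration.

# two-sided Fisher exact p by explicit combinatorial summation
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  point <- function(x) choose(m, x) * choose(n, k - x) / choose(N, k)
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, point, numeric(1))
  obs <- point(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# hypergeometric upper tail P(X >= k) by choose() summation
oracle_hyper_ge <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(vapply(xs, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1)))
}

# exact binomial upper tail P(X >= k | n, 1/2) by coefficient summation
oracle_binom_ge_half <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

# brute-force log-odds scores of all 4^w words of a motif (w <= 10);
# returns the vector of word scores, in word-index order
oracle_all_word_scores <- function(motif) {
  w <- motif$width
  idx <- 0:(4^w - 1)
  total <- numeric(length(idx))
  for (j in seq_len(w)) {
    digit <- (idx %/% 4^(j - 1)) %% 4
    total <- total + motif$score[digit + 1, j]
  }
  total
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

demo_motifs <- function() {
  read_motif_manifest(system.file("extdata/motifs_demo.tsv",
                                  package = "cisreg"))
}

random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
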