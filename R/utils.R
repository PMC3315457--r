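#' @importFrom stats dhyper phyper pbinom cor cor.test pf pt p.adjust
#'   rnorm runif rbinom kmeans hclust cutree as.dist sd setNames
#'   chisq.test qnorm var
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric point probabilities
#' of all tables no more probable than the observed one (the common two-sided
#' convention, identical to \code{stats::fisher.test} for 2x2 tables).
#'
#' @param tab 2x2 numeric matrix of non-negative counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1L, 1L]
  m <- tab[1L, 1L] + tab[1L, 2L]   # row 1 total
  n <- tab[2L, 1L] + tab[2L, 2L]   # row 2 total
  k <- tab[1L, 1L] + tab[2L, 1L]   # column 1 total
  support <- max(0L, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Odds ratio of a 2x2 table (sample odds ratio, 0/Inf allowed)
#' @noRd
odds_ratio_2x2 <- function(tab) {
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Adjusted Rand Index between two labelings
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Pearson correlation with two-sided t-approximation p-value
#' @noRd
cor_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance vector in correlation")
  r <- cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

# deterministic child seed from a master seed (kept below 2^31)
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(index) %% 104729L
}
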