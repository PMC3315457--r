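# Gene-list arithmetic: expression filtering, hypergeometric overlap / fold
# enrichment, fold-change concordance, direction classification, and
# attenuation (reduced fold response after knockdown) tests.

#' Filter genes by expression evidence
#'
#' A gene is kept iff its count is strictly greater than \code{min_reads} in
#' at least \code{min_libraries} libraries.
#'
#' @param counts genes x libraries matrix of non-negative counts (rownames =
#'   gene ids).
#' @param min_reads strict lower bound (default 5, i.e. "> 5 reads").
#' @param min_libraries minimum number of libraries meeting the bound.
#' @return character vector of kept gene ids.
#' @export
filter_expressed <- function(counts, min_reads = 5, min_libraries = 1) {
  counts <- as.matrix(counts)
  if (!length(counts)) stop("empty count matrix")
  stopifnot(all(counts >= 0))
  keep <- rowSums(counts > min_reads) >= min_libraries
  rownames(counts)[keep]
}

#' Hypergeometric overlap test between two gene lists
#'
#' Exact hypergeometric tail probabilities for the observed overlap of two
#' lists drawn from a common universe, plus fold enrichment relative to the
#' expected overlap n*K/N.
#'
#' @param list_a,list_b character vectors of gene ids (duplicates removed).
#' @param universe character vector containing both lists.
#' @return list of class \code{overlap_result}: \code{k} (overlap), \code{n}
#'   (= |A|), \code{K} (= |B|), \code{N}, \code{fold} = k/(nK/N),
#'   \code{p_enrich} = P(X >= k), \code{p_deplete} = P(X <= k), and
#'   \code{genes} (the overlapping ids).
#' @export
overlap_test <- function(list_a, list_b, universe) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  universe <- unique(universe)
  if (!all(list_a %in% universe) || !all(list_b %in% universe))
    stop("lists must be subsets of the universe")
  n <- length(list_a); K <- length(list_b); N <- length(universe)
  shared <- intersect(list_a, list_b)
  k <- length(shared)
  expected <- n * K / N
  structure(
    list(k = k, n = n, K = K, N = N,
         fold = if (expected > 0) k / expected else NA_real_,
         p_enrich = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
         p_deplete = phyper(k, K, N - K, n),
         genes = sort(shared)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of %d x %d in N = %d: fold %.2f, p_enrich = %.3g\n",
              x$k, x$n, x$K, x$N, x$fold, x$p_enrich))
  invisible(x)
}

# pull the log2fc of a gene set out of a DE table
fc_of <- function(table, genes) {
  idx <- match(genes, table$gene_id)
  if (anyNA(idx))
    stop("gene(s) missing from DE table: ",
         paste(head(genes[is.na(idx)], 3), collapse = ", "))
  setNames(table$log2fc[idx], genes)
}

#' Fold-change concordance between two contrasts
#'
#' Pearson correlation of log2 fold changes over a shared gene set, with a
#' two-sided t-approximation p-value.
#'
#' @param table_a,table_b DE tables (data.frames with \code{gene_id},
#'   \code{log2fc}).
#' @param genes gene ids present in both tables.
#' @return list \code{r}, \code{p}, \code{n}.
#' @export
foldchange_concordance <- function(table_a, table_b, genes) {
  cor_with_p(fc_of(table_a, genes), fc_of(table_b, genes))
}

#' Classify shared genes by response direction in two contrasts
#'
#' @inheritParams foldchange_concordance
#' @return list with \code{counts} (named vector \code{up_up},
#'   \code{up_down}, \code{down_up}, \code{down_down}; first position =
#'   direction in table_a), \code{dominant} (name of the largest quadrant)
#'   and \code{dominant_pct}.
#' @export
direction_classification <- function(table_a, table_b, genes) {
  fa <- fc_of(table_a, genes); fb <- fc_of(table_b, genes)
  da <- ifelse(fa >= 0, "up", "down")
  db <- ifelse(fb >= 0, "up", "down")
  lab <- paste(da, db, sep = "_")
  counts <- setNames(integer(4), c("up_up", "up_down", "down_up", "down_down"))
  tb <- table(lab)
  counts[names(tb)] <- as.integer(tb)
  dom <- names(counts)[which.max(counts)]
  list(counts = counts, dominant = dom,
       dominant_pct = 100 * max(counts) / length(genes))
}

#' Attenuation of fold responses after knockdown
#'
#' Counts how many genes respond less strongly (smaller |log2 fold|) to a
#' treatment under knockdown than under control, and tests the predominance
#' of attenuation two ways: an exact binomial test against 0.5, and a Fisher
#' exact comparison against a background gene set (to rule out a dataset-wide
#' bias). Ties in |fold| are excluded from the binomial count.
#'
#' @param fc_control,fc_knockdown named numeric vectors of log2 fold
#'   responses to the treatment (names = gene ids), covering \code{genes}
#'   and \code{background}.
#' @param genes the focal gene set.
#' @param background optional comparison set (genes in \code{genes} are
#'   excluded from it).
#' @return list: \code{n_smaller}, \code{n_total} (ties excluded),
#'   \code{n_ties}, \code{p_binomial} (two-sided: twice the smaller tail,
#'   capped at 1), \code{p_one_sided} (P(X >= n_smaller)), and when a
#'   background is given \code{p_background} plus the background counts.
#' @export
attenuation_test <- function(fc_control, fc_knockdown, genes,
                             background = NULL) {
  count_smaller <- function(g) {
    a <- abs(fc_control[g]); b <- abs(fc_knockdown[g])
    if (anyNA(a) || anyNA(b)) stop("fold responses missing for some genes")
    list(smaller = sum(b < a), larger = sum(b > a), ties = sum(a == b))
  }
  obs <- count_smaller(genes)
  n <- obs$smaller + obs$larger
  p_lower <- pbinom(obs$smaller, n, 0.5)
  p_upper <- pbinom(obs$smaller - 1, n, 0.5, lower.tail = FALSE)
  out <- list(n_smaller = obs$smaller, n_total = n, n_ties = obs$ties,
              p_binomial = min(1, 2 * min(p_lower, p_upper)),
              p_one_sided = p_upper)
  if (!is.null(background)) {
    bg <- setdiff(background, genes)
    bgc <- count_smaller(bg)
    tab <- matrix(c(obs$smaller, bgc$smaller, obs$larger, bgc$larger), 2, 2)
    out$p_background <- fisher_exact_2x2(tab)
    out$bg_smaller <- bgc$smaller
    out$bg_larger <- bgc$larger
  }
  out
}

#' Venn region counts and pairwise overlap statistics for 2-3 gene lists
#'
#' @param lists named list of 2 or 3 character vectors (no duplicate ids
#'   within a list).
#' @param universe character vector containing all lists.
#' @return list with \code{regions} (named counts over membership patterns
#'   such as \code{"A"}, \code{"A&B"}), \code{pairwise} (list of
#'   \code{\link{overlap_test}} results keyed \code{"A|B"}), and
#'   \code{union_size}.
#' @export
build_venn <- function(lists, universe) {
  stopifnot(length(lists) %in% 2:3, !is.null(names(lists)))
  for (nm in names(lists))
    if (anyDuplicated(lists[[nm]]))
      stop("duplicate gene ids within list ", nm)
  all_genes <- unique(unlist(lists))
  memb <- vapply(lists, function(l) all_genes %in% l, logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1,
                                              dimnames = list(NULL, names(lists)))
  pattern <- apply(memb, 1L, function(r) paste(names(lists)[r], collapse = "&"))
  regions <- table(pattern)
  pairs <- utils::combn(names(lists), 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(pr)
    overlap_test(lists[[pr[1]]], lists[[pr[2]]], universe))
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = "|")
  list(regions = c(regions), pairwise = pairwise,
       union_size = length(all_genes))
}
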