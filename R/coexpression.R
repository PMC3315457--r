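# Two-tissue co-expression module pipeline: quantile normalization,
# WGCNA-style module detection in the primary tissue, resampled tight
# clusters, cross-tissue coherent clusters, and module enrichment tests.
#
# Module sets are named lists of gene-id vectors; names encode the stage
# hierarchy ("f-2" -> "f-2-1" -> "f-2-1-1"), fat-specific remainders carry a
# "-spec" suffix.

#' Quantile-normalize the columns of a matrix
#'
#' Every column is mapped onto the across-column mean of order statistics;
#' ties share the average of their target values.
#'
#' @param m numeric matrix (genes x samples), no missing values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing values not allowed")
  stopifnot(ncol(m) >= 2)
  target <- rowMeans(apply(m, 2L, sort))
  ranks <- apply(m, 2L, rank, ties.method = "average")
  out <- apply(ranks, 2L, function(r)
    stats::approx(seq_len(nrow(m)), target, xout = r)$y)
  dimnames(out) <- dimnames(m)
  out
}

#' WGCNA-style co-expression modules
#'
#' Unsigned adjacency |Pearson r|^beta, topological overlap similarity,
#' average-linkage hierarchical clustering of the TOM dissimilarity, and a
#' static tree cut. Clusters below \code{min_size} go to the unclustered
#' pool (module 0).
#'
#' @param m genes x samples expression matrix (rownames = gene ids).
#' @param beta soft-threshold power (default 6).
#' @param min_size minimum module size (default 30).
#' @param cut_height static cut height on the TOM-dissimilarity dendrogram
#'   (default 0.95).
#' @param prefix module-name prefix (default "f").
#' @return list of class \code{module_set}: \code{stage = "wgcna"},
#'   \code{modules} (named list of gene-id vectors, largest first),
#'   \code{unclustered} (gene ids), \code{labels} (named integer vector,
#'   0 = unclustered).
#' @export
wgcna_modules <- function(m, beta = 6, min_size = 30, cut_height = 0.95,
                          prefix = "f") {
  m <- as.matrix(m)
  stopifnot(ncol(m) >= 4)
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant-expression gene(s) dropped")
    m <- m[sds > 0, , drop = FALSE]
  }
  r <- cor(t(m))
  A <- abs(r)^beta
  diag(A) <- 0
  tom <- tom_similarity(A)
  h <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(h, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  big <- big[order(-sizes[big])]
  modules <- lapply(big, function(b) rownames(m)[cl == as.integer(b)])
  names(modules) <- sprintf("%s-%d", prefix, seq_along(modules))
  labels <- setNames(integer(nrow(m)), rownames(m))
  for (i in seq_along(modules)) labels[modules[[i]]] <- i
  structure(list(stage = "wgcna", modules = modules,
                 unclustered = rownames(m)[labels == 0], labels = labels),
            class = "module_set")
}

# unsigned topological overlap similarity from an adjacency with zero diag
tom_similarity <- function(A) {
  L <- A %*% A
  k <- colSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, length, integer(1))
  cat(sprintf("module_set stage '%s': %d modules (sizes %s)\n", x$stage,
              length(x$modules),
              paste(utils::head(sizes, 10), collapse = ", ")))
  invisible(x)
}

# greedy extraction of maximal gene sets with all pairwise co-membership
# >= consensus, seeded by the gene of highest mean co-membership
extract_consensus_sets <- function(co, consensus, min_size) {
  remaining <- rownames(co)
  sets <- list()
  while (length(remaining) >= min_size) {
    cr <- co[remaining, remaining, drop = FALSE]
    seed_gene <- remaining[which.max(rowMeans(cr))]
    members <- seed_gene
    cand <- setdiff(remaining, seed_gene)
    cand <- cand[order(-co[cand, seed_gene])]
    for (g in cand)
      if (all(co[g, members] >= consensus)) members <- c(members, g)
    if (length(members) < min_size) break
    sets[[length(sets) + 1L]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  sets
}

#' Tight clusters within WGCNA modules by resampled k-means consensus
#'
#' For each module and each candidate cluster count k, k-means is run
#' repeatedly on resampled subsets of the samples, giving a per-k gene-pair
#' co-membership frequency matrix; maximal gene sets with all pairwise
#' co-membership at or above the consensus level are extracted greedily
#' (seeded by the gene of highest mean co-membership). The smallest k whose
#' consensus sets cover at least \code{min_coverage} of the module's genes
#' is retained (the coarsest stable sub-structure); if no k >= 2 yields
#' stable sub-structure the module itself
#' is the single tight cluster (k = 1, where co-membership is trivially 1,
#' so it still honours the consensus threshold).
#'
#' @param m genes x samples matrix (same matrix used for
#'   \code{\link{wgcna_modules}}).
#' @param wgcna a \code{module_set} of stage "wgcna" (or a named list of
#'   gene vectors).
#' @param k_range candidate cluster counts per module (default 2:6; k = 1 is
#'   always a candidate).
#' @param n_resamples resampling rounds per k (default 50).
#' @param consensus minimum pairwise co-membership frequency (default 0.7).
#' @param min_size minimum tight-cluster size (default 3).
#' @param sample_frac fraction of samples kept per resample (default 0.7).
#' @param min_coverage fraction of module genes that a k's consensus sets
#'   must cover for that k to count as stable (default 0.6).
#' @param seed integer seed.
#' @return \code{module_set} of stage "tight"; tight cluster j of module
#'   "f-i" is named "f-i-j". \code{parent} maps tight names to module names.
#' @export
tight_clusters <- function(m, wgcna, k_range = 2:6, n_resamples = 50,
                           consensus = 0.7, min_size = 3,
                           sample_frac = 0.7, min_coverage = 0.6,
                           seed = 1L) {
  mods <- if (inherits(wgcna, "module_set")) wgcna$modules else wgcna
  set.seed(seed)
  out <- list(); parent <- character(0)
  for (mi in seq_along(mods)) {
    genes <- mods[[mi]]
    ng <- length(genes)
    if (ng < min_size)
      stop("module ", names(mods)[mi], " smaller than min_size")
    sub <- m[genes, , drop = FALSE]
    ks <- sort(unique(pmin(k_range, ng - 1L)))
    ks <- ks[ks >= 2L]
    best_sets <- list(genes)   # k = 1 fallback: whole module
    best_k <- 1L
    for (k in ks) {
      co <- matrix(0, ng, ng, dimnames = list(genes, genes))
      nrun <- 0L
      for (r in seq_len(n_resamples)) {
        cols <- sample(ncol(sub), max(2L, round(sample_frac * ncol(sub))))
        km <- tryCatch(kmeans(sub[, cols, drop = FALSE], centers = k,
                              nstart = 1, iter.max = 20),
                       error = function(e) NULL)
        if (is.null(km)) next
        co <- co + outer(km$cluster, km$cluster, "==")
        nrun <- nrun + 1L
      }
      if (nrun == 0L) next
      co <- co / nrun
      sets <- extract_consensus_sets(co, consensus, min_size)
      coverage <- length(unlist(sets)) / ng
      if (coverage >= min_coverage) {
        best_sets <- sets
        best_k <- k
        break   # smallest stable k wins: coarsest stable sub-structure
      }
    }
    for (j in seq_along(best_sets)) {
      nm <- sprintf("%s-%d", names(mods)[mi], j)
      out[[nm]] <- sort(best_sets[[j]])
      parent[nm] <- names(mods)[mi]
    }
  }
  structure(list(stage = "tight", modules = out, parent = parent),
            class = "module_set")
}

# mean pairwise Pearson correlation among a gene set's rows
mean_pairwise_r <- function(m, genes) {
  if (length(genes) < 2) return(NA_real_)
  r <- cor(t(m[genes, , drop = FALSE]))
  mean(r[upper.tri(r)])
}

#' Coherent clusters: genes also co-expressed in a second tissue
#'
#' Within each tight cluster, the gene with the lowest mean correlation to
#' the other members in tissue B is removed iteratively until every
#' remaining gene has mean correlation at least \code{min_r} to the rest
#' (so each survivor is genuinely co-expressed with the others in both
#' tissues); survivors form the coherent cluster, and removed genes (or
#' whole failed clusters) form the tissue-A-specific remainder. Coherent
#' plus specific genes exactly partition each tight cluster.
#'
#' @param tight a \code{module_set} of stage "tight".
#' @param m_b genes x samples matrix for the second tissue (gene ids must
#'   cover the tight clusters).
#' @param min_r minimum mean pairwise Pearson r in tissue B (default 0.5).
#' @param min_size minimum surviving size (default 3).
#' @return list with \code{coherent} and \code{specific} \code{module_set}s;
#'   coherent cluster of tight cluster "f-i-j" is "f-i-j-1", its remainder
#'   "f-i-j-spec".
#' @export
coherent_clusters <- function(tight, m_b, min_r = 0.5, min_size = 3) {
  stopifnot(inherits(tight, "module_set"), tight$stage == "tight")
  missing <- setdiff(unlist(tight$modules), rownames(m_b))
  if (length(missing))
    stop("gene ids absent from tissue-B matrix: ",
         paste(head(missing, 3), collapse = ", "))
  coherent <- list(); specific <- list()
  for (nm in names(tight$modules)) {
    orig <- tight$modules[[nm]]
    cur <- orig
    repeat {
      if (length(cur) < min_size) { cur <- character(0); break }
      r <- cor(t(m_b[cur, , drop = FALSE]))
      diag(r) <- NA
      gene_mean <- rowMeans(r, na.rm = TRUE)
      if (min(gene_mean) >= min_r) break
      cur <- cur[-which.min(gene_mean)]
    }
    if (length(cur)) coherent[[sprintf("%s-1", nm)]] <- sort(cur)
    rem <- setdiff(orig, cur)
    if (length(rem)) specific[[sprintf("%s-spec", nm)]] <- sort(rem)
  }
  list(coherent = structure(list(stage = "coherent", modules = coherent),
                            class = "module_set"),
       specific = structure(list(stage = "fat_specific", modules = specific),
                            class = "module_set"))
}

#' Module enrichment for gene lists
#'
#' Per-module Fisher exact test of module membership against each gene list
#' within a universe, with BH-FDR across all module-list tests; a module is
#' flagged enriched for a list at raw p below \code{p_cut} with odds ratio
#' above 1.
#'
#' @param modules a \code{module_set} or named list of gene-id vectors.
#' @param gene_lists named list of gene-id vectors.
#' @param universe character vector containing modules and lists.
#' @param p_cut enrichment call threshold on the raw p (default 0.05).
#' @return data.frame: \code{module}, \code{list}, \code{overlap},
#'   \code{module_size}, \code{list_size}, \code{odds_ratio}, \code{p},
#'   \code{q}, \code{enriched}.
#' @export
module_enrichment <- function(modules, gene_lists, universe, p_cut = 0.05) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  if (!length(mods)) stop("empty module set")
  N <- length(unique(universe))
  rows <- list()
  for (mn in names(mods)) for (ln in names(gene_lists)) {
    mod <- intersect(mods[[mn]], universe)
    lst <- intersect(gene_lists[[ln]], universe)
    a <- length(intersect(mod, lst))
    tab <- matrix(c(a, length(lst) - a,
                    length(mod) - a, N - length(mod) - length(lst) + a),
                  2, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      module = mn, list = ln, overlap = a, module_size = length(mod),
      list_size = length(lst), odds_ratio = odds_ratio_2x2(tab),
      p = fisher_exact_2x2(tab))
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p < p_cut & out$odds_ratio > 1
  out
}

#' Contingency test between two module-level enrichment flags
#'
#' Cross-tabulates two logical flags over modules (e.g. enriched for
#' maturation genes x enriched for hormone genes, or stage coherent x
#' enriched) and tests association by chi-square with Yates correction and
#' by Fisher exact.
#'
#' @param flag_x,flag_y logical vectors over the same modules.
#' @return list: \code{table} (2x2), \code{p_chisq}, \code{p_fisher}.
#' @export
enrichment_contingency <- function(flag_x, flag_y) {
  stopifnot(length(flag_x) == length(flag_y))
  tab <- table(factor(flag_x, levels = c(TRUE, FALSE)),
               factor(flag_y, levels = c(TRUE, FALSE)))
  p_chisq <- tryCatch(chisq.test(tab, correct = TRUE)$p.value,
                      warning = function(w)
                        suppressWarnings(chisq.test(tab, correct = TRUE)$p.value))
  list(table = tab, p_chisq = p_chisq, p_fisher = fisher_exact_2x2(tab))
}

#' Run the full two-tissue module pipeline
#'
#' Quantile normalization of both tissues, WGCNA modules in tissue A, tight
#' clusters, and coherent / tissue-A-specific partitioning against tissue B.
#'
#' @param m_a,m_b genes x samples matrices for the two tissues (matching
#'   rownames).
#' @param beta,min_module_size,cut_height see \code{\link{wgcna_modules}}.
#' @param k_range,n_resamples,consensus see \code{\link{tight_clusters}}.
#' @param min_r,min_size see \code{\link{coherent_clusters}}.
#' @param normalize quantile-normalize inputs first (default TRUE).
#' @param seed integer seed (drives the tight-cluster resampling).
#' @return list with \code{wgcna}, \code{tight}, \code{coherent},
#'   \code{specific} module sets and the normalized matrices.
#' @export
coexpression_pipeline <- function(m_a, m_b, beta = 6, min_module_size = 30,
                                  cut_height = 0.95, k_range = 2:6,
                                  n_resamples = 50, consensus = 0.7,
                                  min_r = 0.5, min_size = 3,
                                  normalize = TRUE, seed = 1L) {
  stopifnot(identical(rownames(m_a), rownames(m_b)))
  if (normalize) {
    m_a <- quantile_normalize(m_a)
    m_b <- quantile_normalize(m_b)
  }
  w <- wgcna_modules(m_a, beta = beta, min_size = min_module_size,
                     cut_height = cut_height)
  t <- tight_clusters(m_a, w, k_range = k_range, n_resamples = n_resamples,
                      consensus = consensus, min_size = min_size, seed = seed)
  cs <- coherent_clusters(t, m_b, min_r = min_r, min_size = min_size)
  list(wgcna = w, tight = t, coherent = cs$coherent, specific = cs$specific,
       normalized_a = m_a, normalized_b = m_b)
}
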