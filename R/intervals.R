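# Interval plumbing for ChIP analyses: peak unions, length-matched random
# genomic background, target-gene assignment within a distance window, and
# per-peak differential-binding statistics.
#
# All interval data.frames use BED conventions: 0-based, half-open [start, end).

peaks_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)),
            all(df$start < df$end))
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr))
}

#' Union of two interval sets
#'
#' Merges overlapping or touching intervals into the minimal set of maximal
#' intervals covering both inputs (the usual "union of peak calls from two
#' programs" operation).
#'
#' @param a,b data.frames with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open).
#' @return merged data.frame, sorted by chrom and start.
#' @export
union_intervals <- function(a, b) {
  gr <- peaks_to_granges(rbind(a[c("chrom", "start", "end")],
                               b[c("chrom", "start", "end")]))
  out <- granges_to_df(GenomicRanges::reduce(GenomicRanges::sort(gr)))
  rownames(out) <- NULL
  out
}

#' Sample length-matched random genomic background segments
#'
#' Draws, for each peak, one random genomic segment of identical length,
#' uniformly over positions (chromosomes weighted by length), rejecting
#' segments that overlap any peak or contain too many ambiguous bases.
#'
#' @param genome \code{Biostrings::DNAStringSet} of chromosomes (named).
#' @param peaks data.frame of peak intervals on \code{genome}
#'   (\code{chrom}, \code{start}, \code{end}), or NULL to match raw lengths
#'   only (no overlap exclusion).
#' @param lengths integer vector of segment lengths; defaults to the peak
#'   lengths.
#' @param seed integer seed.
#' @param max_n_frac maximum tolerated fraction of non-ACGT bases.
#' @param max_retries placement attempts per segment before failing.
#' @return list with \code{sequences} (named character vector,
#'   \code{bg_0001} style) and \code{coords} (data.frame \code{chrom},
#'   \code{start}, \code{end}).
#' @export
sample_matched_background <- function(genome, peaks = NULL, lengths = NULL,
                                      seed = 1L, max_n_frac = 0.1,
                                      max_retries = 1000L) {
  if (is.null(lengths)) {
    stopifnot(!is.null(peaks))
    lengths <- peaks$end - peaks$start
  }
  set.seed(seed)
  chrom_len <- Biostrings::width(genome)
  chrom_names <- names(genome)
  peak_gr <- if (!is.null(peaks)) peaks_to_granges(peaks)
  n <- length(lengths)
  coords <- data.frame(chrom = character(n), start = integer(n),
                       end = integer(n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    L <- lengths[i]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      ok_chrom <- which(chrom_len >= L)
      if (!length(ok_chrom)) stop("no chromosome long enough for length ", L)
      ci <- if (length(ok_chrom) == 1L) ok_chrom else
        sample(ok_chrom, 1L, prob = chrom_len[ok_chrom])
      s <- sample.int(chrom_len[ci] - L + 1L, 1L) - 1L   # 0-based
      if (!is.null(peak_gr)) {
        cand <- GenomicRanges::GRanges(chrom_names[ci],
                                       IRanges::IRanges(s + 1L, s + L))
        if (length(GenomicRanges::findOverlaps(cand, peak_gr)) > 0) next
      }
      sq <- as.character(Biostrings::subseq(genome[[ci]], s + 1L, s + L))
      n_frac <- 1 - sum(strsplit(sq, "")[[1]] %in% DNA_BASES) / L
      if (n_frac > max_n_frac) next
      coords$chrom[i] <- chrom_names[ci]
      coords$start[i] <- s
      coords$end[i] <- s + L
      seqs[i] <- sq
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place background segment ", i, " after ",
           max_retries, " retries")
  }
  names(seqs) <- sprintf("bg_%04d", seq_len(n))
  list(sequences = seqs, coords = coords)
}

#' Assign target genes to peaks within a distance window
#'
#' A gene is a target of a peak iff the minimal distance between the peak
#' interval and the gene-body interval is at most \code{window} bp
#' (overlapping intervals have distance 0; a gene at exactly \code{window}
#' is included).
#'
#' @param peaks data.frame with \code{chrom}, \code{start}, \code{end} and a
#'   \code{peak_id} column (generated if absent).
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (gene body, 0-based half-open) and optionally \code{strand}.
#' @param window distance cutoff in bp (default 10000).
#' @return list with \code{pairs} (data.frame \code{peak_id}, \code{gene_id},
#'   \code{distance}), \code{peak2gene} and \code{gene2peak} (named lists of
#'   id vectors).
#' @export
assign_target_genes <- function(peaks, genes, window = 10000L) {
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("peak_%04d", seq_len(nrow(peaks)))
  pg <- peaks_to_granges(peaks)
  gg <- peaks_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(pg, gg, maxgap = window)
  d <- GenomicRanges::distance(pg[S4Vectors::queryHits(hits)],
                               gg[S4Vectors::subjectHits(hits)])
  keep <- !is.na(d) & d <= window
  pairs <- data.frame(
    peak_id = peaks$peak_id[S4Vectors::queryHits(hits)[keep]],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)[keep]],
    distance = d[keep])
  pairs <- pairs[order(pairs$peak_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       peak2gene = split(pairs$gene_id, pairs$peak_id),
       gene2peak = split(pairs$peak_id, pairs$gene_id))
}

#' Per-peak differential binding between two groups
#'
#' For each peak, the log2 fold difference between group means and a one-way
#' ANOVA p-value (for two groups this equals the equal-variance two-sample
#' t-test), with Benjamini-Hochberg FDR across peaks.
#'
#' @param intensities data.frame with \code{peak_id}, \code{replicate},
#'   \code{group}, \code{log2ratio} (log2 pulldown/input binding intensity).
#' @param groups length-2 character: (reference group, comparison group);
#'   fold = mean(comparison) - mean(reference). Defaults to the sorted unique
#'   group labels.
#' @return data.frame \code{peak_id}, \code{fold}, \code{p}, \code{q}.
#' @export
differential_binding <- function(intensities, groups = NULL) {
  stopifnot(all(c("peak_id", "group", "log2ratio") %in% names(intensities)))
  if (is.null(groups)) groups <- sort(unique(intensities$group))
  intensities <- intensities[intensities$group %in% groups, , drop = FALSE]
  cnt <- table(intensities$peak_id, intensities$group)
  if (any(cnt < 2))
    stop("each group needs >= 2 replicates for every peak")
  res <- lapply(split(intensities, intensities$peak_id), function(df) {
    y <- df$log2ratio
    g <- factor(df$group, levels = unique(df$group))
    means <- tapply(y, df$group, mean)
    k <- nlevels(g); n <- length(y)
    ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    p <- pf(f, k - 1, n - k, lower.tail = FALSE)
    data.frame(peak_id = df$peak_id[1],
               fold = unname(means[groups[2]] - means[groups[1]]),
               p = p)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Correlation of binding intensity between two samples or groups
#'
#' @param x,y numeric vectors of per-peak intensities (same peak order).
#' @return list \code{r}, \code{p} (two-sided), \code{n}.
#' @export
binding_correlation <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 peaks")
  cor_with_p(x, y)
}

#' Correlation of differential binding with nearby-gene expression change
#'
#' Peaks are filtered to those with at least \code{min_fold}-fold binding
#' difference, joined to target genes (a gene near several retained peaks
#' uses the peak of maximal absolute fold), and the Pearson correlation of
#' binding fold vs expression fold is computed over the joined pairs.
#'
#' @param peak_folds data.frame \code{peak_id}, \code{fold} (log2 binding
#'   fold difference).
#' @param assignment result of \code{\link{assign_target_genes}} (or a
#'   data.frame with \code{peak_id}, \code{gene_id}).
#' @param gene_folds named numeric vector: expression log2 fold change per
#'   gene id.
#' @param min_fold linear fold-difference filter (default 1.25; peaks with
#'   |fold| < log2(min_fold) are dropped).
#' @return list \code{r}, \code{p}, \code{n}, and the joined data.frame
#'   \code{pairs}.
#' @export
binding_expression_correlation <- function(peak_folds, assignment, gene_folds,
                                           min_fold = 1.25) {
  pairs <- if (is.data.frame(assignment)) assignment else assignment$pairs
  keep <- abs(peak_folds$fold) >= log2(min_fold)
  pf_ <- peak_folds[keep, , drop = FALSE]
  j <- merge(pairs, pf_, by = "peak_id")
  j <- j[j$gene_id %in% names(gene_folds), , drop = FALSE]
  if (nrow(j) == 0) stop("empty join between filtered peaks and genes")
  j <- j[order(j$gene_id, -abs(j$fold)), , drop = FALSE]
  j <- j[!duplicated(j$gene_id), , drop = FALSE]
  if (nrow(j) < 3) stop("fewer than 3 joined peak-gene pairs")
  j$expr_fold <- gene_folds[j$gene_id]
  res <- cor_with_p(j$fold, j$expr_fold)
  c(res, list(pairs = j))
}
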