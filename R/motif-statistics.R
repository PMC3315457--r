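# Motif-level statistics around ChIP peaks: presence/absence enrichment
# against matched background, class-differential association, and the
# shuffle-null test for constraints on inter-site spacing of heterotypic
# motif pairs.

#' Collapse motif sites to per-sequence presence
#'
#' A sequence is "present" for a motif iff it carries at least one match on
#' either strand (overlapping matches count once).
#'
#' @param sites data.frame from \code{\link{scan_motif}}.
#' @param seq_ids character vector of all sequence ids scanned (sequences
#'   with zero sites are absent from \code{sites} but must be counted).
#' @param motif_name motif to tabulate; default: the single motif in
#'   \code{sites}.
#' @return named logical vector over \code{seq_ids}.
#' @export
motif_presence <- function(sites, seq_ids, motif_name = NULL) {
  if (!is.null(motif_name)) sites <- sites[sites$motif == motif_name, ]
  setNames(seq_ids %in% sites$seq_id, seq_ids)
}

#' Motif enrichment in peaks versus background sequences
#'
#' Scans both sets at the same calibrated threshold, forms the 2x2 table of
#' (peak / background) x (motif present / absent), and applies a two-sided
#' Fisher exact test.
#'
#' @param peak_seqs,background_seqs named character vectors of sequences.
#' @param motif a \code{motif} object.
#' @param alpha match-defining tail probability (default 1e-3).
#' @param cutoff optional explicit score cutoff (overrides \code{alpha}).
#' @return list of class \code{enrichment_result}: \code{motif_name},
#'   counts \code{a}, \code{b}, \code{c}, \code{d} (peak-present,
#'   peak-absent, background-present, background-absent),
#'   \code{odds_ratio}, \code{p}, \code{enriched} (odds ratio > 1), and the
#'   presence fractions.
#' @export
enrichment_test <- function(peak_seqs, background_seqs, motif, alpha = 1e-3,
                            cutoff = NULL) {
  if (!length(peak_seqs) || !length(background_seqs))
    stop("empty sequence set")
  if (is.null(cutoff)) cutoff <- threshold_for_pvalue(motif, alpha)
  pres_p <- motif_presence(scan_motif(peak_seqs, motif, cutoff = cutoff),
                           names(peak_seqs))
  pres_b <- motif_presence(scan_motif(background_seqs, motif, cutoff = cutoff),
                           names(background_seqs))
  presence_table_test(pres_p, pres_b, motif$name,
                      row_labels = c("peak", "background"))
}

presence_table_test <- function(pres1, pres2, motif_name,
                                row_labels = c("group1", "group2")) {
  a <- sum(pres1); b <- sum(!pres1)
  cc <- sum(pres2); d <- sum(!pres2)
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(row_labels, c("present", "absent")))
  structure(
    list(motif_name = motif_name, a = a, b = b, c = cc, d = d,
         odds_ratio = odds_ratio_2x2(tab), p = fisher_exact_2x2(tab),
         enriched = isTRUE(odds_ratio_2x2(tab) > 1),
         frac1 = a / (a + b), frac2 = cc / (cc + d), table = tab),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("motif %s: %d/%d vs %d/%d present, OR = %.3g, p = %.3g\n",
              x$motif_name, x$a, x$a + x$b, x$c, x$c + x$d,
              x$odds_ratio, x$p))
  invisible(x)
}

#' Screen a motif compendium for enrichment, with BH-FDR
#'
#' @inheritParams enrichment_test
#' @param motifs list of \code{motif} objects.
#' @return data.frame, one row per motif, with counts, odds ratio, raw
#'   \code{p} and BH-adjusted \code{q}, sorted by p.
#' @export
enrichment_screen <- function(peak_seqs, background_seqs, motifs,
                              alpha = 1e-3) {
  rows <- lapply(motifs, function(m) {
    r <- enrichment_test(peak_seqs, background_seqs, m, alpha = alpha)
    data.frame(motif = r$motif_name, peak_present = r$a,
               peak_absent = r$b, bg_present = r$c, bg_absent = r$d,
               odds_ratio = r$odds_ratio, p = r$p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Association of motif presence with a two-class locus labeling
#'
#' Fisher exact test of class x presence, e.g. loci whose assigned gene is
#' induced in foragers versus induced in nurses.
#'
#' @param sequences named character vector of locus sequences.
#' @param classes named factor/character of class labels over the same ids
#'   (exactly two classes, each non-empty).
#' @inheritParams enrichment_test
#' @return an \code{enrichment_result}; \code{enriched} refers to
#'   over-representation in the first class level.
#' @export
class_association_test <- function(sequences, classes, motif, alpha = 1e-3,
                                   cutoff = NULL) {
  classes <- classes[names(sequences)]
  lv <- unique(as.character(classes))
  if (length(lv) != 2)
    stop("need exactly two locus classes, got: ", paste(lv, collapse = ", "))
  if (is.null(cutoff)) cutoff <- threshold_for_pvalue(motif, alpha)
  pres <- motif_presence(scan_motif(sequences, motif, cutoff = cutoff),
                         names(sequences))
  res <- presence_table_test(pres[classes == lv[1]], pres[classes == lv[2]],
                             motif$name, row_labels = lv)
  res$direction <- if (isTRUE(res$odds_ratio > 1)) lv[1] else lv[2]
  res
}

# merged start-sorted site list per sequence -> adjacent heterotypic pairs;
# spacing = cofactor start - anchor start (negative: cofactor to the left)
pair_spacings_one <- function(starts, motifs, anchor, cofactor) {
  o <- order(starts, motifs)
  starts <- starts[o]; motifs <- motifs[o]
  n <- length(starts)
  if (n < 2) return(integer(0))
  a <- motifs[-n]; b <- motifs[-1]
  het <- a != b
  s1 <- starts[-n][het]; m1 <- a[het]
  s2 <- starts[-1][het]
  ifelse(m1 == anchor, s2 - s1, -(s2 - s1))
}

#' Signed spacing histogram of adjacent heterotypic site pairs
#'
#' Per sequence, sites of the two motifs are merged and start-sorted;
#' consecutive entries with different motif names form an "adjacent
#' heterotypic pair". The signed spacing is cofactor start minus anchor
#' start, so negative values put the cofactor to the left of the anchor.
#'
#' @param sites data.frame of sites for both motifs (from
#'   \code{\link{scan_motif}}, rbind-ed), with columns \code{seq_id},
#'   \code{start}, \code{motif}.
#' @param anchor,cofactor motif names.
#' @return list with \code{spacings} (integer vector, one per pair),
#'   \code{histogram} (table over signed spacing), and \code{mode} (spacing
#'   with maximal count; NA when no pairs).
#' @export
spacing_histogram <- function(sites, anchor, cofactor) {
  sites <- sites[sites$motif %in% c(anchor, cofactor), , drop = FALSE]
  sp <- unlist(lapply(split(sites, sites$seq_id), function(df)
    pair_spacings_one(df$start, df$motif, anchor, cofactor)),
    use.names = FALSE)
  sp <- as.integer(sp %||% integer(0))
  h <- table(sp)
  mode <- if (length(sp)) as.integer(names(h)[which.max(h)]) else NA_integer_
  list(spacings = sp, histogram = h, mode = mode)
}

#' Shuffle site locations within each sequence
#'
#' Each site's start is resampled uniformly over the positions where its
#' window fits, independently; per-sequence, per-motif site counts, widths
#' and strands are preserved. Shuffled sites may overlap one another.
#'
#' @param sites data.frame with \code{seq_id}, \code{start}, \code{motif}
#'   and a \code{width} column (or \code{end}; width = end - start).
#' @param seq_lengths named integer vector of sequence lengths.
#' @param seed integer seed.
#' @return data.frame like \code{sites} with new \code{start}/\code{end}.
#' @export
shuffle_sites <- function(sites, seq_lengths, seed = 1L) {
  set.seed(seed)
  w <- sites$width %||% (sites$end - sites$start)
  L <- seq_lengths[sites$seq_id]
  if (any(w > L)) stop("site wider than its sequence")
  npos <- L - w + 1L
  sites$start <- pmin(as.integer(floor(runif(nrow(sites)) * npos)), npos - 1L)
  sites$end <- sites$start + w
  sites
}

#' Permutation test for a constraint on inter-site spacing
#'
#' Adjacent heterotypic anchor/cofactor pairs are classified by |spacing| at
#' a cutoff (default 25 bp). A null is built by shuffling site locations
#' within each sequence \code{n_shuffles} times and pooling the shuffled
#' pair classifications; observed vs pooled-null counts are compared by a
#' two-sided Fisher exact test.
#'
#' @param sites data.frame of observed sites for both motifs (columns
#'   \code{seq_id}, \code{start}, \code{end} or \code{width}, \code{motif}).
#' @param seq_lengths named integer vector (lengths of every scanned
#'   sequence).
#' @param anchor,cofactor motif names.
#' @param cutoff spacing cutoff in bp (default 25; pairs with |spacing| <=
#'   cutoff are "close").
#' @param n_shuffles shuffled datasets pooled into the null (default 50).
#' @param seed master seed; shuffle i uses a stream derived from
#'   (seed, i).
#' @return list of class \code{spacing_result}: \code{n_le}, \code{n_gt}
#'   (observed close/far pair counts), \code{b_le}, \code{b_gt} (pooled
#'   null counts), \code{p}, \code{histogram}, \code{mode},
#'   \code{no_pairs} flag.
#' @export
spacing_constraint_test <- function(sites, seq_lengths, anchor, cofactor,
                                    cutoff = 25L, n_shuffles = 50L,
                                    seed = 1L) {
  sites <- sites[sites$motif %in% c(anchor, cofactor), , drop = FALSE]
  if (is.null(sites$width)) sites$width <- sites$end - sites$start
  obs <- spacing_histogram(sites, anchor, cofactor)
  n_le <- sum(abs(obs$spacings) <= cutoff)
  n_gt <- length(obs$spacings) - n_le
  if (length(obs$spacings) == 0) {
    warning("no heterotypic pairs in observed data")
    return(structure(list(anchor = anchor, cofactor = cofactor,
                          n_le = 0L, n_gt = 0L, b_le = 0L, b_gt = 0L,
                          p = 1, histogram = obs$histogram,
                          mode = NA_integer_, no_pairs = TRUE,
                          cutoff = cutoff, n_shuffles = n_shuffles),
                     class = "spacing_result"))
  }
  b_le <- 0L; b_gt <- 0L
  for (i in seq_len(n_shuffles)) {
    sh <- shuffle_sites(sites, seq_lengths, seed = derive_seed(seed, i))
    ssp <- spacing_histogram(sh, anchor, cofactor)$spacings
    b_le <- b_le + sum(abs(ssp) <= cutoff)
    b_gt <- b_gt + sum(abs(ssp) > cutoff)
  }
  p <- fisher_exact_2x2(matrix(c(n_le, b_le, n_gt, b_gt), 2, 2))
  structure(list(anchor = anchor, cofactor = cofactor,
                 n_le = n_le, n_gt = n_gt, b_le = b_le, b_gt = b_gt,
                 p = p, histogram = obs$histogram, mode = obs$mode,
                 no_pairs = FALSE, cutoff = cutoff,
                 n_shuffles = n_shuffles),
            class = "spacing_result")
}

#' @export
print.spacing_result <- function(x, ...) {
  cat(sprintf("spacing test %s vs %s: %d/%d observed <=%d bp/far, null %d/%d, p = %.3g\n",
              x$anchor, x$cofactor, x$n_le, x$n_gt, x$cutoff,
              x$b_le, x$b_gt, x$p))
  invisible(x)
}

#' Spacing-constraint test from sequences across match thresholds
#'
#' Convenience wrapper: scans the sequences for both motifs at each match
#' tail probability and runs \code{\link{spacing_constraint_test}} at each,
#' mirroring a threshold-robustness screen.
#'
#' @param sequences named character vector.
#' @param anchor,cofactor \code{motif} objects.
#' @param alphas match tail probabilities (default the five-point grid
#'   1e-2, 5e-3, 1e-3, 5e-4, 1e-4).
#' @inheritParams spacing_constraint_test
#' @return data.frame with one row per alpha: pair counts, p, mode.
#' @export
spacing_threshold_screen <- function(sequences, anchor, cofactor,
                                     alphas = c(1e-2, 5e-3, 1e-3, 5e-4, 1e-4),
                                     cutoff = 25L, n_shuffles = 50L,
                                     seed = 1L) {
  seq_lengths <- setNames(nchar(sequences), names(sequences))
  rows <- lapply(alphas, function(al) {
    sa <- scan_motif(sequences, anchor, alpha = al)
    sc <- scan_motif(sequences, cofactor, alpha = al)
    r <- spacing_constraint_test(rbind(sa, sc), seq_lengths,
                                 anchor$name, cofactor$name,
                                 cutoff = cutoff, n_shuffles = n_shuffles,
                                 seed = seed)
    data.frame(alpha = al, n_le = r$n_le, n_gt = r$n_gt,
               b_le = r$b_le, b_gt = r$b_gt, p = r$p, mode = r$mode)
  })
  do.call(rbind, rows)
}
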