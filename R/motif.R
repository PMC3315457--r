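# Position weight models: construction from IUPAC consensus strings or count
# matrices, Patser-style log-odds scoring against a background composition,
# exact score distributions by positionwise convolution, and tail-probability
# calibrated match thresholds.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# score assigned to a zero-probability base when pseudocount = 0; well below
# any calibrated threshold, and keeps the convolution support finite
NEG_SCORE_FLOOR <- -30

#' Build a motif from a nucleotide count (or probability) matrix
#'
#' Column probabilities are \code{(count + pseudocount * background) /
#' (total + pseudocount)}: the total pseudocount weight is distributed over
#' the four bases in proportion to the background.
#'
#' @param counts 4 x w non-negative matrix; rows A, C, G, T (rownames
#'   optional, this order assumed if absent).
#' @param name motif identifier.
#' @param pseudocount total pseudocount weight per column (default 0.01).
#' @param background length-4 background probabilities (A, C, G, T), summing
#'   to 1. Default uniform.
#' @return an object of class \code{motif}: list with \code{name},
#'   \code{prob} (4 x w column-stochastic matrix), \code{width},
#'   \code{background}, \code{pseudocount}, and the log-odds matrix
#'   \code{score} in nats (zero-probability cells floored at -30).
#' @export
build_pwm <- function(counts, name = "motif", pseudocount = 0.01,
                      background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, all(counts >= 0), all(is.finite(counts)))
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-9)
  if (!is.null(rownames(counts))) counts <- counts[DNA_BASES, , drop = FALSE]
  totals <- colSums(counts)
  if (pseudocount == 0 && any(totals == 0))
    stop("all-zero count column with pseudocount = 0")
  prob <- sweep(counts, 2L, totals + pseudocount, "/") +
    outer(background, rep(pseudocount, ncol(counts))) /
      rep(totals + pseudocount, each = 4L)
  dimnames(prob) <- list(DNA_BASES, NULL)
  score <- log(prob / background)
  score[prob == 0] <- NEG_SCORE_FLOOR
  structure(
    list(name = name, prob = prob, width = ncol(prob),
         background = setNames(background, DNA_BASES),
         pseudocount = pseudocount, score = score),
    class = "motif"
  )
}

#' Build a motif from an IUPAC degenerate consensus string
#'
#' Each position puts equal probability on the bases its code allows, then
#' pseudocounts are applied as in \code{\link{build_pwm}}.
#'
#' @param consensus string over the 15 IUPAC nucleotide codes.
#' @param name motif identifier; defaults to the consensus itself.
#' @inheritParams build_pwm
#' @return a \code{motif} object of width \code{nchar(consensus)}.
#' @export
iupac_to_pwm <- function(consensus, name = consensus, pseudocount = 0.01,
                         background = rep(0.25, 4)) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(length(chars) >= 1L)
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad))
    stop("illegal IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  counts <- vapply(chars, function(ch) {
    col <- numeric(4L)
    allowed <- IUPAC_SETS[[ch]]
    col[match(allowed, DNA_BASES)] <- 1 / length(allowed)
    col
  }, numeric(4L))
  m <- build_pwm(counts, name = name, pseudocount = pseudocount,
                 background = background)
  m$consensus <- paste(chars, collapse = "")
  m
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif '%s' (width %d, pseudocount %g)\n",
              x$name, x$width, x$pseudocount))
  print(round(x$prob, 3))
  invisible(x)
}

#' Reverse-complement a motif
#' @param motif a \code{motif} object.
#' @return the reverse-complement \code{motif}.
#' @export
reverse_complement_motif <- function(motif) {
  prob <- motif$prob[4:1, motif$width:1, drop = FALSE]
  dimnames(prob) <- list(DNA_BASES, NULL)
  score <- log(prob / motif$background)
  score[prob == 0] <- NEG_SCORE_FLOOR
  out <- motif
  out$prob <- prob
  out$score <- score
  out
}

#' Exact distribution of per-window log-odds scores under the background
#'
#' Assuming windows drawn i.i.d. from the motif's background composition,
#' the score distribution is computed by positionwise convolution over a
#' discretized score grid.
#'
#' @param motif a \code{motif} object, width at most 16 in exact mode.
#' @param binwidth score discretization step in nats (default 1e-3; the
#'   calibrated threshold's error is bounded by about \code{width * binwidth}).
#' @return list with numeric vectors \code{score} (bin scores, ascending) and
#'   \code{prob} (summing to 1), plus \code{binwidth}.
#' @export
score_distribution <- function(motif, binwidth = 1e-3) {
  stopifnot(inherits(motif, "motif"))
  if (motif$width > 16L)
    stop("exact score distribution limited to width <= 16")
  bins <- round(motif$score / binwidth)          # 4 x w integer bins
  pi_bg <- motif$background
  lo <- 0L; hi <- 0L
  prob <- 1
  for (j in seq_len(motif$width)) {
    bj <- bins[, j]
    nlo <- lo + min(bj); nhi <- hi + max(bj)
    acc <- numeric(nhi - nlo + 1L)
    for (b in 1:4) {
      off <- (lo + bj[b]) - nlo
      idx <- seq_along(prob) + off
      acc[idx] <- acc[idx] + prob * pi_bg[b]
    }
    prob <- acc; lo <- nlo; hi <- nhi
  }
  keep <- prob > 0
  list(score = (lo:hi)[keep] * binwidth, prob = prob[keep],
       binwidth = binwidth)
}

#' Calibrate a match-defining score cutoff from a tail probability
#'
#' Returns the smallest cutoff t such that P(score >= t) <= alpha under the
#' background model, i.e. Patser-style p-value calibration of what counts as
#' a motif match.
#'
#' @param motif a \code{motif} object.
#' @param alpha match-defining tail probability in (0, 1].
#' @param binwidth passed to \code{\link{score_distribution}}.
#' @return list of class \code{score_threshold}: \code{motif_name},
#'   \code{alpha}, \code{score_cutoff} (nats) and the achieved tail
#'   probability \code{tail_prob}.
#' @export
threshold_for_pvalue <- function(motif, alpha, binwidth = 1e-3) {
  stopifnot(alpha > 0, alpha <= 1)
  d <- score_distribution(motif, binwidth = binwidth)
  tail <- rev(cumsum(rev(d$prob)))
  i <- which(tail <= alpha + 1e-12)
  # binning rounds each column score to the nearest grid point, so a word's
  # true score differs from its binned score by at most width * binwidth / 2
  slack <- motif$width * binwidth / 2
  if (!length(i)) {
    # even the single best word exceeds alpha (short/degenerate motifs at
    # stringent alpha): the smallest qualifying cutoff sits just above the
    # maximal attainable score, i.e. nothing matches
    bin_score <- max(d$score) + binwidth
    cutoff <- bin_score + slack
    tail_prob <- 0
  } else {
    bin_score <- d$score[i[1L]]
    # subtracting the slack guarantees no word of the selected bins is lost
    cutoff <- bin_score - slack
    tail_prob <- tail[i[1L]]
  }
  structure(
    list(motif_name = motif$name, alpha = alpha,
         score_cutoff = cutoff, bin_score = bin_score,
         tail_prob = tail_prob),
    class = "score_threshold"
  )
}

# integer-encode a sequence: A=1 C=2 G=3 T=4, anything else NA
encode_seq <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

# scores of all length-w windows of an encoded sequence against a 4 x w
# score matrix; windows containing non-ACGT give NA
window_scores <- function(enc, score) {
  w <- ncol(score)
  n <- length(enc)
  if (n < w) return(numeric(0))
  nw <- n - w + 1L
  tot <- numeric(nw)
  for (j in seq_len(w)) {
    s <- score[, j][enc[j:(j + nw - 1L)]]
    tot <- tot + s
  }
  tot
}

#' Scan sequences for motif matches on both strands
#'
#' Every window whose log-odds score reaches the cutoff is reported;
#' overlapping matches are all kept (presence/absence collapsing is a
#' downstream concern). Reverse-strand matches are reported at the
#' forward-strand start of their window. Windows containing non-ACGT
#' characters are skipped.
#'
#' @param sequences named character vector or \code{Biostrings::DNAStringSet}.
#' @param motif a \code{motif} object.
#' @param alpha match tail probability used to calibrate the cutoff when
#'   \code{cutoff} is not supplied (default 1e-3).
#' @param cutoff explicit score cutoff in nats, or a \code{score_threshold};
#'   overrides \code{alpha}.
#' @param strands \code{"both"} (default), \code{"+"} or \code{"-"}.
#' @return data.frame of motif sites: \code{seq_id}, \code{start} (0-based,
#'   forward strand), \code{end} (exclusive), \code{strand}, \code{score}
#'   (nats), \code{motif}. A sequence shorter than the motif yields no rows.
#' @export
scan_motif <- function(sequences, motif, alpha = 1e-3, cutoff = NULL,
                       strands = "both") {
  stopifnot(inherits(motif, "motif"))
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%04d", seq_along(sequences))
  if (is.null(cutoff)) cutoff <- threshold_for_pvalue(motif, alpha)
  if (inherits(cutoff, "score_threshold")) cutoff <- cutoff$score_cutoff
  strands <- match.arg(strands, c("both", "+", "-"))
  w <- motif$width
  rc <- if (strands != "+") reverse_complement_motif(motif)
  out <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    enc <- encode_seq(sequences[[i]])
    rows <- list()
    if (strands != "-") {
      sc <- window_scores(enc, motif$score)
      hit <- which(!is.na(sc) & sc >= cutoff - 1e-9)
      if (length(hit))
        rows[["+"]] <- data.frame(start = hit - 1L, strand = "+",
                                  score = sc[hit])
    }
    if (strands != "+") {
      sc <- window_scores(enc, rc$score)
      hit <- which(!is.na(sc) & sc >= cutoff - 1e-9)
      if (length(hit))
        rows[["-"]] <- data.frame(start = hit - 1L, strand = "-",
                                  score = sc[hit])
    }
    if (length(rows)) {
      df <- do.call(rbind, rows)
      df <- df[order(df$start, df$strand), , drop = FALSE]
      df <- data.frame(seq_id = names(sequences)[i], df)
      out[[i]] <- df
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), motif = character(0)))
  res <- do.call(rbind, out)
  res$end <- res$start + w
  rownames(res) <- NULL
  data.frame(res[, c("seq_id", "start", "end", "strand", "score")],
             motif = motif$name)
}

#' Rescore one window of a sequence against a motif
#'
#' Utility for verifying reported sites: forward-strand score of the window
#' starting at \code{start} (0-based), or of its reverse complement for
#' strand \code{"-"}.
#'
#' @param sequence single character string.
#' @param motif a \code{motif} object.
#' @param start 0-based window start.
#' @param strand \code{"+"} or \code{"-"}.
#' @return log-odds score in nats (NA if the window has non-ACGT characters).
#' @export
score_window <- function(sequence, motif, start, strand = "+") {
  enc <- encode_seq(sequence)
  w <- motif$width
  idx <- (start + 1L):(start + w)
  stopifnot(start >= 0, start + w <= length(enc))
  sm <- if (strand == "-") reverse_complement_motif(motif)$score else motif$score
  sum(sm[cbind(enc[idx], seq_len(w))])
}
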