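# Synthetic-data generators. Every downstream stage of the pipeline is
# exercised on data produced here, with planted structure recorded in truth
# tables so recovery can be asserted without re-deriving it.

#' Simulation config for peak-like sequences with planted motifs
#'
#' @param n_peaks number of sequences.
#' @param length_range integer (min_bp, max_bp); lengths drawn uniformly.
#' @param gc background GC fraction in [0, 1] (Markov-0 background,
#'   P(G) = P(C) = gc/2).
#' @param planted list of \code{list(motif = <motif>, copies = <int>)}:
#'   motifs planted in every sequence.
#' @param pair_spec optional \code{list(anchor = <motif>, cofactor = <motif>,
#'   spacing = <signed bp>, fraction = <0..1>)}; in a \code{fraction} of
#'   sequences an anchor/cofactor pair is planted with cofactor start minus
#'   anchor start exactly \code{spacing}. Overlapping spans are resolved
#'   jointly; incompatible motif pairs are an error.
#' @param seed integer master seed.
#' @return validated list of class \code{seq_sim_config}.
#' @export
seq_sim_config <- function(n_peaks, length_range, gc = 0.5, planted = list(),
                           pair_spec = NULL, seed = 1L) {
  stopifnot(n_peaks >= 1, length(length_range) == 2,
            length_range[1] <= length_range[2], length_range[1] >= 1,
            gc >= 0, gc <= 1)
  widths <- vapply(planted, function(p) p$motif$width, integer(1))
  if (!is.null(pair_spec)) {
    stopifnot(pair_spec$fraction >= 0, pair_spec$fraction <= 1)
    span <- pair_span_width(pair_spec)
    widths <- c(widths, span)
  }
  if (length(widths) && length_range[1] < max(widths))
    stop("planted motifs do not fit in the minimum sequence length")
  structure(list(n_peaks = as.integer(n_peaks),
                 length_range = as.integer(length_range), gc = gc,
                 planted = planted, pair_spec = pair_spec,
                 seed = as.integer(seed)),
            class = "seq_sim_config")
}

pair_span_width <- function(pair_spec) {
  d <- pair_spec$spacing
  wa <- pair_spec$anchor$width
  wc <- pair_spec$cofactor$width
  max(wa, d + wc) - min(0, d)
}

#' Generate a Markov-0 genome sequence
#'
#' @param length sequence length in bp (>= 1).
#' @param gc GC fraction; bases drawn i.i.d. with P(G) = P(C) = gc/2.
#' @param seed integer seed.
#' @param name sequence name.
#' @return \code{Biostrings::DNAStringSet} with one named sequence.
#' @export
gen_genome <- function(length, gc = 0.5, seed = 1L, name = "chr1") {
  if (length < 1) stop("length must be >= 1")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
             collapse = "")
  setNames(Biostrings::DNAStringSet(s), name)
}

# sample one instance word of a motif: the most-informative base per column
# (ties broken uniformly at random), so planted sites score maximally
sample_motif_word <- function(motif) {
  vapply(seq_len(motif$width), function(j) {
    col <- motif$prob[, j]
    top <- which(col >= max(col) - 1e-12)
    DNA_BASES[if (length(top) == 1L) top else sample(top, 1L)]
  }, character(1))
}

# joint word covering anchor + cofactor spans at signed spacing d; positions
# constrained by both motifs use the intersection of their argmax base sets
sample_pair_word <- function(pair_spec) {
  d <- pair_spec$spacing
  wa <- pair_spec$anchor$width
  wc <- pair_spec$cofactor$width
  lo <- min(0L, d)
  span <- pair_span_width(pair_spec)
  word <- rep(NA_character_, span)
  argmax_sets <- function(m)
    lapply(seq_len(m$width), function(j) {
      col <- m$prob[, j]
      DNA_BASES[col >= max(col) - 1e-12]
    })
  sets <- rep(list(DNA_BASES), span)
  aoff <- 0L - lo; coff <- d - lo
  sa <- argmax_sets(pair_spec$anchor)
  sc <- argmax_sets(pair_spec$cofactor)
  for (j in seq_len(wa)) sets[[aoff + j]] <- intersect(sets[[aoff + j]], sa[[j]])
  for (j in seq_len(wc)) sets[[coff + j]] <- intersect(sets[[coff + j]], sc[[j]])
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    stop("anchor and cofactor motifs are incompatible at spacing ", d)
  for (j in seq_len(span)) {
    s <- sets[[j]]
    word[j] <- if (length(s) == 1L) s else sample(s, 1L)
  }
  list(word = word, anchor_off = aoff, cofactor_off = coff)
}

#' Generate peak-like sequences with planted motif sites
#'
#' Sequences are Markov-0 background with motif instance words written in at
#' random non-overlapping positions; a configured fraction of sequences
#' additionally carries an anchor/cofactor pair at an exact signed start
#' spacing. All planted sites are on the + strand and recorded in the truth
#' table. Background can by chance contain further spurious matches; truth
#' rows cover planted sites only.
#'
#' @param config a \code{\link{seq_sim_config}}.
#' @return list with \code{sequences} (named character vector,
#'   \code{peak_0001} style ids) and \code{truth} (data.frame \code{seq_id},
#'   \code{motif}, \code{start} 0-based, \code{strand}, \code{role} in
#'   \{single, pair_anchor, pair_cofactor\}).
#' @export
gen_peaks <- function(config) {
  stopifnot(inherits(config, "seq_sim_config"))
  set.seed(config$seed)
  n <- config$n_peaks
  ids <- sprintf("peak_%04d", seq_len(n))
  lens <- config$length_range[1] +
    sample.int(config$length_range[2] - config$length_range[1] + 1L, n,
               replace = TRUE) - 1L
  p_bg <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
            (1 - config$gc) / 2)
  n_pair <- if (is.null(config$pair_spec)) 0L else
    round(config$pair_spec$fraction * n)
  truth <- list()
  seqs <- character(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    chars <- sample(DNA_BASES, L, replace = TRUE, prob = p_bg)
    occupied <- integer(0)   # positions already holding a planted word
    place <- function(wlen) {
      for (try in 1:200) {
        s <- sample.int(L - wlen + 1L, 1L) - 1L   # 0-based
        span <- (s + 1L):(s + wlen)
        if (!any(span %in% occupied)) return(s)
      }
      stop("could not place a planted word without overlap (sequence ", i, ")")
    }
    if (i <= n_pair) {
      pw <- sample_pair_word(config$pair_spec)
      s <- place(length(pw$word))
      chars[(s + 1L):(s + length(pw$word))] <- pw$word
      occupied <- c(occupied, (s + 1L):(s + length(pw$word)))
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = ids[i],
        motif = c(config$pair_spec$anchor$name, config$pair_spec$cofactor$name),
        start = c(s + pw$anchor_off, s + pw$cofactor_off),
        strand = "+", role = c("pair_anchor", "pair_cofactor"))
    }
    for (pl in config$planted) {
      for (k in seq_len(pl$copies %||% 1L)) {
        word <- sample_motif_word(pl$motif)
        s <- place(length(word))
        chars[(s + 1L):(s + length(word))] <- word
        occupied <- c(occupied, (s + 1L):(s + length(word)))
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = ids[i], motif = pl$motif$name, start = s,
          strand = "+", role = "single")
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(seq_id = character(0), motif = character(0),
               start = integer(0), strand = character(0), role = character(0))
  rownames(truth) <- NULL
  list(sequences = setNames(seqs, ids), truth = truth)
}

#' Simulation config for paired two-tissue expression matrices
#'
#' @param n_genes total genes.
#' @param n_samples samples per tissue (matched sample ids across tissues).
#' @param modules data.frame with columns \code{size}, \code{loading},
#'   \code{shared} (logical): latent-factor modules. Shared modules use one
#'   factor realization per sample index in both tissues; non-shared modules
#'   are driven only in tissue A and are pure noise in tissue B.
#' @param noise_sd residual standard deviation (expression units).
#' @param seed integer seed.
#' @return validated list of class \code{expr_sim_config}.
#' @export
expr_sim_config <- function(n_genes, n_samples, modules, noise_sd = 1,
                            seed = 1L) {
  modules <- as.data.frame(modules)
  stopifnot(all(c("size", "loading", "shared") %in% names(modules)),
            sum(modules$size) <= n_genes, noise_sd >= 0, n_samples >= 2)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples), modules = modules,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Generate paired two-tissue expression matrices with planted modules
#'
#' Gene g in module m has expression \code{loading * f_m(sample) + noise},
#' with factor scores f drawn N(0,1) per sample; genes outside any module are
#' pure noise. Tissue A realizes every module; tissue B realizes only shared
#' modules (non-shared module genes are noise in B).
#'
#' @param config an \code{\link{expr_sim_config}}.
#' @return list with matrices \code{tissueA}, \code{tissueB} (genes x
#'   samples, dimnames set) and \code{truth} (data.frame \code{gene_id},
#'   \code{module} 0 = none, \code{shared}).
#' @export
gen_two_tissue_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples
  genes <- sprintf("gene_%05d", seq_len(ng))
  samples <- sprintf("sample_%03d", seq_len(ns))
  mods <- config$modules
  module_of <- integer(ng)
  pos <- 0L
  for (m in seq_len(nrow(mods))) {
    module_of[(pos + 1L):(pos + mods$size[m])] <- m
    pos <- pos + mods$size[m]
  }
  A <- matrix(rnorm(ng * ns, sd = config$noise_sd), ng, ns,
              dimnames = list(genes, samples))
  B <- matrix(rnorm(ng * ns, sd = config$noise_sd), ng, ns,
              dimnames = list(genes, samples))
  for (m in seq_len(nrow(mods))) {
    g <- which(module_of == m)
    fA <- rnorm(ns)
    A[g, ] <- A[g, ] + mods$loading[m] * rep(fA, each = length(g))
    if (isTRUE(mods$shared[m]))
      B[g, ] <- B[g, ] + mods$loading[m] * rep(fA, each = length(g))
  }
  truth <- data.frame(gene_id = genes, module = module_of,
                      shared = ifelse(module_of > 0,
                                      mods$shared[pmax(module_of, 1)], NA))
  list(tissueA = A, tissueB = B, truth = truth)
}

#' Simulation config for differential-expression gene lists
#'
#' @param universe_size number of genes in the tested universe.
#' @param list_sizes named integer vector of DE-list sizes per contrast.
#' @param overlaps data.frame with columns \code{a}, \code{b} (list names)
#'   and \code{k} (exact pairwise overlap). Overlap gene sets for different
#'   pairs are kept disjoint, so each overlap gene belongs to exactly the two
#'   named lists; an overlap system that cannot be realized that way is
#'   rejected as infeasible.
#' @param rho target Pearson correlation of log2 fold changes for co-listed
#'   genes (|rho| <= 1).
#' @param seed integer seed.
#' @return validated list of class \code{list_sim_config}.
#' @export
list_sim_config <- function(universe_size, list_sizes, overlaps = NULL,
                            rho = 0, seed = 1L) {
  stopifnot(abs(rho) <= 1, universe_size >= sum(list_sizes))
  if (!is.null(overlaps)) {
    overlaps <- as.data.frame(overlaps)
    stopifnot(all(c("a", "b", "k") %in% names(overlaps)))
    for (i in seq_len(nrow(overlaps)))
      if (overlaps$k[i] > min(list_sizes[[overlaps$a[i]]],
                              list_sizes[[overlaps$b[i]]]))
        stop("overlap exceeds a list size")
    per_list <- tapply(c(overlaps$k, overlaps$k), c(overlaps$a, overlaps$b), sum)
    if (any(per_list > list_sizes[names(per_list)]))
      stop("infeasible overlap system: pairwise overlaps exceed a list size")
  }
  structure(list(universe_size = as.integer(universe_size),
                 list_sizes = list_sizes, overlaps = overlaps, rho = rho,
                 seed = as.integer(seed)),
            class = "list_sim_config")
}

#' Generate differential-expression tables with exact list overlaps
#'
#' Constructs one DE table per contrast over a shared gene universe such that
#' the FDR < 0.1 lists have exactly the configured sizes and pairwise
#' overlaps, and the log2 fold changes of co-listed genes are drawn from a
#' bivariate normal with the configured correlation.
#'
#' @param config a \code{\link{list_sim_config}}.
#' @return list with \code{tables} (named list of data.frames: \code{gene_id},
#'   \code{log2fc}, \code{pvalue}, \code{fdr}, \code{direction}),
#'   \code{lists} (named list of DE gene-id vectors), and \code{universe}.
#' @export
gen_de_tables <- function(config) {
  stopifnot(inherits(config, "list_sim_config"))
  set.seed(config$seed)
  N <- config$universe_size
  genes <- sprintf("gene_%05d", seq_len(N))
  list_names <- names(config$list_sizes)
  members <- setNames(vector("list", length(list_names)), list_names)
  for (nm in list_names) members[[nm]] <- character(0)
  nxt <- 1L
  take <- function(k) {
    if (nxt + k - 1L > N) stop("universe too small for the overlap system")
    out <- genes[nxt:(nxt + k - 1L)]
    nxt <<- nxt + k
    out
  }
  fc <- lapply(setNames(list_names, list_names),
               function(nm) setNames(numeric(0), character(0)))
  ov <- config$overlaps
  if (!is.null(ov)) {
    for (i in seq_len(nrow(ov))) {
      if (ov$k[i] == 0) next
      g <- take(ov$k[i])
      members[[ov$a[i]]] <- c(members[[ov$a[i]]], g)
      members[[ov$b[i]]] <- c(members[[ov$b[i]]], g)
      z1 <- rnorm(ov$k[i]); z2 <- rnorm(ov$k[i])
      fa <- z1
      fb <- config$rho * z1 + sqrt(1 - config$rho^2) * z2
      fc[[ov$a[i]]][g] <- fa
      fc[[ov$b[i]]][g] <- fb
    }
  }
  for (nm in list_names) {
    need <- config$list_sizes[[nm]] - length(members[[nm]])
    if (need < 0) stop("internal: list overfilled")
    if (need > 0) {
      g <- take(need)
      members[[nm]] <- c(members[[nm]], g)
      fc[[nm]][g] <- rnorm(need)
    }
  }
  tables <- lapply(setNames(list_names, list_names), function(nm) {
    in_list <- genes %in% members[[nm]]
    lfc <- rnorm(N, sd = 0.1)
    lfc[in_list] <- fc[[nm]][genes[in_list]]
    # listed genes must have nonzero fc so direction is defined
    lfc[in_list & lfc == 0] <- 1e-6
    p <- ifelse(in_list, runif(N, 0, 2e-3), runif(N, 0.05, 1))
    q <- ifelse(in_list, runif(N, 0, 0.099), runif(N, 0.3, 1))
    data.frame(gene_id = genes, log2fc = lfc, pvalue = p, fdr = q,
               direction = ifelse(lfc >= 0, "up", "down"))
  })
  list(tables = tables, lists = lapply(members, sort), universe = genes)
}
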