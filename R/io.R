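# Readers and writers for the plain-text formats the pipeline consumes and
# emits. BED is 0-based half-open; GFF3 coordinates are converted from
# 1-based inclusive on read.

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning/accepting named character vectors.
#'
#' @param path file path.
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param sequences named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write BED6
#'
#' @param path file path (tab-separated, 3-6 columns, no header).
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{name},
#'   \code{score}, \code{strand} (missing columns filled with ".", 0).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed BED record at line ", which(nf < 3)[1], ": fewer than 3 fields")
  get <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i) p[i] else default, character(1))
  out <- data.frame(chrom = get(1, NA_character_),
                    start = as.integer(get(2, NA_character_)),
                    end = as.integer(get(3, NA_character_)),
                    name = get(4, "."),
                    score = suppressWarnings(as.numeric(get(5, "0"))),
                    strand = get(6, "."))
  bad <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end)
  if (length(bad))
    stop("invalid BED coordinates at line ", bad[1],
         " (need integer start < end)")
  out
}

#' @param bed data.frame with at least \code{chrom}, \code{start}, \code{end}.
#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(bed$start < bed$end))
  out <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                    name = bed$name %||% ".",
                    score = bed$score %||% 0,
                    strand = bed$strand %||% ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts records of the requested feature type into the gene-annotation
#' data.frame the interval operations expect (coordinates converted to
#' 0-based half-open).
#'
#' @param path GFF3 file.
#' @param feature_type feature to keep (default "gene").
#' @return data.frame \code{gene_id} (from the ID attribute), \code{chrom},
#'   \code{start}, \code{end}, \code{strand}.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9))
    stop("malformed GFF3 record at line ", which(keep)[which(nf != 9)[1]],
         ": expected 9 fields")
  type <- vapply(parts, `[`, character(1), 3L)
  parts <- parts[type == feature_type]
  if (!length(parts))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  attr_id <- vapply(parts, function(p) {
    m <- regmatches(p[9], regexec("(?:^|;)ID=([^;]+)", p[9]))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }, character(1))
  start1 <- as.integer(vapply(parts, `[`, character(1), 4L))
  end1 <- as.integer(vapply(parts, `[`, character(1), 5L))
  if (any(is.na(start1) | is.na(end1) | start1 > end1))
    stop("invalid GFF3 coordinates (need integer start <= end)")
  data.frame(gene_id = attr_id,
             chrom = vapply(parts, `[`, character(1), 1L),
             start = start1 - 1L, end = end1,
             strand = vapply(parts, `[`, character(1), 7L))
}

#' Read a TSV numeric matrix (first column = row ids, header = column ids)
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Write a numeric matrix as TSV (row ids in first column)
#' @param m matrix with dimnames.
#' @param path file path.
#' @param id_col header for the id column.
#' @export
write_tsv_matrix <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Requires columns \code{gene_id}, \code{log2fc}, \code{pvalue},
#' \code{fdr}; a \code{direction} column is derived from the fold-change
#' sign if absent.
#'
#' @param path TSV file with header.
#' @return data.frame with the four required columns plus \code{direction}.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  required <- c("gene_id", "log2fc", "pvalue", "fdr")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("DE table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("DE table has duplicate gene_id rows")
  if (is.null(df$direction))
    df$direction <- ifelse(df$log2fc >= 0, "up", "down")
  df
}

#' Read a motif manifest
#'
#' TSV with header columns \code{name} and \code{consensus} (IUPAC string)
#' or \code{matrix} (path, relative to the manifest, of a MEME-minimal
#' matrix file).
#'
#' @param path manifest file.
#' @param pseudocount,background passed to the motif constructors.
#' @return named list of \code{motif} objects.
#' @export
read_motif_manifest <- function(path, pseudocount = 0.01,
                                background = rep(0.25, 4)) {
  df <- read.delim(path, check.names = FALSE)
  stopifnot("name" %in% names(df))
  out <- list()
  for (i in seq_len(nrow(df))) {
    if (!is.null(df$consensus) && !is.na(df$consensus[i]) &&
        nzchar(df$consensus[i])) {
      out[[df$name[i]]] <- iupac_to_pwm(df$consensus[i], name = df$name[i],
                                        pseudocount = pseudocount,
                                        background = background)
    } else if (!is.null(df$matrix) && nzchar(df$matrix[i])) {
      mpath <- file.path(dirname(path), df$matrix[i])
      out[[df$name[i]]] <- read_meme_minimal(mpath, name = df$name[i],
                                             pseudocount = pseudocount,
                                             background = background)
    } else {
      stop("manifest row ", i, " has neither consensus nor matrix")
    }
  }
  out
}

#' Read a single motif from a MEME-minimal motif file
#'
#' Parses the first MOTIF block's letter-probability matrix.
#'
#' @param path MEME-minimal file.
#' @param name motif name override (default: name in the file).
#' @inheritParams read_motif_manifest
#' @return a \code{motif} object.
#' @export
read_meme_minimal <- function(path, name = NULL, pseudocount = 0.01,
                              background = rep(0.25, 4)) {
  lines <- readLines(path)
  mi <- grep("^MOTIF", lines)
  if (!length(mi)) stop("no MOTIF block in ", path)
  header <- strsplit(trimws(lines[mi[1]]), "\\s+")[[1]]
  fname <- if (length(header) >= 2) header[2] else "motif"
  li <- grep("^letter-probability matrix", lines)
  li <- li[li > mi[1]][1]
  if (is.na(li)) stop("no letter-probability matrix in ", path)
  rows <- list()
  for (j in (li + 1):length(lines)) {
    ln <- trimws(lines[j])
    if (!nzchar(ln) || grepl("^(MOTIF|URL)", ln)) break
    rows[[length(rows) + 1L]] <- as.numeric(strsplit(ln, "\\s+")[[1]])
  }
  probs <- t(do.call(rbind, rows))   # 4 x w, rows A C G T
  build_pwm(probs, name = name %||% fname, pseudocount = pseudocount,
            background = background)
}

#' Write motif sites as BED6 (score column = log-odds)
#'
#' @param sites data.frame from \code{\link{scan_motif}}.
#' @param path file path.
#' @export
write_sites_bed <- function(sites, path) {
  write_bed(data.frame(chrom = sites$seq_id, start = sites$start,
                       end = sites$end, name = sites$motif,
                       score = round(sites$score, 4),
                       strand = sites$strand), path)
}
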