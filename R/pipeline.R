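# Orchestration: a run configuration with the pipeline's fixed constants as
# defaults, subcommand dispatch, and run metadata so every result is
# reproducible from the recorded seed and thresholds.

PIPELINE_DEFAULTS <- list(
  alpha = 1e-3,
  alphas = c(1e-2, 5e-3, 1e-3, 5e-4, 1e-4),
  spacing_cutoff = 25L,
  n_shuffles = 50L,
  window = 10000L,
  min_reads = 5,
  fdr = 0.1,
  beta = 6,
  consensus = 0.7,
  min_r = 0.5,
  min_module_size = 30,
  min_cluster_size = 3,
  seed = 1L
)

#' Read a pipeline run configuration (YAML or JSON)
#'
#' Unspecified thresholds fall back to the pipeline defaults (25 bp spacing
#' cutoff, 50 shuffles, 10 kb window, > 5 reads, FDR 0.1, match alpha 1e-3).
#'
#' @param path config file; format chosen by extension (.yaml/.yml needs the
#'   yaml package, .json uses jsonlite).
#' @return named list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  run_config(cfg)
}

#' Build a validated run configuration from a named list
#' @param cfg named list; see \code{\link{run_pipeline}} for the keys each
#'   subcommand uses.
#' @return list of class \code{run_config} with defaults filled in.
#' @export
run_config <- function(cfg = list()) {
  out <- utils::modifyList(PIPELINE_DEFAULTS, cfg)
  stopifnot(out$n_shuffles >= 1, out$window >= 0, out$spacing_cutoff >= 0)
  structure(out, class = "run_config")
}

write_run_metadata <- function(out_dir, config, extra = list()) {
  inputs <- config[grepl("_path$", names(config))]
  digests <- lapply(inputs, function(p)
    if (is.character(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL)
  meta <- c(list(package = "cisreg",
                 version = as.character(utils::packageVersion("cisreg")),
                 subcommand = config$subcommand,
                 seed = config$seed,
                 thresholds = config[c("alpha", "spacing_cutoff", "n_shuffles",
                                       "window", "min_reads", "fdr", "beta",
                                       "consensus", "min_r")],
                 input_digests = digests),
            extra)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Subcommands (selected by \code{config$subcommand}):
#' \describe{
#'   \item{simulate}{plant motifs/pairs in synthetic peaks. Keys:
#'     \code{manifest_path}, \code{n_peaks}, \code{length_range}, \code{gc},
#'     \code{planted} (names + copies), \code{pair} (anchor, cofactor,
#'     spacing, fraction). Writes \code{peaks.fasta}, \code{truth.bed}.}
#'   \item{scan}{scan sequences with every manifest motif at \code{alpha}.
#'     Keys: \code{fasta_path}, \code{manifest_path}. Writes
#'     \code{sites.bed}.}
#'   \item{enrich}{peak-vs-background motif screen. Keys: \code{fasta_path},
#'     \code{manifest_path}, and either \code{background_path} or
#'     \code{genome_path} (background auto-sampled, one length-matched
#'     segment per peak). Writes \code{enrichment.tsv}.}
#'   \item{spacing}{spacing-constraint screen across \code{alphas}. Keys:
#'     \code{fasta_path}, \code{manifest_path}, \code{anchor},
#'     \code{cofactor}. Writes \code{spacing.tsv}.}
#'   \item{overlap}{DE-list overlap statistics. Keys: \code{de_a_path},
#'     \code{de_b_path}, \code{universe_path} (one id per line). Writes
#'     \code{overlap.tsv}.}
#'   \item{coexpr}{two-tissue module pipeline. Keys: \code{matrix_a_path},
#'     \code{matrix_b_path}. Writes \code{modules.tsv},
#'     \code{module_stats.json}.}
#'   \item{report}{collate \code{run_metadata.json} files under
#'     \code{config$runs_dir} into \code{report.json}.}
#' }
#' Every run writes \code{run_metadata.json} (version, seed, thresholds,
#' input digests). Outputs are deterministic given config + seed.
#'
#' @param config a \code{\link{run_config}} (or plain list).
#' @param out_dir output directory (created; must not contain prior outputs
#'   of the same stage).
#' @return invisible list of written file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- run_config(as.list(config))
  if (is.null(config$subcommand)) stop("config error: no subcommand")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- switch(
    config$subcommand,
    simulate = stage_simulate(config, out_dir),
    scan = stage_scan(config, out_dir),
    enrich = stage_enrich(config, out_dir),
    spacing = stage_spacing(config, out_dir),
    overlap = stage_overlap(config, out_dir),
    coexpr = stage_coexpr(config, out_dir),
    report = stage_report(config, out_dir),
    stop("config error: unknown subcommand '", config$subcommand, "'")
  )
  write_run_metadata(out_dir, config, extra = list(outputs = written))
  invisible(written)
}

stage_simulate <- function(config, out_dir) {
  motifs <- read_motif_manifest(config$manifest_path)
  planted <- lapply(config$planted %||% list(), function(p)
    list(motif = motifs[[p$name]], copies = p$copies %||% 1L))
  pair <- NULL
  if (!is.null(config$pair))
    pair <- list(anchor = motifs[[config$pair$anchor]],
                 cofactor = motifs[[config$pair$cofactor]],
                 spacing = config$pair$spacing,
                 fraction = config$pair$fraction %||% 1)
  sim <- gen_peaks(seq_sim_config(
    n_peaks = config$n_peaks %||% 200L,
    length_range = config$length_range %||% c(300L, 800L),
    gc = config$gc %||% 0.5, planted = planted, pair_spec = pair,
    seed = config$seed))
  fa <- file.path(out_dir, "peaks.fasta")
  write_fasta(sim$sequences, fa)
  bed <- file.path(out_dir, "truth.bed")
  widths <- vapply(sim$truth$motif, function(mn)
    if (mn %in% names(motifs)) motifs[[mn]]$width else 1L, integer(1))
  write_bed(data.frame(chrom = sim$truth$seq_id, start = sim$truth$start,
                       end = sim$truth$start + widths,
                       name = sim$truth$motif, score = 0,
                       strand = sim$truth$strand), bed)
  message("simulate: ", length(sim$sequences), " sequences, ",
          nrow(sim$truth), " planted sites")
  list(fasta = fa, truth = bed)
}

stage_scan <- function(config, out_dir) {
  seqs <- read_fasta(config$fasta_path)
  motifs <- read_motif_manifest(config$manifest_path)
  sites <- do.call(rbind, lapply(motifs, function(m)
    scan_motif(seqs, m, alpha = config$alpha)))
  path <- file.path(out_dir, "sites.bed")
  write_sites_bed(sites, path)
  message("scan: ", length(seqs), " sequences, ", nrow(sites), " sites (",
          length(motifs), " motifs, alpha ", config$alpha, ")")
  list(sites = path)
}

stage_enrich <- function(config, out_dir) {
  peaks <- read_fasta(config$fasta_path)
  motifs <- read_motif_manifest(config$manifest_path)
  if (!is.null(config$background_path)) {
    bg <- read_fasta(config$background_path)
  } else if (!is.null(config$genome_path)) {
    genome <- Biostrings::readDNAStringSet(config$genome_path)
    bg <- sample_matched_background(genome, lengths = nchar(peaks),
                                    seed = config$seed)$sequences
  } else stop("config error: enrich needs background_path or genome_path")
  res <- enrichment_screen(peaks, bg, motifs, alpha = config$alpha)
  path <- file.path(out_dir, "enrichment.tsv")
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("enrich: ", length(peaks), " peaks vs ", length(bg),
          " background sequences, top motif ", res$motif[1])
  list(enrichment = path)
}

stage_spacing <- function(config, out_dir) {
  seqs <- read_fasta(config$fasta_path)
  motifs <- read_motif_manifest(config$manifest_path)
  res <- spacing_threshold_screen(
    seqs, motifs[[config$anchor]], motifs[[config$cofactor]],
    alphas = config$alphas, cutoff = config$spacing_cutoff,
    n_shuffles = config$n_shuffles, seed = config$seed)
  path <- file.path(out_dir, "spacing.tsv")
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("spacing: ", nrow(res), " thresholds, min p ",
          format(min(res$p), digits = 3))
  list(spacing = path)
}

stage_overlap <- function(config, out_dir) {
  ta <- read_de_table(config$de_a_path)
  tb <- read_de_table(config$de_b_path)
  universe <- readLines(config$universe_path)
  la <- ta$gene_id[ta$fdr < config$fdr]
  lb <- tb$gene_id[tb$fdr < config$fdr]
  ov <- overlap_test(la, lb, universe)
  conc <- if (ov$k >= 3) foldchange_concordance(ta, tb, ov$genes) else
    list(r = NA_real_, p = NA_real_, n = ov$k)
  res <- data.frame(n_a = ov$n, n_b = ov$K, overlap = ov$k, N = ov$N,
                    fold = ov$fold, p_enrich = ov$p_enrich,
                    p_deplete = ov$p_deplete, r_fc = conc$r, p_fc = conc$p)
  path <- file.path(out_dir, "overlap.tsv")
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("overlap: ", ov$k, " shared of ", ov$n, " x ", ov$K,
          ", fold ", round(ov$fold, 2))
  list(overlap = path)
}

stage_coexpr <- function(config, out_dir) {
  m_a <- read_tsv_matrix(config$matrix_a_path)
  m_b <- read_tsv_matrix(config$matrix_b_path)
  res <- coexpression_pipeline(
    m_a, m_b, beta = config$beta, min_module_size = config$min_module_size,
    cut_height = config$cut_height %||% 0.95, consensus = config$consensus,
    min_r = config$min_r, min_size = config$min_cluster_size,
    seed = config$seed)
  rows <- list()
  for (stage in c("wgcna", "tight", "coherent", "specific")) {
    ms <- res[[stage]]
    for (nm in names(ms$modules))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = ms$modules[[nm]], module = nm, stage = ms$stage)
  }
  tab <- do.call(rbind, rows)
  path <- file.path(out_dir, "modules.tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  stats <- lapply(res$coherent$modules, function(g) list(
    size = length(g),
    mean_r_a = mean_pairwise_r(res$normalized_a, g),
    mean_r_b = mean_pairwise_r(res$normalized_b, g)))
  spath <- file.path(out_dir, "module_stats.json")
  jsonlite::write_json(stats, spath, auto_unbox = TRUE, digits = NA)
  message("coexpr: ", length(res$wgcna$modules), " modules, ",
          length(res$tight$modules), " tight, ",
          length(res$coherent$modules), " coherent")
  list(modules = path, stats = spath)
}

stage_report <- function(config, out_dir) {
  files <- list.files(config$runs_dir, "run_metadata.json", recursive = TRUE,
                      full.names = TRUE)
  meta <- lapply(files, jsonlite::read_json)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  list(report = path)
}

#' Command-line entry point
#'
#' \code{cisreg_main(c("<subcommand>", "--config", "cfg.yaml", "--out",
#' "dir", "--seed", "7"))}; flag values override config-file keys. Exit
#' codes (when \code{exit = TRUE}): 0 success, 2 configuration error, 3
#' data error.
#'
#' @param args character vector (default: the process command line).
#' @param exit call \code{quit()} with the exit code instead of returning it.
#' @return exit code, invisibly (when \code{exit = FALSE}).
#' @export
cisreg_main <- function(args = commandArgs(trailingOnly = TRUE),
                        exit = FALSE) {
  code <- tryCatch({
    if (!length(args)) stop("config error: usage: cisreg <subcommand> --config <file> --out <dir> [--seed <int>]")
    sub <- args[1]
    getopt <- function(flag) {
      i <- which(args == flag)
      if (length(i)) args[i[1] + 1] else NULL
    }
    cfg <- if (!is.null(getopt("--config")))
      as.list(read_run_config(getopt("--config"))) else list()
    cfg$subcommand <- sub
    if (!is.null(getopt("--seed"))) cfg$seed <- as.integer(getopt("--seed"))
    out <- getopt("--out") %||% "cisreg_run"
    run_pipeline(cfg, out)
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config error", conditionMessage(e))) 2L else 3L
  })
  if (exit) quit(status = code, save = "no")
  invisible(code)
}
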