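#' Run the full SV-calling pipeline on precomputed inputs
#'
#' Parses the coassembly graph and the per-sample alignments, builds the
#' collapsed graph, computes floored/normalized coverage and log-fold-change
#' tables, calls SVs, and writes the output set: the SV call table,
#' coverage/lfc dumps, one Bandage color CSV per step pair, a JSON run
#' summary and a manifest sufficient to reproduce the run.
#'
#' @param gfa Path to the GFA 1.0 coassembly graph.
#' @param gafs One GAF path per sample, in series order (>= 2).
#' @param out_dir Output directory (created if needed).
#' @param sample_ids Sample names (default `s1..sN`).
#' @param log_base,floor_value,normalization_mode,sd_mode See
#'   [series_config()].
#' @param min_mapq,min_length Alignment filters (defaults keep everything).
#' @param pairing Optional complementary-pair map (see [collapse_graph()]).
#' @param seed Recorded in the manifest; the calling path itself is
#'   deterministic.
#' @return Invisibly, a list with `calls`, `coverage`, `lfc`, `graph`,
#'   `summary` and `paths` (the files written).
#' @export
run_call <- function(gfa, gafs, out_dir,
                     sample_ids = NULL,
                     log_base = 2, floor_value = 1,
                     normalization_mode = "median_ratio",
                     sd_mode = "population",
                     min_mapq = 0, min_length = 0,
                     pairing = NULL, seed = 0) {
  gafs <- as.character(gafs)
  if (length(gafs) < 2) {
    stop("usage error: a series needs at least 2 samples (got ",
         length(gafs), " GAF file(s); no step pairs to compare)")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_along(gafs))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- series_config(sample_ids, log_base = log_base,
                       floor_value = floor_value,
                       normalization_mode = normalization_mode,
                       sd_mode = sd_mode)
  graph <- collapse_graph(parse_gfa(gfa), pairing = pairing)
  cov <- coverage_table(gafs, graph, cfg, min_mapq = min_mapq,
                        min_length = min_length)
  lfc <- lfc_table(cov)
  calls <- call_all(graph, lfc)

  paths <- list(
    sv_table = file.path(out_dir, "sv_calls.tsv"),
    node_coverage = file.path(out_dir, "node_coverage.tsv"),
    node_lfc = file.path(out_dir, "node_lfc.tsv"),
    edge_lfc = file.path(out_dir, "edge_lfc.tsv"),
    summary = file.path(out_dir, "summary.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_sv_table(calls, paths$sv_table)
  write_matrix_tsv(cov$node_cov, paths$node_coverage, id_col = "node")
  write_matrix_tsv(lfc$node_lfc, paths$node_lfc, id_col = "node")
  write_matrix_tsv(lfc$edge_lfc, paths$edge_lfc, id_col = "edge")
  bandage <- character(nrow(lfc$node_lfc))
  for (p in seq_len(nrow(lfc$node_lfc))) {
    bandage[p] <- file.path(out_dir, sprintf("bandage_step_%02d.csv", p))
    write_bandage_csv(graph, lfc, p, bandage[p])
  }
  paths$bandage <- bandage

  counts <- table(calls$sv_type)
  summary <- list(
    n_samples = length(gafs),
    n_step_pairs = nrow(lfc$node_lfc),
    n_nodes = nrow(graph$nodes),
    n_edges = nrow(graph$edges),
    bp_totals = as.numeric(cov$config$bp_totals),
    calls_by_type = as.list(counts),
    calls_by_step = as.list(table(calls$step_pair)),
    motif_instances = attr(calls, "motif_instances")
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    tool = "graphsv",
    version = as.character(utils::packageVersion("graphsv")),
    inputs = list(gfa = normalizePath(gfa), gafs = normalizePath(gafs)),
    sample_ids = sample_ids,
    options = list(log_base = log_base, floor_value = floor_value,
                   normalization_mode = normalization_mode,
                   sd_mode = sd_mode, min_mapq = min_mapq,
                   min_length = min_length),
    seed = seed,
    out_dir = normalizePath(out_dir)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(calls = calls, coverage = cov, lfc = lfc, graph = graph,
                 summary = summary, paths = paths))
}

#' Assemble pooled reads and align each sample back to the graph
#'
#' External-tool path of the pipeline: pools the reads of all samples into
#' one metaFlye coassembly (with haplotypes kept, so strain variation stays
#' in the graph) and aligns each sample separately with minigraph. Both
#' binaries must be discoverable on PATH; they are invoked, never
#' reimplemented. The exact command lines are recorded in the returned
#' manifest fragment.
#'
#' @param reads One FASTQ/FASTA path per sample, in series order.
#' @param out_dir Working/output directory.
#' @param read_type metaFlye read type, `"nano-raw"` or `"pacbio-hifi"`.
#' @param threads Threads for both tools.
#' @return List with `gfa`, `gafs` (paths for [run_call()]) and `commands`
#'   (the verbatim command lines run).
#' @export
assemble_and_align <- function(reads, out_dir,
                               read_type = c("nano-raw", "pacbio-hifi"),
                               threads = 1) {
  read_type <- match.arg(read_type)
  if (length(reads) < 2) stop("usage error: a series needs at least 2 samples")
  missing_files <- reads[!file.exists(reads)]
  if (length(missing_files) > 0) {
    stop("read file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  flye <- Sys.which("flye")
  minigraph <- Sys.which("minigraph")
  if (flye == "" || minigraph == "") {
    stop("external binaries required for the raw-read path are missing ",
         "from PATH (flye: ", if (flye == "") "NOT FOUND" else flye,
         "; minigraph: ",
         if (minigraph == "") "NOT FOUND" else minigraph, "). ",
         "Install metaFlye and minigraph, or supply a precomputed graph ",
         "(--graph) plus one GAF per sample (--aln) instead.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  asm_dir <- file.path(out_dir, "assembly")
  type_flag <- if (read_type == "pacbio-hifi") "--pacbio-hifi" else
    "--nano-raw"
  asm_cmd <- paste(c(shQuote(flye), "--meta", "--keep-haplotypes",
                     type_flag, shQuote(reads), "--threads", threads,
                     "--out-dir", shQuote(asm_dir)), collapse = " ")
  status <- system(asm_cmd)
  if (status != 0) stop("metaFlye failed (exit ", status, "): ", asm_cmd)
  gfa <- file.path(asm_dir, "assembly_graph.gfa")
  if (!file.exists(gfa)) stop("metaFlye did not produce ", gfa)
  gafs <- file.path(out_dir, sprintf("sample_%02d.gaf", seq_along(reads)))
  aln_cmds <- character(length(reads))
  for (i in seq_along(reads)) {
    aln_cmds[i] <- paste(shQuote(minigraph), "-c", "-t", threads,
                         shQuote(gfa), shQuote(reads[i]), ">",
                         shQuote(gafs[i]))
    status <- system(aln_cmds[i])
    if (status != 0) {
      stop("minigraph failed (exit ", status, "): ", aln_cmds[i])
    }
  }
  list(gfa = gfa, gafs = gafs, commands = c(asm_cmd, aln_cmds))
}
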